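#' @keywords internal
chemtools_script <- function() {
  path <- system.file("python", "chemtools.py", package = "pfascluster")
  if (!nzchar(path)) {
    # devtools::load_all() keeps inst/ unexpanded
    path <- system.file("inst", "python", "chemtools.py", package = "pfascluster")
  }
  if (!nzchar(path)) stop("chemtools.py helper not found in installed package")
  path
}

python_binary <- function() {
  bin <- getOption("pfascluster.python", Sys.which("python"))
  if (!nzchar(bin)) stop("no 'python' executable on PATH; RDKit bridge unavailable")
  bin
}

#' Run a batch of chemistry/embedding operations through the Python helper
#'
#' One subprocess call executes a whole list of operations (SMILES
#' canonicalization, Morgan fingerprints, SMARTS matching, FMCS, t-SNE), so
#' the RDKit import cost is paid once per batch rather than once per molecule.
#'
#' @param ops list of operation objects, each a named list with an `op` field.
#' @return list of result objects, same order as `ops`.
#' @keywords internal
chem_bridge <- function(ops) {
  stopifnot(is.list(ops), length(ops) > 0L)
  req <- tempfile(fileext = ".json")
  res <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, res)), add = TRUE)
  jsonlite::write_json(ops, req, auto_unbox = TRUE, digits = NA, null = "null")
  status <- suppressWarnings(system2(
    python_binary(), c(chemtools_script(), req, res),
    stdout = FALSE, stderr = FALSE
  ))
  if (!identical(status, 0L) || !file.exists(res)) {
    stop("python chemistry helper failed (exit status ", status, ")")
  }
  out <- jsonlite::read_json(res, simplifyVector = FALSE)
  for (k in seq_along(out)) {
    if (!is.null(out[[k]]$error)) {
      stop("chemtools op '", ops[[k]]$op, "' failed: ", out[[k]]$error)
    }
  }
  out
}

# single-op convenience
chem_call <- function(op) chem_bridge(list(op))[[1L]]
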