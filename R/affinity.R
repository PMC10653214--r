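#' Read a docking-affinity table
#'
#' Affinities come from external docking runs (e.g. AutoDock) and enter this
#' workflow as plain numbers: a CSV with `id`, `target`, `affinity`
#' (kcal/mol; more negative = stronger binding). Duplicate `(id, target)`
#' keys resolve last-wins with a warning.
#'
#' @param path CSV file path.
#' @return an `affinity_table`: data.frame `id`, `target`, `affinity` with
#'   one row per `(id, target)` key.
#' @export
read_affinity_table <- function(path) {
  if (!file.exists(path)) stop("affinity table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  for (col in c("id", "target", "affinity")) {
    if (!col %in% names(raw)) stop("missing column '", col, "' in ", path)
  }
  aff <- suppressWarnings(as.numeric(raw$affinity))
  bad <- which(is.na(aff) | !is.finite(aff))
  if (length(bad) > 0L) {
    stop("non-numeric affinity at row(s) ", paste(bad, collapse = ", "),
         " of ", path)
  }
  tab <- data.frame(id = raw$id, target = raw$target, affinity = aff,
                    stringsAsFactors = FALSE)
  key <- paste(tab$id, tab$target, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate (id, target) affinity key(s); ",
            "keeping the last occurrence")
    tab <- tab[!duplicated(key, fromLast = TRUE), , drop = FALSE]
    rownames(tab) <- NULL
  }
  class(tab) <- c("affinity_table", "data.frame")
  tab
}

#' Write an affinity table
#' @param table an `affinity_table`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_affinity_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Summarize affinities against a bioactivity threshold
#'
#' Computes, for one target, the fraction of molecules binding *stronger*
#' than a threshold — read strictly: `affinity < threshold`, since more
#' negative is stronger, so entries exactly at the threshold do not count —
#' together with the arithmetic mean affinity.
#'
#' @param table an `affinity_table`.
#' @param target target name to summarize.
#' @param threshold kcal/mol cutoff (default -5).
#' @param ids optional molecule id subset; ids without an affinity entry are
#'   skipped and counted in `n_missing`.
#' @return list with `fraction_stronger`, `mean`, `n`, `n_missing`.
#' @export
affinity_summary <- function(table, target, threshold = -5, ids = NULL) {
  rows <- table[table$target == target, , drop = FALSE]
  n_missing <- 0L
  if (!is.null(ids)) {
    n_missing <- sum(!(ids %in% rows$id))
    rows <- rows[rows$id %in% ids, , drop = FALSE]
  }
  if (nrow(rows) == 0L) {
    stop("empty-selection error: no affinity entries for target '",
         target, "'")
  }
  list(
    fraction_stronger = mean(rows$affinity < threshold),
    mean = mean(rows$affinity),
    n = nrow(rows),
    n_missing = n_missing
  )
}
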