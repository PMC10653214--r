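CF_SMARTS <- "[#6][F]"
C3F6_SMARTS <- "[CX4]([F])([F])[CX4]([F])([F])[CX4][F]"

#' Normalize an activity label string
#'
#' Case-insensitive mapping: `active`/`1`/`true` to `"ACTIVE"`,
#' `inactive`/`0`/`false` to `"INACTIVE"`, empty/`na`/`unlabeled` (and `NA`)
#' to `"UNLABELED"` — the semi-supervised default.
#'
#' @param x character vector of raw label strings.
#' @return character vector over `{"ACTIVE","INACTIVE","UNLABELED"}`.
#' @export
normalize_label <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep("UNLABELED", length(lx))
  out[lx %in% c("active", "1", "true")] <- "ACTIVE"
  out[lx %in% c("inactive", "0", "false")] <- "INACTIVE"
  bad <- !(lx %in% c("active", "1", "true", "inactive", "0", "false",
                     "", "na", "unlabeled")) & !is.na(x)
  if (any(bad)) {
    stop("unrecognized activity label(s): ",
         paste(unique(lx[bad]), collapse = ", "))
  }
  out
}

#' Read a molecule table
#'
#' Reads a delimited text table of molecules with an id column, a SMILES
#' column and one or more per-target activity columns. SMILES are
#' canonicalized through RDKit on ingest; rows whose SMILES do not parse are
#' excluded and reported in the `rejects` attribute (row number + reason).
#' Duplicate canonical SMILES are reported (attribute `duplicate_smiles`) but
#' not removed.
#'
#' @param path CSV/TSV file path (delimiter inferred from extension, or set
#'   `sep`). A header row is required.
#' @param id_col,smiles_col column names for the molecule id and SMILES.
#' @param activity_cols character vector of activity column names (the
#'   biological targets). Default: every column other than id and SMILES.
#' @param sep field separator; default `","` (`"\t"` for `.tsv` files).
#' @return a `molecule_table`: data.frame with columns `id`, `smiles`
#'   (canonical), and one `"ACTIVE"/"INACTIVE"/"UNLABELED"` column per target,
#'   plus attributes `targets`, `rejects` (data.frame row/id/reason) and
#'   `duplicate_smiles`.
#' @export
read_molecule_table <- function(path, id_col = "id", smiles_col = "smiles",
                                activity_cols = NULL, sep = NULL) {
  if (!file.exists(path)) stop("molecule table not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  for (col in c(id_col, smiles_col)) {
    if (!col %in% names(raw)) stop("missing mandatory column '", col, "' in ", path)
  }
  if (is.null(activity_cols)) {
    activity_cols <- setdiff(names(raw), c(id_col, smiles_col))
  } else if (!all(activity_cols %in% names(raw))) {
    stop("missing activity column(s): ",
         paste(setdiff(activity_cols, names(raw)), collapse = ", "))
  }
  if (length(activity_cols) < 1L) stop("need at least one activity column")
  ids <- raw[[id_col]]
  if (anyDuplicated(ids)) {
    stop("duplicate molecule id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  canon <- chem_call(list(op = "canonicalize", smiles = as.list(raw[[smiles_col]])))
  valid <- unlist(canon$valid)
  rejects <- data.frame(
    row = which(!valid), id = ids[!valid],
    reason = rep("unparseable SMILES", sum(!valid)),
    stringsAsFactors = FALSE
  )
  keep <- which(valid)
  tab <- data.frame(
    id = ids[keep],
    smiles = unlist(lapply(canon$canonical[keep], identity)),
    stringsAsFactors = FALSE
  )
  for (col in activity_cols) tab[[col]] <- normalize_label(raw[[col]][keep])
  dup <- unique(tab$smiles[duplicated(tab$smiles)])
  structure(tab, targets = activity_cols, rejects = rejects,
            duplicate_smiles = dup, class = c("molecule_table", "data.frame"))
}

#' Write a molecule table
#'
#' Emits the CSV dialect [read_molecule_table()] reads, so write/read
#' round-trips to equal records (canonical-SMILES equality).
#'
#' @param records a `molecule_table` (or plain data.frame with `id`, `smiles`
#'   and activity columns).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_molecule_table <- function(records, path) {
  utils::write.csv(as.data.frame(records)[, , drop = FALSE], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Targets of a molecule table
#' @param records a `molecule_table`.
#' @return character vector of activity column names.
#' @export
molecule_targets <- function(records) {
  tg <- attr(records, "targets")
  if (is.null(tg)) setdiff(names(records), c("id", "smiles")) else tg
}

match_smarts_mask <- function(smiles, smarts) {
  if (length(smiles) == 0L) return(logical(0))
  res <- chem_call(list(op = "match", smiles = as.list(smiles), smarts = smarts))
  unname(unlist(res$match))
}

#' Filter for substances with at least one carbon-fluorine bond
#'
#' Membership rule for the broad "CF" PFAS dataset: keep molecules containing
#' at least one C-F bond, aromatic carbons included (SMARTS `[#6][F]`).
#' Order-preserving subset of the input; idempotent.
#'
#' @param records a `molecule_table`.
#' @return the retained rows, same class and attributes.
#' @export
filter_cf <- function(records) {
  mask <- match_smarts_mask(records$smiles, CF_SMARTS)
  subset_molecule_table(records, mask)
}

#' Filter for a perfluoroalkyl moiety of three or more carbons
#'
#' Membership rule for the narrow "C3F6" PFAS dataset: keep molecules with a
#' chain of >= 3 contiguous saturated carbons bearing only fluorine
#' substituents along the chain (SMARTS
#' `[CX4]([F])([F])[CX4]([F])([F])[CX4][F]`). Always a subset of
#' [filter_cf()]; idempotent. The native chain-walk route
#' [has_perfluoro_c3()] provides the independent check of this SMARTS
#' reading.
#'
#' @param records a `molecule_table`.
#' @return the retained rows, same class and attributes.
#' @export
filter_c3f6 <- function(records) {
  mask <- match_smarts_mask(records$smiles, C3F6_SMARTS)
  subset_molecule_table(records, mask)
}

subset_molecule_table <- function(records, mask) {
  stopifnot(length(mask) == nrow(records))
  out <- records[mask, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "targets") <- attr(records, "targets")
  class(out) <- class(records)
  out
}
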