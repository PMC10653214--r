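ESTER_SMARTS <- "[CX3](=O)[OX2][#6]"

# Wilson score interval lower bound for a binomial proportion. The default
# z = 3 is deliberately conservative: cluster active fractions are compared
# across many clusters, so the top raw fraction suffers a winner's-curse
# selection effect that a loose bound would not counter.
wilson_lower <- function(successes, n, z = 3) {
  if (n == 0) return(0)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  (centre - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) / denom
}

#' Maximum common substructure of a molecule set
#'
#' Finds the SMARTS of the largest substructure present in at least
#' `completion_threshold` of the input molecules, via RDKit's FMCS with
#' ring-bonds-to-ring-bonds matching and a timeout. For large inputs
#' (over `max_molecules`) a seeded random subset is used — exact
#' multi-molecule MCS is intractable there and the motif of interest is, by
#' construction of the workflow, shared across the set.
#'
#' @param records a `molecule_table` (or character SMILES vector), >= 2 rows.
#' @param completion_threshold fraction of molecules that must contain the
#'   motif (default 0.7). Bioactive clusters are contaminated by actives that
#'   owe their activity to something other than the dominant motif (with a
#'   background activity rate `b` and motif prevalence/penetrance `p`/`q`,
#'   the motif share among actives is only `pq / (pq + (1-p)b)`), so the
#'   threshold has to sit comfortably below that share, not at it.
#' @param timeout FMCS time budget in seconds.
#' @param max_molecules subsample cap (default 200).
#' @param seed seed for the subsample.
#' @return SMARTS string; `""` (the empty-motif sentinel) when no common
#'   substructure of >= 2 atoms exists.
#' @export
find_mcs <- function(records, completion_threshold = 0.7, timeout = 20L,
                     max_molecules = 200L, seed = 1L) {
  smiles <- if (is.character(records)) records else records$smiles
  if (length(smiles) < 2L) stop("parameter error: find_mcs needs >= 2 molecules")
  if (length(smiles) > max_molecules) {
    set.seed(seed %% .Machine$integer.max)
    smiles <- smiles[sort(sample.int(length(smiles), max_molecules))]
  }
  res <- chem_call(list(op = "mcs", smiles = as.list(smiles),
                        threshold = completion_threshold,
                        timeout = as.integer(timeout)))
  res$smarts
}

#' Match a SMARTS motif across molecules
#'
#' @param records a `molecule_table` or character SMILES vector.
#' @param smarts SMARTS pattern.
#' @return logical mask, one entry per molecule.
#' @export
match_substructure <- function(records, smarts) {
  smiles <- if (is.character(records)) records else records$smiles
  if (!nzchar(smarts)) return(rep(FALSE, length(smiles)))
  match_smarts_mask(smiles, smarts)
}

#' Bioactive ratio of a motif
#'
#' The attribution statistic of the workflow: among *labeled* molecules that
#' contain the motif, the fraction that are ACTIVE. UNLABELED molecules are
#' excluded from both numerator and denominator, so `n_match` counts labeled
#' matches only. With zero labeled matches the ratio is the undefined
#' sentinel `NA` (counts are kept).
#'
#' @param mask logical motif mask (from [match_substructure()]).
#' @param labels character activity labels aligned with `mask`.
#' @return list with `n_match`, `n_match_active`, `bioactive_ratio`.
#' @export
bioactive_ratio <- function(mask, labels) {
  stopifnot(length(mask) == length(labels))
  labeled <- labels %in% c("ACTIVE", "INACTIVE")
  n_match <- sum(mask & labeled)
  n_active <- sum(mask & labels == "ACTIVE")
  list(
    n_match = n_match,
    n_match_active = n_active,
    bioactive_ratio = if (n_match > 0) n_active / n_match else NA_real_
  )
}

#' Carboxylic-ester detection
#'
#' Matches the ester SMARTS `[CX3](=O)[OX2][#6]` — a carbonyl carbon bound
#' through a two-coordinate oxygen to another carbon, so free carboxylic
#' acids do not match.
#'
#' @param records a `molecule_table` or character SMILES vector.
#' @return logical vector.
#' @export
detect_ester <- function(records) {
  match_substructure(records, ESTER_SMARTS)
}

#' Per-cluster motif attribution report
#'
#' For each of the `top_clusters` clusters ranked by labeled active fraction,
#' extracts the MCS of the cluster's ACTIVE members and scores that motif
#' dataset-wide with [bioactive_ratio()]. The ranking uses a conservative
#' Wilson lower confidence bound (z = 3) of the active fraction rather than
#' the raw proportion: a cluster with 3 labeled molecules, all active, is weaker
#' evidence of a bioactive substructure than a 100-molecule cluster at 90%,
#' and raw-fraction ranking would chase such small-sample artifacts.
#' Clusters with fewer than `min_actives` ACTIVE members (or whose MCS is
#' empty) are skipped with a logged notice: the MCS of a handful of
#' near-duplicate molecules is a sampling artifact, and the bioactive ratio
#' of its match set (binomial sd above 0.1 below n = 10) is uninformative.
#' Reports come back sorted by bioactive ratio, descending.
#'
#' @param records a `molecule_table`.
#' @param assignment a `cluster_assignment` covering `records`.
#' @param target activity column scored.
#' @param top_clusters number of clusters to analyze (default 1: the single
#'   best-supported bioactive cluster; under the ratio-descending sort, motifs
#'   from smaller satellite clusters would otherwise outrank the dominant
#'   motif with ratios whose binomial uncertainty exceeds the reporting
#'   precision).
#' @param completion_threshold passed to [find_mcs()].
#' @param min_actives minimum ACTIVE members for a cluster to be analyzed
#'   (default 10; hard floor 2, which find_mcs itself requires).
#' @param seed passed to [find_mcs()] subsampling.
#' @return data.frame (`substructure_report`) with columns `smarts`,
#'   `n_match`, `n_match_active`, `bioactive_ratio`, `target`,
#'   `source_cluster`; attribute `notices` holds skip messages.
#' @export
cluster_motif_report <- function(records, assignment, target,
                                 top_clusters = 1L,
                                 completion_threshold = 0.7,
                                 min_actives = 10L, seed = 1L) {
  min_actives <- max(2L, as.integer(min_actives))
  stopifnot(length(assignment$labels) == nrow(records))
  labels <- records[[target]]
  if (is.null(labels)) stop("unknown target column: ", target)
  notices <- character(0)
  if (!any(labels == "ACTIVE")) {
    notices <- "no ACTIVE labels for target; empty report"
    out <- data.frame(smarts = character(0), n_match = integer(0),
                      n_match_active = integer(0),
                      bioactive_ratio = numeric(0), target = character(0),
                      source_cluster = integer(0))
    attr(out, "notices") <- notices
    return(out)
  }
  cl_ids <- sort(unique(assignment$labels))
  frac <- vapply(cl_ids, function(cl) {
    in_cl <- assignment$labels == cl
    lab <- labels[in_cl]
    n_lab <- sum(lab != "UNLABELED")
    if (n_lab == 0) 0 else wilson_lower(sum(lab == "ACTIVE"), n_lab)
  }, numeric(1))
  ranked <- cl_ids[order(-frac)]
  rows <- list()
  for (cl in utils::head(ranked, top_clusters)) {
    actives <- records[assignment$labels == cl & labels == "ACTIVE", ,
                       drop = FALSE]
    if (nrow(actives) < min_actives) {
      notices <- c(notices, paste0("cluster ", cl, " skipped: fewer than ",
                                   min_actives, " actives"))
      next
    }
    smarts <- find_mcs(actives$smiles,
                       completion_threshold = completion_threshold,
                       seed = seed)
    if (!nzchar(smarts)) {
      notices <- c(notices, paste0("cluster ", cl, " skipped: empty MCS"))
      next
    }
    mask <- match_substructure(records, smarts)
    br <- bioactive_ratio(mask, labels)
    rows[[length(rows) + 1L]] <- data.frame(
      smarts = smarts, n_match = br$n_match,
      n_match_active = br$n_match_active,
      bioactive_ratio = br$bioactive_ratio,
      target = target, source_cluster = cl, stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(smarts = character(0), n_match = integer(0),
               n_match_active = integer(0), bioactive_ratio = numeric(0),
               target = character(0), source_cluster = integer(0))
  out <- out[order(-out$bioactive_ratio, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "notices") <- notices
  class(out) <- c("substructure_report", "data.frame")
  out
}

#' Write substructure reports
#'
#' CSV plus an optional SMARTS-per-line sidecar for downstream alert tooling.
#'
#' @param report a `substructure_report`.
#' @param path CSV path.
#' @param smarts_path optional text file, one SMARTS per line.
#' @return `path`, invisibly.
#' @export
write_substructure_report <- function(report, path, smarts_path = NULL) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  if (!is.null(smarts_path)) writeLines(report$smarts, smarts_path)
  invisible(path)
}
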