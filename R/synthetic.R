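#' Specification for a synthetic PFAS bioassay dataset
#'
#' The generator emulates the statistical shape the pipeline assumes: mostly
#' fluorinated molecules, a planted activity-inducing motif (a carboxylic
#' ester by default), activity drawn conditionally on the motif, sparse
#' labels, and optionally an affinity separation between true actives and
#' inactives. Molecules are assembled from a scaffold grammar (alkyl/aryl
#' cores, optional perfluoroalkyl runs of >= 3 carbons, optional light
#' fluorination, the grafted motif, non-motif decorations), which guarantees
#' valid chemistry and exact ground truth for every structural property.
#'
#' @param n_molecules number of molecules (default 2000).
#' @param p_motif fraction built to contain the planted ester motif (0.2).
#' @param p_active_given_motif,p_active_given_no_motif conditional activity
#'   probabilities (0.9 / 0.05) — the recoverable structure-activity signal.
#' @param labeled_fraction fraction of activity labels revealed (0.3); the
#'   rest are UNLABELED, the semi-supervised regime.
#' @param p_cf fraction containing at least one C-F bond (0.9).
#' @param p_c3f6 fraction containing a perfluoroalkyl run of >= 3 carbons
#'   (0.4); must not exceed `p_cf` (a C3F6 run implies a C-F bond).
#' @param affinity_model `NULL`, or list `mu_active`, `mu_inactive`, `sd`
#'   (kcal/mol) for [generate_affinities()].
#' @param target name of the single activity column (default `"CYP2C9"`).
#' @param seed integer seed; fully determines the output.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_molecules = 2000L, p_motif = 0.2,
                           p_active_given_motif = 0.9,
                           p_active_given_no_motif = 0.05,
                           labeled_fraction = 0.3,
                           p_cf = 0.9, p_c3f6 = 0.4,
                           affinity_model = NULL,
                           target = "CYP2C9", seed = 1L) {
  probs <- c(p_motif, p_active_given_motif, p_active_given_no_motif,
             labeled_fraction, p_cf, p_c3f6)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p_c3f6 > p_cf) stop("p_c3f6 cannot exceed p_cf")
  if (p_active_given_motif <= p_active_given_no_motif) {
    stop("p_active_given_motif must exceed p_active_given_no_motif ",
         "(otherwise the planted signal is unrecoverable)")
  }
  if (!is.null(affinity_model)) {
    stopifnot(all(c("mu_active", "mu_inactive", "sd") %in% names(affinity_model)))
    if (affinity_model$sd <= 0) stop("parameter error: affinity sd must be > 0")
  }
  structure(
    list(n_molecules = as.integer(n_molecules), p_motif = p_motif,
         p_active_given_motif = p_active_given_motif,
         p_active_given_no_motif = p_active_given_no_motif,
         labeled_fraction = labeled_fraction, p_cf = p_cf, p_c3f6 = p_c3f6,
         affinity_model = affinity_model, target = target,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# scaffold grammar pieces; each string extends a linear SMILES chain and is
# guaranteed to end on an extendable carbon (never O/N), so grafting the
# motif or a terminal fluoro part can never create an unintended ester or
# an O-F bond. The grammar is deliberately high-entropy (branching, ethers,
# ring substitution) so that a 2000-molecule draw is not dominated by exact
# duplicates — curated bioassay collections are diverse, and duplicate
# clumps would distort both clustering and MCS extraction.
syn_alkyl <- function(len_range = 1:6, p_branch = 0.25, p_gem = 0.08) {
  len <- sample(len_range, 1L)
  units <- rep("C", len)
  if (len > 2L) {
    for (pos in 2:(len - 1L)) {
      u <- stats::runif(1)
      if (u < p_gem) units[pos] <- "C(C)(C)"
      else if (u < p_gem + p_branch) units[pos] <- "C(C)"
    }
  }
  paste(units, collapse = "")
}

syn_aryl <- function() {
  switch(sample.int(6L, 1L),
         "c1ccccc1", "c1ccc(C)cc1", "c1cc(C)ccc1", "c1c(C)cccc1",
         "c1ccc(CC)cc1", "c1cc(C)cc(C)c1")
}

# Segment pieces are kept short and hetero-broken on purpose: no generic
# alkyl/aryl fragment should be shared by most of an arbitrary molecule
# subset, otherwise MCS extraction would surface ubiquitous chains instead
# of the discriminating motif (real bioassay chemistry is diverse in the
# same sense).
syn_segment <- function() {
  pick <- stats::runif(1)
  if (pick < 0.55) syn_alkyl()
  else if (pick < 0.85) {
    # hetero-linked backbones use N/S, never O: a mid-chain oxygen is then
    # unique to the grafted ester, so no backbone fragment can mimic the
    # motif's C-O-C skeleton, while the linker variety still keeps generic
    # chains below any MCS completion threshold
    linker <- sample(c("N", "S"), 1L)
    paste0(syn_alkyl(1:3), linker, syn_alkyl(2:4))  # ends on carbon
  } else if (pick < 0.925) syn_aryl()
  else paste0(syn_alkyl(1:2), syn_aryl())            # arylalkyl
}

# two independent segments: squares the scaffold entropy, keeping the
# duplicate rate of a 2000-molecule draw low
syn_core <- function() paste0(syn_segment(), syn_segment())

syn_motif <- function() paste0("C(=O)O", syn_alkyl(2:4))

# decorations chosen never to create an ester or a C-F bond
syn_decoration <- function() {
  switch(sample.int(4L, 1L), "", "O", "N", "C(C)=O")
}

syn_fluoro <- function(kind) {
  if (kind == "c3f6") paste0(strrep("C(F)(F)", sample(3:6, 1L)), "F")
  else if (kind == "cf") if (stats::runif(1) < 0.5) "C(F)(F)F" else "F"
  else ""
}

#' Generate a synthetic molecule/bioassay dataset
#'
#' See [synthetic_spec()] for what is planted. The returned table is exactly
#' what [read_molecule_table()] would produce (canonical SMILES via RDKit);
#' the exact structural/activity ground truth is attached as the
#' `ground_truth` attribute — a sidecar for assertions, never an input to the
#' pipeline under test.
#'
#' @param spec a `synthetic_spec`.
#' @return a `molecule_table` with one activity column (`spec$target`) and
#'   attribute `ground_truth` (data.frame: `id`, `has_motif`, `has_cf`,
#'   `has_c3f6`, `active_true`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_molecules
  u_f <- stats::runif(n)
  fluoro_kind <- ifelse(u_f < spec$p_c3f6, "c3f6",
                        ifelse(u_f < spec$p_cf, "cf", "none"))
  has_motif <- stats::runif(n) < spec$p_motif
  smiles <- character(n)
  for (i in seq_len(n)) {
    # decorations terminate the chain (e.g. ketone oxygen), so they are only
    # drawn when no terminal fluoro part follows; this keeps every emitted
    # SMILES valid and the C-F ground truth exact
    middle <- if (has_motif[i]) syn_motif()
              else if (fluoro_kind[i] == "none") syn_decoration() else ""
    smiles[i] <- paste0(syn_core(), middle, syn_fluoro(fluoro_kind[i]))
  }
  p_act <- ifelse(has_motif, spec$p_active_given_motif,
                  spec$p_active_given_no_motif)
  active_true <- stats::runif(n) < p_act
  revealed <- stats::runif(n) < spec$labeled_fraction
  label <- ifelse(!revealed, "UNLABELED",
                  ifelse(active_true, "ACTIVE", "INACTIVE"))
  ids <- sprintf("SYN%05d", seq_len(n))

  canon <- chem_call(list(op = "canonicalize", smiles = as.list(smiles)))
  if (!all(unlist(canon$valid))) {
    stop("generation error: grammar emitted unparseable SMILES (",
         paste(smiles[!unlist(canon$valid)], collapse = ", "), ")")
  }
  tab <- data.frame(id = ids, smiles = unlist(canon$canonical),
                    stringsAsFactors = FALSE)
  tab[[spec$target]] <- label
  gt <- data.frame(id = ids, has_motif = has_motif,
                   has_cf = fluoro_kind != "none",
                   has_c3f6 = fluoro_kind == "c3f6",
                   active_true = active_true, stringsAsFactors = FALSE)
  structure(tab, targets = spec$target,
            rejects = data.frame(row = integer(0), id = character(0),
                                 reason = character(0)),
            ground_truth = gt,
            class = c("molecule_table", "data.frame"))
}

#' Generate synthetic docking affinities
#'
#' Affinities are drawn `Normal(mu_active, sd)` for ground-truth actives and
#' `Normal(mu_inactive, sd)` otherwise — the planted affinity separation the
#' co-descriptor pathway is supposed to exploit.
#'
#' @param records output of [generate_dataset()] (carries the ground truth).
#' @param spec the `synthetic_spec`, with `affinity_model` set.
#' @param seed optional seed override (default `spec$seed + 1`).
#' @return an `affinity_table`.
#' @export
generate_affinities <- function(records, spec, seed = NULL) {
  am <- spec$affinity_model
  if (is.null(am)) stop("spec$affinity_model is not set")
  if (am$sd <= 0) stop("parameter error: affinity sd must be > 0")
  gt <- attr(records, "ground_truth")
  stopifnot(!is.null(gt), identical(gt$id, records$id))
  set.seed(if (is.null(seed)) spec$seed + 1L else as.integer(seed))
  mu <- ifelse(gt$active_true, am$mu_active, am$mu_inactive)
  tab <- data.frame(id = records$id, target = spec$target,
                    affinity = stats::rnorm(nrow(records), mu, am$sd),
                    stringsAsFactors = FALSE)
  class(tab) <- c("affinity_table", "data.frame")
  tab
}

#' Write a synthetic dataset with its ground-truth sidecar
#'
#' Emits `molecules.csv` (the dialect [read_molecule_table()] reads) and
#' `ground_truth.csv` (clearly named; for assertions only).
#'
#' @param records output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return character vector of the two paths, invisibly.
#' @export
write_dataset <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mol <- file.path(dir, "molecules.csv")
  gt <- file.path(dir, "ground_truth.csv")
  write_molecule_table(records, mol)
  utils::write.csv(attr(records, "ground_truth"), gt, row.names = FALSE)
  invisible(c(molecules = mol, ground_truth = gt))
}
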