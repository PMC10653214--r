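#' Derive a stage sub-seed from the run seed
#'
#' A fixed splitmix-style integer mix of the global seed and a stage tag, so
#' one mandatory config seed fans out deterministically to every stage and
#' stays inside 32-bit integer range.
#'
#' @param seed integer run seed.
#' @param tag stage name.
#' @return integer sub-seed in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.double(seed) * 48271 + h * 2654435761) %% 2147483647)
}

pipeline_defaults <- function() {
  list(
    input = NULL,                 # molecules CSV; NULL -> synthetic
    affinity_input = NULL,        # optional affinity CSV
    target = NULL,                # default: first activity column
    seed = NULL,                  # mandatory
    out_dir = NULL,               # mandatory
    synthetic = list(n_molecules = 2000L, p_motif = 0.2,
                     p_active_given_motif = 0.9,
                     p_active_given_no_motif = 0.05,
                     labeled_fraction = 0.3, p_cf = 0.9, p_c3f6 = 0.4),
    filter = "none",              # "none" | "cf" | "c3f6"
    featurize = list(n_bits = 2048L, use_affinity = FALSE,
                     affinity_scale = NULL),
    metric = list(d_out = 64L, margin = 1.0, learning_rate = 0.05,
                  epochs = 100L, batch_size = 256L, max_pairs = 2000L),
    embed = list(pca_components = 50L),
    tsne = list(enabled = FALSE, perplexity = 30),
    cluster = list(k = NULL, k_grid = seq(5L, 60L, by = 5L), n_init = 10L,
                   space = "pca"),   # "pca" | "tsne"
    motif = list(top_clusters = 1L, completion_threshold = 0.7,
                 min_actives = 10L),
    affinity = list(threshold = -5)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) stop("unknown config key: ", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) stop("config key ", full, " must be a block")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      # list-assignment so an explicit null in the config keeps the key
      defaults[key] <- list(user[[key]])
    }
  }
  defaults
}

#' Validate and resolve a pipeline configuration
#'
#' Reads a JSON (or, when the `yaml` package is available, YAML) config,
#' applies defaults, and fails fast on unknown keys (typo guard) or a missing
#' seed. The resolved config records which keys the user set
#' (attribute `user_keys`).
#'
#' @param path config file, or a named list already in memory.
#' @return a fully resolved `pipeline_config` list.
#' @export
validate_config <- function(path) {
  user <- if (is.list(path)) {
    path
  } else if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- merge_config(pipeline_defaults(), user)
  if (is.null(cfg$seed)) stop("config error: 'seed' is mandatory")
  cfg$seed <- as.integer(cfg$seed)
  for (p in c(cfg$input, cfg$affinity_input)) {
    if (!is.null(p) && !file.exists(p)) stop("config error: missing file ", p)
  }
  if (!cfg$filter %in% c("none", "cf", "c3f6")) {
    stop("config error: filter must be one of none/cf/c3f6")
  }
  if (!cfg$cluster$space %in% c("pca", "tsne")) {
    stop("config error: cluster$space must be 'pca' or 'tsne'")
  }
  attr(cfg, "user_keys") <- names(user)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

log_stage <- function(lines, stage, n_in, n_out) {
  msg <- sprintf("[%s] in=%d out=%d", stage, n_in, n_out)
  message(msg)
  c(lines, msg)
}

#' Run the full QSAR pipeline
#'
#' Orchestrates ingest/filtering, ECFP4 featurization (optionally
#' affinity-augmented), semi-supervised metric learning on the labeled pairs,
#' PCA embedding of *all* molecules in the learned space, k-means clustering
#' with silhouette selection (or a fixed k), and per-cluster MCS motif
#' attribution with the bioactive-ratio statistic; an affinity threshold
#' summary is appended when an affinity table is configured. Per-stage CSV
#' artifacts, a manifest with every resolved parameter, and a human-readable
#' summary are written to `config$out_dir`.
#'
#' @param config a `pipeline_config` from [validate_config()] (or a path /
#'   list accepted by it).
#' @return invisibly, a list with the key stage outputs (`records`, `model`,
#'   `assignment`, `report`, `affinity_summary`, `summary_path`).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  if (is.null(cfg$out_dir)) stop("config error: 'out_dir' is mandatory")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)

  # --- stage 1: ingest -------------------------------------------------
  if (is.null(cfg$input)) {
    spec <- do.call(synthetic_spec, c(cfg$synthetic,
                                      list(seed = derive_seed(cfg$seed, "generate"))))
    records <- generate_dataset(spec)
  } else {
    records <- read_molecule_table(cfg$input)
  }
  n0 <- nrow(records)
  if (cfg$filter == "cf") records <- filter_cf(records)
  if (cfg$filter == "c3f6") records <- filter_c3f6(records)
  log_lines <- log_stage(log_lines, "chemio", n0, nrow(records))
  target <- if (is.null(cfg$target)) molecule_targets(records)[1L] else cfg$target
  write_molecule_table(records, file.path(cfg$out_dir, "molecules.csv"))

  # --- stage 2: featurize ----------------------------------------------
  X <- ecfp4(records, n_bits = cfg$featurize$n_bits)
  aff_tab <- NULL
  if (!is.null(cfg$affinity_input)) {
    aff_tab <- read_affinity_table(cfg$affinity_input)
    if (isTRUE(cfg$featurize$use_affinity)) {
      aff <- aff_tab$affinity[match(paste(records$id, target),
                                    paste(aff_tab$id, aff_tab$target))]
      if (any(is.na(aff))) {
        stop("data error: ", sum(is.na(aff)),
             " molecule(s) lack an affinity for target ", target)
      }
      X <- augment_with_affinity(X, aff, scale = cfg$featurize$affinity_scale)
    }
  }
  log_lines <- log_stage(log_lines, "featurize", nrow(records), nrow(X))

  # --- stage 3: metric learning ----------------------------------------
  cons <- build_constraints(records, target,
                            max_pairs = cfg$metric$max_pairs,
                            seed = derive_seed(cfg$seed, "pairs"))
  model <- fit_metric(unclass(X), cons,
                      d_out = cfg$metric$d_out, margin = cfg$metric$margin,
                      learning_rate = cfg$metric$learning_rate,
                      epochs = cfg$metric$epochs,
                      batch_size = cfg$metric$batch_size,
                      seed = derive_seed(cfg$seed, "metric"))
  save_metric_model(model, file.path(cfg$out_dir, "metric_model.json"))
  embedded <- metric_transform(model, unclass(X))
  log_lines <- log_stage(log_lines, "metric_learning", nrow(cons), nrow(embedded))

  # --- stage 4: embed + cluster ----------------------------------------
  n_comp <- min(cfg$embed$pca_components, ncol(embedded),
                nrow(embedded) - 1L)
  pca <- pca_embed(embedded, n_comp)
  coords <- NULL
  if (isTRUE(cfg$tsne$enabled) || cfg$cluster$space == "tsne") {
    coords <- tsne_embed(pca$scores, perplexity = cfg$tsne$perplexity,
                         seed = derive_seed(cfg$seed, "tsne"))
  }
  cluster_space <- if (cfg$cluster$space == "tsne") coords else pca$scores
  if (!is.null(cfg$cluster$k)) {
    assignment <- kmeans_cluster(cluster_space, cfg$cluster$k,
                                 seed = derive_seed(cfg$seed, "kmeans"),
                                 n_init = cfg$cluster$n_init)
  } else {
    grid <- cfg$cluster$k_grid
    grid <- grid[grid >= 2 & grid <= nrow(cluster_space) - 1L]
    assignment <- select_k(cluster_space, grid,
                           seed = derive_seed(cfg$seed, "kmeans"),
                           n_init = cfg$cluster$n_init)
  }
  clus_df <- data.frame(id = records$id, cluster = assignment$labels,
                        x = if (is.null(coords)) NA_real_ else coords[, 1],
                        y = if (is.null(coords)) NA_real_ else coords[, 2],
                        silhouette_overall = assignment$silhouette)
  utils::write.csv(clus_df, file.path(cfg$out_dir, "clusters.csv"),
                   row.names = FALSE)
  log_lines <- log_stage(log_lines, "embed_cluster", nrow(embedded),
                         assignment$k)

  # --- stage 5: motif attribution --------------------------------------
  report <- cluster_motif_report(
    records, assignment, target,
    top_clusters = cfg$motif$top_clusters,
    completion_threshold = cfg$motif$completion_threshold,
    min_actives = cfg$motif$min_actives,
    seed = derive_seed(cfg$seed, "mcs")
  )
  write_substructure_report(report, file.path(cfg$out_dir, "motifs.csv"),
                            file.path(cfg$out_dir, "motifs.smarts"))
  log_lines <- log_stage(log_lines, "substructure", assignment$k, nrow(report))

  # --- optional affinity summary ---------------------------------------
  aff_sum <- NULL
  if (!is.null(aff_tab)) {
    aff_sum <- affinity_summary(aff_tab, target,
                                threshold = cfg$affinity$threshold,
                                ids = records$id)
    log_lines <- log_stage(log_lines, "affinity", aff_sum$n + aff_sum$n_missing,
                           aff_sum$n)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pfascluster")),
    r_version = R.version.string,
    config = unclass(cfg),
    resolved_target = target,
    stage_seeds = list(
      generate = derive_seed(cfg$seed, "generate"),
      pairs = derive_seed(cfg$seed, "pairs"),
      metric = derive_seed(cfg$seed, "metric"),
      tsne = derive_seed(cfg$seed, "tsne"),
      kmeans = derive_seed(cfg$seed, "kmeans"),
      mcs = derive_seed(cfg$seed, "mcs")
    ),
    log = log_lines
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  summary_lines <- c(
    sprintf("pfascluster run (seed %d)", cfg$seed),
    sprintf("molecules: %d (target %s)", nrow(records), target),
    sprintf("metric: %d -> %d, loss %.6g -> %.6g", model$d_in, model$d_out,
            model$loss_trace[1], model$loss_trace[length(model$loss_trace)]),
    sprintf("clusters: k = %d, silhouette = %.4f", assignment$k,
            assignment$silhouette),
    if (nrow(report) > 0) {
      sprintf("top motif: %s (bioactive ratio %.3f, %d/%d labeled matches)",
              report$smarts[1], report$bioactive_ratio[1],
              report$n_match_active[1], report$n_match[1])
    } else "top motif: none",
    if (!is.null(aff_sum)) {
      sprintf("affinity: %.1f%% stronger than %g kcal/mol (mean %.2f, n=%d)",
              100 * aff_sum$fraction_stronger, cfg$affinity$threshold,
              aff_sum$mean, aff_sum$n)
    }
  )
  summary_path <- file.path(cfg$out_dir, "summary.txt")
  writeLines(summary_lines, summary_path)

  invisible(list(records = records, model = model, assignment = assignment,
                 report = report, affinity_summary = aff_sum,
                 pca = pca, coords = coords, summary_path = summary_path))
}
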