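#' Build pairwise constraints from sparse activity labels
#'
#' Draws a balanced, seed-reproducible sample of SIMILAR (same label) and
#' DISSIMILAR (opposite label) pairs among the *labeled* molecules for one
#' target; unlabeled molecules contribute no constraints — they are carried
#' through by the learned transform instead. When the exhaustive pair set fits
#' in `max_pairs` it is returned whole.
#'
#' @param records a `molecule_table`.
#' @param target activity column to train on.
#' @param max_pairs cap on returned pairs (default 2000; `Inf` = exhaustive).
#' @param seed integer seed controlling the sample.
#' @return data.frame with columns `i`, `j` (row indices into `records`,
#'   `i < j`) and `relation` (`"SIMILAR"`/`"DISSIMILAR"`).
#' @export
build_constraints <- function(records, target, max_pairs = 2000L, seed = 1L) {
  labels <- records[[target]]
  if (is.null(labels)) stop("unknown target column: ", target)
  act <- which(labels == "ACTIVE")
  inact <- which(labels == "INACTIVE")
  if (length(act) < 1L || length(inact) < 1L) {
    stop("insufficient labels: need at least one ACTIVE and one INACTIVE ",
         "record for target '", target, "'")
  }
  pair_grid <- function(idx) {
    if (length(idx) < 2L) return(cbind(integer(0), integer(0)))
    t(utils::combn(idx, 2L))
  }
  sim <- rbind(pair_grid(act), pair_grid(inact))
  dis <- as.matrix(expand.grid(i = act, j = inact))
  dis <- cbind(pmin(dis[, 1], dis[, 2]), pmax(dis[, 1], dis[, 2]))
  all_pairs <- rbind(
    if (nrow(sim)) data.frame(i = sim[, 1], j = sim[, 2], relation = "SIMILAR"),
    if (nrow(dis)) data.frame(i = dis[, 1], j = dis[, 2], relation = "DISSIMILAR")
  )
  all_pairs <- all_pairs[order(all_pairs$i, all_pairs$j), , drop = FALSE]
  rownames(all_pairs) <- NULL
  if (nrow(all_pairs) <= max_pairs) return(all_pairs)
  # balanced subsample: up to half the budget from each relation
  set.seed(seed %% .Machine$integer.max)
  take <- function(df, n_want) {
    if (nrow(df) <= n_want) df else df[sort(sample.int(nrow(df), n_want)), ]
  }
  half <- floor(max_pairs / 2)
  sim_df <- all_pairs[all_pairs$relation == "SIMILAR", , drop = FALSE]
  dis_df <- all_pairs[all_pairs$relation == "DISSIMILAR", , drop = FALSE]
  n_sim <- min(nrow(sim_df), half)
  n_dis <- min(nrow(dis_df), max_pairs - n_sim)
  n_sim <- min(nrow(sim_df), max_pairs - n_dis)
  out <- rbind(take(sim_df, n_sim), take(dis_df, n_dis))
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a Mahalanobis metric from pairwise constraints
#'
#' The semi-supervised core: learns a linear map `L` (`d_out x d_in`) so that
#' the distance `d(x, y) = ||L (x - y)||` contracts SIMILAR pairs and pushes
#' DISSIMILAR pairs beyond a margin, by mini-batch gradient descent on the
#' contrastive loss
#' `sum_SIMILAR d^2 + sum_DISSIMILAR max(0, margin - d)^2`.
#' The implied metric matrix `M = L'L` is positive semi-definite by
#' construction. `L` is initialized from the top principal components of `X`
#' (identity truncation when PCA is unavailable, e.g. constant `X`).
#' Constraints are sorted canonically before batching, so the fit is
#' invariant to their input order; all randomness flows from `seed`.
#' If the final-epoch loss exceeds the best seen, the best-epoch `L` is
#' returned, so the trace contract (final <= initial) holds even for an
#' aggressive learning rate.
#'
#' @param X numeric descriptor matrix (rows = molecules).
#' @param constraints data.frame from [build_constraints()].
#' @param d_out embedding dimension (default 64, capped at `ncol(X)`).
#' @param margin push margin for dissimilar pairs (default 1.0).
#' @param learning_rate gradient step size (default 0.05; at the default
#'   batch/epoch budget the contrastive loss reaches its plateau, while 0.01
#'   leaves it several-fold higher after 100 epochs on 2048-bit input).
#' @param epochs passes over the constraint set (default 100, >= 1).
#' @param batch_size constraints per gradient step (default 256).
#' @param seed integer seed (batch shuffling).
#' @param init `"pca"` (default) or `"identity"` (truncated identity rows,
#'   so with `d_out = d_in` and a zero learning rate the metric is plain
#'   Euclidean distance).
#' @return a `metric_model`: list with `L`, `d_in`, `d_out`, `margin`,
#'   `loss_trace` (initial loss followed by one entry per epoch).
#' @export
fit_metric <- function(X, constraints, d_out = 64L, margin = 1.0,
                       learning_rate = 0.05, epochs = 100L,
                       batch_size = 256L, seed = 1L,
                       init = c("pca", "identity")) {
  init <- match.arg(init)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (epochs < 1L) stop("epochs must be >= 1")
  if (nrow(constraints) < 1L) stop("no constraints supplied")
  if (max(constraints$i, constraints$j) > nrow(X)) {
    stop("constraint indices exceed descriptor rows")
  }
  d_in <- ncol(X)
  d_out <- min(as.integer(d_out), d_in)
  cons <- constraints[order(constraints$i, constraints$j, constraints$relation), ]
  Vall <- t(X[cons$i, , drop = FALSE] - X[cons$j, , drop = FALSE])  # d_in x m
  sim <- cons$relation == "SIMILAR"
  m <- ncol(Vall)

  L <- if (init == "identity") diag(1, d_out, d_in) else metric_init(X, d_out)
  loss_of <- function(L) {
    d <- sqrt(colSums((L %*% Vall)^2))
    sum(d[sim]^2) + sum(pmax(0, margin - d[!sim])^2)
  }
  set.seed(seed %% .Machine$integer.max)
  trace <- loss_of(L)
  best <- list(L = L, loss = trace[1])
  for (ep in seq_len(epochs)) {
    ord <- sample.int(m)
    for (start in seq(1L, m, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, m)]
      V <- Vall[, idx, drop = FALSE]
      Z <- L %*% V
      d <- sqrt(colSums(Z^2))
      coef <- numeric(length(idx))
      coef[sim[idx]] <- 2
      viol <- !sim[idx] & d < margin & d > 0
      coef[viol] <- -2 * (margin - d[viol]) / d[viol]
      grad <- (Z * rep(coef, each = nrow(Z))) %*% t(V) / length(idx)
      L <- L - learning_rate * grad
    }
    ep_loss <- loss_of(L)
    if (!is.finite(ep_loss)) {
      stop("divergence error: loss became non-finite at epoch ", ep,
           "; try a smaller learning_rate")
    }
    trace <- c(trace, ep_loss)
    if (ep_loss < best$loss) best <- list(L = L, loss = ep_loss)
  }
  if (trace[length(trace)] > best$loss) L <- best$L
  structure(
    list(L = L, d_in = d_in, d_out = d_out, margin = margin,
         loss_trace = trace),
    class = "metric_model"
  )
}

metric_init <- function(X, d_out) {
  d_in <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  pcs <- tryCatch({
    sv <- randomized_svd(Xc, d_out, seed = 0L)
    t(sv$v)
  }, error = function(e) NULL)
  if (is.null(pcs) || any(!is.finite(pcs))) {
    pcs <- diag(1, d_out, d_in)
  }
  pcs
}

#' Apply a learned metric
#'
#' Embeds descriptor rows by `X L'` — this is where the semi-supervision pays
#' off: the transform learned from the few labeled pairs is applied to every
#' molecule, labeled or not. Euclidean distances in the output equal
#' Mahalanobis distances under `M = L'L` in the input space.
#'
#' @param model a `metric_model`.
#' @param X matrix with `model$d_in` columns.
#' @return numeric matrix `nrow(X) x d_out`.
#' @export
metric_transform <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$d_in) {
    stop("dimension error: X has ", ncol(X), " columns, model expects ",
         model$d_in)
  }
  out <- X %*% t(model$L)
  rownames(out) <- rownames(X)
  out
}

#' Pairwise metric distance
#' @param model a `metric_model`.
#' @param x,y descriptor vectors of length `model$d_in`.
#' @return `||L (x - y)||`.
#' @export
metric_distance <- function(model, x, y) {
  sqrt(sum((model$L %*% (as.numeric(x) - as.numeric(y)))^2))
}

#' Save / load a metric model as a JSON artifact
#'
#' The flattened `L`, dimensions, margin and loss trace round-trip exactly
#' (doubles serialized at full precision).
#'
#' @param model a `metric_model`.
#' @param path JSON file path.
#' @return `save_metric_model`: `path` invisibly; `load_metric_model`: the
#'   restored `metric_model`.
#' @export
save_metric_model <- function(model, path) {
  payload <- list(
    d_in = model$d_in, d_out = model$d_out, margin = model$margin,
    L = as.numeric(model$L), loss_trace = model$loss_trace
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_metric_model
#' @export
load_metric_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(L = matrix(p$L, nrow = p$d_out, ncol = p$d_in),
         d_in = as.integer(p$d_in), d_out = as.integer(p$d_out),
         margin = p$margin, loss_trace = p$loss_trace),
    class = "metric_model"
  )
}

#' @export
print.metric_model <- function(x, ...) {
  cat("Mahalanobis metric model: ", x$d_in, " -> ", x$d_out,
      " (margin ", x$margin, ")\n", sep = "")
  cat("loss: ", x$loss_trace[1], " -> ", x$loss_trace[length(x$loss_trace)],
      " over ", length(x$loss_trace) - 1L, " epochs\n", sep = "")
  invisible(x)
}
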