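# Randomized range-finder SVD (subspace iteration); deterministic via seed.
# Used for top-k PCA on wide fingerprint matrices where a full LAPACK SVD
# would dominate runtime. Accuracy is checked against exact eigen in tests.
randomized_svd <- function(X, k, q = 6L, seed = 0L, oversample = 10L) {
  n <- nrow(X); p <- ncol(X)
  k <- min(k, n, p)
  l <- min(k + oversample, p)
  set.seed(seed %% .Machine$integer.max)
  Omega <- matrix(stats::rnorm(p * l), p, l)
  Y <- X %*% Omega
  for (step in seq_len(q)) {
    Y <- qr.Q(qr(Y))
    Y <- X %*% crossprod(X, Y)
  }
  Q <- qr.Q(qr(Y))
  B <- crossprod(Q, X)          # l x p
  sv <- svd(B, nu = k, nv = k)
  list(u = Q %*% sv$u[, seq_len(k), drop = FALSE],
       d = sv$d[seq_len(k)],
       v = sv$v[, seq_len(k), drop = FALSE])
}

#' Principal component analysis
#'
#' Column-centers `X` and projects onto the top eigenvectors of the sample
#' covariance. Small problems use an exact SVD; large ones (`n * p` over
#' `5e5` with few requested components) a seeded randomized SVD with subspace
#' iteration, accurate to working precision for the decaying spectra of
#' fingerprint data. Deterministic for fixed input.
#'
#' @param X numeric matrix (rows = observations).
#' @param n_components number of components, `<= min(nrow - 1, ncol)`.
#' @param exact force the exact path (used by the oracle tests).
#' @return list with `scores` (`n x n_components`),
#'   `explained_variance_ratio` (non-increasing, sums to <= 1), and
#'   `rotation` (`p x n_components`).
#' @export
pca_embed <- function(X, n_components, exact = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n_components < 1L || n_components > min(n - 1L, p)) {
    stop("n_components must be in [1, min(rows-1, cols)]")
  }
  Xc <- sweep(X, 2, colMeans(X))
  total_var <- sum(Xc^2) / (n - 1)
  if (is.null(exact)) {
    exact <- (as.double(n) * p <= 5e5) || (n_components > min(n, p) / 2)
  }
  if (exact) {
    sv <- svd(Xc, nu = n_components, nv = n_components)
    d <- sv$d[seq_len(n_components)]
    scores <- sv$u %*% diag(d, n_components)
    rot <- sv$v
  } else {
    sv <- randomized_svd(Xc, n_components)
    d <- sv$d
    scores <- sv$u %*% diag(d, n_components)
    rot <- sv$v
  }
  evr <- if (total_var > 0) (d^2 / (n - 1)) / total_var else rep(0, n_components)
  rownames(scores) <- rownames(X)
  list(scores = scores, explained_variance_ratio = evr, rotation = rot)
}

#' 2-D t-SNE embedding
#'
#' Delegates to scikit-learn's Barnes-Hut t-SNE (PCA initialization) through
#' the bundled Python helper; deterministic under a fixed seed. Used for the
#' 2-D chemical-space maps; clustering does not run on this space by default.
#'
#' @param X numeric matrix; requires `nrow(X) > 3 * perplexity`.
#' @param perplexity t-SNE perplexity (default 30).
#' @param seed integer seed.
#' @return `n x 2` coordinate matrix.
#' @export
tsne_embed <- function(X, perplexity = 30, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) <= 3 * perplexity) {
    stop("parameter error: perplexity ", perplexity, " too large for n = ",
         nrow(X), " (need n > 3 * perplexity)")
  }
  res <- chem_call(list(
    op = "tsne",
    x = apply(X, 1, as.numeric, simplify = FALSE),
    perplexity = perplexity, seed = as.integer(seed)
  ))
  out <- do.call(rbind, lapply(res$y, unlist))
  rownames(out) <- rownames(X)
  out
}

# squared Euclidean distances rows(X) x rows(C)
sqdist_to <- function(X, C) {
  xx <- rowSums(X^2)
  cc <- rowSums(C^2)
  d2 <- outer(xx, cc, "+") - 2 * tcrossprod(X, C)
  d2[d2 < 0] <- 0
  d2
}

# full pairwise Euclidean distance matrix via BLAS (fast path for silhouette)
euclid_dist_matrix <- function(X) {
  d2 <- sqdist_to(X, X)
  diag(d2) <- 0
  sqrt(d2)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  first <- sample.int(n, 1L)
  centers[1, ] <- X[first, ]
  d2 <- sqdist_to(X, centers[1, , drop = FALSE])[, 1]
  for (j in seq_len(k - 1L) + 1L) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    pick <- sample.int(n, 1L, prob = probs)
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, sqdist_to(X, centers[j, , drop = FALSE])[, 1])
  }
  centers
}

#' K-means clustering (k-means++ seeding, Lloyd iterations)
#'
#' Runs Lloyd's algorithm from `n_init` k-means++ initializations and keeps
#' the restart with the lowest inertia (total within-cluster sum of squares).
#' Empty clusters are repaired by reseeding them at the point farthest from
#' its center. Deterministic under `seed`.
#'
#' @param X numeric matrix.
#' @param k number of clusters, `2 <= k <= nrow(X)`.
#' @param seed integer seed.
#' @param n_init restarts (default 10; k-means++ still lands in poor local
#'   optima often enough at moderate k that fewer restarts destabilize the
#'   silhouette-based k selection).
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @return a `cluster_assignment`: list with `labels` (0-based cluster index
#'   per row), `k`, `centers`, `inertia`, `inertia_trace` (non-increasing,
#'   winning restart), `silhouette` (of the partition, in `[-1, 1]`), `seed`.
#' @export
kmeans_cluster <- function(X, k, seed = 1L, n_init = 10L, max_iter = 100L) {
  assignment <- kmeans_core(X, k, seed, n_init, max_iter)
  assignment$silhouette <- silhouette_score(X, assignment$labels)
  assignment
}

# Lloyd + k-means++ without the silhouette (select_k shares one distance
# matrix across candidates instead). Assignment uses the inner-product form
# argmin ||x - c||^2 = argmax (x.c - |c|^2/2), which keeps the hot loop in
# BLAS.
kmeans_core <- function(X, k, seed, n_init, max_iter) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 2L || k > n) stop("parameter error: k must be in [2, nrow(X)]")
  set.seed(seed %% .Machine$integer.max)
  sum_x2 <- sum(X^2)
  xx <- rowSums(X^2)
  best <- NULL
  for (restart in seq_len(n_init)) {
    centers <- kmeanspp_init(X, k)
    trace <- numeric(0)
    labels <- rep(1L, n)
    for (iter in seq_len(max_iter)) {
      cc <- rowSums(centers^2)
      score <- sweep(tcrossprod(X, centers), 2, cc / 2)
      labels <- max.col(score, ties.method = "first")
      for (j in seq_len(k)) {   # repair empty clusters
        if (!any(labels == j)) {
          d2_own <- xx - 2 * score[cbind(seq_len(n), labels)]
          labels[which.max(d2_own)] <- j
        }
      }
      counts <- tabulate(labels, k)
      new_centers <- rowsum(X, labels, reorder = TRUE) / counts
      # within-SS about the label centroids (the quantity Lloyd decreases)
      inertia <- sum_x2 - sum(counts * rowSums(new_centers^2))
      trace <- c(trace, inertia)
      if (max(abs(new_centers - centers)) < 1e-12) { centers <- new_centers; break }
      centers <- new_centers
    }
    if (is.null(best) || trace[length(trace)] < best$inertia) {
      best <- list(labels = labels, centers = centers,
                   inertia = trace[length(trace)], trace = trace)
    }
  }
  structure(
    list(labels = best$labels - 1L, k = as.integer(k), centers = best$centers,
         inertia = best$inertia, inertia_trace = best$trace,
         silhouette = NA_real_, seed = as.integer(seed)),
    class = "cluster_assignment"
  )
}

#' Mean silhouette score of a partition
#'
#' For each point, `a` is its mean Euclidean distance to the rest of its own
#' cluster and `b` the minimum over other clusters of the mean distance to
#' that cluster; the point's silhouette is `(b - a) / max(a, b)` (0 for
#' singleton clusters), and the score is the mean over points.
#'
#' @param X numeric matrix.
#' @param labels integer cluster labels (any coding; >= 2 distinct values).
#' @return score in `[-1, 1]`.
#' @export
silhouette_score <- function(X, labels) {
  X <- as.matrix(X)
  # stats::dist is numerically exact (no inner-product cancellation); the
  # BLAS path is reserved for large n where the speed matters
  D <- if (nrow(X) <= 1000L) as.matrix(stats::dist(X)) else
    euclid_dist_matrix(X)
  silhouette_from_dist(D, labels)
}

# silhouette given a precomputed distance matrix; fully vectorized
silhouette_from_dist <- function(D, labels) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("undefined-score error: silhouette needs >= 2 clusters")
  n <- nrow(D)
  member <- matrix(0, n, k)
  member[cbind(seq_len(n), labels)] <- 1
  sums <- D %*% member                      # point-to-cluster distance sums
  sizes <- tabulate(labels, k)
  idx_own <- cbind(seq_len(n), labels)
  a <- sums[idx_own] / pmax(sizes[labels] - 1L, 1L)
  means <- sweep(sums, 2, sizes, "/")
  means[idx_own] <- Inf                     # exclude the own cluster from b
  b <- do.call(pmin, lapply(seq_len(k), function(j) means[, j]))
  s <- (b - a) / pmax(a, b)
  s[sizes[labels] == 1L] <- 0               # singleton convention
  mean(s)
}

#' Silhouette-based selection of the cluster count
#'
#' Runs [kmeans_cluster()] for every candidate `k` and returns the assignment
#' with the highest silhouette; ties break toward the smaller `k`
#' (parsimony).
#'
#' @param X numeric matrix.
#' @param k_candidates integer vector of candidate cluster counts (default
#'   `seq(5, 60, by = 5)`).
#' @param seed integer seed (shared across candidates).
#' @param n_init restarts per candidate.
#' @return the winning `cluster_assignment`, with attribute `candidates`
#'   (data.frame of k and silhouette).
#' @export
select_k <- function(X, k_candidates = seq(5L, 60L, by = 5L), seed = 1L,
                     n_init = 10L) {
  if (length(k_candidates) == 0L) stop("parameter error: empty candidate list")
  k_candidates <- sort(unique(as.integer(k_candidates)))
  D <- euclid_dist_matrix(as.matrix(X))     # shared across candidates
  fits <- lapply(k_candidates, function(k) {
    f <- kmeans_core(X, k, seed = seed, n_init = n_init, max_iter = 100L)
    f$silhouette <- silhouette_from_dist(D, f$labels)
    f
  })
  sils <- vapply(fits, function(f) f$silhouette, numeric(1))
  win <- which.max(sils)   # which.max takes the first (smallest k) on ties
  out <- fits[[win]]
  attr(out, "candidates") <- data.frame(k = k_candidates, silhouette = sils)
  out
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("k-means assignment: k = ", x$k, ", inertia = ",
      signif(x$inertia, 6), ", silhouette = ", signif(x$silhouette, 4),
      "\n", sep = "")
  invisible(x)
}
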