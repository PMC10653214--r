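test_that("pca handles the rank-1 case and reconstructs completely", {
  set.seed(1)
  t_param <- stats::rnorm(40)
  X <- cbind(2 * t_param, -t_param, 0.5 * t_param)  # exact line in 3-D
  p <- pca_embed(X, 3)
  expect_equal(p$explained_variance_ratio[1], 1.0, tolerance = 1e-9)
  expect_equal(p$explained_variance_ratio[2:3], c(0, 0), tolerance = 1e-9)

  Y <- matrix(stats::rnorm(25 * 6), 25, 6)
  p2 <- pca_embed(Y, 6)
  Yc <- sweep(Y, 2, colMeans(Y))
  expect_equal(p2$scores %*% t(p2$rotation), Yc, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(pca_embed(Y, 7), "n_components")
})

test_that("explained variance matches an independent eigen-decomposition", {
  set.seed(2)
  X <- matrix(stats::rnorm(30 * 8), 30, 8) %*% diag(c(4, 3, 2, 1, 1, 1, 1, 1))
  p <- pca_embed(X, 8)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(p$explained_variance_ratio, ev / sum(ev), tolerance = 1e-9)
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(p$explained_variance_ratio), 1 + 1e-12)
})

test_that("randomized path agrees with the exact path on top components", {
  set.seed(3)
  X <- matrix(stats::rnorm(300 * 40), 300, 40) %*%
    diag(5 * 0.8^(0:39))   # decaying spectrum, the regime this path serves
  exact <- pca_embed(X, 5, exact = TRUE)
  approx <- pca_embed(X, 5, exact = FALSE)
  expect_equal(approx$explained_variance_ratio,
               exact$explained_variance_ratio, tolerance = 1e-6)
  # scores match up to per-component sign
  for (j in 1:5) {
    expect_equal(abs(stats::cor(exact$scores[, j], approx$scores[, j])), 1,
                 tolerance = 1e-6)
  }
})

test_that("kmeans recovers separable blobs and beats random partitions", {
  set.seed(4)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  X <- do.call(rbind, lapply(1:3, function(j) {
    sweep(matrix(stats::rnorm(30 * 2, sd = 0.5), 30, 2), 2, centers[j, ], "+")
  }))
  truth <- rep(1:3, each = 30)
  a <- kmeans_cluster(X, 3, seed = 1)
  expect_equal(a$k, 3L)
  # exact recovery up to label permutation
  tab <- table(a$labels, truth)
  expect_equal(sum(apply(tab, 2, max)), 90)
  expect_true(all(diff(a$inertia_trace) <= 1e-9))     # Lloyd monotonicity
  # random-restart bound
  set.seed(5)
  for (rep in 1:100) {
    rand_lab <- sample.int(3, 90, replace = TRUE)
    rand_inertia <- sum(vapply(1:3, function(j) {
      pts <- X[rand_lab == j, , drop = FALSE]
      if (nrow(pts) == 0) 0 else sum(sweep(pts, 2, colMeans(pts))^2)
    }, numeric(1)))
    expect_lte(a$inertia, rand_inertia + 1e-9)
  }
  expect_error(kmeans_cluster(X, 1, seed = 1), "parameter")
  expect_error(kmeans_cluster(X, 91, seed = 1), "parameter")
})

test_that("three collinear equidistant points split as middle-plus-neighbor", {
  X <- matrix(c(0, 1, 2), ncol = 1)
  a <- kmeans_cluster(X, 2, seed = 1)
  # hand enumeration: {0,1}+{2} or {0}+{1,2}, both with inertia 0.5
  expect_equal(a$inertia, 0.5, tolerance = 1e-12)
  expect_true(a$labels[1] != a$labels[3])
})

test_that("silhouette matches the brute-force oracle and the limit cases", {
  set.seed(6)
  X <- rbind(matrix(stats::rnorm(40, sd = 0.1), 20, 2),
             matrix(stats::rnorm(40, sd = 0.1) + 50, 20, 2))
  lab <- rep(1:2, each = 20)
  expect_gt(silhouette_score(X, lab), 0.95)

  for (rep in 1:5) {
    n <- sample(20:60, 1)
    k <- sample(2:5, 1)
    Y <- matrix(stats::rnorm(n * 3), n, 3)
    labs <- sample.int(k, n, replace = TRUE)
    labs[seq_len(k)] <- seq_len(k)      # every cluster non-empty
    expect_equal(silhouette_score(Y, labs), silhouette_bruteforce(Y, labs),
                 tolerance = 1e-12)
  }
  expect_error(silhouette_score(X, rep(1, 40)), "2 clusters")
})

test_that("random labels on one blob give silhouette near zero", {
  set.seed(7)
  X <- matrix(stats::rnorm(500 * 4), 500, 4)
  lab <- sample.int(3, 500, replace = TRUE)
  expect_lt(abs(silhouette_score(X, lab)), 0.1)
})

test_that("select_k recovers a planted k and is self-consistent", {
  set.seed(8)
  centers <- rbind(c(0, 0), c(12, 0), c(0, 12))
  X <- do.call(rbind, lapply(1:3, function(j) {
    sweep(matrix(stats::rnorm(40 * 2, sd = 0.6), 40, 2), 2, centers[j, ], "+")
  }))
  best <- select_k(X, 2:8, seed = 1)
  expect_equal(best$k, 3L)
  expect_equal(best$silhouette, silhouette_score(X, best$labels))
  cands <- attr(best, "candidates")
  expect_equal(cands$k, 2:8)

  only2 <- select_k(X, 2L, seed = 1)
  expect_equal(only2$k, 2L)
  expect_error(select_k(X, integer(0)), "empty candidate")
})

test_that("tsne embeds separable blobs recoverably and deterministically", {
  set.seed(9)
  X <- rbind(matrix(stats::rnorm(100 * 5), 100, 5),
             matrix(stats::rnorm(100 * 5) + 8, 100, 5))
  emb <- tsne_embed(X, perplexity = 20, seed = 3)
  expect_equal(dim(emb), c(200L, 2L))
  a <- kmeans_cluster(emb, 2, seed = 1)
  truth <- rep(1:2, each = 100)
  agree <- max(mean((a$labels + 1L) == truth), mean((2L - a$labels) == truth))
  expect_gte(agree, 0.95)
  expect_identical(tsne_embed(X, perplexity = 20, seed = 3), emb)
  expect_error(tsne_embed(X[1:10, ], perplexity = 5), "perplexity")
})
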