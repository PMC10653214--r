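test_that("build_constraints enumerates labeled pairs exhaustively", {
  df <- data.frame(id = paste0("m", 1:5),
                   smiles = c("C", "CC", "CCC", "CCCC", "CCCCC"),
                   t = c("ACTIVE", "ACTIVE", "INACTIVE", "INACTIVE",
                         "UNLABELED"))
  cons <- build_constraints(df, "t", max_pairs = Inf)
  # independent enumeration: C(4,2) = 6 pairs among the 4 labeled records
  expect_equal(nrow(cons), 6L)
  expect_equal(sum(cons$relation == "SIMILAR"), 2L)      # A-A and I-I
  expect_equal(sum(cons$relation == "DISSIMILAR"), 4L)   # 2 x 2
  expect_false(5L %in% c(cons$i, cons$j))                # unlabeled excluded
  expect_true(all(cons$i < cons$j))
})

test_that("build_constraints fails without both label classes and caps pairs", {
  df <- data.frame(id = paste0("m", 1:3), smiles = c("C", "CC", "CCC"),
                   t = rep("UNLABELED", 3))
  expect_error(build_constraints(df, "t"), "insufficient labels")
  df$t <- c("ACTIVE", "ACTIVE", "UNLABELED")
  expect_error(build_constraints(df, "t"), "insufficient labels")

  df2 <- data.frame(id = paste0("m", 1:20), smiles = rep("CC", 20),
                    t = rep(c("ACTIVE", "INACTIVE"), 10))
  capped <- build_constraints(df2, "t", max_pairs = 40L, seed = 3)
  expect_lte(nrow(capped), 40L)
  expect_equal(sum(capped$relation == "SIMILAR"), 20L)   # balanced halves
  expect_identical(capped, build_constraints(df2, "t", max_pairs = 40L, seed = 3))
  expect_false(identical(capped,
                         build_constraints(df2, "t", max_pairs = 40L, seed = 4)))
})

test_that("null update leaves the metric Euclidean; epochs must be >= 1", {
  tc <- two_clouds(n = 40, d = 6)
  rec <- data.frame(id = seq_len(40), smiles = "C", t = tc$labels)
  cons <- build_constraints(rec, "t", max_pairs = 100L, seed = 1)
  expect_error(fit_metric(tc$X, cons, epochs = 0), "epochs")
  m <- fit_metric(tc$X, cons, d_out = 6, learning_rate = 0, epochs = 1,
                  init = "identity")
  expect_equal(m$L, diag(6))
  expect_equal(metric_distance(m, tc$X[1, ], tc$X[2, ]),
               sqrt(sum((tc$X[1, ] - tc$X[2, ])^2)))
})

test_that("two-cloud recovery: learned metric shrinks the distance ratio", {
  tc <- two_clouds(n = 200, d = 10, sep = 3, seed = 7)
  rec <- data.frame(id = seq_len(200), smiles = "C", t = tc$labels)
  cons <- build_constraints(rec, "t", max_pairs = 600L, seed = 1)
  ratio_of <- function(L) {
    E <- tc$X %*% t(L)
    d <- as.matrix(stats::dist(E))
    same <- outer(tc$labels, tc$labels, "==")
    diag(same) <- NA
    mean(d[same & !is.na(same)]) / mean(d[!same & !is.na(same)])
  }
  m <- fit_metric(tc$X, cons, d_out = 5, epochs = 50, seed = 2)
  expect_lt(ratio_of(m$L), ratio_of(diag(1, 5, 10)))
  expect_lte(m$loss_trace[length(m$loss_trace)], m$loss_trace[1])
})

test_that("transform is the linear map it claims to be", {
  tc <- two_clouds(n = 30, d = 8)
  rec <- data.frame(id = seq_len(30), smiles = "C", t = tc$labels)
  cons <- build_constraints(rec, "t", max_pairs = 50L, seed = 1)
  m <- fit_metric(tc$X, cons, d_out = 4, epochs = 5, seed = 1)

  E <- metric_transform(m, tc$X)
  expect_equal(dim(E), c(30L, 4L))
  # quadratic-form oracle: ||L(x-y)|| == sqrt((x-y)' M (x-y)), M = L'L
  M <- t(m$L) %*% m$L
  for (pair in list(c(1, 2), c(5, 17), c(30, 3))) {
    v <- tc$X[pair[1], ] - tc$X[pair[2], ]
    expect_equal(sqrt(sum((E[pair[1], ] - E[pair[2], ])^2)),
                 sqrt(drop(t(v) %*% M %*% v)), tolerance = 1e-9)
  }
  ident <- m; ident$L <- diag(1, 8, 8); ident$d_out <- 8L
  expect_equal(metric_transform(ident, tc$X), tc$X, ignore_attr = TRUE)
  zero <- m; zero$L <- matrix(0, 4, 8)
  expect_true(all(metric_transform(zero, tc$X) == 0))
  expect_error(metric_transform(m, tc$X[, 1:5]), "dimension")
})

test_that("metric distances satisfy the pseudo-metric axioms", {
  tc <- two_clouds(n = 30, d = 8)
  rec <- data.frame(id = seq_len(30), smiles = "C", t = tc$labels)
  cons <- build_constraints(rec, "t", max_pairs = 60L, seed = 1)
  m <- fit_metric(tc$X, cons, d_out = 4, epochs = 10, seed = 1)
  set.seed(11)
  for (rep in 1:25) {
    ijk <- sample.int(30, 3L)
    x <- tc$X[ijk[1], ]; y <- tc$X[ijk[2], ]; z <- tc$X[ijk[3], ]
    expect_equal(metric_distance(m, x, x), 0)
    expect_equal(metric_distance(m, x, y), metric_distance(m, y, x))
    expect_lte(metric_distance(m, x, z),
               metric_distance(m, x, y) + metric_distance(m, y, z) + 1e-12)
  }
})

test_that("similar-only training contracts constrained distances", {
  tc <- two_clouds(n = 40, d = 6, seed = 3)
  cons <- data.frame(i = seq(1, 39, by = 2), j = seq(2, 40, by = 2),
                     relation = "SIMILAR")
  m <- fit_metric(tc$X, cons, d_out = 6, epochs = 30, learning_rate = 0.01,
                  seed = 1)
  expect_lt(m$loss_trace[length(m$loss_trace)], m$loss_trace[1])
})

test_that("fit is invariant to constraint order and bit-reproducible", {
  tc <- two_clouds(n = 60, d = 8)
  rec <- data.frame(id = seq_len(60), smiles = "C", t = tc$labels)
  cons <- build_constraints(rec, "t", max_pairs = 100L, seed = 1)
  shuffled <- cons[sample.int(nrow(cons)), ]
  m1 <- fit_metric(tc$X, cons, d_out = 4, epochs = 8, seed = 5)
  m2 <- fit_metric(tc$X, shuffled, d_out = 4, epochs = 8, seed = 5)
  expect_identical(m1$L, m2$L)
  expect_identical(m1$loss_trace, m2$loss_trace)
})

test_that("model JSON persistence round-trips exactly", {
  tc <- two_clouds(n = 30, d = 8)
  rec <- data.frame(id = seq_len(30), smiles = "C", t = tc$labels)
  cons <- build_constraints(rec, "t", max_pairs = 40L, seed = 1)
  m <- fit_metric(tc$X, cons, d_out = 3, epochs = 5, seed = 1)
  path <- tempfile(fileext = ".json")
  save_metric_model(m, path)
  back <- load_metric_model(path)
  expect_identical(back$L, m$L)
  expect_identical(back$loss_trace, m$loss_trace)
  expect_equal(back$d_in, m$d_in)
  expect_equal(back$margin, m$margin)
})

test_that("exploding steps raise a divergence error", {
  tc <- two_clouds(n = 40, d = 6)
  rec <- data.frame(id = seq_len(40), smiles = "C", t = tc$labels)
  cons <- build_constraints(rec, "t", max_pairs = 100L, seed = 1)
  expect_error(fit_metric(tc$X, cons, learning_rate = 1e6, epochs = 50,
                          seed = 1),
               "divergence|smaller learning_rate")
})
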