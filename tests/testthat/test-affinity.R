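test_that("affinity tables read, validate and round-trip", {
  path <- tempfile(fileext = ".csv")
  tab <- data.frame(id = c("a", "b", "c"), target = "CYP2C9",
                    affinity = c(-6.1, -4.9, -5.0))
  utils::write.csv(tab, path, row.names = FALSE)
  got <- read_affinity_table(path)
  expect_equal(nrow(got), 3L)
  expect_equal(got$affinity, tab$affinity)

  back <- tempfile(fileext = ".csv")
  write_affinity_table(got, back)
  expect_equal(read_affinity_table(back), got)

  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(id = "a", target = "t", affinity = "strong"),
                   bad, row.names = FALSE)
  expect_error(read_affinity_table(bad), "row")
  expect_error(read_affinity_table(tempfile()), "not found")
})

test_that("duplicate keys resolve last-wins with a warning", {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(id = c("a", "a"), target = "t",
                              affinity = c(-1, -2)), path, row.names = FALSE)
  expect_warning(got <- read_affinity_table(path), "duplicate")
  expect_equal(nrow(got), 1L)
  expect_equal(got$affinity, -2)
})

test_that("affinity_summary implements the strict threshold", {
  tab <- data.frame(id = c("a", "b"), target = "t", affinity = c(-6, -4))
  class(tab) <- c("affinity_table", "data.frame")
  s <- affinity_summary(tab, "t", threshold = -5)
  expect_equal(s$fraction_stronger, 0.5)
  expect_equal(s$mean, -5.0)
  expect_equal(s$n, 2L)

  at_thr <- data.frame(id = letters[1:3], target = "t", affinity = rep(-5, 3))
  class(at_thr) <- class(tab)
  expect_equal(affinity_summary(at_thr, "t", -5)$fraction_stronger, 0)

  expect_error(affinity_summary(tab, "other"), "empty-selection")
  sub <- affinity_summary(tab, "t", ids = c("a", "zzz"))
  expect_equal(sub$n, 1L)
  expect_equal(sub$n_missing, 1L)
})

test_that("fraction_stronger is monotone in the threshold", {
  set.seed(3)
  tab <- data.frame(id = as.character(1:200), target = "t",
                    affinity = stats::rnorm(200, -5.5, 1))
  class(tab) <- c("affinity_table", "data.frame")
  fr <- vapply(c(-4, -5, -6, -7), function(thr) {
    affinity_summary(tab, "t", thr)$fraction_stronger
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
  perm <- tab[sample.int(200), ]
  class(perm) <- class(tab)
  expect_equal(affinity_summary(perm, "t", -5), affinity_summary(tab, "t", -5))
})

test_that("generated affinities follow the planted normal model", {
  spec <- synthetic_spec(n_molecules = 400, labeled_fraction = 1,
                         affinity_model = list(mu_active = -5.77,
                                               mu_inactive = -4.5, sd = 1.0),
                         seed = 77L)
  rec <- generate_dataset(spec)
  gt <- attr(rec, "ground_truth")
  aff <- generate_affinities(rec, spec)
  # CLT bound on both group means
  for (grp in c(TRUE, FALSE)) {
    x <- aff$affinity[gt$active_true == grp]
    mu <- if (grp) -5.77 else -4.5
    expect_lt(abs(mean(x) - mu), 3 / sqrt(length(x)))
  }
  # sd -> 0 limit: degenerate draws sit at the mean
  spec0 <- synthetic_spec(n_molecules = 50, labeled_fraction = 1,
                          affinity_model = list(mu_active = -5.77,
                                                mu_inactive = -4.5,
                                                sd = 1e-12),
                          seed = 78L)
  rec0 <- generate_dataset(spec0)
  aff0 <- generate_affinities(rec0, spec0)
  gt0 <- attr(rec0, "ground_truth")
  expect_equal(aff0$affinity[gt0$active_true],
               rep(-5.77, sum(gt0$active_true)), tolerance = 1e-9)
  # round-trips through the reader
  path <- tempfile(fileext = ".csv")
  write_affinity_table(aff, path)
  expect_equal(read_affinity_table(path)$affinity, aff$affinity)
  # parameter errors
  expect_error(synthetic_spec(affinity_model = list(mu_active = -5, mu_inactive = -4, sd = 0)),
               "sd")
  expect_error(generate_affinities(rec, synthetic_spec(seed = 1)), "not set")
})
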