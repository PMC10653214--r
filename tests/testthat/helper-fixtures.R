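# Shared fixtures, generated in code (no stored data files). The small
# dataset is memoized so the RDKit subprocess is paid once per test run.

.fixture_cache <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- generate_dataset(
      synthetic_spec(n_molecules = 300, seed = 20240901L)
    )
  }
  .fixture_cache$small
}

small_fingerprints <- function() {
  if (is.null(.fixture_cache$small_fp)) {
    .fixture_cache$small_fp <- ecfp4(small_dataset())
  }
  .fixture_cache$small_fp
}

write_mol_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# two isotropic Gaussian label-clouds in d dims, separated along axis 1
two_clouds <- function(n = 400, d = 10, sep = 3, seed = 1) {
  set.seed(seed)
  lab <- rep(c("ACTIVE", "INACTIVE"), each = n / 2)
  X <- matrix(stats::rnorm(n * d), n, d)
  X[lab == "ACTIVE", 1] <- X[lab == "ACTIVE", 1] + sep
  list(X = X, labels = lab)
}

# brute-force silhouette: literal per-point double loop over the definition
silhouette_bruteforce <- function(X, labels) {
  labels <- as.integer(factor(labels))
  n <- nrow(X)
  ed <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) ed(i, j), numeric(1)))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      members <- which(labels == cl)
      b <- min(b, mean(vapply(members, function(j) ed(i, j), numeric(1))))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
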