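test_that("find_mcs recovers a shared ester core and the empty sentinel", {
  mcs <- find_mcs(c("COC(C)=O", "CCOC(C)=O"), completion_threshold = 1.0)
  expect_true(nzchar(mcs))
  # the motif must itself contain the ester linkage: every molecule matching
  # it must be an ester, and both inputs must match it
  expect_equal(match_substructure(c("COC(C)=O", "CCOC(C)=O", "CCO"), mcs),
               c(TRUE, TRUE, FALSE))
  expect_equal(find_mcs(c("C", "N")), "")
  expect_error(find_mcs("CCO"), "2 molecules")
})

test_that("find_mcs on planted-motif actives returns an ester-bearing motif", {
  rec <- small_dataset()
  gt <- attr(rec, "ground_truth")
  actives <- rec$smiles[gt$has_motif & gt$active_true]
  mcs <- find_mcs(actives, completion_threshold = 0.7, seed = 1)
  expect_true(nzchar(mcs))
  mask <- match_substructure(rec, mcs)
  # substructure-match equivalence with the planted ester motif: nothing
  # outside the ester carriers may match
  expect_true(all(!mask | gt$has_motif))
  expect_gt(sum(mask), 0.5 * sum(gt$has_motif))
})

test_that("match_substructure agrees with the subgraph-isomorphism oracle", {
  expect_true(match_substructure("COC(C)=O", "[CX3](=O)[OX2][#6]"))
  expect_false(match_substructure("CCO", "[CX3](=O)[OX2][#6]"))
  expect_error(match_substructure("CCO", "[[bogus"), "failed")
  rec <- small_dataset()
  smiles <- rec$smiles[1:100]
  for (frag in c("CC(=O)OC", "C(F)(F)C(F)(F)", "c1ccccc1")) {
    mask <- match_substructure(smiles, frag)
    oracle <- vapply(smiles, contains_subgraph, logical(1),
                     pattern_smiles = frag, USE.NAMES = FALSE)
    expect_equal(mask, oracle)
  }
})

test_that("bioactive_ratio counts labeled matches only", {
  expect_equal(bioactive_ratio(rep(TRUE, 4), rep("ACTIVE", 4))$bioactive_ratio, 1.0)
  br <- bioactive_ratio(rep(TRUE, 40),
                        c(rep("ACTIVE", 10), rep("INACTIVE", 30)))
  expect_equal(br$bioactive_ratio, 0.25)
  expect_equal(br$n_match, 40L)

  mixed <- bioactive_ratio(c(TRUE, TRUE, TRUE, FALSE),
                           c("ACTIVE", "UNLABELED", "INACTIVE", "ACTIVE"))
  expect_equal(mixed$n_match, 2L)            # the unlabeled match is excluded
  expect_equal(mixed$bioactive_ratio, 0.5)

  undef <- bioactive_ratio(c(TRUE, TRUE), c("UNLABELED", "UNLABELED"))
  expect_true(is.na(undef$bioactive_ratio))
  expect_equal(undef$n_match, 0L)

  # permutation invariance
  set.seed(1)
  mask <- stats::runif(200) < 0.3
  labs <- sample(c("ACTIVE", "INACTIVE", "UNLABELED"), 200, replace = TRUE)
  perm <- sample.int(200)
  expect_equal(bioactive_ratio(mask, labs), bioactive_ratio(mask[perm], labs[perm]))
})

test_that("planted conditional activity is recovered within binomial error", {
  set.seed(414)
  n <- 1000
  mask <- rep(TRUE, n)
  labs <- ifelse(stats::runif(n) < 0.9, "ACTIVE", "INACTIVE")
  br <- bioactive_ratio(mask, labs)
  expect_lt(abs(br$bioactive_ratio - 0.9), 0.05)
})

test_that("detect_ester separates esters from acids, consistently", {
  expect_true(detect_ester("COC(C)=O"))
  expect_false(detect_ester("CC(=O)O"))
  rec <- small_dataset()
  expect_equal(detect_ester(rec),
               match_substructure(rec, "[CX3](=O)[OX2][#6]"))
  expect_equal(detect_ester(rec),
               vapply(rec$smiles, has_ester_linkage, logical(1),
                      USE.NAMES = FALSE))
})

test_that("cluster_motif_report recovers a planted motif from a pure cluster", {
  rec <- small_dataset()
  gt <- attr(rec, "ground_truth")
  # artificial assignment: cluster 0 = motif actives, cluster 1 = the rest
  labels <- ifelse(gt$has_motif & rec$CYP2C9 == "ACTIVE", 0L, 1L)
  assignment <- list(labels = labels, k = 2L, silhouette = NA_real_)
  rep1 <- cluster_motif_report(rec, assignment, "CYP2C9", top_clusters = 1L,
                               completion_threshold = 0.7)
  expect_equal(nrow(rep1), 1L)
  mask <- match_substructure(rec, rep1$smarts[1])
  expect_true(all(!mask | gt$has_motif))
  expect_gt(rep1$n_match[1], 0L)
})

test_that("report edge cases: no actives, skipped clusters, sort order", {
  rec <- small_dataset()
  rec$CYP2C9 <- "INACTIVE"
  assignment <- list(labels = rep(0:1, length.out = nrow(rec)), k = 2L)
  out <- cluster_motif_report(rec, assignment, "CYP2C9")
  expect_equal(nrow(out), 0L)
  expect_match(attr(out, "notices"), "no ACTIVE")

  rec2 <- small_dataset()
  assignment2 <- list(labels = seq_len(nrow(rec2)) %% 5L, k = 5L)
  out2 <- cluster_motif_report(rec2, assignment2, "CYP2C9",
                               top_clusters = 5L,
                               completion_threshold = 0.7)
  if (nrow(out2) > 1L) {
    expect_true(all(diff(out2$bioactive_ratio) <= 1e-12))
  }
})
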