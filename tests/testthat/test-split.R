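# build a fake bit-fingerprint feature_matrix from a list of bit-index sets
.fake_fp <- function(sets, n_bits = 256) {
  vals <- matrix(0, length(sets), n_bits,
                 dimnames = list(NULL, paste0("b", seq_len(n_bits))))
  for (i in seq_along(sets)) vals[i, sets[[i]]] <- 1
  feature_matrix(vals, "morgan_bits", list(radius = 3, n_bits = n_bits),
                 row_keys = paste0("mol", seq_along(sets)))
}

test_that("similarity groups are transitive connected components", {
  # sliding windows: T(A,B) = T(B,C) = 90/110 = 0.818, T(A,C) = 80/120 = 0.667
  fp <- .fake_fp(list(1:100, 11:110, 21:120))
  g <- similarity_groups(NULL, threshold = 0.8, fp = fp)
  expect_length(unique(g), 1L)   # one group via the B bridge
  g2 <- similarity_groups(NULL, threshold = 0.9, fp = fp)
  expect_length(unique(g2), 3L)  # all similarities < 0.9
  # threshold 1: identical fingerprints only
  fp3 <- .fake_fp(list(1:10, 1:10, 5:20))
  g3 <- similarity_groups(NULL, threshold = 1, fp = fp3)
  expect_equal(g3[1], g3[2])
  expect_length(unique(g3), 2L)
})

test_that("grouped stratified holdout hits exact targets in the divisible singleton case", {
  labels <- rep(0:3, each = 25)
  plan <- grouped_stratified_holdout(labels, seq_along(labels), 0.2, seed = 9)
  expect_equal(sum(plan$holdout), 20)
  expect_true(all(table(labels[plan$holdout]) == 5))
  plan2 <- grouped_stratified_holdout(labels, seq_along(labels), 0.2, seed = 9)
  expect_identical(plan$holdout, plan2$holdout)
})

test_that("groups are atomic and oversized groups are rejected", {
  labels <- rep(0:3, each = 25)
  groups <- c(rep(1L, 30), 31:100)  # one group holds 30% of records
  plan <- grouped_stratified_holdout(labels, groups, 0.2, seed = 2)
  side <- unique(plan$holdout[groups == 1L])
  expect_length(side, 1L)
  expect_error(grouped_stratified_holdout(labels, rep(1L, 100), 0.2),
               "group")
  expect_error(grouped_stratified_holdout(labels, groups, 1.2), "test_fraction")
})

test_that("repeated grouped k-fold partitions every repeat", {
  labels <- rep(0:3, 25)
  folds <- repeated_grouped_stratified_kfold(labels, seq_along(labels),
                                             n_folds = 10, n_repeats = 3,
                                             seed = 4)
  expect_equal(dim(folds), c(100L, 3L))
  for (r in 1:3) {
    expect_true(all(table(folds[, r]) == 10))
    expect_setequal(unique(folds[, r]), 1:10)
  }
  expect_false(identical(folds[, 1], folds[, 2]))
  expect_error(repeated_grouped_stratified_kfold(labels, rep(1:3, length.out = 100),
                                                 n_folds = 10), "exceeds")
})

test_that("holdout and folds never separate similar molecules (generator data)", {
  mols <- fixture_molecules(80, seed = 31)
  fp <- fingerprint(mols, "morgan_bits")
  groups <- similarity_groups(mols, 0.8, fp = fp)
  ds <- fixture_dataset(80, seed = 31)
  plan <- grouped_stratified_holdout(ds$true_labels, groups, 0.2, seed = 3)
  expect_equal(nrow(leakage_audit(fp, plan$holdout, 0.8)), 0L)
  folds <- repeated_grouped_stratified_kfold(ds$true_labels, groups,
                                             n_folds = 4, n_repeats = 2,
                                             seed = 5)
  for (r in 1:2) expect_equal(nrow(leakage_audit(fp, folds[, r], 0.8)), 0L)
  # stratification tolerance on singleton-dominated data
  p_global <- tabulate(ds$true_labels + 1L, 4) / 80
  p_test <- tabulate(ds$true_labels[plan$holdout] + 1L, 4) / sum(plan$holdout)
  expect_true(all(abs(p_test - p_global) <= 0.15))
})
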