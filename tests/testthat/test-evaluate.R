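test_that("macro MSE reproduces worked values and excludes absent classes", {
  expect_equal(as.numeric(macro_mse(0:3, 0:3)), 0)
  expect_equal(as.numeric(macro_mse(0:3, rep(3L, 4))), 3.5)  # (9+4+1+0)/4
  m <- macro_mse(c(0, 0, 2, 2), c(1, 1, 2, 2))
  expect_equal(as.numeric(m), 0.5)                            # (1+0)/2
  expect_equal(attr(m, "n_classes"), 2L)
  expect_error(macro_mse(integer(0), integer(0)), "empty")
})

test_that("macro MSE agrees with a per-class brute-force oracle", {
  set.seed(10)
  for (i in 1:50) {
    n <- sample(8:60, 1)
    yt <- sample(0:3, n, replace = TRUE)
    yp <- sample(0:3, n, replace = TRUE)
    expect_equal(as.numeric(macro_mse(yt, yp)), oracle_macro_mse(yt, yp))
  }
})

test_that("macro equals micro MSE on exactly balanced classes", {
  yt <- rep(0:3, each = 6)
  set.seed(3)
  yp <- sample(0:3, 24, replace = TRUE)
  expect_equal(as.numeric(macro_mse(yt, yp)), micro_mse(yt, yp))
})

test_that("the evaluation report populates consistent fields", {
  ev <- evaluation_report(c(0, 0, 1, 1), c(0, 1, 1, 1))
  expect_equal(unname(ev$confusion_normalized[1, ]), c(0.5, 0.5, 0, 0))
  expect_equal(ev$per_class$f1[1], 2 / 3)
  expect_equal(sum(ev$confusion), ev$n_test)
  expect_equal(ev$micro_mse,
               sum(ev$confusion * outer(0:3, 0:3, function(i, j) (i - j)^2)) /
                 ev$n_test)
  # perfect predictions
  evp <- evaluation_report(0:3, 0:3)
  expect_equal(unname(diag(evp$confusion_normalized)), rep(1, 4))
  expect_equal(evp$f1_macro, 1)
  expect_equal(evp$micro_mse, 0)
  # bad probability rows are rejected
  expect_error(evaluation_report(0:3, 0:3, matrix(0.3, 4, 4)), "sum to 1")
})

test_that("chance-level probabilities give ROC AUC near 0.5", {
  set.seed(11)
  n <- 2000
  yt <- sample(0:3, n, replace = TRUE)
  p <- matrix(rexp(n * 4), n, 4)
  p <- p / rowSums(p)
  ev <- evaluation_report(yt, max.col(p) - 1L, p)
  expect_lt(abs(ev$roc_auc - 0.5), 0.05)
})

test_that("the 5x2cv t statistic follows its formula and conventions", {
  # p_1^(1) = 0.1 and s_i^2 = (p1 - p2)^2 / 2 = 0.01 per replication
  # -> t = 0.1 / sqrt(mean(s_i^2)) = 0.1 / 0.1 = 1
  p1 <- c(0.1, 0.2, 0.15, 0.05, 0.1)
  diffs <- unname(cbind(p1, p1 - sqrt(0.02)))
  res <- paired_ttest_from_diffs(diffs)
  expect_equal(res$t_statistic, 1)
  expect_equal(res$dof, 5L)
  expect_equal(res$p_value, 2 * pt(-1, 5))
  # negating all differences negates t, p unchanged
  resn <- paired_ttest_from_diffs(-diffs)
  expect_equal(resn$t_statistic, -1)
  expect_equal(resn$p_value, res$p_value)
  # all-zero differences
  z <- paired_ttest_from_diffs(matrix(0, 5, 2))
  expect_equal(z$t_statistic, 0)
  expect_equal(z$p_value, 1)
  # zero variance, nonzero first difference
  inf <- paired_ttest_from_diffs(matrix(0.2, 5, 2))
  expect_true(inf$infinite)
  expect_equal(inf$p_value, 0)
})

test_that("identical learners give t = 0, p = 1 on real folds", {
  prob <- make_threshold_problem(160, seed = 14)
  la <- function(Xtr, ytr, Xte)
    predict_ordinal(train_direct(Xtr, ytr, model_spec("logistic", seed = 3)),
                    Xte)$code
  res <- paired_ttest_5x2cv(la, la, prob$X, prob$y, seed = 5)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(dim(res$score_pairs), c(5L, 2L))
})

test_that("ordinal-vs-continuous comparison summarizes ratings per code", {
  codes <- 0:3
  ratings <- c(1, 5, 20, 80)  # strictly increasing with the code
  res <- ordinal_vs_continuous(codes, ratings)
  expect_equal(as.numeric(res$rank_correlation), 1, tolerance = 1e-8)
  res2 <- ordinal_vs_continuous(c(0, 0, 3, 3), c(0, 0, 100, 100))
  expect_equal(res2$per_code$mean, c(0, 100))
  # independent shuffling gives near-zero correlation
  set.seed(12)
  codes3 <- sample(0:3, 1000, replace = TRUE)
  r3 <- ordinal_vs_continuous(codes3, runif(1000))
  expect_lt(abs(as.numeric(r3$rank_correlation)), 0.08)
  # constant input flagged undefined
  rc <- ordinal_vs_continuous(rep(2L, 5), 1:5)
  expect_true(is.na(rc$rank_correlation))
  expect_true(attr(rc$rank_correlation, "undefined"))
})
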