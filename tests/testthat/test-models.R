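test_that("balanced class weights follow n / (K * n_k)", {
  w <- class_weights(rep(0:3, each = 10))
  expect_true(all(w == 1))
  y <- rep(0:3, c(40, 12, 100, 48))
  w2 <- class_weights(y)
  expect_equal(unname(w2["1"]), 200 / (4 * 12))  # ~4.17 for the minority
  expect_equal(unname(w2["2"]), 200 / (4 * 100))
  expect_error(class_weights(c(0, 1, 2), classes = 0:3), "absent")
})

test_that("every direct algorithm fits a separable problem and predicts well", {
  prob <- make_threshold_problem(300, seed = 1)
  for (alg in c("logistic", "random_forest", "xgb", "mlp", "coral")) {
    m <- train_direct(prob$X, prob$y, model_spec(alg, seed = 7))
    pr <- predict_ordinal(m, prob$X)
    expect_gte(mean(pr$code == prob$y), 0.95)
    expect_true(all(pr$code %in% 0:3))
    expect_true(all(abs(rowSums(pr$prob) - 1) < 1e-6))
  }
})

test_that("the direct approach requires all four categories", {
  prob <- make_threshold_problem(200, seed = 2)
  y <- pmin(prob$y, 2L)
  expect_error(train_direct(prob$X, y, model_spec("logistic")), "class")
})

test_that("prediction validates feature compatibility", {
  prob <- make_threshold_problem(200, seed = 3)
  m <- train_direct(prob$X, prob$y, model_spec("random_forest"))
  Xbad <- prob$X
  colnames(Xbad) <- c("other", "junk")
  expect_error(predict_ordinal(m, Xbad), "feature")
  expect_error(predict_ordinal(m, prob$X[, 1, drop = FALSE]), "feature")
})

test_that("CORAL cumulative probabilities are rank-consistent for any input", {
  prob <- make_threshold_problem(200, seed = 4)
  m <- train_coral(prob$X, prob$y, model_spec("coral", seed = 11))
  set.seed(5)
  Xr <- cbind(f = runif(500, -10, 10), junk = rnorm(500, sd = 5))
  cum <- coral_cumulative_probs(m, Xr)
  expect_true(all(cum[, 1] >= cum[, 2] & cum[, 2] >= cum[, 3]))
})

test_that("the CORAL decision rule counts cumulative probabilities above 0.5", {
  # construct a linear-body fit whose cumulative probabilities at x = 0 are
  # exactly (0.9, 0.7, 0.2)
  lgt <- function(p) log(p / (1 - p))
  sp_inv <- function(y) log(exp(y) - 1)  # inverse softplus
  fit <- list(params = list(w = 0,
                            b1 = lgt(0.9),
                            delta = c(sp_inv(lgt(0.9) - lgt(0.7)),
                                      sp_inv(lgt(0.7) - lgt(0.2)))),
              hidden = 0L, K = 4L)
  model <- structure(list(algorithm = "coral", fit = fit, classes = 0:3,
                          scaling = NULL, feature_names = "f",
                          seed = 1L), class = "odor_model")
  X <- matrix(0, 1, 1, dimnames = list(NULL, "f"))
  pr <- predict_ordinal(model, X)
  expect_equal(as.numeric(coral_cumulative_probs(model, X)), c(0.9, 0.7, 0.2),
               tolerance = 1e-8)
  expect_identical(pr$code, 2L)  # two cumulative probabilities above 0.5
  # per-class probabilities are adjacent differences, renormalized
  expect_equal(unname(pr$prob[1, ]), c(0.1, 0.2, 0.5, 0.2), tolerance = 1e-8)
  # all-below and all-above corner cases
  fit$params$b1 <- lgt(0.4)
  fit$params$delta <- rep(sp_inv(0.1), 2)
  model$fit <- fit
  expect_identical(predict_ordinal(model, X)$code, 0L)
  fit$params$b1 <- lgt(0.99)
  fit$params$delta <- rep(sp_inv(lgt(0.99) - lgt(0.95)), 2)
  model$fit <- fit
  expect_identical(predict_ordinal(model, X)$code, 3L)
})

test_that("CORAL inverts its predictions when the labels are inverted", {
  prob <- make_threshold_problem(300, seed = 6)
  m1 <- train_coral(prob$X, prob$y, model_spec("coral", seed = 13))
  m2 <- train_coral(prob$X, 3L - prob$y, model_spec("coral", seed = 13))
  p1 <- predict_ordinal(m1, prob$X)$code
  p2 <- predict_ordinal(m2, prob$X)$code
  expect_gte(mean(p2 == 3L - p1), 0.9)
})

test_that("balanced weighting raises minority recall on imbalanced data", {
  set.seed(8)
  recalls <- vapply(1:5, function(rep) {
    n <- 400
    x <- c(rnorm(n * 0.9, 0), rnorm(n * 0.1, 1.5))
    y <- rep(c(0L, 1L), c(n * 0.9, n * 0.1))
    X <- cbind(f = x, g = rnorm(n))
    sp_b <- model_spec("logistic", seed = rep)
    sp_u <- model_spec("logistic", class_weighting = "none", seed = rep)
    mb <- odorstrength:::.train_classifier(X, y, sp_b, classes = 0:1)
    mu <- odorstrength:::.train_classifier(X, y, sp_u, classes = 0:1)
    rb <- mean(predict_ordinal(mb, X)$code[y == 1] == 1)
    ru <- mean(predict_ordinal(mu, X)$code[y == 1] == 1)
    rb - ru
  }, numeric(1))
  expect_gt(mean(recalls), 0)
})

test_that("the hierarchical model composes its two stages correctly", {
  prob <- make_threshold_problem(400, seed = 9)
  hm <- train_hierarchical(prob$X, prob$y, model_spec("random_forest"),
                           model_spec("random_forest"))
  pr <- predict_hierarchical(hm, prob$X)
  expect_gte(mean(pr$code == prob$y), 0.95)
  # stage-1 odorless verdict forces code 0
  p1 <- odorstrength:::.predict_prob(hm$stage1, prob$X)
  expect_true(all(pr$code[p1[, "1"] <= 0.5] == 0L))
  # degenerate label sets are rejected
  expect_error(train_hierarchical(prob$X, rep(0L, 400),
                                  model_spec("logistic"), model_spec("logistic")),
               "odorless")
  y2 <- prob$y; y2[y2 == 3L] <- 2L
  expect_error(train_hierarchical(prob$X, y2, model_spec("logistic"),
                                  model_spec("logistic")), "missing")
})

test_that("ensemble averaging rounds half away from zero", {
  prob <- make_threshold_problem(150, seed = 10)
  # the documented rounding rule: (2,2,3) -> 2.33 -> 2; (1,2) -> 1.5 -> 2
  round_half_away <- function(x) pmin(pmax(floor(x + 0.5), 0L), 3L)
  expect_equal(round_half_away(mean(c(2, 2, 3))), 2)
  expect_equal(round_half_away(mean(c(1, 2))), 2)
  # identical members reproduce any member
  ms <- list(train_direct(prob$X, prob$y, model_spec("xgb", seed = 2)),
             train_direct(prob$X, prob$y, model_spec("xgb", seed = 2)))
  e <- ensemble_predict(ms, prob$X)
  expect_identical(e$code, predict_ordinal(ms[[1]], prob$X)$code)
  expect_equal(ncol(e$members), 2L)
  expect_error(ensemble_predict(list(ms[[1]]), prob$X), "2")
})

test_that("mixed-encoder ensembles are rejected", {
  prob <- make_threshold_problem(120, seed = 12)
  fmA <- feature_matrix(prob$X, "descriptors", row_keys = as.character(1:120))
  fmB <- feature_matrix(prob$X, "morgan_bits", row_keys = as.character(1:120))
  m1 <- train_direct(fmA, prob$y, model_spec("xgb"))
  m2 <- train_direct(fmB, prob$y, model_spec("xgb"))
  expect_error(ensemble_predict(list(m1, m2), fmA), "encoder")
})

test_that("budgeted tuning returns the best completed trial and a full ledger", {
  prob <- make_threshold_problem(160, seed = 13)
  res <- tune("xgb",
              list(max_depth = list(low = 2, high = 6, integer = TRUE),
                   eta = list(low = 0.05, high = 0.3, log = TRUE),
                   nrounds = c(40L)),
              prob$X, prob$y, budget = 5, n_folds = 3, n_repeats = 2, seed = 3)
  expect_s3_class(res$best_spec, "model_spec")
  expect_equal(nrow(res$trials), 5L)
  done <- res$trials[!res$trials$pruned, ]
  expect_equal(res$best_score, min(done$score))
  expect_error(tune("xgb", list(nrounds = c(40L)), prob$X, prob$y, budget = 0),
               "budget")
})
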