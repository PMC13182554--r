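test_that("attribution satisfies local accuracy and ignores unused features", {
  set.seed(20)
  X <- cbind(x1 = rnorm(8), x2 = rnorm(8))
  B <- cbind(x1 = rnorm(15), x2 = rnorm(15))
  f <- function(M) 2 * M[, "x1"]
  at <- attribute(f, X, B, n_perm = 4, n_background = 15, seed = 1)
  # a feature the model never touches gets exactly zero
  expect_true(all(at$values[, "x2"] == 0))
  # telescoping makes local accuracy exact
  expect_equal(at$base_value + rowSums(at$values), f(X), tolerance = 1e-12)
  # closed form for a linear model with the full background
  expect_equal(unname(at$values[, "x1"]), 2 * (X[, "x1"] - mean(B[, "x1"])),
               tolerance = 1e-12)
  # constant model: all attributions zero
  atc <- attribute(function(M) rep(1.5, nrow(M)), X, B, n_perm = 2,
                   n_background = 5, seed = 2)
  expect_true(all(atc$values == 0))
})

test_that("tree-path attributions concentrate on the splitting feature", {
  prob <- make_threshold_problem(300, seed = 21)
  m <- train_direct(prob$X, prob$y, model_spec("xgb", seed = 1))
  at <- attribute(m, prob$X[1:30, ], prob$X)
  expect_identical(at$estimator, "treeshap_path")
  expect_gt(mean(abs(at$values[, "f"])), 10 * mean(abs(at$values[, "junk"])))
})

test_that("sampling attribution of a fitted model keeps local accuracy", {
  prob <- make_threshold_problem(200, seed = 22)
  m <- train_direct(prob$X, prob$y, model_spec("random_forest", seed = 2))
  Xe <- prob$X[1:10, ]
  at <- attribute(m, Xe, prob$X[1:40, ], n_perm = 3, n_background = 8, seed = 3)
  f <- odorstrength:::.attribution_fun(m)
  expect_equal(at$base_value + rowSums(at$values), f(Xe), tolerance = 1e-10)
})

test_that("correlated features group together; independent features stay apart", {
  set.seed(23)
  base <- rnorm(400)
  X <- cbind(a = base, b = base + rnorm(400, sd = 1e-6),
             c = rnorm(400), d = rnorm(400), e = rnorm(400))
  gr <- correlation_grouping(X, threshold_grid = c(0.5, 0.75, 0.9))
  expect_equal(gr$group[["a"]], gr$group[["b"]])
  expect_length(unique(gr$group[c("c", "d", "e")]), 3L)
  # returned threshold is the silhouette-curve argmax
  sc <- gr$silhouette_curve
  expect_equal(gr$threshold, sc$threshold[which.max(sc$score)])
  # independent features at 0.75: all singletons
  Xi <- matrix(rnorm(500 * 6), 500, 6, dimnames = list(NULL, letters[1:6]))
  gi <- correlation_grouping(Xi, threshold_grid = 0.75)
  expect_equal(gi$n_groups, 6L)
  # zero-variance features land in the degenerate group 0
  Xz <- cbind(X, const = rep(1, 400))
  gz <- correlation_grouping(Xz, threshold_grid = c(0.5, 0.75))
  expect_equal(gz$group[["const"]], 0L)
})

test_that("group importance is additive and conserved under regrouping", {
  set.seed(24)
  at <- structure(list(values = matrix(rnorm(60), 10, 6,
                                       dimnames = list(NULL, letters[1:6])),
                       base_value = 0, estimator = "test", n_background = 1),
                  class = "attribution_matrix")
  singletons <- structure(list(group = setNames(1:6, letters[1:6]),
                               threshold = 0.75, n_groups = 6),
                          class = "feature_grouping")
  merged <- structure(list(group = setNames(c(1, 1, 2, 2, 3, 3), letters[1:6]),
                           threshold = 0.75, n_groups = 3),
                      class = "feature_grouping")
  gs <- group_importance(at, singletons)
  gm <- group_importance(at, merged)
  # singleton ranking equals the feature ranking
  fi <- sort(colMeans(abs(at$values)), decreasing = TRUE)
  expect_identical(gs$groups$members, names(fi))
  # merged importance equals the sum of parts; total is conserved
  expect_equal(gm$groups$importance[gm$groups$members == "a;b"],
               sum(fi[c("a", "b")]))
  expect_equal(sum(gs$groups$importance), sum(gm$groups$importance))
  # uncovered features are an error
  bad <- structure(list(group = setNames(1:5, letters[1:5]), threshold = 0.75,
                        n_groups = 5), class = "feature_grouping")
  expect_error(group_importance(at, bad), "cover")
})
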