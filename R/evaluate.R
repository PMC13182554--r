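# Evaluation: macro-averaged ordinal MSE and companion metrics, the
# normalized confusion matrix, the 5x2cv paired t-test, and the
# ordinal-vs-continuous rating comparison.

#' Macro-averaged ordinal mean squared error
#'
#' \eqn{MSE_i} is the mean squared difference between predicted and true
#' codes over the records whose true class is \eqn{i}; the macro MSE is the
#' unweighted mean of \eqn{MSE_i} over the categories present in `y_true`,
#' so each strength category counts equally regardless of its prevalence.
#' Categories absent from `y_true` are excluded; their number is reported in
#' the `n_classes` attribute.
#'
#' @param y_true,y_pred integer codes 0..3, equal nonempty length.
#' @return macro MSE (non-negative), with attribute `n_classes` = number of
#'   categories included.
#' @export
#' @examples
#' macro_mse(c(0, 1, 2, 3), c(3, 3, 3, 3))  # (9 + 4 + 1 + 0) / 4 = 3.5
macro_mse <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (!length(y_true)) stop("empty input")
  cls <- sort(unique(y_true))
  per <- vapply(cls, function(cc) mean((y_pred[y_true == cc] - cc)^2), numeric(1))
  structure(mean(per), n_classes = length(cls))
}

#' Micro (pooled) ordinal mean squared error
#'
#' @inheritParams macro_mse
#' @return pooled mean squared code difference.
#' @export
micro_mse <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  mean((y_pred - y_true)^2)
}

# one-vs-rest macro-averaged ROC AUC from per-class probabilities
.roc_auc_ovr <- function(y_true, prob) {
  aucs <- c()
  for (k in seq_len(ncol(prob))) {
    cls <- k - 1L
    truth <- y_true == cls
    if (all(truth) || !any(truth)) next
    r <- pROC::roc(response = truth, predictor = prob[, k], quiet = TRUE,
                   direction = "<", levels = c(FALSE, TRUE))
    aucs <- c(aucs, as.numeric(pROC::auc(r)))
  }
  if (length(aucs)) mean(aucs) else NA_real_
}

#' Full evaluation report
#'
#' Computes the macro and micro MSE, macro/micro F1, one-vs-rest
#' macro-averaged ROC AUC (when per-class probabilities are supplied), the
#' 4x4 confusion matrix with row-wise normalization by true-class counts,
#' and per-class precision/recall/F1/MSE.
#'
#' @param y_true,y_pred integer codes 0..3.
#' @param probabilities optional n x 4 matrix of class probabilities with
#'   rows summing to 1 (tolerance 1e-6).
#' @return object of class `evaluation_report`.
#' @export
evaluation_report <- function(y_true, y_pred, probabilities = NULL) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  if (!is.null(probabilities)) {
    probabilities <- as.matrix(probabilities)
    stopifnot(nrow(probabilities) == length(y_true), ncol(probabilities) == .K)
    if (any(abs(rowSums(probabilities) - 1) > 1e-6))
      stop("probability rows must sum to 1 within 1e-6")
  }
  lev <- 0:(.K - 1)
  conf <- unclass(table(factor(y_true, levels = lev),
                        factor(y_pred, levels = lev)))
  row_tot <- rowSums(conf)
  conf_norm <- conf / ifelse(row_tot > 0, row_tot, 1)
  per_class <- do.call(rbind, lapply(lev, function(cc) {
    tp <- conf[cc + 1, cc + 1]
    fp <- sum(conf[, cc + 1]) - tp
    fn <- sum(conf[cc + 1, ]) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else if (tp + fp + fn > 0) 0 else NA_real_
    mse_c <- if (any(y_true == cc)) mean((y_pred[y_true == cc] - cc)^2)
             else NA_real_
    data.frame(class = cc, precision = prec, recall = rec, f1 = f1,
               mse = mse_c, n = sum(y_true == cc))
  }))
  present <- per_class$n > 0
  structure(list(
    macro_mse = as.numeric(macro_mse(y_true, y_pred)),
    micro_mse = micro_mse(y_true, y_pred),
    f1_macro = mean(per_class$f1[present]),
    f1_micro = mean(y_true == y_pred),
    roc_auc = if (!is.null(probabilities)) .roc_auc_ovr(y_true, probabilities)
              else NA_real_,
    confusion = conf,
    confusion_normalized = conf_norm,
    per_class = per_class,
    n_test = length(y_true)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report> n = %d | macro MSE %.3f | micro MSE",
                     " %.3f | F1 macro %.3f | accuracy %.3f | ROC AUC %s\n"),
              x$n_test, x$macro_mse, x$micro_mse, x$f1_macro, x$f1_micro,
              ifelse(is.na(x$roc_auc), "-", sprintf("%.3f", x$roc_auc))))
  invisible(x)
}

#' 5x2cv paired t-test between two learners
#'
#' Five replications of 2-fold cross-validation (grouped and stratified via
#' the split module). Per replication \eqn{i} and fold \eqn{j} the score
#' difference \eqn{p_i^{(j)}} between the learners is recorded;
#' \eqn{s_i^2 = (p_i^{(1)} - \bar p_i)^2 + (p_i^{(2)} - \bar p_i)^2} and
#' \eqn{t = p_1^{(1)} / \sqrt{\frac{1}{5}\sum_i s_i^2}} with 5 degrees of
#' freedom, two-sided.
#'
#' Degenerate conventions: when every difference is zero the result is
#' t = 0, p = 1; when the variance is zero but the first difference is not,
#' the result is flagged infinite (`infinite = TRUE`, p = 0).
#'
#' @param learner_a,learner_b functions `(X_train, y_train, X_test)` that
#'   return predicted codes for `X_test`.
#' @param features numeric feature matrix for the whole dataset.
#' @param labels integer codes 0..3.
#' @param groups similarity group ids (default: singletons).
#' @param metric scoring function `(y_true, y_pred) -> numeric`; default
#'   [macro_mse()].
#' @param seed integer seed.
#' @return object of class `paired_ttest_result`: `t_statistic`, `p_value`,
#'   `dof` (= 5), `score_pairs` (5x2 matrix of differences), `infinite`.
#' @export
paired_ttest_5x2cv <- function(learner_a, learner_b, features, labels,
                               groups = seq_along(labels),
                               metric = function(yt, yp) as.numeric(macro_mse(yt, yp)),
                               seed = 1L) {
  diffs <- matrix(NA_real_, nrow = 5, ncol = 2)
  for (i in 1:5) {
    folds <- repeated_grouped_stratified_kfold(labels, groups, n_folds = 2L,
                                               n_repeats = 1L,
                                               seed = seed + 17L * i)[, 1]
    for (j in 1:2) {
      te <- folds == j
      pa <- learner_a(features[!te, , drop = FALSE], labels[!te],
                      features[te, , drop = FALSE])
      pb <- learner_b(features[!te, , drop = FALSE], labels[!te],
                      features[te, , drop = FALSE])
      diffs[i, j] <- metric(labels[te], pa) - metric(labels[te], pb)
    }
  }
  out <- paired_ttest_from_diffs(diffs)
  out$seed <- seed
  out
}

#' @rdname paired_ttest_5x2cv
#' @param diffs 5 x 2 matrix of per-replication, per-fold score differences.
#' @export
paired_ttest_from_diffs <- function(diffs) {
  stopifnot(is.matrix(diffs), nrow(diffs) == 5, ncol(diffs) == 2)
  s2 <- rowSums((diffs - rowMeans(diffs))^2)
  denom <- sqrt(mean(s2))
  if (denom == 0) {
    if (diffs[1, 1] == 0) {
      res <- list(t_statistic = 0, p_value = 1, infinite = FALSE)
    } else {
      res <- list(t_statistic = sign(diffs[1, 1]) * Inf, p_value = 0,
                  infinite = TRUE)
    }
  } else {
    t_stat <- unname(diffs[1, 1] / denom)
    res <- list(t_statistic = t_stat,
                p_value = 2 * stats::pt(-abs(t_stat), df = 5),
                infinite = FALSE)
  }
  structure(c(res, list(dof = 5L, score_pairs = diffs)),
            class = "paired_ttest_result")
}

#' @export
print.paired_ttest_result <- function(x, ...) {
  cat(sprintf("<paired_ttest_result> t = %.3f, p = %.4f (5x2cv, 5 dof)\n",
              x$t_statistic, x$p_value))
  invisible(x)
}

#' Compare ordinal predictions with continuous intensity ratings
#'
#' Rank (Spearman) correlation between predicted ordinal codes and
#' continuous ratings, plus the mean and standard deviation of the ratings
#' within each predicted code.
#'
#' @param pred_codes integer codes 0..3.
#' @param ratings numeric ratings (e.g. perceived intensity 0-100).
#' @return list with `rank_correlation` (`NA` with `undefined = TRUE`
#'   attribute for constant input), and `per_code` summary data.frame.
#' @export
ordinal_vs_continuous <- function(pred_codes, ratings) {
  stopifnot(length(pred_codes) == length(ratings))
  rc <- if (length(unique(pred_codes)) < 2 || length(unique(ratings)) < 2)
    structure(NA_real_, undefined = TRUE)
  else suppressWarnings(stats::cor(pred_codes, ratings, method = "spearman"))
  per_code <- do.call(rbind, lapply(sort(unique(pred_codes)), function(cc) {
    r <- ratings[pred_codes == cc]
    data.frame(code = cc, n = length(r), mean = mean(r),
               sd = if (length(r) > 1) stats::sd(r) else NA_real_)
  }))
  list(rank_correlation = rc, per_code = per_code)
}
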