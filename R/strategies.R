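# Prediction strategies beyond a single direct learner: the hierarchical
# (odorous-vs-odorless, then strength) two-step pipeline, the ensemble of
# direct models, and budgeted hyperparameter search with percentile pruning.

#' Train the hierarchical two-step model
#'
#' Stage 1 is a binary classifier for "does the molecule smell at all"
#' (target `1{y > 0}`) with minority-class-sensitive balanced weighting;
#' stage 2 is a 3-class strength model (codes 1..3) trained on the truly
#' odorous training records only, so no stage-1 errors propagate into
#' stage-2 training. At prediction time a record classified odorless by
#' stage 1 receives code 0 regardless of stage 2.
#'
#' @param features [feature_matrix()] or matrix.
#' @param labels integer codes 0..3.
#' @param spec1,spec2 [model_spec()]s for the two stages.
#' @return object of class `hierarchical_model`.
#' @export
train_hierarchical <- function(features, labels, spec1, spec2) {
  X <- .fm_values(features)
  labels <- as.integer(labels)
  if (all(labels == 0L)) stop("all training labels are odorless; stage 2 untrainable")
  odorous <- labels > 0L
  if (!any(!odorous)) stop("no odorless training records; stage 1 untrainable")
  missing2 <- setdiff(1:3, unique(labels[odorous]))
  if (length(missing2))
    stop("stage 2 requires classes 1..3 among odorous records; missing: ",
         paste(missing2, collapse = ", "))
  stage1 <- .train_classifier(X, as.integer(odorous), spec1, classes = 0:1)
  stage2 <- .train_classifier(X[odorous, , drop = FALSE], labels[odorous],
                              spec2, classes = 1:3)
  structure(list(stage1 = stage1, stage2 = stage2,
                 encoder_id = .fm_encoder(features)),
            class = "hierarchical_model")
}

#' @export
print.hierarchical_model <- function(x, ...) {
  cat(sprintf("<hierarchical_model> stage1 %s (odorous?), stage2 %s (1..3)\n",
              x$stage1$algorithm, x$stage2$algorithm))
  invisible(x)
}

#' Predict with the hierarchical model
#'
#' @param model a `hierarchical_model`.
#' @param features features aligned with training columns.
#' @return a `prediction_set` (codes only; per-class probabilities combine
#'   stage-1 odorless probability with stage-2 strength probabilities).
#' @export
predict_hierarchical <- function(model, features) {
  X <- .fm_values(features)
  p1 <- .predict_prob(model$stage1, X)
  odorous <- p1[, "1"] > 0.5
  code <- integer(nrow(X))
  prob <- matrix(0, nrow(X), .K, dimnames = list(NULL, as.character(0:3)))
  prob[, "0"] <- p1[, "0"]
  p2 <- .predict_prob(model$stage2, X)
  prob[, c("1", "2", "3")] <- p1[, "1"] * p2
  if (any(odorous)) {
    code[odorous] <- model$stage2$classes[
      max.col(p2[odorous, , drop = FALSE], ties.method = "first")]
  }
  structure(list(code = code, prob = prob, cumprob = NULL),
            class = "prediction_set")
}

#' Ensemble prediction from several direct models
#'
#' Combines member models by averaging their predicted ordinal codes and
#' rounding half away from zero to the nearest valid code (default), or by
#' averaging per-class probabilities and taking the argmax
#' (`method = "probabilities"`). Member predictions are retained for audit.
#'
#' @param models list of at least two fitted `odor_model`s sharing the same
#'   feature encoder.
#' @param features features aligned with the members' training columns.
#' @param method `"codes"` (default) or `"probabilities"`.
#' @return a `prediction_set` with an extra `members` matrix of per-member
#'   codes.
#' @export
#' @examples
#' # member codes (1, 2) average to 1.5 and round half away from zero to 2
ensemble_predict <- function(models, features, method = c("codes", "probabilities")) {
  method <- match.arg(method)
  stopifnot(is.list(models), length(models) >= 2)
  encoders <- unique(vapply(models, function(m) {
    e <- m$encoder_id
    if (is.null(e) || is.na(e)) "unknown" else e
  }, character(1)))
  if (length(encoders) > 1)
    stop("ensemble members use different encoders: ",
         paste(encoders, collapse = ", "))
  preds <- lapply(models, predict_ordinal, features = features)
  member_codes <- do.call(cbind, lapply(preds, `[[`, "code"))
  if (method == "codes") {
    m <- rowMeans(member_codes)
    code <- pmin(pmax(floor(m + 0.5), 0L), .K - 1L)  # half away from zero
  } else {
    prob <- Reduce(`+`, lapply(preds, `[[`, "prob")) / length(preds)
    code <- as.integer(colnames(prob)[max.col(prob, ties.method = "first")])
  }
  prob <- Reduce(`+`, lapply(preds, `[[`, "prob")) / length(preds)
  structure(list(code = as.integer(code), prob = prob, cumprob = NULL,
                 members = member_codes),
            class = "prediction_set")
}

# continuous ensemble score (mean member code) for attribution
.ensemble_score_fun <- function(models) {
  function(X) {
    rowMeans(do.call(cbind, lapply(models, function(m)
      predict_ordinal(m, X)$code)))
  }
}

#' Budgeted hyperparameter search with percentile pruning
#'
#' Sequential random search over a hyperparameter space. Each trial is
#' scored by repeated grouped stratified cross-validation; after each
#' repetition a trial is pruned when its running mean trails the 25th
#' percentile of the completed trials' scores by more than `tolerance`
#' (macro MSE scale: 0.02; minority-F1 scale: 0.015).
#'
#' @param algorithm algorithm name for [model_spec()].
#' @param space named list; each element is either a vector of candidate
#'   values (sampled uniformly) or a list `list(low =, high =, log = FALSE,
#'   integer = FALSE)` defining a numeric range.
#' @param features,labels training data.
#' @param groups similarity groups (default singletons).
#' @param budget number of trials (>= 1).
#' @param objective `"macro_mse"` (minimized) or `"minority_f1"`
#'   (maximized, F1 of the least frequent class).
#' @param n_folds,n_repeats cross-validation layout per trial.
#' @param percentile pruning percentile (default 0.25).
#' @param tolerance pruning tolerance on the objective scale.
#' @param seed integer seed.
#' @return list with `best_spec`, `best_score`, and `trials` (data.frame
#'   ledger with one row per trial: sampled values, score, pruned flag).
#' @export
tune <- function(algorithm, space, features, labels,
                 groups = seq_along(labels), budget = 20L,
                 objective = c("macro_mse", "minority_f1"),
                 n_folds = 3L, n_repeats = 2L, percentile = 0.25,
                 tolerance = if (match.arg(objective) == "macro_mse") 0.02 else 0.015,
                 seed = 1L) {
  objective <- match.arg(objective)
  if (budget < 1) stop("budget must be at least 1")
  X <- .fm_values(features)
  labels <- as.integer(labels)
  minority <- as.integer(names(which.min(table(labels))))
  score_pred <- function(yt, yp) {
    if (objective == "macro_mse") as.numeric(macro_mse(yt, yp))
    else {
      tp <- sum(yt == minority & yp == minority)
      fp <- sum(yt != minority & yp == minority)
      fn <- sum(yt == minority & yp != minority)
      f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
      -f1  # internal convention: always minimize
    }
  }
  sample_space <- function() {
    out <- list()
    for (nm in names(space)) {
      el <- space[[nm]]
      if (is.list(el)) {
        u <- stats::runif(1)
        v <- if (isTRUE(el$log))
          exp(log(el$low) + u * (log(el$high) - log(el$low)))
        else el$low + u * (el$high - el$low)
        if (isTRUE(el$integer)) v <- as.integer(round(v))
        out[[nm]] <- v
      } else out[[nm]] <- el[[sample.int(length(el), 1)]]
    }
    out
  }
  trials <- list()
  completed_scores <- numeric(0)
  .with_seed(seed, {
    for (tr in seq_len(budget)) {
      hp <- sample_space()
      spec <- model_spec(algorithm, hp, seed = seed + tr)
      folds <- repeated_grouped_stratified_kfold(labels, groups, n_folds,
                                                n_repeats, seed = seed + 31L * tr)
      rep_scores <- numeric(0)
      pruned <- FALSE
      for (r in seq_len(n_repeats)) {
        fold_scores <- vapply(seq_len(n_folds), function(f) {
          te <- folds[, r] == f
          m <- .train_classifier(X[!te, , drop = FALSE], labels[!te], spec,
                                 classes = sort(unique(labels)))
          yp <- predict_ordinal(m, X[te, , drop = FALSE])$code
          score_pred(labels[te], yp)
        }, numeric(1))
        rep_scores <- c(rep_scores, mean(fold_scores))
        if (length(completed_scores) >= 4 && r < n_repeats) {
          cut <- stats::quantile(completed_scores, percentile)
          if (mean(rep_scores) > cut + tolerance) { pruned <- TRUE; break }
        }
      }
      score <- mean(rep_scores)
      if (!pruned) completed_scores <- c(completed_scores, score)
      trials[[tr]] <- data.frame(trial = tr, score = score, pruned = pruned,
                                 as.data.frame(hp, stringsAsFactors = FALSE))
    }
  })
  ledger <- do.call(rbind, trials)
  done <- ledger[!ledger$pruned, , drop = FALSE]
  best_row <- done[which.min(done$score), , drop = FALSE]
  hp_best <- as.list(best_row[, setdiff(names(best_row),
                                        c("trial", "score", "pruned")),
                              drop = FALSE])
  list(best_spec = model_spec(algorithm, hp_best, seed = seed + best_row$trial),
       best_score = if (objective == "minority_f1") -best_row$score
                    else best_row$score,
       trials = ledger)
}
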