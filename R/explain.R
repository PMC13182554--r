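# Model explanation: additive per-feature attributions (Shapley values via
# permutation sampling, or exact TreeSHAP for gradient-boosted trees through
# the booster's native path-dependent contributions), aggregated into
# correlation-clustered feature groups with a silhouette-selected threshold.

#' Additive feature attributions
#'
#' Computes per-record, per-feature attributions `phi` with the local
#' accuracy property: `base_value + rowSums(phi)` equals the model output
#' for that record (up to the estimator's tolerance; the permutation
#' estimator satisfies it exactly by telescoping). The default estimator
#' samples feature permutations against background rows and averages the
#' marginal contributions (a sampling approximation of Shapley values);
#' for a single xgboost `odor_model` the booster's exact tree-path
#' contributions are used instead.
#'
#' A feature the model never uses receives attribution exactly 0 under both
#' estimators.
#'
#' @param model a fitted `odor_model`, a list of `odor_model`s (ensemble,
#'   attributed on its continuous mean-code score), or a function
#'   `f(matrix) -> numeric`.
#' @param X numeric matrix (or [feature_matrix()]) of records to explain.
#' @param background numeric matrix (or `feature_matrix`) of background
#'   (training) rows defining the reference distribution.
#' @param n_perm permutations per record for the sampling estimator.
#' @param n_background background rows sampled per record (capped at the
#'   number available).
#' @param seed integer seed.
#' @return object of class `attribution_matrix`: `values` (n x d),
#'   `base_value` (mean model output on the background sample),
#'   `estimator`, `n_background`.
#' @export
attribute <- function(model, X, background, n_perm = 10L,
                      n_background = 20L, seed = 1L) {
  Xm <- .fm_values(X)
  Bm <- .fm_values(background)
  if (!nrow(Bm)) stop("background must be nonempty")
  if (ncol(Xm) != ncol(Bm)) stop("X and background have different feature counts")
  if (inherits(X, "feature_matrix") && inherits(background, "feature_matrix") &&
      !identical(X$encoder_id, background$encoder_id))
    stop("X and background use different encoders")
  if (inherits(model, "odor_model") && model$algorithm == "xgb" &&
      length(model$classes) >= 2) {
    return(.attribute_xgb(model, Xm, Bm))
  }
  f <- .attribution_fun(model)
  d <- ncol(Xm)
  n <- nrow(Xm)
  phi <- matrix(0, n, d, dimnames = list(NULL, colnames(Xm)))
  .with_seed(seed, {
    nb <- min(n_background, nrow(Bm))
    bg_idx <- sample.int(nrow(Bm), nb)
    B <- Bm[bg_idx, , drop = FALSE]
    base_value <- mean(f(B))
    perms <- lapply(seq_len(n_perm), function(i) sample.int(d))
    for (pi in seq_len(n_perm)) {
      ord <- perms[[pi]]
      for (bi in seq_len(nb)) {
        # telescoping walk from the background row to each explained row:
        # hybrid_j has the first j features (in permuted order) from x
        prev <- matrix(B[bi, ], n, d, byrow = TRUE)
        colnames(prev) <- colnames(Xm)
        f_prev <- f(prev)
        for (j in seq_len(d)) {
          cur <- prev
          cur[, ord[j]] <- Xm[, ord[j]]
          f_cur <- f(cur)
          phi[, ord[j]] <- phi[, ord[j]] + (f_cur - f_prev)
          prev <- cur
          f_prev <- f_cur
        }
      }
    }
    phi <- phi / (n_perm * nb)
    structure(list(values = phi, base_value = base_value,
                   estimator = "permutation_sampling",
                   n_background = nb, n_perm = n_perm),
              class = "attribution_matrix")
  })
}

.attribution_fun <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "odor_model")) {
    # multi-class output reduced to the predicted-class probability
    return(function(Xn) {
      pr <- .predict_prob(model, Xn)
      # reduce to the class predicted for each row
      pr[cbind(seq_len(nrow(pr)), max.col(pr, ties.method = "first"))]
    })
  }
  if (is.list(model) && all(vapply(model, inherits, logical(1), "odor_model")))
    return(.ensemble_score_fun(model))
  stop("model must be an odor_model, a list of them, or a function")
}

# exact path-dependent TreeSHAP from the booster, reduced to the
# predicted-class attribution per record
.attribute_xgb <- function(model, Xm, Bm) {
  dm <- xgboost::xgb.DMatrix(Xm)
  contrib <- stats::predict(model$fit, dm, predcontrib = TRUE)
  prob <- .predict_prob(model, Xm)
  pred_cls <- max.col(prob, ties.method = "first")
  if (is.list(contrib)) {
    vals <- do.call(rbind, lapply(seq_along(pred_cls), function(i)
      contrib[[pred_cls[i]]][i, ]))
  } else {
    # 3-d array n x class x (d+1)
    vals <- t(vapply(seq_along(pred_cls), function(i) contrib[i, pred_cls[i], ],
                     numeric(dim(contrib)[3])))
  }
  bias <- vals[, ncol(vals)]
  vals <- vals[, -ncol(vals), drop = FALSE]
  colnames(vals) <- colnames(Xm)
  structure(list(values = vals, base_value = mean(bias),
                 estimator = "treeshap_path", n_background = nrow(Bm),
                 n_perm = NA_integer_),
            class = "attribution_matrix")
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat(sprintf("<attribution_matrix> %d x %d (%s), base value %.4f\n",
              nrow(x$values), ncol(x$values), x$estimator, x$base_value))
  invisible(x)
}

#' Group features by value correlation
#'
#' Pairwise Pearson correlation of feature values (configurable to
#' Spearman), distance `1 - |r|`, complete-linkage agglomerative clustering
#' cut at distance `1 - threshold` for each threshold on the grid. The
#' silhouette score on the same distance selects the returned threshold
#' (grid argmax); the full curve is reported. Zero-variance features go to
#' a dedicated degenerate group and are excluded from the correlation.
#'
#' @param features [feature_matrix()] or matrix (d >= 2 columns).
#' @param threshold_grid candidate correlation thresholds in (0, 1).
#' @param method correlation type, `"pearson"` (default) or `"spearman"`.
#' @return object of class `feature_grouping`: `group` (named integer per
#'   feature; 0 marks the degenerate zero-variance group), `threshold`,
#'   `silhouette_curve` (data.frame threshold/score), `n_groups`.
#' @export
correlation_grouping <- function(features, threshold_grid = seq(0.5, 0.95, by = 0.05),
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- .fm_values(features)
  if (ncol(X) < 2) stop("need at least 2 features")
  stopifnot(all(threshold_grid > 0), all(threshold_grid < 1))
  sds <- apply(X, 2, stats::sd)
  degen <- colnames(X)[sds == 0 | !is.finite(sds)]
  keep <- setdiff(colnames(X), degen)
  Xc <- X[, keep, drop = FALSE]
  R <- suppressWarnings(stats::cor(Xc, method = method))
  R[!is.finite(R)] <- 0
  D <- 1 - abs(R)
  diag(D) <- 0
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  curve <- data.frame(threshold = threshold_grid, score = NA_real_,
                      n_groups = NA_integer_)
  parts <- list()
  for (i in seq_along(threshold_grid)) {
    cl <- stats::cutree(hc, h = 1 - threshold_grid[i])
    parts[[i]] <- cl
    k <- length(unique(cl))
    curve$n_groups[i] <- k
    if (k >= 2 && k <= length(cl) - 1) {
      sil <- cluster::silhouette(cl, dmatrix = D)
      curve$score[i] <- mean(sil[, "sil_width"])
    }
  }
  best <- if (all(is.na(curve$score))) which.min(abs(threshold_grid - 0.75))
          else which.max(curve$score)
  group <- stats::setNames(rep(0L, ncol(X)), colnames(X))
  group[keep] <- as.integer(parts[[best]])
  structure(list(group = group, threshold = threshold_grid[best],
                 silhouette_curve = curve,
                 n_groups = length(unique(group))),
            class = "feature_grouping")
}

#' @export
print.feature_grouping <- function(x, ...) {
  cat(sprintf("<feature_grouping> %d features in %d groups (threshold %.2f)\n",
              length(x$group), x$n_groups, x$threshold))
  invisible(x)
}

#' Group-level attribution importance
#'
#' Per-feature importance is the mean absolute attribution over records;
#' group importance is the sum of its members' importances (so total
#' importance is conserved under any regrouping). The optional per-class
#' variant averages within each true class before summing.
#'
#' @param attr an `attribution_matrix`.
#' @param grouping a `feature_grouping` covering every attribution column.
#' @param y_true optional true codes for the per-class breakdown.
#' @return object of class `group_importance_report`: `groups` (data.frame
#'   ranked by importance with member features), `feature_importance`
#'   (named vector), optional `per_class` list.
#' @export
group_importance <- function(attr, grouping, y_true = NULL) {
  stopifnot(inherits(attr, "attribution_matrix"),
            inherits(grouping, "feature_grouping"))
  feats <- colnames(attr$values)
  missing <- setdiff(feats, names(grouping$group))
  if (length(missing))
    stop("grouping does not cover feature(s): ", paste(missing, collapse = ", "))
  fi <- colMeans(abs(attr$values))
  gid <- grouping$group[feats]
  imp <- vapply(split(fi, gid), sum, numeric(1))
  members <- vapply(split(feats, gid), paste, character(1), collapse = ";")
  groups <- data.frame(group = as.integer(names(imp)), importance = unname(imp),
                       members = unname(members), stringsAsFactors = FALSE)
  groups <- groups[order(-groups$importance), ]
  groups$rank <- seq_len(nrow(groups))
  per_class <- NULL
  if (!is.null(y_true)) {
    per_class <- lapply(sort(unique(y_true)), function(cc) {
      fic <- colMeans(abs(attr$values[y_true == cc, , drop = FALSE]))
      vapply(split(fic, gid), sum, numeric(1))
    })
    names(per_class) <- as.character(sort(unique(y_true)))
  }
  structure(list(groups = groups, feature_importance = fi,
                 per_class = per_class),
            class = "group_importance_report")
}

#' @export
print.group_importance_report <- function(x, ...) {
  cat(sprintf("<group_importance_report> %d groups; top: %s (%.4f)\n",
              nrow(x$groups), x$groups$members[1], x$groups$importance[1]))
  invisible(x)
}
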