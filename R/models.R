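# Ordinal model training: direct 4-class learners (logistic, random forest,
# gradient boosting, MLP, CORAL), with cost-sensitive class weighting and
# train-set feature standardization for the gradient-based learners.

.ALGORITHMS <- c("logistic", "random_forest", "xgb", "mlp", "coral")

.DEFAULT_HYPER <- list(
  logistic = list(decay = 0, maxit = 200),
  random_forest = list(num_trees = 500, min_node_size = 3, mtry = NULL),
  xgb = list(nrounds = 400, eta = 0.05, max_depth = 6, subsample = 1),
  mlp = list(size = 32, decay = 1e-3, maxit = 600),
  coral = list(hidden = 8, lambda = 1e-4, maxit = 400)
)

#' Specify a model
#'
#' @param algorithm one of `"logistic"`, `"random_forest"`, `"xgb"`,
#'   `"mlp"`, `"coral"`.
#' @param hyperparameters named list; unknown names for the algorithm are
#'   rejected, omitted ones take defaults.
#' @param class_weighting `"balanced"` (weight `n / (K * n_k)` per class) or
#'   `"none"`.
#' @param seed integer seed controlling initialization and any stochastic
#'   fitting.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(algorithm, hyperparameters = list(),
                       class_weighting = c("balanced", "none"), seed = 1L) {
  algorithm <- match.arg(algorithm, .ALGORITHMS)
  class_weighting <- match.arg(class_weighting)
  defaults <- .DEFAULT_HYPER[[algorithm]]
  unknown <- setdiff(names(hyperparameters), names(defaults))
  if (length(unknown))
    stop("unknown hyperparameters for ", algorithm, ": ",
         paste(unknown, collapse = ", "))
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 class_weighting = class_weighting, seed = as.integer(seed)),
            class = "model_spec")
}

#' Balanced class weights
#'
#' Cost-sensitive weights `n / (K * n_k)` for class k, where K is the number
#' of distinct classes and n_k the class count; the minority class gets the
#' largest weight.
#'
#' @param labels integer class codes.
#' @param classes the class codes the model is trained over.
#' @return named numeric vector of per-class weights.
#' @export
class_weights <- function(labels, classes = sort(unique(labels))) {
  K <- length(classes)
  n <- length(labels)
  counts <- vapply(classes, function(cc) sum(labels == cc), numeric(1))
  if (any(counts == 0)) stop("class ", classes[counts == 0][1],
                             " absent from training labels")
  stats::setNames(n / (K * counts), classes)
}

.fm_values <- function(features) {
  if (inherits(features, "feature_matrix")) features$values
  else as.matrix(features)
}

.fm_encoder <- function(features) {
  if (inherits(features, "feature_matrix")) features$encoder_id else NA_character_
}

# train-set standardization for gradient-based learners
.fit_scaling <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

.apply_scaling <- function(X, scaling) {
  if (is.null(scaling)) return(X)
  sweep(sweep(X, 2, scaling$center, "-"), 2, scaling$scale, "/")
}

# core classifier trainer over an arbitrary contiguous class set
.train_classifier <- function(X, y, spec, classes) {
  stopifnot(inherits(spec, "model_spec"))
  missing_cls <- setdiff(classes, unique(y))
  if (length(missing_cls))
    stop("training data lacks class(es) ", paste(missing_cls, collapse = ", "))
  hp <- spec$hyperparameters
  cw <- if (spec$class_weighting == "balanced") class_weights(y, classes)
        else stats::setNames(rep(1, length(classes)), classes)
  w <- unname(cw[as.character(y)])
  scaling <- NULL
  if (spec$algorithm %in% c("logistic", "mlp", "coral")) {
    scaling <- .fit_scaling(X)
    X <- .apply_scaling(X, scaling)
  }
  fit <- .with_seed(spec$seed, switch(spec$algorithm,
    logistic = {
      df <- data.frame(.y = factor(y, levels = classes), X)
      nnet::multinom(.y ~ ., data = df, weights = w, decay = hp$decay,
                     maxit = hp$maxit, trace = FALSE,
                     MaxNWts = (ncol(X) + 2) * length(classes) + 10)
    },
    random_forest = ranger::ranger(
      x = as.data.frame(X), y = factor(y, levels = classes),
      probability = TRUE, num.trees = hp$num_trees,
      min.node.size = hp$min_node_size,
      mtry = if (is.null(hp$mtry)) NULL else min(hp$mtry, ncol(X)),
      case.weights = w, seed = spec$seed, num.threads = 1),
    xgb = {
      dtr <- xgboost::xgb.DMatrix(X, label = match(y, classes) - 1L, weight = w)
      xgboost::xgb.train(params = list(objective = "multi:softprob",
                                       num_class = length(classes),
                                       eta = hp$eta, max_depth = hp$max_depth,
                                       subsample = hp$subsample,
                                       nthread = 1, seed = spec$seed),
                         data = dtr, nrounds = hp$nrounds, verbose = 0)
    },
    mlp = {
      targets <- nnet::class.ind(factor(y, levels = classes))
      nnet::nnet(x = X, y = targets, size = hp$size, decay = hp$decay,
                 maxit = hp$maxit, softmax = TRUE, trace = FALSE,
                 weights = w, MaxNWts = 20000)
    },
    coral = .coral_fit(X, match(y, classes) - 1L, w, hidden = hp$hidden,
                       lambda = hp$lambda, maxit = hp$maxit)
  ))
  structure(list(algorithm = spec$algorithm, fit = fit,
                 classes = as.integer(classes), scaling = scaling,
                 feature_names = colnames(X), spec = spec, seed = spec$seed),
            class = "odor_model")
}

#' Train a direct ordinal classifier on all four categories
#'
#' Fits the requested algorithm on the full four-class problem with
#' cost-sensitive class weights (when `class_weighting = "balanced"`).
#' Logistic, MLP and CORAL models standardize features by the train-set mean
#' and standard deviation (stored in the model bundle); tree models consume
#' raw features.
#'
#' @param features [feature_matrix()] or numeric matrix, rows aligned with
#'   `labels`.
#' @param labels integer codes 0..3; all four classes must be present.
#' @param spec a [model_spec()].
#' @return fitted model bundle of class `odor_model`.
#' @export
train_direct <- function(features, labels, spec) {
  X <- .fm_values(features)
  labels <- as.integer(labels)
  model <- .train_classifier(X, labels, spec, classes = 0:(.K - 1))
  model$encoder_id <- .fm_encoder(features)
  model
}

#' @export
print.odor_model <- function(x, ...) {
  cat(sprintf("<odor_model> %s over classes {%s}, %d features\n",
              x$algorithm, paste(x$classes, collapse = ","),
              length(x$feature_names)))
  invisible(x)
}

# class-probability matrix over model$classes
.predict_prob <- function(model, X) {
  X <- .apply_scaling(X, model$scaling)
  K <- length(model$classes)
  prob <- switch(model$algorithm,
    logistic = {
      p <- stats::predict(model$fit, newdata = data.frame(X), type = "probs")
      if (is.null(dim(p))) {
        if (K == 2) cbind(1 - p, p) else matrix(p, nrow = 1)
      } else p
    },
    random_forest = stats::predict(model$fit, data = as.data.frame(X),
                                   num.threads = 1)$predictions,
    xgb = {
      p <- stats::predict(model$fit, xgboost::xgb.DMatrix(X))
      if (is.null(dim(p))) matrix(p, ncol = K, byrow = TRUE) else p
    },
    mlp = {
      p <- stats::predict(model$fit, X)
      if (is.null(dim(p))) matrix(p, nrow = 1) else p
    },
    coral = .coral_class_prob(model$fit, X)
  )
  prob <- as.matrix(prob)
  colnames(prob) <- as.character(model$classes)
  prob
}

#' Predict ordinal codes (and probabilities)
#'
#' Probabilistic classifiers return the argmax class; CORAL returns the
#' count of cumulative probabilities above 0.5 (its per-class probabilities
#' are adjacent differences of the cumulative ones, clipped at 0 and
#' renormalized). The feature columns must match the training columns.
#'
#' @param model an `odor_model` from [train_direct()].
#' @param features [feature_matrix()] or matrix with the training columns.
#' @return object of class `prediction_set`: list with `code` (integer
#'   vector), `prob` (n x K matrix) and, for CORAL, `cumprob`
#'   (n x K-1 matrix of P(y > k)).
#' @export
predict_ordinal <- function(model, features) {
  stopifnot(inherits(model, "odor_model"))
  X <- .fm_values(features)
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), model$feature_names))
    stop("feature columns do not match the training features")
  if (ncol(X) != length(model$feature_names))
    stop("feature count does not match the training features")
  if (model$algorithm == "coral") {
    Xs <- .apply_scaling(X, model$scaling)
    cum <- .coral_cumprob(model$fit, Xs)
    code <- model$classes[1] + as.integer(rowSums(cum > 0.5))
    prob <- .coral_class_prob(model$fit, Xs)
    colnames(prob) <- as.character(model$classes)
    out <- list(code = code, prob = prob, cumprob = cum)
  } else {
    prob <- .predict_prob(model, X)
    code <- model$classes[max.col(prob, ties.method = "first")]
    out <- list(code = as.integer(code), prob = prob, cumprob = NULL)
  }
  structure(out, class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> %d predictions; code counts: %s\n",
              length(x$code),
              paste(table(factor(x$code, levels = 0:(.K - 1))), collapse = "/")))
  invisible(x)
}
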