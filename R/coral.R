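# CORAL: consistent rank logits for ordinal regression.
#
# A small MLP body h(x) is shared across the K-1 cumulative binary tasks
# "is y > k?"; each task adds only its own threshold bias to the shared
# logit g(x) = w . h(x). The biases are parameterized as
# b_k = b_1 - sum_{j<k} softplus(delta_j), which makes them non-increasing
# BY CONSTRUCTION, so the cumulative probabilities
# P(y > k | x) = sigmoid(g(x) + b_k) are rank-consistent for every input and
# every parameter value, not just at the optimum. Training minimizes the
# sample-weighted sum of the K-1 binary cross-entropies (weight = the class
# weight of the true label), with an L2 penalty on the weights.

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
.sigmoid <- function(x) 1 / (1 + exp(-x))

# pack/unpack parameters for optim
.coral_shapes <- function(d, hidden, K) {
  if (hidden > 0)
    list(W1 = c(d, hidden), b1h = hidden, w = hidden, b1 = 1, delta = K - 2)
  else
    list(w = d, b1 = 1, delta = K - 2)
}

.coral_unpack <- function(par, shp) {
  out <- list()
  pos <- 0L
  for (nm in names(shp)) {
    len <- prod(shp[[nm]])
    v <- par[pos + seq_len(len)]
    out[[nm]] <- if (length(shp[[nm]]) == 2) matrix(v, shp[[nm]][1], shp[[nm]][2])
                 else v
    pos <- pos + len
  }
  out
}

# body output g(x) (n-vector) and hidden activations
.coral_forward <- function(p, X, hidden) {
  if (hidden > 0) {
    A <- tanh(sweep(X %*% p$W1, 2, p$b1h, "+"))
    list(g = as.numeric(A %*% p$w), A = A)
  } else {
    list(g = as.numeric(X %*% p$w), A = NULL)
  }
}

.coral_biases <- function(p, K) {
  p$b1 - cumsum(c(0, .softplus(p$delta)))  # length K-1, non-increasing
}

.coral_fit <- function(X, y, w, hidden = 8L, lambda = 1e-4, maxit = 400L,
                       K = max(y) + 1L) {
  stopifnot(all(y %in% 0:(K - 1)), K >= 2)
  d <- ncol(X)
  hidden <- as.integer(hidden)
  shp <- .coral_shapes(d, hidden, K)
  npar <- sum(vapply(shp, prod, numeric(1)))
  # targets for the cumulative tasks: t_ik = 1{y_i > k}
  Tm <- outer(y, 0:(K - 2), ">") * 1
  Wm <- matrix(w, nrow = length(y), ncol = K - 1)
  obj <- function(par) {
    p <- .coral_unpack(par, shp)
    fw <- .coral_forward(p, X, hidden)
    b <- .coral_biases(p, K)
    logits <- outer(fw$g, b, "+")
    z <- .sigmoid(logits)
    eps <- 1e-12
    nll <- -sum(Wm * (Tm * log(z + eps) + (1 - Tm) * log(1 - z + eps)))
    pen <- lambda * (sum(p$w^2) + if (hidden > 0) sum(p$W1^2) else 0)
    nll + pen
  }
  grad <- function(par) {
    p <- .coral_unpack(par, shp)
    fw <- .coral_forward(p, X, hidden)
    b <- .coral_biases(p, K)
    z <- .sigmoid(outer(fw$g, b, "+"))
    dlogit <- Wm * (z - Tm)                  # n x (K-1)
    db <- colSums(dlogit)                    # per-threshold
    dg <- rowSums(dlogit)                    # per-sample
    g_out <- list()
    if (hidden > 0) {
      dA <- outer(dg, p$w)                   # n x hidden
      dZ <- dA * (1 - fw$A^2)
      g_out$W1 <- as.numeric(t(X) %*% dZ + 2 * lambda * p$W1)
      g_out$b1h <- colSums(dZ)
      g_out$w <- as.numeric(t(fw$A) %*% dg + 2 * lambda * p$w)
    } else {
      g_out$w <- as.numeric(t(X) %*% dg + 2 * lambda * p$w)
    }
    g_out$b1 <- sum(db)
    if (K > 2) {
      # b_k includes -softplus(delta_j) for all k > j
      tail_sums <- rev(cumsum(rev(db)))[-1]  # sum over k > j of db_k
      g_out$delta <- -.sigmoid(p$delta) * tail_sums
    } else g_out$delta <- numeric(0)
    unlist(g_out[names(shp)], use.names = FALSE)
  }
  init <- stats::rnorm(npar, sd = 0.1)
  opt <- stats::optim(init, obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  p <- .coral_unpack(opt$par, shp)
  list(params = p, hidden = hidden, K = K, value = opt$value,
       convergence = opt$convergence)
}

# cumulative probabilities P(y > k), n x (K-1), non-increasing across k
.coral_cumprob <- function(fit, X) {
  fw <- .coral_forward(fit$params, X, fit$hidden)
  b <- .coral_biases(fit$params, fit$K)
  .sigmoid(outer(fw$g, b, "+"))
}

# per-class probabilities by differencing cumulative ones (clip, renormalize)
.coral_class_prob <- function(fit, X) {
  cum <- .coral_cumprob(fit, X)
  K <- fit$K
  p <- cbind(1 - cum[, 1, drop = FALSE],
             if (K > 2) cum[, -(K - 1), drop = FALSE] - cum[, -1, drop = FALSE],
             cum[, K - 1, drop = FALSE])
  p <- pmax(p, 0)
  p / rowSums(p)
}

#' Train a CORAL rank-consistent ordinal model
#'
#' Convenience wrapper equivalent to `train_direct(features, labels,
#' model_spec("coral", ...))`. The threshold biases are monotone by
#' construction, so the cumulative probabilities `P(y > k | x)` are
#' non-increasing in k for every input. Prediction counts cumulative
#' probabilities above 0.5.
#'
#' @inheritParams train_direct
#' @return fitted `odor_model` with `algorithm = "coral"`.
#' @export
train_coral <- function(features, labels, spec = model_spec("coral")) {
  if (!identical(spec$algorithm, "coral")) stop("spec must have algorithm 'coral'")
  train_direct(features, labels, spec)
}

#' Cumulative probabilities from a CORAL model
#'
#' @param model a fitted `odor_model` with `algorithm = "coral"`.
#' @param features features aligned with training columns.
#' @return n x (K-1) matrix of P(y > k | x), non-increasing along each row.
#' @export
coral_cumulative_probs <- function(model, features) {
  stopifnot(inherits(model, "odor_model"), model$algorithm == "coral")
  X <- .apply_scaling(.fm_values(features), model$scaling)
  .coral_cumprob(model$fit, X)
}
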