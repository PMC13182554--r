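# Independent brute-force oracles, implemented directly from definitions and
# kept separate from the package's own code paths.

# macro MSE by an explicit per-class loop
oracle_macro_mse <- function(y_true, y_pred) {
  total <- 0
  k <- 0
  for (cc in 0:3) {
    idx <- which(y_true == cc)
    if (!length(idx)) next
    s <- 0
    for (i in idx) s <- s + (y_pred[i] - y_true[i])^2
    total <- total + s / length(idx)
    k <- k + 1
  }
  total / k
}

# quadratically weighted kappa from the raw definition
oracle_kappa <- function(a, b, K = 4) {
  n <- length(a)
  w <- function(i, j) (i - j)^2 / (K - 1)^2
  obs <- 0
  for (i in seq_len(n)) obs <- obs + w(a[i], b[i])
  obs <- obs / n
  exp_d <- 0
  for (i in 0:(K - 1)) for (j in 0:(K - 1)) {
    exp_d <- exp_d + mean(a == i) * mean(b == j) * w(i, j)
  }
  if (exp_d == 0) return(NA_real_)
  1 - obs / exp_d
}

# ordinal Krippendorff alpha from the coincidence definition, built by
# enumerating every ordered pair of annotations within each unit
oracle_alpha_ordinal <- function(ratings, levels = 0:3) {
  L <- length(levels)
  o <- matrix(0, L, L)
  for (u in seq_len(nrow(ratings))) {
    vals <- ratings[u, ][!is.na(ratings[u, ])]
    m <- length(vals)
    if (m < 2) next
    for (i in seq_len(m)) for (j in seq_len(m)) if (i != j) {
      ci <- match(vals[i], levels); cj <- match(vals[j], levels)
      o[ci, cj] <- o[ci, cj] + 1 / (m - 1)
    }
  }
  nc <- rowSums(o)
  n <- sum(nc)
  metric <- function(ci, cj) {
    if (ci == cj) return(0)
    lo <- min(ci, cj); hi <- max(ci, cj)
    (sum(nc[lo:hi]) - (nc[ci] + nc[cj]) / 2)^2
  }
  Do <- 0; De <- 0
  for (ci in seq_len(L)) for (cj in seq_len(L)) {
    Do <- Do + o[ci, cj] * metric(ci, cj)
    De <- De + nc[ci] * nc[cj] * metric(ci, cj)
  }
  if (De == 0) return(NA_real_)
  1 - (n - 1) * Do / De
}

# adjusted Rand index from pair counting (not the contingency shortcut)
oracle_ari_pairs <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  np <- choose(n, 2)
  expected <- (n11 + n10) * (n11 + n01) / np
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxi == expected) return(0)
  (n11 - expected) / (maxi - expected)
}

# NMI from explicit probability sums
oracle_nmi <- function(a, b) {
  ua <- unique(a); ub <- unique(b); n <- length(a)
  h <- function(labs, u) {
    s <- 0
    for (x in u) { p <- mean(labs == x); if (p > 0) s <- s - p * log(p) }
    s
  }
  mi <- 0
  for (x in ua) for (y in ub) {
    pxy <- mean(a == x & b == y)
    if (pxy > 0) mi <- mi + pxy * log(pxy / (mean(a == x) * mean(b == y)))
  }
  ha <- h(a, ua); hb <- h(b, ub)
  if (ha == 0 && hb == 0) return(1)
  if (mi == 0 && (ha == 0 || hb == 0)) return(0)
  mi / ((ha + hb) / 2)
}

# Monte-Carlo oracle for the adjacent-flip annotation noise channel:
# expected quadratic kappa between two independent noisy views of labels
# drawn from class distribution p_class
oracle_noise_kappa <- function(p_class, noise, n_pairs = 1e5, seed = 99) {
  set.seed(seed)
  y <- sample(0:3, n_pairs, replace = TRUE, prob = p_class)
  flip <- function(y) {
    do_flip <- runif(length(y)) < noise
    dir <- ifelse(y == 0, 1, ifelse(y == 3, -1, ifelse(runif(length(y)) < 0.5, -1, 1)))
    ifelse(do_flip, y + dir, y)
  }
  oracle_kappa(flip(y), flip(y))
}
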