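# Descriptor-space characterization: standardized PCA with loading reports,
# and the clustering-vs-label agreement analysis (do unsupervised partitions
# of descriptor space recover odor-strength categories?).

#' Principal component analysis of a feature matrix
#'
#' Columns are standardized (mean 0, sd 1); zero-variance columns are
#' dropped and reported. The loading sign is fixed by making each column's
#' largest-magnitude entry positive, so results are deterministic.
#'
#' @param features [feature_matrix()] or numeric matrix.
#' @param k number of components (<= min(n - 1, d)).
#' @return object of class `pca_result`: `scores` (n x k), `loadings`
#'   (d x k, orthonormal columns), `explained_variance_ratio` (k-vector),
#'   `dropped_columns`, `center`, `scale`.
#' @export
pca_features <- function(features, k = 2L) {
  X <- .fm_values(features)
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0 | !is.finite(sds)]
  X <- X[, sds > 0 & is.finite(sds), drop = FALSE]
  if (k > min(nrow(X) - 1L, ncol(X)))
    stop("k must be at most min(n - 1, d) = ", min(nrow(X) - 1L, ncol(X)))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = evr[seq_len(k)],
                 dropped_columns = dropped,
                 center = pc$center, scale = pc$scale),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d x %d scores; explained variance: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio),
                    collapse = ", ")))
  invisible(x)
}

#' Top-loading features of a principal component
#'
#' @param result a `pca_result`.
#' @param component component index (1-based).
#' @param m number of features to return (clamped to d with a warning).
#' @return data.frame of `feature` and `loading`, ordered by absolute
#'   loading descending, ties by name.
#' @export
top_loadings <- function(result, component = 1L, m = 10L) {
  stopifnot(inherits(result, "pca_result"))
  if (component > ncol(result$loadings)) stop("component exceeds k")
  l <- result$loadings[, component]
  if (m > length(l)) {
    warning("m exceeds the number of features; clamped to ", length(l))
    m <- length(l)
  }
  ord <- order(-abs(l), names(l))[seq_len(m)]
  data.frame(feature = names(l)[ord], loading = unname(l[ord]),
             stringsAsFactors = FALSE)
}

# ---- partition agreement indices -------------------------------------------

#' Agreement indices between two partitions
#'
#' Contingency-table implementations of the adjusted Rand index (`ari`),
#' normalized mutual information (`nmi`, arithmetic-mean normalization) and
#' adjusted mutual information (`ami`, expected MI under the hypergeometric
#' model). The degenerate single-cluster-vs-mixed case returns 0 for ARI by
#' convention.
#'
#' @param a,b two partitions (any label vectors of equal length).
#' @return named numeric vector.
#' @name partition_agreement
#' @export
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(0)
  unname((sum_ij - expected) / (maxi - expected))
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

.mutual_info <- function(tab) {
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); p_j <- colSums(pij)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (pij[i, j] > 0)
      mi <- mi + pij[i, j] * log(pij[i, j] / (pi_[i] * p_j[j]))
  }
  mi
}

#' @rdname partition_agreement
#' @export
nmi <- function(a, b) {
  tab <- table(a, b)
  mi <- .mutual_info(tab)
  ha <- .entropy(rowSums(tab) / sum(tab))
  hb <- .entropy(colSums(tab) / sum(tab))
  if (ha == 0 && hb == 0) return(1)
  if (mi == 0 && (ha == 0 || hb == 0)) return(0)
  unname(mi / ((ha + hb) / 2))
}

# expected mutual information under the hypergeometric (permutation) model
.expected_mi <- function(a_counts, b_counts, n) {
  emi <- 0
  for (ai in a_counts) for (bj in b_counts) {
    lo <- max(1, ai + bj - n)
    hi <- min(ai, bj)
    if (lo > hi) next
    for (nij in lo:hi) {
      p <- exp(stats::dhyper(nij, ai, n - ai, bj, log = TRUE))
      if (p > 0 && nij > 0)
        emi <- emi + p * (nij / n) * log(n * nij / (ai * bj))
    }
  }
  emi
}

#' @rdname partition_agreement
#' @export
ami <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  mi <- .mutual_info(tab)
  ha <- .entropy(rowSums(tab) / n)
  hb <- .entropy(colSums(tab) / n)
  if (ha == 0 && hb == 0) return(1)
  emi <- .expected_mi(rowSums(tab), colSums(tab), n)
  denom <- (ha + hb) / 2 - emi
  if (denom == 0) return(0)
  unname((mi - emi) / denom)
}

# ---- clustering algorithms --------------------------------------------------

# plain DBSCAN on a distance matrix (no dedicated package in the stack);
# eps defaults to the median 5th-neighbor distance
.dbscan_simple <- function(D, eps, min_pts = 5L) {
  n <- nrow(D)
  labels <- rep(0L, n)  # 0 = unvisited/noise
  cl <- 0L
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= min_pts
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      for (nb in nbrs[[q]]) {
        if (labels[nb] == 0L) {
          labels[nb] <- cl
          if (core[nb]) queue <- c(queue, nb)
        }
      }
    }
  }
  labels  # noise points keep label 0
}

#' Agreement between unsupervised clusterings and ordinal labels
#'
#' Fits each requested clustering algorithm on the (standardized) features
#' only — never on the labels — and scores the resulting partition against
#' the odor-strength labels with ARI, NMI and AMI. Partitional methods use
#' `n_clusters` (default 4, the category count); DBSCAN uses the median
#' 5th-neighbor distance as its radius. An algorithm that yields a single
#' cluster is still scored (ARI = 0 by convention) and flagged.
#'
#' @param features [feature_matrix()] or matrix.
#' @param labels integer ordinal codes (>= 2 distinct values).
#' @param algorithms subset of `c("kmeans", "gmm", "agglomerative",
#'   "spectral", "dbscan")`.
#' @param n_clusters number of clusters for partitional methods.
#' @param seed integer seed.
#' @return data.frame with one row per algorithm: `algorithm`, `ari`,
#'   `nmi`, `ami`, `n_clusters_found`, `degenerate`.
#' @export
clustering_agreement <- function(features, labels,
                                 algorithms = c("kmeans", "gmm",
                                                "agglomerative", "dbscan"),
                                 n_clusters = 4L, seed = 1L) {
  if (length(unique(labels)) < 2) stop("need at least 2 distinct labels")
  algorithms <- match.arg(algorithms,
                          c("kmeans", "gmm", "agglomerative", "spectral",
                            "dbscan"), several.ok = TRUE)
  X <- .fm_values(features)
  sds <- apply(X, 2, stats::sd)
  X <- scale(X[, sds > 0 & is.finite(sds), drop = FALSE])
  D <- as.matrix(stats::dist(X))
  rows <- lapply(algorithms, function(alg) {
    part <- .with_seed(seed, tryCatch(switch(alg,
      kmeans = stats::kmeans(X, centers = n_clusters, nstart = 5)$cluster,
      gmm = mclust::Mclust(X, G = n_clusters, verbose = FALSE)$classification,
      agglomerative = stats::cutree(stats::hclust(stats::as.dist(D),
                                                  method = "ward.D2"),
                                    k = n_clusters),
      spectral = {
        if (!requireNamespace("kernlab", quietly = TRUE))
          stop("kernlab not available")
        as.integer(kernlab::specc(X, centers = n_clusters))
      },
      dbscan = {
        nn5 <- apply(D, 1, function(r) sort(r)[6])  # 5th neighbor (excl self)
        .dbscan_simple(D, eps = stats::median(nn5))
      }), error = function(e) NULL))
    if (is.null(part))
      return(data.frame(algorithm = alg, ari = NA_real_, nmi = NA_real_,
                        ami = NA_real_, n_clusters_found = NA_integer_,
                        degenerate = TRUE))
    degenerate <- length(unique(part)) < 2
    data.frame(algorithm = alg, ari = ari(part, labels),
               nmi = nmi(part, labels), ami = ami(part, labels),
               n_clusters_found = length(unique(part)),
               degenerate = degenerate)
  })
  do.call(rbind, rows)
}
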