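# Leakage-aware data splitting: molecules with Tanimoto similarity at or
# above a threshold (Morgan bits, radius 3, 2048 bits) are grouped and every
# group is assigned atomically to one side of every partition, with greedy
# stratification on the group's majority label.

#' Similarity groups for leakage-aware splitting
#'
#' Builds a graph with an edge between any two molecules whose Tanimoto
#' similarity (bit Morgan fingerprints, radius 3, 2048 bits) is at least
#' `threshold`; groups are the connected components, so near-duplicates can
#' never straddle a train/test or fold boundary.
#'
#' @param smiles_list character vector of SMILES.
#' @param threshold similarity threshold in (0, 1\]; default 0.8.
#' @param fp optional precomputed fingerprint [feature_matrix()] for the
#'   same molecules (rows aligned with `smiles_list`).
#' @return integer vector of group ids (1..n_groups), one per molecule.
#' @export
similarity_groups <- function(smiles_list, threshold = 0.8, fp = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  if (is.null(fp)) fp <- fingerprint(smiles_list, "morgan_bits")
  sim <- tanimoto_matrix(fp)
  n <- nrow(sim)
  adj <- sim >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(igraph::components(g)$membership)
}

# majority label of each group; ties resolved to the lower category
.group_labels <- function(labels, groups) {
  vapply(split(labels, groups), function(y) {
    tab <- table(factor(y, levels = sort(unique(labels))))
    as.integer(names(tab)[which.max(tab)])  # which.max takes first = lowest
  }, integer(1))
}

#' Grouped, stratified train/holdout split
#'
#' Assigns whole similarity groups to the training or holdout side,
#' stratified on each group's majority label (ties to the lower category).
#' Within each class, groups are processed largest first in seeded random
#' order and greedily placed on the side that keeps the class's holdout
#' count closest to its target. Deterministic under `seed`.
#'
#' @param labels integer ordinal codes, one per record.
#' @param groups group ids from [similarity_groups()] (or any atomic
#'   grouping; singletons give a plain stratified split).
#' @param test_fraction holdout fraction in (0, 1).
#' @param seed integer seed.
#' @return object of class `split_plan`: list with `holdout` (logical per
#'   record), `groups`, `test_fraction`, `seed`.
#' @export
grouped_stratified_holdout <- function(labels, groups, test_fraction = 0.2,
                                       seed = 1L) {
  stopifnot(length(labels) == length(groups))
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must be in (0, 1)")
  n <- length(labels)
  sizes <- table(groups)
  big <- names(sizes)[sizes / n > max(test_fraction, 1 - test_fraction)]
  if (length(big))
    stop("group ", big[1], " holds ", sizes[big[1]], "/", n,
         " records, more than either side of the split can accept")
  glab <- .group_labels(labels, groups)
  gsize <- as.integer(table(groups)[names(glab)])
  holdout_group <- stats::setNames(rep(FALSE, length(glab)), names(glab))
  .with_seed(seed, {
    for (cls in sort(unique(glab))) {
      gs <- names(glab)[glab == cls]
      target <- test_fraction * sum(gsize[match(gs, names(glab))])
      gs <- gs[order(-gsize[match(gs, names(glab))],
                     stats::runif(length(gs)))]
      got <- 0
      for (g in gs) {
        sz <- gsize[match(g, names(glab))]
        if (abs(got + sz - target) < abs(got - target)) {
          holdout_group[g] <- TRUE
          got <- got + sz
        }
      }
    }
  })
  structure(list(holdout = unname(holdout_group[as.character(groups)]),
                 groups = groups, test_fraction = test_fraction, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d records, %d groups, holdout %d (%.1f%%)\n",
              length(x$holdout), length(unique(x$groups)), sum(x$holdout),
              100 * mean(x$holdout)))
  invisible(x)
}

#' Repeated grouped, stratified k-fold assignments
#'
#' Per repeat, every similarity group lands in exactly one fold; groups are
#' packed greedily (largest first, seeded random tie order) into the fold
#' whose class composition is most deficient for the group's majority label,
#' with fold size as tie-break. Repeats use seeds derived from `seed`.
#'
#' @param labels integer ordinal codes.
#' @param groups group ids.
#' @param n_folds number of folds (>= 2, <= number of groups).
#' @param n_repeats number of repetitions.
#' @param seed integer seed.
#' @return integer matrix `n_records x n_repeats` of fold ids 1..n_folds.
#' @export
repeated_grouped_stratified_kfold <- function(labels, groups, n_folds = 10L,
                                              n_repeats = 10L, seed = 1L) {
  stopifnot(length(labels) == length(groups), n_folds >= 2, n_repeats >= 1)
  glab <- .group_labels(labels, groups)
  if (n_folds > length(glab))
    stop("n_folds = ", n_folds, " exceeds the number of similarity groups (",
         length(glab), ")")
  gsize <- as.integer(table(groups)[names(glab)])
  out <- matrix(NA_integer_, nrow = length(labels), ncol = n_repeats)
  for (r in seq_len(n_repeats)) {
    fold_of_group <- .with_seed(seed + 1000L * r, {
      fold_sizes <- numeric(n_folds)
      class_in_fold <- matrix(0, nrow = n_folds, ncol = .K)
      assign <- stats::setNames(integer(length(glab)), names(glab))
      ord <- order(-gsize, stats::runif(length(glab)))
      for (gi in ord) {
        cls <- glab[gi] + 1L
        # prefer the fold with the least of this class, then the smallest
        score <- class_in_fold[, cls] * 1e6 + fold_sizes
        f <- which.min(score + stats::runif(n_folds) * 0.5)
        assign[gi] <- f
        fold_sizes[f] <- fold_sizes[f] + gsize[gi]
        class_in_fold[f, cls] <- class_in_fold[f, cls] + gsize[gi]
      }
      assign
    })
    out[, r] <- fold_of_group[as.character(groups)]
  }
  out
}

#' Audit a partition for similarity leakage
#'
#' Exhaustively checks every pair of records with Tanimoto similarity at or
#' above `threshold` and reports any pair separated by the partition.
#'
#' @param fp fingerprint [feature_matrix()] for all records.
#' @param assignment vector (holdout flag or fold id) per record.
#' @param threshold similarity threshold.
#' @return data.frame of violating pairs (empty when the partition is leak
#'   free).
#' @export
leakage_audit <- function(fp, assignment, threshold = 0.8) {
  sim <- tanimoto_matrix(fp)
  idx <- which(upper.tri(sim) & sim >= threshold, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(i = integer(0), j = integer(0),
                                    similarity = numeric(0)))
  bad <- assignment[idx[, 1]] != assignment[idx[, 2]]
  data.frame(i = idx[bad, 1], j = idx[bad, 2],
             similarity = sim[idx[bad, , drop = FALSE]])
}
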