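# Molecular featurization: descriptor vectors, hashed graph fingerprints,
# MACCS keys, and Tanimoto similarity.

#' Construct a feature matrix
#'
#' Container for an n x d numeric feature block with its encoder identity and
#' parameters, keyed by canonical SMILES. Most users obtain one from
#' [descriptors()] or [fingerprint()] rather than calling this directly.
#'
#' @param values numeric matrix (rows = molecules, columns = features).
#' @param encoder_id one of `"descriptors"`, `"morgan_bits"`,
#'   `"morgan_counts"`, `"maccs"`, `"path_fp"`, `"torsion_fp"`,
#'   `"atompair_fp"`.
#' @param encoder_params named list of encoder parameters (radius, n_bits,
#'   imputation policy, backend version ...).
#' @param row_keys canonical SMILES, one per row.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, encoder_id, encoder_params = list(), row_keys) {
  stopifnot(is.matrix(values), is.numeric(values),
            length(row_keys) == nrow(values), !is.null(colnames(values)))
  encoder_id <- match.arg(encoder_id, c("descriptors", "morgan_bits",
                                        "morgan_counts", "maccs", "path_fp",
                                        "torsion_fp", "atompair_fp"))
  structure(list(values = values, feature_names = colnames(values),
                 encoder_id = encoder_id, encoder_params = encoder_params,
                 row_keys = row_keys),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d molecules x %d features\n",
              x$encoder_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# subset rows, keeping metadata
fm_subset <- function(fm, idx) {
  feature_matrix(fm$values[idx, , drop = FALSE], fm$encoder_id,
                 fm$encoder_params, fm$row_keys[idx])
}

#' Physicochemical and topological molecular descriptors
#'
#' Computes the backend's built-in property set (OpenBabel: molecular weight
#' `MW`, `logP`, molar refractivity `MR`, topological polar surface area
#' `TPSA`, hydrogen-bond donor/acceptor counts `HBD`, `HBA1`, `HBA2`,
#' fluorine count `nF`) augmented with graph-topological descriptors computed
#' from the parsed Kekulé graph (atom/ring/rotatable-bond counts, heteroatom
#' composition, Randic-type connectivity indices `Chi0`/`Chi1`, Wiener and
#' Zagreb indices, fraction of sp3 carbons). Columns that are entirely
#' non-finite are dropped; remaining non-finite holes are median-imputed.
#' Both steps are recorded in `encoder_params`.
#'
#' @param smiles_list character vector of SMILES (canonicalized internally,
#'   so equivalent spellings of one molecule give identical rows).
#' @return a [feature_matrix()] with `encoder_id = "descriptors"`. Rows for
#'   unparseable SMILES are excluded and reported in
#'   `encoder_params$failed_smiles`.
#' @export
#' @examples
#' fm <- descriptors(c("CCO", "c1ccccc1C=O"))
#' fm$values[, c("MW", "logP", "HBD")]
descriptors <- function(smiles_list) {
  can <- canonicalize_smiles(smiles_list)
  keep <- which(!is.na(can))
  if (!length(keep)) stop("no SMILES could be parsed")
  can_ok <- can[keep]
  sdf <- ChemmineR::smiles2sdf(stats::setNames(can_ok, paste0("m", seq_along(can_ok))))
  prop <- ChemmineR::propOB(sdf)
  ob_cols <- c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA")
  ob_cols <- intersect(ob_cols, colnames(prop))
  ob <- as.matrix(prop[, ob_cols, drop = FALSE])
  graphs <- lapply(seq_along(can_ok), function(i) .mol_graph_from_sdf(sdf[[i]], can_ok[i]))
  topo <- t(vapply(graphs, .graph_descriptors, numeric(length(.TOPO_NAMES))))
  colnames(topo) <- .TOPO_NAMES
  vals <- cbind(ob, topo)
  rownames(vals) <- NULL
  storage.mode(vals) <- "double"
  # imputation policy: drop all-non-finite columns, then median-impute holes
  finite_any <- apply(vals, 2, function(v) any(is.finite(v)))
  dropped <- colnames(vals)[!finite_any]
  vals <- vals[, finite_any, drop = FALSE]
  imputed <- character(0)
  for (j in seq_len(ncol(vals))) {
    bad <- !is.finite(vals[, j])
    if (any(bad)) {
      vals[bad, j] <- stats::median(vals[!bad, j])
      imputed <- c(imputed, colnames(vals)[j])
    }
  }
  feature_matrix(vals, "descriptors",
                 encoder_params = list(
                   backend = .chem_engine(),
                   imputation = "drop all-non-finite columns, median-impute remaining holes",
                   dropped_columns = dropped,
                   imputed_columns = imputed,
                   failed_smiles = smiles_list[is.na(can)]),
                 row_keys = can_ok)
}

.TOPO_NAMES <- c("HeavyAtomCount", "NumC", "NumN", "NumO", "NumS",
                 "NumHeteroatoms", "NumRings", "NumRingAtoms",
                 "NumRotatableBonds", "NumDoubleBonds", "NumTripleBonds",
                 "Chi0", "Chi1", "WienerIndex", "ZagrebIndex",
                 "FractionCSP3", "MeanAtomicMass", "NumHImplicit")

.graph_descriptors <- function(g) {
  n <- length(g$elements)
  deg <- g$degree
  ords <- g$bonds[, "order"]
  n_comp <- if (nrow(g$bonds)) {
    sum(!is.finite(g$dist[1, ])) + 1L  # crude; exact below
  } else n
  # cyclomatic number: m - n + number of connected components
  comp <- if (n > 1) {
    d <- g$dist
    # count components from the distance matrix
    seen <- rep(FALSE, n); k <- 0L
    for (i in seq_len(n)) if (!seen[i]) { k <- k + 1L; seen[is.finite(d[i, ])] <- TRUE }
    k
  } else 1L
  n_rings <- nrow(g$bonds) - n + comp
  rot <- 0L
  if (nrow(g$bonds)) {
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds[b, "from"]; j <- g$bonds[b, "to"]
      if (ords[b] == 1L && deg[i] > 1L && deg[j] > 1L) {
        # acyclic single bond between non-terminal atoms
        ring_bond <- g$in_ring[i] && g$in_ring[j] &&
          .bond_in_ring(g, b)
        if (!ring_bond) rot <- rot + 1L
      }
    }
  }
  chi0 <- sum(1 / sqrt(pmax(deg, 1)))
  chi1 <- if (nrow(g$bonds))
    sum(1 / sqrt(deg[g$bonds[, "from"]] * deg[g$bonds[, "to"]])) else 0
  dfin <- g$dist[is.finite(g$dist)]
  wiener <- sum(dfin) / 2
  is_c <- g$elements == "C"
  sp3 <- if (any(is_c)) {
    csp3 <- vapply(which(is_c), function(i) {
      touches <- g$bonds[, "from"] == i | g$bonds[, "to"] == i
      !any(ords[touches] > 1L)
    }, logical(1))
    mean(csp3)
  } else 0
  mass <- .ATOMIC_MASS[g$elements]
  c(n, sum(is_c), sum(g$elements == "N"), sum(g$elements == "O"),
    sum(g$elements == "S"), sum(!is_c), n_rings, sum(g$in_ring),
    rot, sum(ords == 2L), sum(ords == 3L),
    chi0, chi1, wiener, sum(deg^2), sp3,
    mean(mass, na.rm = TRUE), sum(g$n_h))
}

.bond_in_ring <- function(g, b) {
  # a bond is in a ring iff it is not a bridge; recompute via igraph lazily
  gr <- igraph::graph_from_edgelist(g$bonds[, c("from", "to"), drop = FALSE],
                                    directed = FALSE)
  !(b %in% as.integer(igraph::bridges(gr)))
}

# ---- hashed graph fingerprints ---------------------------------------------

# deterministic 31-bit polynomial hash of an integer sequence
.hash_ints <- function(v) {
  h <- 5381
  for (x in v) h <- (h * 33 + x + 1) %% 2147483629
  h
}

.atom_ids <- function(g) {
  vapply(seq_along(g$elements), function(i)
    .hash_ints(c(g$anum[i], g$degree[i], g$n_h[i], as.integer(g$in_ring[i]))),
    numeric(1))
}

# neighbor lists with bond orders
.nbrs <- function(g) {
  n <- length(g$elements)
  out <- replicate(n, list(idx = integer(0), ord = integer(0)), simplify = FALSE)
  if (nrow(g$bonds)) for (b in seq_len(nrow(g$bonds))) {
    i <- g$bonds[b, "from"]; j <- g$bonds[b, "to"]; o <- g$bonds[b, "order"]
    out[[i]]$idx <- c(out[[i]]$idx, j); out[[i]]$ord <- c(out[[i]]$ord, o)
    out[[j]]$idx <- c(out[[j]]$idx, i); out[[j]]$ord <- c(out[[j]]$ord, o)
  }
  out
}

.morgan_features <- function(g, radius) {
  ids <- .atom_ids(g)
  nb <- .nbrs(g)
  feats <- ids
  cur <- ids
  for (r in seq_len(radius)) {
    nxt <- cur
    for (i in seq_along(cur)) {
      if (length(nb[[i]]$idx)) {
        pairs <- cbind(nb[[i]]$ord, cur[nb[[i]]$idx])
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        nxt[i] <- .hash_ints(c(r, cur[i], as.vector(t(pairs))))
      } else {
        nxt[i] <- .hash_ints(c(r, cur[i]))
      }
    }
    feats <- c(feats, nxt)
    cur <- nxt
  }
  feats
}

.torsion_features <- function(g) {
  nb <- .nbrs(g)
  tids <- vapply(seq_along(g$elements), function(i)
    .hash_ints(c(g$anum[i], g$degree[i], g$n_h[i])), numeric(1))
  feats <- numeric(0)
  if (!nrow(g$bonds)) return(feats)
  for (b in seq_len(nrow(g$bonds))) {
    j <- g$bonds[b, "from"]; k <- g$bonds[b, "to"]; ojk <- g$bonds[b, "order"]
    for (ii in seq_along(nb[[j]]$idx)) {
      i <- nb[[j]]$idx[ii]
      if (i == k) next
      for (ll in seq_along(nb[[k]]$idx)) {
        l <- nb[[k]]$idx[ll]
        if (l == j || l == i) next
        fwd <- c(tids[i], nb[[j]]$ord[ii], tids[j], ojk, tids[k],
                 nb[[k]]$ord[ll], tids[l])
        rev <- base::rev(fwd)
        seqv <- if (.lex_le(fwd, rev)) fwd else rev
        feats <- c(feats, .hash_ints(seqv))
      }
    }
  }
  feats
}

.atompair_features <- function(g) {
  tids <- vapply(seq_along(g$elements), function(i)
    .hash_ints(c(g$anum[i], g$degree[i], g$n_h[i])), numeric(1))
  n <- length(tids)
  feats <- numeric(0)
  if (n < 2) return(feats)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d <- g$dist[i, j]
    if (!is.finite(d)) next
    lo <- min(tids[i], tids[j]); hi <- max(tids[i], tids[j])
    feats <- c(feats, .hash_ints(c(lo, d, hi)))
  }
  feats
}

.path_features <- function(g, max_len = 7L) {
  nb <- .nbrs(g)
  n <- length(g$elements)
  feats <- numeric(0)
  if (!nrow(g$bonds)) return(feats)
  walk <- function(path, ords, visited) {
    if (length(path) > 1L) {
      fwd <- .path_seq(g, path, ords)
      rev <- .path_seq(g, base::rev(path), base::rev(ords))
      seqv <- if (.lex_le(fwd, rev)) fwd else rev
      feats <<- c(feats, .hash_ints(seqv))
    }
    if (length(ords) >= max_len) return(invisible())
    tip <- path[length(path)]
    for (ii in seq_along(nb[[tip]]$idx)) {
      nx <- nb[[tip]]$idx[ii]
      if (!visited[nx]) {
        visited[nx] <- TRUE
        walk(c(path, nx), c(ords, nb[[tip]]$ord[ii]), visited)
        visited[nx] <- FALSE
      }
    }
  }
  for (s in seq_len(n)) {
    visited <- rep(FALSE, n); visited[s] <- TRUE
    walk(s, integer(0), visited)
  }
  feats
}

.path_seq <- function(g, path, ords) {
  out <- g$anum[path[1]]
  for (i in seq_along(ords)) out <- c(out, ords[i], g$anum[path[i + 1]])
  out
}

.lex_le <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  TRUE
}

#' Molecular fingerprints
#'
#' Deterministic fingerprint encodings of molecules. `morgan_bits` and
#' `morgan_counts` are hashed circular (Morgan-type) fingerprints of atom
#' environments up to `radius` (default 3, folded to `n_bits` = 2048, the
#' setting also used for similarity grouping); `torsion_fp` hashes 4-atom
#' linear torsions; `atompair_fp` hashes (atom type, atom type, topological
#' distance) triples; `path_fp` hashes linear paths of 1-7 bonds; `maccs`
#' is the fixed 166-key substructure fingerprint computed by OpenBabel.
#' Inputs are canonicalized first, so equivalent SMILES spellings of one
#' molecule yield identical fingerprints.
#'
#' @param smiles_list character vector of SMILES.
#' @param kind one of `"morgan_bits"`, `"morgan_counts"`, `"maccs"`,
#'   `"path_fp"`, `"torsion_fp"`, `"atompair_fp"`.
#' @param radius circular-environment radius for Morgan fingerprints.
#' @param n_bits folded length for hashed fingerprints.
#' @return a [feature_matrix()]; bit encoders contain only 0/1, count
#'   encoders non-negative integers.
#' @export
#' @examples
#' fp <- fingerprint(c("CCO", "OCC"), "morgan_bits")
#' identical(fp$values[1, ], fp$values[2, ])
fingerprint <- function(smiles_list, kind = "morgan_bits", radius = 3L,
                        n_bits = 2048L) {
  kind <- match.arg(kind, c("morgan_bits", "morgan_counts", "maccs",
                            "path_fp", "torsion_fp", "atompair_fp"))
  can <- canonicalize_smiles(smiles_list)
  keep <- which(!is.na(can))
  if (!length(keep)) stop("no SMILES could be parsed")
  can_ok <- can[keep]
  params <- list(backend = .chem_engine(), radius = radius, n_bits = n_bits)
  if (kind == "maccs") {
    mols <- ChemmineOB::forEachMol(
      "SMILES", paste(can_ok, seq_along(can_ok), sep = "\t", collapse = "\n"),
      identity)
    vals <- ChemmineOB::fingerprint_OB(mols, "MACCS")
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
    vals <- vals[, seq_len(min(167L, ncol(vals))), drop = FALSE]
    colnames(vals) <- paste0("maccs_", seq_len(ncol(vals)))
    rownames(vals) <- NULL
    storage.mode(vals) <- "double"
    params$n_bits <- ncol(vals)
    return(feature_matrix(vals, "maccs", params, can_ok))
  }
  graphs <- parse_molecules(can_ok)
  featfun <- switch(kind,
    morgan_bits = , morgan_counts = function(g) .morgan_features(g, radius),
    torsion_fp = .torsion_features,
    atompair_fp = .atompair_features,
    path_fp = function(g) .path_features(g))
  counts <- kind %in% c("morgan_counts", "torsion_fp", "atompair_fp")
  vals <- matrix(0, nrow = length(graphs), ncol = n_bits,
                 dimnames = list(NULL, paste0(kind, "_", seq_len(n_bits) - 1L)))
  for (i in seq_along(graphs)) {
    feats <- featfun(graphs[[i]])
    if (!length(feats)) next
    slots <- (feats %% n_bits) + 1L
    tab <- table(slots)
    j <- as.integer(names(tab))
    vals[i, j] <- if (counts) as.numeric(tab) else 1
  }
  feature_matrix(vals, kind, params, can_ok)
}

#' Tanimoto similarity between two fingerprints
#'
#' \eqn{|a \cap b| / |a \cup b|} over set bits. Count fingerprints are
#' binarized (> 0). When both fingerprints are empty the similarity is
#' defined as 0 (maximally dissimilar) and flagged with an
#' `empty_pair` attribute, so downstream grouping never merges featureless
#' molecules.
#'
#' @param a,b numeric fingerprint vectors of equal length (rows of a
#'   fingerprint [feature_matrix()]), or two single-row `feature_matrix`
#'   objects of the same `encoder_id` and parameters.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (inherits(a, "feature_matrix") || inherits(b, "feature_matrix")) {
    stopifnot(inherits(a, "feature_matrix"), inherits(b, "feature_matrix"))
    if (!identical(a$encoder_id, b$encoder_id) ||
        !identical(a$encoder_params[c("radius", "n_bits")],
                   b$encoder_params[c("radius", "n_bits")]))
      stop("fingerprints have mismatched encoders or parameters")
    a <- a$values[1, ]; b <- b$values[1, ]
  }
  if (length(a) != length(b)) stop("fingerprints have different lengths")
  av <- a > 0; bv <- b > 0
  inter <- sum(av & bv)
  uni <- sum(av | bv)
  if (uni == 0) return(structure(0, empty_pair = TRUE))
  inter / uni
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param fm a bit fingerprint [feature_matrix()] (counts are binarized).
#' @return symmetric n x n similarity matrix.
#' @export
tanimoto_matrix <- function(fm) {
  X <- (fm$values > 0) * 1
  inter <- X %*% t(X)
  pop <- rowSums(X)
  uni <- outer(pop, pop, "+") - inter
  sim <- ifelse(uni > 0, inter / uni, 0)
  diag(sim) <- 1
  sim
}
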