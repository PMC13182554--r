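# SMILES handling: syntax validation, canonicalization, and molecular graphs.
#
# OpenBabel (via ChemmineOB) is the single canonicalization engine. It is
# permissive and silently repairs some syntactically broken strings
# ("C(" parses as methane), so a structural pre-check enforces balanced
# parentheses, ring-bond closures and bracket atoms before the engine runs.

#' Check basic SMILES syntax
#'
#' Lightweight structural validation: legal character set, balanced
#' parentheses, paired ring-closure digits (including `%nn` two-digit
#' closures) and closed bracket atoms. This is a necessary, not sufficient,
#' condition for validity; the canonicalization engine has the final word.
#'
#' @param s a single SMILES string.
#' @return `TRUE` or `FALSE`.
#' @export
smiles_syntax_valid <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s)) return(FALSE)
  if (grepl("[[:space:]]", s)) return(FALSE)
  if (grepl("[^A-Za-z0-9()\\[\\]=#:+/\\\\.%@-]", s)) return(FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_bracket <- FALSE
  ring_open <- integer(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (in_bracket) {
      if (ch == "[") return(FALSE)
      if (ch == "]") in_bracket <- FALSE
    } else if (ch == "[") {
      in_bracket <- TRUE
    } else if (ch == "]") {
      return(FALSE)
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
        return(FALSE)
      num <- as.integer(paste0(chars[i + 1L], chars[i + 2L]))
      ring_open <- .toggle_ring(ring_open, num)
      i <- i + 2L
    } else if (grepl("[0-9]", ch)) {
      ring_open <- .toggle_ring(ring_open, as.integer(ch))
    }
    i <- i + 1L
  }
  !in_bracket && depth == 0L && length(ring_open) == 0L
}

.toggle_ring <- function(open, num) {
  hit <- match(num, open)
  if (is.na(hit)) c(open, num) else open[-hit]
}

#' Canonicalize SMILES strings
#'
#' Produces a deterministic canonical SMILES for each input using the
#' OpenBabel canonicalization engine, after a structural syntax pre-check.
#' Unparseable input yields `NA` (the failure marker) rather than an error,
#' so batch pipelines never abort on a single bad record; the per-element
#' failure message is available in `attr(result, "failure_message")`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of the same length: canonical SMILES, or `NA`
#'   for failures, with a `failure_message` attribute (NA where successful)
#'   and an `engine` attribute naming the backend.
#' @export
#' @examples
#' canonicalize_smiles(c("OCC", "CCO", "C("))
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  msg <- rep(NA_character_, length(smiles))
  if (length(smiles) == 0L) {
    attr(out, "failure_message") <- msg
    attr(out, "engine") <- .chem_engine()
    return(out)
  }
  ok <- vapply(smiles, smiles_syntax_valid, logical(1), USE.NAMES = FALSE)
  msg[!ok] <- "SMILES syntax error: unbalanced parentheses, ring closures or brackets, or illegal character"
  idx <- which(ok)
  if (length(idx)) {
    inp <- paste(paste0(smiles[idx], "\t", seq_along(idx)), collapse = "\n")
    res <- ChemmineOB::convertFormat("SMI", "CAN", inp)
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      p <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(p) >= 2L) {
        i <- suppressWarnings(as.integer(p[2]))
        if (!is.na(i) && nzchar(trimws(p[1]))) out[idx[i]] <- trimws(p[1])
      }
    }
    failed <- idx[is.na(out[idx])]
    msg[failed] <- "SMILES rejected by the canonicalization engine"
  }
  attr(out, "failure_message") <- msg
  attr(out, "engine") <- .chem_engine()
  out
}

.chem_engine <- function() {
  paste0("openbabel/ChemmineOB ", as.character(utils::packageVersion("ChemmineOB")))
}

# ---- molecular graphs ------------------------------------------------------

# standard valences used to infer implicit hydrogen counts on Kekulé graphs
.VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1,
              B = 3, Si = 4)
.ATOMIC_NUM <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                 S = 16, Cl = 17, Br = 35, I = 53)
.ATOMIC_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, Si = 28.086, P = 30.974, S = 32.06,
                  Cl = 35.453, Br = 79.904, I = 126.904)

#' Parse canonical SMILES into molecular graphs
#'
#' Converts each SMILES to a Kekulé molecular graph (heavy atoms only) with
#' per-atom element, degree, implicit hydrogen count and ring membership,
#' plus the bond list and the topological distance matrix. This is the
#' substrate for the native graph fingerprints and topological descriptors.
#'
#' @param smiles character vector of valid (ideally canonical) SMILES.
#' @return list of `mol_graph` objects (one per input), each a list with
#'   `elements`, `anum`, `degree`, `n_h`, `in_ring`, `bonds`
#'   (from/to/order matrix), `dist` (topological distances) and `smiles`.
#' @export
parse_molecules <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0L, !anyNA(smiles))
  sdf <- suppressWarnings(
    ChemmineR::smiles2sdf(stats::setNames(smiles, paste0("m", seq_along(smiles)))))
  lapply(seq_along(smiles), function(i) .mol_graph_from_sdf(sdf[[i]], smiles[i]))
}

.mol_graph_from_sdf <- function(mol, smi) {
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  elements <- sub("_.*$", "", rownames(ab))
  if (!length(elements) || !any(grepl("_", rownames(ab)))) {
    # single-heavy-atom molecules come back as degenerate SDF blocks;
    # recover the element from the SMILES itself
    m <- regmatches(smi, regexec("^\\[?([A-Z][a-z]?)", smi))[[1]]
    if (length(m) == 2) {
      elements <- m[2]
      bb <- matrix(integer(0), 0, 3)
    } else stop("cannot parse molecule: ", smi)
  }
  n <- length(elements)
  bb <- as.matrix(bb)
  if (is.null(dim(bb)) && length(bb) >= 3) bb <- matrix(bb, nrow = 1L)
  bonds <- if (length(bb) && nrow(bb) > 0 && ncol(bb) >= 3)
    cbind(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
          order = as.integer(bb[, 3]))
  else matrix(integer(0), ncol = 3,
              dimnames = list(NULL, c("from", "to", "order")))
  degree <- integer(n)
  sum_order <- integer(n)
  if (nrow(bonds)) {
    degree <- tabulate(c(bonds[, "from"], bonds[, "to"]), nbins = n)
    for (b in seq_len(nrow(bonds))) {
      sum_order[bonds[b, "from"]] <- sum_order[bonds[b, "from"]] + bonds[b, "order"]
      sum_order[bonds[b, "to"]] <- sum_order[bonds[b, "to"]] + bonds[b, "order"]
    }
  }
  val <- .VALENCE[elements]
  val[is.na(val)] <- 0
  n_h <- pmax(0L, as.integer(val) - sum_order)
  g <- igraph::graph_from_edgelist(bonds[, c("from", "to"), drop = FALSE],
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  in_ring <- rep(FALSE, n)
  if (nrow(bonds)) {
    bridge_eids <- igraph::bridges(g)
    ring_edges <- setdiff(seq_len(nrow(bonds)), as.integer(bridge_eids))
    in_ring[unique(c(bonds[ring_edges, "from"], bonds[ring_edges, "to"]))] <- TRUE
  }
  structure(list(
    elements = elements,
    anum = unname(.ATOMIC_NUM[elements]),
    degree = degree,
    n_h = n_h,
    in_ring = in_ring,
    bonds = bonds,
    dist = igraph::distances(g),
    smiles = smi
  ), class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d heavy atoms, %d bonds\n",
              x$smiles, length(x$elements), nrow(x$bonds)))
  invisible(x)
}
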