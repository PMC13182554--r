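# Curation: raw two-source records -> clean ordinal dataset.
#
# Free-text odor descriptions are mapped to the scale by an ordered
# case-insensitive keyword table (first match wins); records with invalid or
# multi-fragment (dot) SMILES are excluded; "very high" labels are
# reclassified to high; duplicates within the description-based source are
# removed; sources are merged with a configurable precedence; agreement on
# the overlap is quantified with quadratically weighted Cohen's kappa and
# ordinal Krippendorff's alpha.

#' Default keyword table for mapping odor descriptions
#'
#' An ordered table of lowercase keywords and the ordinal category each maps
#' to, scanned by substring in order with first match winning. These
#' defaults are illustrative phrase stems for the four strength categories;
#' callers with domain-specific vocabularies should load their own table
#' with [read_keyword_table()].
#'
#' @return data.frame with columns `keyword` and `category` (codes 0..3).
#' @export
default_keyword_table <- function() {
  data.frame(
    keyword = c("odorless", "odourless", "no odor", "no odour", "no smell",
                "scentless",
                "faint", "weak", "slight", "mild", "delicate",
                "moderate", "distinct", "noticeable", "characteristic",
                "strong", "intense", "pungent", "powerful", "penetrating"),
    category = c(rep(0L, 6), rep(1L, 5), rep(2L, 4), rep(3L, 5)),
    stringsAsFactors = FALSE
  )
}

#' Read or validate a keyword table
#'
#' @param path CSV file with columns `keyword`, `category`.
#' @param table a keyword data.frame to validate in place.
#' @return validated keyword table.
#' @export
read_keyword_table <- function(path) {
  validate_keyword_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_keyword_table
#' @export
validate_keyword_table <- function(table) {
  stopifnot(is.data.frame(table), all(c("keyword", "category") %in% names(table)))
  table$keyword <- tolower(table$keyword)
  if (any(!nzchar(table$keyword))) stop("keyword table contains empty keywords")
  if (anyDuplicated(table$keyword)) stop("keyword table contains duplicate keywords")
  if (!all(table$category %in% 0:3)) stop("categories must be codes 0..3")
  table
}

#' Map a free-text odor description to an ordinal code
#'
#' Case-insensitive substring scan over the keyword table in table order;
#' the first matching keyword's category is returned. No match returns `NA`.
#'
#' @param text character vector of descriptions.
#' @param table keyword table (see [default_keyword_table()]).
#' @return integer codes 0..3, `NA` where no keyword is present.
#' @export
#' @examples
#' map_description("Colorless, odorless gas.", default_keyword_table())
map_description <- function(text, table = default_keyword_table()) {
  table <- validate_keyword_table(table)
  lower <- tolower(text)
  out <- rep(NA_integer_, length(text))
  for (i in seq_len(nrow(table))) {
    hit <- is.na(out) & grepl(table$keyword[i], lower, fixed = TRUE)
    out[hit] <- table$category[i]
  }
  out
}

#' Prepare raw records for filtering
#'
#' Canonicalizes SMILES and resolves the strength code for each record: a
#' categorical `strength` word is mapped through the ordinal scale ("very
#' high" is kept for [apply_filters()] to reclassify); otherwise the
#' description is mapped through the keyword table. Records whose
#' description maps to nothing are flagged `unmapped_description`.
#'
#' @param records data.frame with columns `smiles`, `source`, `description`,
#'   `strength` (word or empty/NA).
#' @param keyword_table keyword table for description mapping.
#' @return data.frame with added columns `smiles_raw`, `smiles_canonical`,
#'   `strength_code`, `audit_flags`.
#' @export
prepare_records <- function(records, keyword_table = default_keyword_table()) {
  stopifnot(is.data.frame(records),
            all(c("smiles", "source") %in% names(records)))
  if (is.null(records$description)) records$description <- ""
  if (is.null(records$strength)) records$strength <- NA_character_
  out <- data.frame(smiles_raw = as.character(records$smiles),
                    source = as.character(records$source),
                    description = as.character(records$description),
                    strength_raw = as.character(records$strength),
                    stringsAsFactors = FALSE)
  out$smiles_canonical <- as.character(canonicalize_smiles(out$smiles_raw))
  has_word <- !is.na(out$strength_raw) & nzchar(trimws(out$strength_raw))
  out$strength_code <- NA_integer_
  out$strength_code[has_word] <- strength_code(out$strength_raw[has_word])
  very_high <- has_word & tolower(trimws(out$strength_raw)) == "very high"
  need_map <- !has_word & !is.na(out$description) & nzchar(out$description)
  out$strength_code[need_map] <- map_description(out$description[need_map],
                                                keyword_table)
  flags <- character(nrow(out))
  unmapped <- is.na(out$strength_code) & !very_high
  flags[unmapped] <- "unmapped_description"
  out$audit_flags <- flags
  out
}

.add_flag <- function(flags, idx, flag) {
  flags[idx] <- ifelse(nzchar(flags[idx]), paste(flags[idx], flag, sep = ";"),
                       flag)
  flags
}

#' Apply the curation filters
#'
#' Removes records with invalid SMILES; removes multi-fragment records (raw
#' SMILES containing a dot); within source B removes duplicate canonical
#' SMILES keeping the first occurrence; reclassifies the textual label
#' "very high" to high (code 3) with the `reclassified_very_high` flag; and
#' removes records without a resolved strength. Every removal or relabel is
#' counted by reason in the audit log.
#'
#' @param records output of [prepare_records()].
#' @return list with `retained` (filtered data.frame) and `audit` (named
#'   counts: `input`, `retained`, `invalid_smiles`, `dot_smiles`,
#'   `duplicate`, `unmapped_description`, `reclassified_very_high`).
#' @export
apply_filters <- function(records) {
  stopifnot(all(c("smiles_raw", "smiles_canonical", "source",
                  "strength_code", "audit_flags") %in% names(records)))
  n_in <- nrow(records)
  flags <- records$audit_flags
  very_high <- !is.na(records$strength_raw) &
    tolower(trimws(records$strength_raw)) == "very high"
  records$strength_code[very_high] <- 3L
  flags <- .add_flag(flags, which(very_high), "reclassified_very_high")

  dot <- grepl(".", records$smiles_raw, fixed = TRUE)
  invalid <- is.na(records$smiles_canonical) & !dot
  flags <- .add_flag(flags, which(invalid), "invalid_smiles")
  flags <- .add_flag(flags, which(dot), "dot_smiles")
  unmapped <- is.na(records$strength_code)

  drop <- invalid | dot | unmapped
  dup <- rep(FALSE, n_in)
  in_b <- which(records$source == "B" & !drop)
  if (length(in_b)) {
    d <- duplicated(records$smiles_canonical[in_b])
    dup[in_b[d]] <- TRUE
    flags <- .add_flag(flags, in_b[d], "duplicate")
  }
  records$audit_flags <- flags
  keep <- !(drop | dup)
  audit <- c(input = n_in,
             retained = sum(keep),
             invalid_smiles = sum(invalid),
             dot_smiles = sum(dot),
             duplicate = sum(dup),
             unmapped_description = sum(unmapped & !invalid & !dot),
             reclassified_very_high = sum(very_high & keep))
  # reasons are applied in order invalid/dot > unmapped > duplicate, and a
  # record is counted once under its first applicable removal reason
  audit[["unmapped_description"]] <- sum(unmapped & !invalid & !dot)
  list(retained = records[keep, , drop = FALSE], audit = audit)
}

#' Merge the two curated sources
#'
#' Union on canonical SMILES. When both sources label the same molecule the
#' configured precedence selects the kept label (default: source A, the
#' categorical-label source, wins); both originals are retained in the
#' overlap table for agreement analysis.
#'
#' @param records_a,records_b filtered records from [apply_filters()] for
#'   sources A and B.
#' @param precedence `"A"` or `"B"`.
#' @return list with `merged` (data.frame `smiles_canonical`, `strength_code`,
#'   `source`) and `overlap` (data.frame `smiles_canonical`, `label_A`,
#'   `label_B`).
#' @export
merge_sources <- function(records_a, records_b, precedence = c("A", "B")) {
  precedence <- match.arg(precedence)
  a <- records_a[!duplicated(records_a$smiles_canonical), , drop = FALSE]
  b <- records_b[!duplicated(records_b$smiles_canonical), , drop = FALSE]
  common <- intersect(a$smiles_canonical, b$smiles_canonical)
  overlap <- data.frame(
    smiles_canonical = common,
    label_A = a$strength_code[match(common, a$smiles_canonical)],
    label_B = b$strength_code[match(common, b$smiles_canonical)],
    stringsAsFactors = FALSE)
  only_a <- setdiff(a$smiles_canonical, common)
  only_b <- setdiff(b$smiles_canonical, common)
  win <- if (precedence == "A") overlap$label_A else overlap$label_B
  merged <- rbind(
    if (length(only_a))
      data.frame(smiles_canonical = only_a,
                 strength_code = a$strength_code[match(only_a, a$smiles_canonical)],
                 source = "A", stringsAsFactors = FALSE),
    if (length(only_b))
      data.frame(smiles_canonical = only_b,
                 strength_code = b$strength_code[match(only_b, b$smiles_canonical)],
                 source = "B", stringsAsFactors = FALSE),
    if (length(common))
      data.frame(smiles_canonical = common, strength_code = win,
                 source = precedence, stringsAsFactors = FALSE)
  )
  rownames(merged) <- NULL
  list(merged = merged, overlap = overlap)
}

# ---- agreement statistics ---------------------------------------------------

#' Quadratically weighted Cohen's kappa
#'
#' Chance-corrected agreement for two annotators on ordinal codes 0..K-1
#' with disagreement weights \eqn{w_{ij} = (i-j)^2/(K-1)^2} and
#' \eqn{\kappa = 1 - \sum w O / \sum w E}, E from the marginal products.
#' Negative values are reported as computed (agreement below chance).
#'
#' @param a,b integer codes of the two annotators, equal length.
#' @param K number of categories (default 4).
#' @return kappa in \[-1, 1\], or `NA` with attribute
#'   `undefined = TRUE` when the expected disagreement is 0 (all
#'   annotations in a single category).
#' @export
kappa_quadratic <- function(a, b, K = .K) {
  stopifnot(length(a) == length(b), length(a) > 0)
  a <- factor(as.integer(a), levels = 0:(K - 1))
  b <- factor(as.integer(b), levels = 0:(K - 1))
  O <- table(a, b) / length(a)
  E <- outer(rowSums(O), colSums(O))
  W <- outer(0:(K - 1), 0:(K - 1), function(i, j) (i - j)^2) / (K - 1)^2
  denom <- sum(W * E)
  if (denom == 0) return(structure(NA_real_, undefined = TRUE))
  1 - sum(W * O) / denom
}

#' Krippendorff's alpha at the ordinal level
#'
#' Coincidence-matrix formulation for any number of coders with missing
#' annotations. The ordinal distance between categories c < k is the squared
#' difference of their coincidence-marginal mid-ranks,
#' \eqn{(\sum_{g=c}^{k} n_g - (n_c + n_k)/2)^2}.
#'
#' @param ratings numeric matrix, units in rows, coders in columns, `NA`
#'   for missing annotations; values are ordinal codes.
#' @param levels the ordered codes of the scale (default 0..3).
#' @return alpha in \[-1, 1\], or `NA` with attribute `undefined = TRUE`
#'   when expected disagreement is 0.
#' @export
krippendorff_alpha_ordinal <- function(ratings, levels = 0:(.K - 1)) {
  stopifnot(is.matrix(ratings))
  L <- length(levels)
  o <- matrix(0, L, L, dimnames = list(levels, levels))
  for (u in seq_len(nrow(ratings))) {
    vals <- ratings[u, ]
    vals <- vals[!is.na(vals)]
    m <- length(vals)
    if (m < 2) next
    idx <- match(vals, levels)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i != j) o[idx[i], idx[j]] <- o[idx[i], idx[j]] + 1 / (m - 1)
    }
  }
  n_c <- rowSums(o)
  n <- sum(n_c)
  if (n <= 1) return(structure(NA_real_, undefined = TRUE))
  delta <- matrix(0, L, L)
  for (ci in seq_len(L)) for (ki in seq_len(L)) {
    if (ci == ki) next
    lo <- min(ci, ki); hi <- max(ci, ki)
    delta[ci, ki] <- (sum(n_c[lo:hi]) - (n_c[ci] + n_c[ki]) / 2)^2
  }
  d_o <- sum(o * delta) / n
  d_e <- sum(outer(n_c, n_c) * delta) / (n * (n - 1))
  if (d_e == 0) return(structure(NA_real_, undefined = TRUE))
  1 - d_o / d_e
}

#' Inter-source agreement report
#'
#' Computes the quadratically weighted Cohen's kappa on the overlap pairs
#' and ordinal Krippendorff's alpha on the full two-source reliability
#' matrix (molecules annotated by only one source enter with a missing
#' second annotation).
#'
#' @param overlap_pairs data.frame or matrix with two columns of ordinal
#'   codes (one row per molecule annotated by both sources).
#' @param full_a,full_b optional data.frames with columns `smiles_canonical`
#'   and `strength_code` covering each complete source; when supplied, alpha
#'   is computed on their union.
#' @return object of class `agreement_report`: `kappa_quadratic`,
#'   `krippendorff_alpha`, `n_overlap`, `contingency` (4x4 counts), plus
#'   `undefined` flags where a statistic's expected disagreement is 0.
#' @export
agreement <- function(overlap_pairs, full_a = NULL, full_b = NULL) {
  op <- as.data.frame(overlap_pairs)
  stopifnot(ncol(op) >= 2)
  a <- as.integer(op[[1]]); b <- as.integer(op[[2]])
  kap <- if (length(a)) kappa_quadratic(a, b) else structure(NA_real_, undefined = TRUE)
  if (!is.null(full_a) && !is.null(full_b)) {
    keys <- union(full_a$smiles_canonical, full_b$smiles_canonical)
    rel <- cbind(full_a$strength_code[match(keys, full_a$smiles_canonical)],
                 full_b$strength_code[match(keys, full_b$smiles_canonical)])
  } else {
    rel <- cbind(a, b)
  }
  alp <- krippendorff_alpha_ordinal(rel)
  cont <- table(factor(a, levels = 0:3), factor(b, levels = 0:3))
  structure(list(kappa_quadratic = as.numeric(kap),
                 krippendorff_alpha = as.numeric(alp),
                 n_overlap = length(a),
                 contingency = unclass(cont),
                 undefined = c(kappa = isTRUE(attr(kap, "undefined")),
                               alpha = isTRUE(attr(alp, "undefined")))),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n_overlap = %d, weighted kappa = %.3f, ordinal alpha = %.3f\n",
              x$n_overlap, x$kappa_quadratic, x$krippendorff_alpha))
  invisible(x)
}

#' Run the full curation pipeline on a raw record table
#'
#' Convenience composition: [prepare_records()], per-source
#' [apply_filters()], [merge_sources()] and [agreement()].
#'
#' @param records raw record data.frame (`smiles`, `source`, `description`,
#'   `strength`).
#' @param keyword_table keyword table for description mapping.
#' @param precedence merge precedence, `"A"` (default) or `"B"`.
#' @return list with `curated` (merged data.frame), `overlap`, `audit`
#'   (per-source audit counts) and `agreement` (an `agreement_report`).
#' @export
curate <- function(records, keyword_table = default_keyword_table(),
                   precedence = "A") {
  prep <- prepare_records(records, keyword_table)
  fa <- apply_filters(prep[prep$source == "A", , drop = FALSE])
  fb <- apply_filters(prep[prep$source == "B", , drop = FALSE])
  mrg <- merge_sources(fa$retained, fb$retained, precedence)
  agr <- agreement(mrg$overlap[, c("label_A", "label_B")],
                   full_a = fa$retained, full_b = fb$retained)
  list(curated = mrg$merged, overlap = mrg$overlap,
       audit = list(A = fa$audit, B = fb$audit), agreement = agr)
}
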