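#' The four-level ordinal odor-strength scale
#'
#' Odor strength is modeled as an ordered categorical variable with four
#' levels: odorless (0) < low (1) < medium (2) < high (3). All ordinal codes
#' in the package refer to this scale.
#'
#' @return An object of class `ordinal_scale` with the ordered category
#'   names and their integer codes.
#' @export
#' @examples
#' ordinal_scale()
ordinal_scale <- function() {
  structure(
    list(categories = c("odorless", "low", "medium", "high"), codes = 0:3),
    class = "ordinal_scale"
  )
}

#' @export
print.ordinal_scale <- function(x, ...) {
  cat("Ordinal odor-strength scale:",
      paste(sprintf("%s(%d)", x$categories, x$codes), collapse = " < "), "\n")
  invisible(x)
}

#' Convert strength words to ordinal codes
#'
#' Maps category names ("odorless", "low", "medium", "high") to codes 0..3.
#' The label "very high" is intentionally not part of the scale; the curation
#' filters reclassify it to high (see [apply_filters()]).
#'
#' @param x character vector of category names.
#' @return integer vector of codes, `NA` where the word is not on the scale.
#' @export
strength_code <- function(x) {
  sc <- ordinal_scale()
  m <- match(tolower(trimws(x)), sc$categories)
  as.integer(sc$codes[m])
}

#' @rdname strength_code
#' @param code integer vector of codes 0..3.
#' @export
strength_label <- function(code) {
  sc <- ordinal_scale()
  sc$categories[match(as.integer(code), sc$codes)]
}

# number of categories on the scale
.K <- 4L
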