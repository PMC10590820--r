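#' Parse a chemical formula into element counts
#'
#' Handles standard Hill-notation formulas such as `"C6H12O6"`, including
#' multi-letter elements and omitted counts. Charges and isotope labels are
#' not supported (they do not occur in the model dialects read here).
#'
#' @param formula formula string; `NA` or `""` give an empty count vector.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula))
    return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)
  if (m[[1]][1] == -1 || sum(attr(m[[1]], "match.length")) != nchar(formula))
    stop("cannot parse formula: '", formula, "'")
  toks <- regmatches(formula, m)[[1]]
  toks <- toks[nzchar(toks)]
  el <- sub("[0-9]*$", "", toks)
  ct <- sub("^[A-Za-z]+", "", toks)
  ct <- ifelse(ct == "", 1L, as.integer(ct))
  tapply(ct, el, sum)
}

#' Number of carbon atoms in a formula
#'
#' @inheritParams parse_formula
#' @return integer carbon count (0 for carbon-free or empty formulas).
#' @export
carbon_count <- function(formula) {
  counts <- tryCatch(parse_formula(formula), error = function(e) NULL)
  if (is.null(counts)) return(NA_integer_)
  cc <- counts["C"]
  if (length(cc) == 0 || is.na(cc)) 0L else as.integer(cc)
}
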