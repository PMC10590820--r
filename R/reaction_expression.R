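#' Map gene-level expression onto reactions through GPR rules
#'
#' Evaluates each reaction's GPR rule against gene values with the standard
#' min/max semantics (`and` = complex = minimum of subunits, `or` = isozyme =
#' maximum). Genes without data are ignored within an operator as long as at
#' least one child is scored; a reaction is `NA` only when its rule is empty
#' or no leaf has data. Raising any gene's value can never lower a reaction's
#' value (the mapping is monotone).
#'
#' @param net a [metabolic_network()].
#' @param gene_values named numeric vector of per-gene expression (one stage).
#' @param and_fun,or_fun aggregation functions, see [eval_gpr_value()].
#' @return named numeric vector over `net`'s reactions (the reaction
#'   expression array), `NA` where undefined.
#' @export
map_expression_to_reactions <- function(net, gene_values,
                                        and_fun = min, or_fun = max) {
  out <- vapply(net$reactions$gpr, function(rule)
    eval_gpr_value(parse_gpr(rule), gene_values, and_fun, or_fun),
    numeric(1), USE.NAMES = FALSE)
  stats::setNames(out, net$reactions$id)
}
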