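#' Reactions perturbed between two stage flux states
#'
#' Applies a fold-change cut-off to the flux values of reactions present in
#' both stages. With the noise floor `eps` (the global activity tolerance),
#' a common reaction is perturbed iff
#' `ratio = max(|vB|, eps) / max(|vA|, eps)` reaches the cut-off in either
#' direction (inclusive), or the two fluxes have opposite signs with both
#' magnitudes above `eps` (a direction reversal counts as a perturbation even
#' at equal magnitude). Fluxes both below `eps` never count.
#'
#' @param state_a,state_b [select_optimal_state()] results (or named flux
#'   vectors) for the initial and later stage.
#' @param fold_cutoff fold-change threshold (default 2, inclusive).
#' @param eps noise floor for ratios (default 1e-6).
#' @return object of class `transition_report`: list with `common`
#'   (character), `perturbed` (character), `log2_ratio` (named, over common),
#'   and `baseline_correlation` (Pearson r of the two flux profiles over the
#'   perturbed set; `NA` if undefined).
#' @export
perturbed_reactions <- function(state_a, state_b, fold_cutoff = 2, eps = 1e-6) {
  va <- if (inherits(state_a, "flux_state")) state_a$flux else state_a
  vb <- if (inherits(state_b, "flux_state")) state_b$flux else state_b
  common <- intersect(names(va), names(vb))
  if (!length(common)) stop("no reactions common to both states")
  a <- va[common]; b <- vb[common]
  ratio <- pmax(abs(b), eps) / pmax(abs(a), eps)
  fold_hit <- ratio >= fold_cutoff | ratio <= 1 / fold_cutoff
  sign_flip <- (sign(a) * sign(b) < 0) & abs(a) > eps & abs(b) > eps
  perturbed <- common[fold_hit | sign_flip]
  bc <- tryCatch(baseline_correlation(a, b, perturbed), error = function(e) NA_real_)
  structure(list(common = common, perturbed = perturbed,
                 log2_ratio = log2(ratio), baseline_correlation = bc,
                 fold_cutoff = fold_cutoff, eps = eps),
            class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  cat("<transition_report> ", length(x$perturbed), " perturbed of ",
      length(x$common), " common reactions; baseline correlation ",
      signif(x$baseline_correlation, 4), "\n", sep = "")
  invisible(x)
}

#' Correlation between two flux profiles over a reaction set
#'
#' Pearson correlation of the two (signed) flux vectors restricted to the
#' given reactions - the transition's baseline when the set is the perturbed
#' set.
#'
#' @param state_a,state_b flux states or named flux vectors.
#' @param reactions reaction ids to correlate over (>= 3, both vectors must
#'   vary).
#' @return Pearson correlation coefficient.
#' @export
baseline_correlation <- function(state_a, state_b, reactions) {
  va <- if (inherits(state_a, "flux_state")) state_a$flux else state_a
  vb <- if (inherits(state_b, "flux_state")) state_b$flux else state_b
  if (length(reactions) < 3) stop("need >= 3 reactions for a correlation")
  a <- va[reactions]; b <- vb[reactions]
  if (anyNA(a) || anyNA(b)) stop("reaction missing from a state")
  if (sd(a) < 1e-15 || sd(b) < 1e-15) stop("zero flux variance over the set")
  cor(a, b)
}

#' Hypergeometric subsystem enrichment of a perturbed reaction set
#'
#' For each subsystem, the upper-tail hypergeometric probability of observing
#' at least the seen overlap between the subsystem's reactions and the
#' perturbed set, in a universe of `N` reactions (by default the reactions of
#' `net`, i.e. those common to both stage models when `net` is restricted
#' accordingly). Reactions without a subsystem are pooled under
#' `"unassigned"`.
#'
#' @param perturbed character vector of perturbed reaction ids.
#' @param net a [metabolic_network()] defining universe and subsystem labels.
#' @param p_cutoff significance flag threshold (default 0.05, raw p).
#' @param adjust p adjustment method (default `"none"`; `"BH"` available).
#' @return data.frame sorted by p: `subsystem`, `overlap` (k), `size` (K),
#'   `perturbed_total` (n), `universe` (N), `p`, `p_adj`, `significant`.
#' @export
subsystem_enrichment <- function(perturbed, net, p_cutoff = 0.05,
                                 adjust = "none") {
  ids <- net$reactions$id
  perturbed <- intersect(perturbed, ids)
  subs <- net$reactions$subsystem
  subs[is.na(subs) | !nzchar(subs)] <- "unassigned"
  N <- length(ids)
  n <- length(perturbed)
  hit <- ids %in% perturbed
  out <- do.call(rbind, lapply(unique(subs), function(s) {
    inset <- subs == s
    K <- sum(inset)
    k <- sum(inset & hit)
    data.frame(subsystem = s, overlap = k, size = K, perturbed_total = n,
               universe = N,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out$significant <- out$p_adj < p_cutoff
  out <- out[order(out$p, out$subsystem), , drop = FALSE]
  rownames(out) <- NULL
  out
}
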