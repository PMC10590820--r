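#' Select the expression-correlated optimal flux state
#'
#' From a set of sampled flux vectors, returns the one whose flux magnitudes
#' correlate best (Pearson, by default) with the reaction expression array,
#' computed over the scored reactions. Samples with zero flux variance over
#' the scored set are skipped (correlation undefined, logged). Ties go to the
#' lowest sample index.
#'
#' @param samples a [sample_fluxes()] result.
#' @param exp reaction expression array (named numeric, `NA` = unscored).
#' @param method correlation flavour, `"pearson"` (default) or `"spearman"`.
#' @param use_abs correlate `|flux|` (default) or signed flux.
#' @return object of class `flux_state`: list with `flux` (named vector),
#'   `correlation`, `sample_index`, `seed`.
#' @export
select_optimal_state <- function(samples, exp, method = "pearson",
                                 use_abs = TRUE) {
  pts <- samples$points
  exp <- exp[rownames(pts)]
  scored <- which(!is.na(exp))
  if (length(scored) < 3) stop("need >= 3 scored reactions")
  if (!ncol(pts)) stop("no samples")
  e <- exp[scored]
  if (sd(e) < 1e-15) stop("expression has zero variance over scored reactions")
  best <- -Inf; best_j <- NA_integer_
  skipped <- 0L
  for (j in seq_len(ncol(pts))) {
    f <- pts[scored, j]
    if (use_abs) f <- abs(f)
    if (sd(f) < 1e-15) { skipped <- skipped + 1L; next }
    r <- cor(f, e, method = method)
    if (is.finite(r) && r > best) { best <- r; best_j <- j }
  }
  if (skipped) message("select_optimal_state: skipped ", skipped,
                       " zero-variance sample(s)")
  if (is.na(best_j)) stop("no sample with defined correlation")
  structure(list(flux = pts[, best_j], correlation = best,
                 sample_index = best_j, seed = samples$seed),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state> ", length(x$flux), " reactions; correlation with expression ",
      signif(x$correlation, 4), " (sample ", x$sample_index, ")\n", sep = "")
  invisible(x)
}

#' Metabolic functionality score
#'
#' Number of sink reactions whose FBA maximum exceeds the reaction activity
#' threshold, i.e. how many growth-essential metabolites the model can still
#' synthesise. Sinks absent from the model count as inactive.
#'
#' @param net a [metabolic_network()] with sink reactions added.
#' @param sink_ids sink reaction ids (see [sink_ids()]).
#' @param activity_tol activity threshold (default 1e-6).
#' @return list with `score` (integer) and `flux` (named per-sink maxima,
#'   `NA` for sinks not in the model).
#' @export
functionality_score <- function(net, sink_ids, activity_tol = 1e-6) {
  flux <- stats::setNames(rep(NA_real_, length(sink_ids)), sink_ids)
  present <- sink_ids[sink_ids %in% net$reactions$id]
  # a sink in an infeasible (over-constrained) model cannot be produced
  for (s in present)
    flux[s] <- tryCatch(fba_maximize(net, s), error = function(e) 0)
  list(score = sum(!is.na(flux) & flux > activity_tol), flux = flux)
}

# draw a flux-consistent random subnetwork of (approximately) a target size:
# start from a uniform random reaction subset, prune to consistency, and
# greedily re-add removed reactions (or re-draw from an overshooting set)
# until the consistent size is within the slack; the best draw seen is kept
random_consistent_model <- function(parent, size, tol = 1e-6,
                                    size_slack = 0.02, max_tries = 25L) {
  ids <- parent$reactions$id
  stopifnot(size <= length(ids))
  cand <- sample(ids, size)
  cur <- flux_consistent_subnetwork2(parent, cand, tol)
  best <- cur
  tries <- 0L
  while (abs(nrow(cur$reactions) - size) > size_slack * size &&
         tries < max_tries) {
    tries <- tries + 1L
    deficit <- size - nrow(cur$reactions)
    if (deficit > 0) {
      pool <- setdiff(ids, cand)
      if (!length(pool)) break
      cand <- union(cand, sample(pool, min(length(pool), max(deficit, 1L))))
    } else {
      cand <- sample(cur$reactions$id, size)
    }
    cur <- flux_consistent_subnetwork2(parent, cand, tol)
    if (abs(nrow(cur$reactions) - size) < abs(nrow(best$reactions) - size))
      best <- cur
  }
  if (abs(nrow(cur$reactions) - size) <= abs(nrow(best$reactions) - size))
    best <- cur
  best
}

# consistent subnetwork of a reaction subset (empty-safe helper)
flux_consistent_subnetwork2 <- function(parent, rxn_ids, tol) {
  sub <- subnetwork(parent, rxn_ids)
  if (!nrow(sub$reactions)) return(sub)
  tryCatch(flux_consistent_subnetwork(sub, tol),
           error = function(e) subnetwork(parent, character(0)))
}

#' Randomisation significance of a functionality score
#'
#' Compares a context model's functionality score with the scores of `iter`
#' random flux-consistent subnetworks of the parent drawn at (approximately)
#' the same reaction count. The p value is the fraction of random models
#' scoring strictly higher, as the strict inequality is defined: p = 0 is
#' attainable for a maximal score.
#'
#' @param parent the parent [metabolic_network()] (with sinks added).
#' @param context the extracted context model (network or `context_model`).
#' @param sink_ids sink reaction ids.
#' @param iter number of random models (default 1000).
#' @param seed integer random seed.
#' @param activity_tol activity threshold for the score.
#' @return list with `met_score`, `sink_flux`, `p_value`, `random_scores`.
#' @export
functionality_significance <- function(parent, context, sink_ids, iter = 1000L,
                                       seed = 1L, activity_tol = 1e-6) {
  stopifnot(nrow(context$reactions) <= nrow(parent$reactions))
  fs <- functionality_score(context, sink_ids, activity_tol)
  size <- nrow(context$reactions)
  scores <- with_seed(seed, {
    vapply(seq_len(iter), function(i) {
      rnd <- random_consistent_model(parent, size, tol = activity_tol)
      if (abs(nrow(rnd$reactions) - size) > 0.02 * size)
        warning("random model draw ", i, ": achieved size ",
                nrow(rnd$reactions), " (target ", size, ")")
      functionality_score(rnd, sink_ids, activity_tol)$score
    }, numeric(1))
  })
  list(met_score = fs$score, sink_flux = fs$flux,
       p_value = sum(scores > fs$score) / iter, random_scores = scores)
}
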