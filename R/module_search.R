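#' Clamp a reaction's bounds to its reference (initial-stage) flux
#'
#' The reaction-modulation bound rule: a negative reference flux gives
#' `(lb, ub) = (ref, 0)`, a positive one `(0, ref)`, and zero `(0, 0)`.
#' Re-clamping an already clamped reaction changes nothing.
#'
#' @param net a [metabolic_network()] (the later-stage model).
#' @param reaction reaction id to modulate.
#' @param ref_flux the reaction's flux in the initial-stage state.
#' @return the modulated network.
#' @export
clamp_to_reference <- function(net, reaction, ref_flux) {
  if (!reaction %in% net$reactions$id) stop("unknown reaction: ", reaction)
  if (ref_flux < 0) set_bounds(net, reaction, lb = ref_flux, ub = 0)
  else if (ref_flux > 0) set_bounds(net, reaction, lb = 0, ub = ref_flux)
  else set_bounds(net, reaction, lb = 0, ub = 0)
}

#' Correlation with the initial state after modulating a model
#'
#' Re-estimates the modulated model's flux state and returns its Pearson
#' correlation with the initial-stage state over the perturbed reaction set.
#' Two evaluators are provided:
#' \describe{
#'   \item{`"sample"`}{fresh hit-and-run sampling run (protocol fixed by
#'     `seed`), optimal state selected by correlation with the later-stage
#'     reaction expression - the full protocol.}
#'   \item{`"project"`}{a deterministic LP surrogate: the feasible flux
#'     vector of the modulated model with minimal L1 distance to the initial
#'     state over the perturbed set. Cheap and noise-free; preferable for
#'     small networks where a sampled correlation over few reactions is
#'     dominated by chain noise.}
#' }
#' An infeasible modulated model yields `-Inf` (candidate rejected, logged).
#'
#' @param net_mod the modulated [metabolic_network()].
#' @param exp_later reaction expression array of the later stage (used by the
#'   sampling evaluator to select the optimal state).
#' @param perturbed perturbed reaction ids (correlation support).
#' @param initial_state [select_optimal_state()] result or named flux vector
#'   of the initial stage.
#' @param mode `"sample"` or `"project"`.
#' @param seed integer seed for the sampling evaluator.
#' @param sampler named list overriding [sample_fluxes()] arguments
#'   (`n_points`, `burn_in`, `thin`, `n_warmup`).
#' @return a correlation value, or `-Inf` if the model is infeasible.
#' @export
evaluate_modulated <- function(net_mod, exp_later, perturbed, initial_state,
                               mode = c("sample", "project"), seed = 1L,
                               sampler = list()) {
  mode <- match.arg(mode)
  ref <- if (inherits(initial_state, "flux_state")) initial_state$flux else initial_state
  perturbed <- intersect(perturbed, net_mod$reactions$id)
  if (length(perturbed) < 3) stop("need >= 3 perturbed reactions in the model")
  if (mode == "sample") {
    st <- tryCatch({
      args <- c(list(net = net_mod, seed = seed), sampler)
      sm <- do.call(sample_fluxes, args)
      select_optimal_state(sm, exp_later)
    }, error = function(e) NULL)
    if (is.null(st)) {
      message("evaluate_modulated: infeasible or degenerate modulated model")
      return(-Inf)
    }
    v <- st$flux
  } else {
    v <- l1_projection(net_mod, ref, perturbed)
    if (is.null(v)) {
      message("evaluate_modulated: infeasible modulated model")
      return(-Inf)
    }
  }
  tryCatch(baseline_correlation(ref, v, perturbed), error = function(e) -Inf)
}

# feasible flux vector minimizing sum_{r in set} |v_r - target_r|
l1_projection <- function(net, target, set) {
  n <- nrow(net$reactions)
  S <- stoich_matrix(net)
  m <- nrow(S)
  idx <- match(set, net$reactions$id)
  p <- length(idx)
  A <- cbind(S, matrix(0, m, p))
  rows <- matrix(0, 2 * p, n + p)
  b2 <- numeric(2 * p)
  for (k in seq_len(p)) {
    rows[2 * k - 1, idx[k]] <- 1;  rows[2 * k - 1, n + k] <- -1
    b2[2 * k - 1] <- target[set[k]]
    rows[2 * k, idx[k]] <- -1; rows[2 * k, n + k] <- -1
    b2[2 * k] <- -target[set[k]]
  }
  res <- lp_solve(c(rep(0, n), rep(1, p)), rbind(A, rows),
                  c(rep(0, m), b2),
                  sense = c(rep("=", m), rep("<=", 2 * p)),
                  lb = c(net$reactions$lower_bound, rep(0, p)),
                  ub = c(net$reactions$upper_bound, rep(Inf, p)),
                  maximize = FALSE)
  if (res$status != "optimal") return(NULL)
  stats::setNames(res$x[seq_len(n)], net$reactions$id)
}

#' Single-reaction modulation scan
#'
#' Modulates each perturbed reaction individually (bounds clamped to its
#' initial-stage flux) and records the resulting correlation with the
#' initial state. The ranking (descending correlation, ties by reaction id)
#' seeds and orders the greedy module search.
#'
#' @param later_net later-stage [metabolic_network()].
#' @param initial_state initial-stage flux state.
#' @param perturbed perturbed reaction ids.
#' @param exp_later later-stage reaction expression array.
#' @inheritParams evaluate_modulated
#' @return data.frame `reaction`, `correlation`, sorted; infeasible clamps are
#'   dropped (empty result with a warning if all are).
#' @export
single_modulation_scan <- function(later_net, initial_state, perturbed,
                                   exp_later = NULL,
                                   mode = c("sample", "project"), seed = 1L,
                                   sampler = list()) {
  mode <- match.arg(mode)
  ref <- if (inherits(initial_state, "flux_state")) initial_state$flux else initial_state
  perturbed <- sort(intersect(perturbed, later_net$reactions$id), method = "radix")
  res <- vapply(perturbed, function(r) {
    netm <- clamp_to_reference(later_net, r, unname(ref[r]))
    evaluate_modulated(netm, exp_later, perturbed, ref, mode = mode,
                       seed = derive_seed(seed, "scan", r), sampler = sampler)
  }, numeric(1))
  keep <- is.finite(res)
  if (!any(keep)) {
    warning("all single modulations infeasible")
    return(data.frame(reaction = character(0), correlation = numeric(0)))
  }
  out <- data.frame(reaction = perturbed[keep], correlation = res[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$correlation, out$reaction, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy search for reaction-modulation modules
#'
#' The core module-discovery algorithm. Starting from each of the top
#' `n_seeds` single modulations, perturbed reactions are attempted
#' sequentially in the single-scan order; a clamp is kept only if it raises
#' the correlation with the initial-stage state by at least
#' `internal_cutoff` (otherwise it is reverted). One full pass is a level;
#' levels repeat until the gain between consecutive levels drops below
#' `external_cutoff`. Accepted-step correlations are therefore non-decreasing
#' with a per-step gain of at least the internal cut-off, by construction.
#'
#' @inheritParams single_modulation_scan
#' @param internal_cutoff minimum per-reaction correlation gain (default 0.001).
#' @param external_cutoff minimum per-level gain to continue (default 0.01).
#' @param n_seeds number of strategies launched (default 20, the number of
#'   top single modulations reported).
#' @param scan optional precomputed [single_modulation_scan()] result.
#' @param max_levels safety cap on levels per strategy.
#' @return list of `modulation_strategy` objects: `reactions` (ordered),
#'   `ref_flux`, `correlation`, `trace`, `levels`, `seed_reaction`.
#' @export
greedy_module_search <- function(later_net, initial_state, perturbed,
                                 exp_later = NULL,
                                 internal_cutoff = 0.001,
                                 external_cutoff = 0.01,
                                 n_seeds = 20L,
                                 mode = c("sample", "project"), seed = 1L,
                                 sampler = list(), scan = NULL,
                                 max_levels = 10L) {
  mode <- match.arg(mode)
  ref <- if (inherits(initial_state, "flux_state")) initial_state$flux else initial_state
  if (is.null(scan))
    scan <- single_modulation_scan(later_net, initial_state, perturbed,
                                   exp_later, mode = mode, seed = seed,
                                   sampler = sampler)
  if (!nrow(scan)) return(list())
  ranking <- scan$reaction
  seeds <- utils::head(ranking, n_seeds)

  strategies <- lapply(seq_along(seeds), function(si) {
    s <- seeds[si]
    netm <- clamp_to_reference(later_net, s, unname(ref[s]))
    set <- s
    corr <- scan$correlation[match(s, scan$reaction)]
    trace <- corr
    step <- 0L
    level <- 0L
    repeat {
      level <- level + 1L
      level_start <- corr
      for (r in setdiff(ranking, set)) {
        step <- step + 1L
        cand <- clamp_to_reference(netm, r, unname(ref[r]))
        c2 <- evaluate_modulated(cand, exp_later, perturbed, ref, mode = mode,
                                 seed = derive_seed(seed, si, step),
                                 sampler = sampler)
        if (is.finite(c2) && c2 - corr >= internal_cutoff) {
          netm <- cand
          set <- c(set, r)
          corr <- c2
          trace <- c(trace, corr)
        }
      }
      if (corr - level_start < external_cutoff || level >= max_levels) break
    }
    structure(list(reactions = set, ref_flux = ref[set], correlation = corr,
                   trace = trace, levels = level, seed_reaction = s),
              class = "modulation_strategy")
  })
  strategies[order(-vapply(strategies, `[[`, numeric(1), "correlation"),
                   vapply(strategies, `[[`, character(1), "seed_reaction"),
                   method = "radix")]
}

#' @export
print.modulation_strategy <- function(x, ...) {
  cat("<modulation_strategy> ", length(x$reactions), " reaction(s), correlation ",
      signif(x$correlation, 4), " after ", x$levels, " level(s)\n", sep = "")
  invisible(x)
}

#' Targetability score of a modulation strategy
#'
#' Percentage of non-essential genes among the genes catalyzing the
#' strategy's reactions (union over GPR rules). Strategies without any
#' gene-associated reaction get `NA`.
#'
#' @param strategy a `modulation_strategy` (or character vector of reaction
#'   ids).
#' @param nonessential character vector of non-essential gene ids.
#' @param net the [metabolic_network()] supplying GPR rules.
#' @return percentage in `[0, 100]`, or `NA`.
#' @export
targetability <- function(strategy, nonessential, net) {
  rxns <- if (inherits(strategy, "modulation_strategy")) strategy$reactions
          else strategy
  genes <- reaction_genes(net, rxns)
  if (!length(genes)) {
    message("targetability: no gene-associated reaction in strategy")
    return(NA_real_)
  }
  100 * length(intersect(genes, nonessential)) / length(genes)
}
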