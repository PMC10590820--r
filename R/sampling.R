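#' Sample the steady-state flux polytope
#'
#' Artificial-centering hit-and-run sampling of
#' \{v : S v = 0, lb <= v <= ub\}. Warmup points are flux-variability
#' optima (per-reaction maxima/minima); chain directions are differences
#' between a randomly chosen stored point and the running center, and the
#' step size is uniform on the feasible chord, so the next point always stays
#' inside the solution space. Points are re-projected onto the null space of
#' S periodically to stop numerical drift; a point that escapes the polytope
#' is rejected and redrawn (logged). Fully reproducible for a given `seed`.
#'
#' @param net a feasible [metabolic_network()].
#' @param n_points number of samples to return; default 2 x number of
#'   reactions.
#' @param seed integer random seed.
#' @param burn_in chain iterations discarded before collection (default
#'   one tenth of the total chain length, i.e. `n_points * thin / 10`,
#'   rounded up).
#' @param thin keep every `thin`-th chain point (default 60; the chain needs
#'   many sweeps per returned point to decorrelate in high dimension).
#' @param n_warmup number of warmup LP solves (default `2 * n` capped at 200).
#' @return object of class `flux_samples`: list with `points` (reactions x
#'   samples matrix), `n_points`, `seed`, `burn_in`, `thin`.
#' @export
sample_fluxes <- function(net, n_points = 2L * nrow(net$reactions), seed = 1L,
                          thin = 60L, burn_in = ceiling(n_points * thin / 10),
                          n_warmup = min(2L * nrow(net$reactions), 200L)) {
  n <- nrow(net$reactions)
  if (!n) stop("empty network")
  lb <- net$reactions$lower_bound
  ub <- net$reactions$upper_bound
  S <- stoich_matrix(net)
  zero <- rep(0, nrow(S))

  # orthonormal basis of the null space of S (for re-projection)
  sv <- svd(S, nu = 0, nv = n)
  rank <- sum(sv$d > max(dim(S)) * max(sv$d, 0) * 1e-12)
  NB <- sv$v[, setdiff(seq_len(n), seq_len(rank)), drop = FALSE]

  # warmup: FVA-style vertices in a deterministic reaction order
  warm <- list()
  nw <- max(2L, n_warmup)
  dirs <- rep(seq_len(n), each = 2L)[seq_len(min(nw, 2L * n))]
  sgn <- rep(c(1, -1), n)[seq_len(min(nw, 2L * n))]
  for (k in seq_along(dirs)) {
    obj <- numeric(n); obj[dirs[k]] <- sgn[k]
    res <- lp_solve(obj, S, zero, lb = lb, ub = ub, maximize = TRUE)
    if (res$status != "optimal") stop("infeasible model: flux sampling aborted")
    warm[[k]] <- res$x
  }
  W <- do.call(cbind, warm)

  project <- function(x) as.vector(NB %*% crossprod(NB, x))
  inside <- function(x, slack = 1e-9)
    all(x >= lb - slack) && all(x <= ub + slack) && max(abs(S %*% x)) < 1e-7

  out <- matrix(NA_real_, n, n_points,
                dimnames = list(net$reactions$id, NULL))
  if (ncol(NB) == 0L || max(abs(W - W[, 1])) < 1e-9) {
    # fully determined flux space: the polytope is a single point
    out[] <- W[, 1]
    return(structure(list(points = out, n_points = n_points, seed = seed,
                          burn_in = burn_in, thin = thin),
                     class = "flux_samples"))
  }
  # empirical flux range per reaction (warmup spans the FVA extremes)
  fva_range <- apply(W, 1, max) - apply(W, 1, min)
  fva_range <- pmax(fva_range, 1e-9 * max(fva_range))
  res <- with_seed(seed, .achr_chain_cpp(NB, lb, ub, rowMeans(W), W, fva_range,
                                         as.integer(n_points), as.integer(thin),
                                         as.integer(burn_in)))
  if (res$rejects > 0)
    message("sample_fluxes: ", res$rejects,
            " proposal(s) left the polytope numerically and were redrawn")
  out[] <- res$points
  structure(list(points = out, n_points = n_points, seed = seed,
                 burn_in = burn_in, thin = thin),
            class = "flux_samples")
}

#' @export
print.flux_samples <- function(x, ...) {
  cat("<flux_samples> ", nrow(x$points), " reactions x ", ncol(x$points),
      " samples (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
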