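#' Solve a small dense linear program
#'
#' Maximises (or minimises) `obj %*% x` subject to `A x (sense) b` and
#' `lb <= x <= ub`, using the package's bounded-variable two-phase simplex.
#' Inequality rows are converted to equalities with slack variables.
#' Infinite bounds are replaced by a large finite box (`big`), which is safe
#' for the well-scaled stoichiometric problems this package generates.
#'
#' @param obj objective coefficient vector (length n).
#' @param A constraint matrix (m x n), dense.
#' @param b right-hand side (length m).
#' @param sense character vector of `"="`, `"<="`, `">="` per row
#'   (default all `"="`).
#' @param lb,ub variable bounds (scalars recycled).
#' @param maximize logical; maximise when `TRUE` (default).
#' @param big substitute for infinite bounds.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), `objective` and the primal solution `x`.
#' @export
lp_solve <- function(obj, A, b, sense = NULL, lb = 0, ub = Inf,
                     maximize = TRUE, big = 1e7) {
  A <- as.matrix(A)
  n <- ncol(A)
  m <- nrow(A)
  stopifnot(length(obj) == n, length(b) == m)
  sense <- sense %||% rep("=", m)
  stopifnot(length(sense) == m, all(sense %in% c("=", "<=", ">=")))
  lb <- rep_len(lb, n)
  ub <- rep_len(ub, n)

  ineq <- which(sense != "=")
  if (length(ineq)) {
    Sl <- matrix(0, m, length(ineq))
    for (k in seq_along(ineq)) Sl[ineq[k], k] <- if (sense[ineq[k]] == "<=") 1 else -1
    A <- cbind(A, Sl)
    obj <- c(obj, rep(0, length(ineq)))
    lb <- c(lb, rep(0, length(ineq)))
    ub <- c(ub, rep(Inf, length(ineq)))
  }
  lb[!is.finite(lb)] <- -big
  ub[!is.finite(ub)] <- big
  if (any(lb > ub + 1e-12)) return(list(status = "infeasible", objective = NA_real_, x = NULL))

  cc <- if (maximize) obj else -obj
  res <- .simplex_cpp(A, as.numeric(b), as.numeric(cc), lb, ub)
  status <- switch(as.character(res$status),
    "0" = "optimal", "1" = "infeasible", "2" = "unbounded", "iteration_limit")
  if (status != "optimal") return(list(status = status, objective = NA_real_, x = NULL))
  list(status = "optimal",
       objective = if (maximize) res$objective else -res$objective,
       x = res$x[seq_len(n)])
}

# Stoichiometric LP: optimise coefficient vector `obj` over {v : S v = 0, lb<=v<=ub}.
solve_flux_lp <- function(net, obj, maximize = TRUE) {
  S <- stoich_matrix(net)
  lp_solve(obj, S, rep(0, nrow(S)), lb = net$reactions$lower_bound,
           ub = net$reactions$upper_bound, maximize = maximize)
}

#' Flux balance analysis: maximise flux through one reaction
#'
#' @param net a [metabolic_network()].
#' @param reaction_id reaction to optimise.
#' @param maximize maximise (default) or minimise.
#' @return optimal flux value (a single number).
#' @export
fba_maximize <- function(net, reaction_id, maximize = TRUE) {
  idx <- match(reaction_id, net$reactions$id)
  if (is.na(idx)) stop("unknown reaction: ", reaction_id)
  obj <- numeric(nrow(net$reactions))
  obj[idx] <- 1
  res <- solve_flux_lp(net, obj, maximize = maximize)
  if (res$status == "unbounded") return(if (maximize) Inf else -Inf)
  if (res$status != "optimal") stop("FBA failed (", res$status, ") for ", reaction_id)
  res$objective
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum steady-state flux.
#'
#' @param net a [metabolic_network()].
#' @param reaction_ids reactions to analyse (default all).
#' @return data.frame with `id`, `min`, `max`.
#' @export
fva <- function(net, reaction_ids = net$reactions$id) {
  S <- stoich_matrix(net)
  zero <- rep(0, nrow(S))
  lbv <- net$reactions$lower_bound
  ubv <- net$reactions$upper_bound
  out <- data.frame(id = reaction_ids, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(reaction_ids)) {
    idx <- match(reaction_ids[k], net$reactions$id)
    if (is.na(idx)) stop("unknown reaction: ", reaction_ids[k])
    obj <- numeric(ncol(S))
    obj[idx] <- 1
    hi <- lp_solve(obj, S, zero, lb = lbv, ub = ubv, maximize = TRUE)
    lo <- lp_solve(obj, S, zero, lb = lbv, ub = ubv, maximize = FALSE)
    if (hi$status != "optimal" || lo$status != "optimal")
      stop("network infeasible: no steady state satisfies the bounds")
    out$max[k] <- hi$objective
    out$min[k] <- lo$objective
  }
  out
}
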