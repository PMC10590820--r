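#' Solve a small mixed binary linear program by branch-and-bound
#'
#' Depth-first branch-and-bound over the variables listed in `binary_idx`
#' (bounds restricted to \{0,1\}), each node solved with [lp_solve()].
#' Among the integer solutions the search encounters, objective ties prefer
#' fewer active binaries, then the lexicographically smaller pattern;
#' together with the deterministic depth-first order this makes the returned
#' optimum reproducible across runs and platforms (alternative optima that
#' the relaxation never exposes are not enumerated).
#'
#' @inheritParams lp_solve
#' @param binary_idx integer indices of binary variables.
#' @param int_tol integrality tolerance.
#' @return list with `status`, `objective`, `x`.
#' @export
milp_solve <- function(obj, A, b, sense = NULL, lb = 0, ub = Inf,
                       binary_idx = integer(0), maximize = TRUE,
                       int_tol = 1e-6) {
  n <- ncol(A)
  lb <- rep_len(lb, n)
  ub <- rep_len(ub, n)
  if (!length(binary_idx)) return(lp_solve(obj, A, b, sense, lb, ub, maximize))

  sgn <- if (maximize) 1 else -1
  best <- NULL
  best_obj <- -Inf   # in maximization orientation

  better_tie <- function(x_new, x_old) {
    yn <- round(x_new[binary_idx]); yo <- round(x_old[binary_idx])
    if (sum(yn) != sum(yo)) return(sum(yn) < sum(yo))
    d <- which(yn != yo)
    length(d) > 0 && yn[d[1]] < yo[d[1]]
  }

  stack <- list(list(lb = lb, ub = ub))
  nodes <- 0L
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > 200000L) stop("branch-and-bound node limit exceeded")

    rel <- lp_solve(obj, A, b, sense, node$lb, node$ub, maximize = maximize)
    if (rel$status != "optimal") next
    rel_obj <- sgn * rel$objective
    if (rel_obj < best_obj - 1e-9) next                 # dominated
    y <- rel$x[binary_idx]
    frac <- abs(y - round(y))
    if (all(frac <= int_tol)) {
      if (rel_obj > best_obj + 1e-9 ||
          (rel_obj > best_obj - 1e-9 && !is.null(best) && better_tie(rel$x, best))) {
        best <- rel$x
        best_obj <- max(best_obj, rel_obj)
      } else if (is.null(best)) {
        best <- rel$x
        best_obj <- rel_obj
      }
      next
    }
    j <- binary_idx[which.max(frac)]
    dn <- node; dn$ub[j] <- 0
    up <- node; up$lb[j] <- 1
    # explore the branch nearest the relaxation value first (push it last)
    if (rel$x[j] >= 0.5) stack <- c(stack, list(dn), list(up))
    else                 stack <- c(stack, list(up), list(dn))
  }
  if (is.null(best)) return(list(status = "infeasible", objective = NA_real_, x = NULL))
  x <- best
  x[binary_idx] <- round(x[binary_idx])
  list(status = "optimal", objective = sum(obj * x), x = x)
}
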