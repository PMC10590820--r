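#' Expression thresholds for context-specific model extraction
#'
#' Thresholds are always computed from the supplied reaction expression
#' array, never hard-coded. Two schemes per method:
#' \describe{
#'   \item{iMAT Th1}{lower = minimum of the scored array; upper = smallest
#'     value of the top decile ("minimum value of top 10%").}
#'   \item{iMAT Th2}{lower = mean - sd; upper = mean + sd.}
#'   \item{FASTCORE / INIT Th1}{single threshold = top-decile minimum.}
#'   \item{FASTCORE / INIT Th2}{single threshold = array minimum.}
#' }
#' The top-10% boundary uses a ceiling on the count of scored reactions, so
#' it is deterministic for any array length.
#'
#' @param exp reaction expression array (named numeric, `NA` = no data).
#' @param method `"iMAT"`, `"FASTCORE"` or `"INIT"`.
#' @param scheme `"Th1"` or `"Th2"`.
#' @return a `threshold_scheme` list with `method`, `scheme`, `lower`,
#'   `upper` (`NA` for the single-threshold methods).
#' @export
compute_thresholds <- function(exp, method = c("iMAT", "FASTCORE", "INIT"),
                               scheme = c("Th1", "Th2")) {
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  scored <- exp[!is.na(exp)]
  if (length(scored) < 10)
    stop("need at least 10 scored reactions to compute thresholds (got ",
         length(scored), ")")
  k <- ceiling(0.1 * length(scored))
  top10_min <- unname(sort(scored, decreasing = TRUE)[k])
  lo_all <- unname(min(scored))
  th <- switch(paste(method, scheme),
    "iMAT Th1"     = list(lower = lo_all, upper = top10_min),
    "iMAT Th2"     = list(lower = mean(scored) - sd(scored),
                          upper = mean(scored) + sd(scored)),
    "FASTCORE Th1" = list(lower = top10_min, upper = NA_real_),
    "FASTCORE Th2" = list(lower = lo_all, upper = NA_real_),
    "INIT Th1"     = list(lower = top10_min, upper = NA_real_),
    "INIT Th2"     = list(lower = lo_all, upper = NA_real_))
  if (max(scored) - lo_all < 1e-12)
    warning("constant expression array: degenerate thresholds")
  structure(c(list(method = method, scheme = scheme), th),
            class = "threshold_scheme")
}

# wrap an extracted subnetwork with provenance
as_context_model <- function(net, method, scheme, parent, extra = list()) {
  net$provenance <- c(list(method = method, scheme = scheme,
                           parent_reactions = nrow(parent$reactions)), extra)
  class(net) <- unique(c("context_model", class(net)))
  net
}

#' Context-specific model extraction with iMAT
#'
#' Solves the iMAT integer program: maximise the number of high-expression
#' reactions carrying flux of magnitude at least `eps` plus the number of
#' low-expression reactions carrying zero flux, subject to steady state and
#' bounds. High reactions are those with expression `>= upper`; low reactions
#' those with scored expression strictly below `lower` (reactions without
#' data are neither). The returned model is the flux-consistent subnetwork of
#' reactions active in the optimum.
#'
#' @param net a [metabolic_network()] (flux-consistent input recommended).
#' @param exp reaction expression array over `net`'s reactions.
#' @param lower,upper expression thresholds (see [compute_thresholds()]).
#' @param eps minimum activation flux for a "carried" reaction (default 1e-3).
#' @param tol activity tolerance for the returned subnetwork.
#' @return a `context_model`; its `provenance$objective` holds the optimal
#'   iMAT objective value.
#' @export
imat_extract <- function(net, exp, lower, upper, eps = 1e-3, tol = 1e-6) {
  stopifnot(eps > 0)
  exp <- exp[net$reactions$id]
  n <- nrow(net$reactions)
  lb <- net$reactions$lower_bound
  ub <- net$reactions$upper_bound
  high <- which(!is.na(exp) & exp >= upper)
  low <- which(!is.na(exp) & exp < lower)

  S <- stoich_matrix(net)
  m <- nrow(S)
  # variable layout: v (n) | y+ (high) | y- (reversible high) | y0 (low)
  hi_rev <- high[lb[high] < -eps]
  nh <- length(high); nr <- length(hi_rev); nl <- length(low)
  N <- n + nh + nr + nl
  col_yp <- n + seq_len(nh)
  col_ym <- n + nh + seq_len(nr)
  col_y0 <- n + nh + nr + seq_len(nl)

  rows <- list(); rhs <- c(); sen <- c()
  add_row <- function(cols, vals, sense, b) {
    r <- numeric(N); r[cols] <- vals
    rows[[length(rows) + 1L]] <<- r
    rhs <<- c(rhs, b); sen <<- c(sen, sense)
  }
  for (k in seq_len(nh)) {
    i <- high[k]
    add_row(c(i, col_yp[k]), c(1, lb[i] - eps), ">=", lb[i])
  }
  for (k in seq_len(nr)) {
    i <- hi_rev[k]
    add_row(c(i, col_ym[k]), c(1, ub[i] + eps), "<=", ub[i])
    kp <- match(i, high)
    add_row(c(col_yp[kp], col_ym[k]), c(1, 1), "<=", 1)
  }
  for (k in seq_len(nl)) {
    i <- low[k]
    add_row(c(i, col_y0[k]), c(1, lb[i]), ">=", lb[i])
    add_row(c(i, col_y0[k]), c(1, ub[i]), "<=", ub[i])
  }
  A <- rbind(cbind(S, matrix(0, m, N - n)),
             if (length(rows)) do.call(rbind, rows))
  b <- c(rep(0, m), rhs)
  sense <- c(rep("=", m), sen)
  obj <- c(rep(0, n), rep(1, nh + nr + nl))
  lbv <- c(lb, rep(0, N - n))
  ubv <- c(ub, rep(1, N - n))
  bin <- (n + 1):N
  res <- milp_solve(obj, A, b, sense, lbv, ubv,
                    binary_idx = if (N > n) bin else integer(0))
  if (res$status != "optimal") stop("iMAT MILP ", res$status)
  v <- res$x[seq_len(n)]
  active <- abs(v) >= tol
  # reactions *activatable* under the optimal activity pattern: fix the
  # binary pattern, re-bound the network accordingly, and probe the rest by FVA
  fixed <- net
  for (k in seq_len(nh)) {
    i <- high[k]
    if (res$x[col_yp[k]] > 0.5)
      fixed$reactions$lower_bound[i] <- max(fixed$reactions$lower_bound[i], eps)
  }
  for (k in seq_len(nr)) {
    i <- hi_rev[k]
    if (res$x[col_ym[k]] > 0.5)
      fixed$reactions$upper_bound[i] <- min(fixed$reactions$upper_bound[i], -eps)
  }
  for (k in seq_len(nl)) {
    i <- low[k]
    if (res$x[col_y0[k]] > 0.5) {
      fixed$reactions$lower_bound[i] <- 0
      fixed$reactions$upper_bound[i] <- 0
    }
  }
  if (any(!active)) {
    rng <- fva(fixed, net$reactions$id[!active])
    active[!active] <- rng$max >= tol | rng$min <= -tol
  }
  keep <- net$reactions$id[active]
  sub <- if (length(keep)) flux_consistent_subnetwork(subnetwork(net, keep), tol)
         else subnetwork(net, character(0))
  as_context_model(sub, "iMAT", NA_character_, net,
                   list(objective = res$objective, lower = lower, upper = upper,
                        eps = eps))
}

# ---- FASTCORE ----------------------------------------------------------

# LP-7: maximize the number of reactions in J carrying forward flux >= eps
fastcore_lp7 <- function(S, lb, ub, J, eps) {
  n <- ncol(S); m <- nrow(S); k <- length(J)
  # variables v (n) | z (k); maximize sum z, z_i <= v_{J_i}, 0 <= z <= eps
  A <- cbind(S, matrix(0, m, k))
  rows <- matrix(0, k, n + k)
  for (i in seq_len(k)) { rows[i, J[i]] <- -1; rows[i, n + i] <- 1 }
  A <- rbind(A, rows)
  res <- lp_solve(c(rep(0, n), rep(1, k)), A, rep(0, m + k),
                  sense = c(rep("=", m), rep("<=", k)),
                  lb = c(lb, rep(0, k)), ub = c(ub, rep(eps, k)))
  if (res$status != "optimal") stop("FASTCORE LP7 ", res$status)
  res$x[seq_len(n)]
}

# LP-10: support K with v_k >= eps while minimizing the L1 norm over P
fastcore_lp10 <- function(S, lb, ub, K, P, eps) {
  n <- ncol(S); m <- nrow(S); p <- length(P)
  # variables v (n) | w (p); minimize sum w, -w <= v_P <= w
  A <- cbind(S, matrix(0, m, p))
  rows <- matrix(0, 2 * p, n + p)
  for (i in seq_len(p)) {
    rows[2 * i - 1, P[i]] <- 1;  rows[2 * i - 1, n + i] <- -1   # v - w <= 0
    rows[2 * i,     P[i]] <- -1; rows[2 * i,     n + i] <- -1   # -v - w <= 0
  }
  A <- rbind(A, rows)
  lbv <- c(lb, rep(0, p))
  lbv[K] <- pmax(lbv[K], eps)
  res <- lp_solve(c(rep(0, n), rep(1, p)), A, rep(0, m + 2 * p),
                  sense = c(rep("=", m), rep("<=", 2 * p)),
                  lb = lbv, ub = c(ub, rep(Inf, p)), maximize = FALSE)
  if (res$status != "optimal") return(NULL)
  res$x[seq_len(n)]
}

fastcore_sparse_mode <- function(S, lb, ub, J, P, eps, singleton) {
  if (!length(J)) return(integer(0))
  Juse <- if (singleton) J[1] else J
  v <- fastcore_lp7(S, lb, ub, Juse, eps)
  K <- Juse[v[Juse] >= 0.99 * eps]
  if (!length(K)) return(integer(0))
  v <- fastcore_lp10(S, lb, ub, K, P, eps)
  if (is.null(v)) return(integer(0))
  which(abs(v) >= 0.99 * eps)
}

#' Context-specific model extraction with FASTCORE
#'
#' The fast LP sequence of Vlassis et al.: find a flux-consistent subnetwork
#' that contains every core reaction plus a small (sparse L1-minimised)
#' supporting set. Reactions without expression data must not be in the core.
#'
#' @param consistent_net a flux-consistent [metabolic_network()].
#' @param core character vector of core reaction ids.
#' @param tol minimum activation flux (default 1e-3).
#' @return a `context_model` containing all of `core`.
#' @export
fastcore_extract <- function(consistent_net, core, tol = 1e-3) {
  net <- consistent_net
  ids <- net$reactions$id
  bad <- setdiff(core, ids)
  if (length(bad)) stop("core reaction(s) not in network: ",
                        paste(bad, collapse = ", "))
  if (!length(core))
    return(as_context_model(subnetwork(net, character(0)), "FASTCORE",
                            NA_character_, net))
  S <- stoich_matrix(net)
  lb <- net$reactions$lower_bound
  ub <- net$reactions$upper_bound
  eps <- tol
  C <- match(core, ids)
  irrev <- which(lb >= 0)
  flipped <- FALSE; singleton <- FALSE

  J <- intersect(C, irrev)
  P <- setdiff(seq_along(ids), C)
  A <- fastcore_sparse_mode(S, lb, ub, J, P, eps, FALSE)
  if (length(setdiff(J, A)))
    stop("inconsistent irreversible core reaction(s): ",
         paste(ids[setdiff(J, A)], collapse = ", "))
  J <- setdiff(C, A)
  guard <- 0L
  while (length(J)) {
    if ((guard <- guard + 1L) > 40L * length(C) + 200L)
      stop("FASTCORE failed to converge")
    P <- setdiff(P, A)
    supp <- fastcore_sparse_mode(S, lb, ub, J, P, eps, singleton)
    A <- union(A, supp)
    if (length(intersect(J, A))) {
      J <- setdiff(J, A)
      flipped <- FALSE
    } else {
      JiRev <- setdiff(if (singleton) J[1] else J, irrev)
      if (flipped || !length(JiRev)) {
        if (singleton)
          stop("core reaction infeasible in the consistent network: ", ids[J[1]])
        flipped <- FALSE
        singleton <- TRUE
      } else {
        # flip the direction of the reversible core reactions not yet supported
        tmp <- lb[JiRev]
        lb[JiRev] <- -ub[JiRev]
        ub[JiRev] <- -tmp
        S[, JiRev] <- -S[, JiRev]
        flipped <- TRUE
      }
    }
  }
  sub <- subnetwork(net, ids[sort(A)])
  as_context_model(sub, "FASTCORE", NA_character_, net,
                   list(core_size = length(core), eps = eps))
}

# ---- INIT --------------------------------------------------------------

#' INIT reaction weights
#'
#' `weight = 5 * log2(expression / threshold)`; reactions without expression
#' data receive a fixed weight of -2.
#'
#' @param exp reaction expression array (named numeric, `NA` = no data).
#' @param threshold positive expression threshold.
#' @return named numeric weight vector.
#' @export
init_weights <- function(exp, threshold) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be positive")
  w <- 5 * log2(exp / threshold)
  w[is.na(exp)] <- -2
  w
}

#' Context-specific model extraction with INIT
#'
#' Mixed-integer program selecting the reaction set that maximises the sum
#' of weights of included reactions, subject to every included reaction
#' carrying a flux of magnitude at least `eps` in one common steady state of
#' the reduced network (excluded reactions are forced to zero). The selected
#' set is pruned to flux consistency.
#'
#' @param net a [metabolic_network()].
#' @param w named weight vector from [init_weights()] covering all reactions.
#' @param eps minimum activation flux (default 1e-3).
#' @param tol activity tolerance for the returned subnetwork.
#' @return a `context_model`; `provenance$objective` is the achieved total
#'   weight of the selected set.
#' @export
init_extract <- function(net, w, eps = 1e-3, tol = 1e-6) {
  w <- w[net$reactions$id]
  if (anyNA(w)) stop("weights must cover every reaction")
  n <- nrow(net$reactions)
  lb <- net$reactions$lower_bound
  ub <- net$reactions$upper_bound
  S <- stoich_matrix(net)
  m <- nrow(S)
  rev <- lb < -eps
  # variables: v (n) | y+ (all) | y- (reversible only)
  ym_of <- cumsum(rev)
  N <- n + n + sum(rev)
  rows <- list(); rhs <- c(); sen <- c(); nrw <- 0L
  add_row <- function(cols, vals, sense, b) {
    r <- numeric(N); r[cols] <- vals
    rows[[length(rows) + 1L]] <<- r
    rhs <<- c(rhs, b); sen <<- c(sen, sense)
  }
  for (i in seq_len(n)) {
    yp <- n + i
    if (rev[i]) {
      ym <- 2L * n + ym_of[i]
      add_row(c(i, yp, ym), c(1, -eps, -lb[i]), ">=", 0)
      add_row(c(i, yp, ym), c(1, -ub[i], eps), "<=", 0)
      add_row(c(yp, ym), c(1, 1), "<=", 1)
    } else {
      add_row(c(i, yp), c(1, -eps), ">=", 0)
      add_row(c(i, yp), c(1, -ub[i]), "<=", 0)
    }
  }
  A <- rbind(cbind(S, matrix(0, m, N - n)), do.call(rbind, rows))
  b <- c(rep(0, m), rhs)
  sense <- c(rep("=", m), sen)
  obj <- numeric(N)
  obj[n + seq_len(n)] <- w
  if (sum(rev)) obj[2L * n + seq_len(sum(rev))] <- w[rev]
  res <- milp_solve(obj, A, b, sense,
                    lb = c(pmax(lb, ifelse(rev, lb, 0)), rep(0, N - n)),
                    ub = c(ub, rep(1, N - n)),
                    binary_idx = (n + 1):N)
  if (res$status != "optimal") stop("INIT MILP ", res$status)
  y <- res$x[n + seq_len(n)]
  if (sum(rev)) y[rev] <- y[rev] + res$x[2L * n + seq_len(sum(rev))]
  kept <- net$reactions$id[y > 0.5]
  sub <- if (length(kept)) flux_consistent_subnetwork(subnetwork(net, kept), tol)
         else subnetwork(net, character(0))
  as_context_model(sub, "INIT", NA_character_, net,
                   list(objective = res$objective, eps = eps))
}
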