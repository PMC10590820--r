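#' Cap uptake of carbon-source exchanges
#'
#' Every exchange reaction whose metabolite contains at least one carbon atom
#' is treated as a carbon source and its maximum uptake is capped at
#' `uptake_limit` (default 10 mmol gDW^-1 h^-1). CO2 and bicarbonate are
#' exempt - they are carbon-bearing but not usable carbon sources - and are
#' recognised both by id pattern (`co2`, `hco3`) and by formula (`CO2`,
#' `CHO3`/`HCO3`). Exchanged metabolites without a parseable formula are
#' treated as non-carbon with a warning. All other bounds are untouched, so
#' the operation is idempotent.
#'
#' @param net a [metabolic_network()].
#' @param uptake_limit maximum uptake magnitude (positive number).
#' @return the re-bounded network.
#' @export
fix_carbon_bounds <- function(net, uptake_limit = 10) {
  stopifnot(uptake_limit > 0)
  ex <- exchange_reactions(net)
  for (rid in ex) {
    i <- match(rid, net$reactions$id)
    met <- names(net$reactions$stoichiometry[[i]])
    j <- match(met, net$metabolites$id)
    formula <- net$metabolites$formula[j]
    nC <- if (is.na(formula) || !nzchar(formula)) NA_integer_ else carbon_count(formula)
    if (is.na(nC)) {
      warning("exchange '", rid, "': metabolite '", met,
              "' has no parseable formula; treated as non-carbon")
      next
    }
    if (nC < 1) next
    base <- tolower(sub("_[a-z0-9]+$", "", met))
    fstd <- toupper(gsub("[^A-Za-z0-9]", "", formula %||% ""))
    is_co2 <- base %in% c("co2", "hco3") || fstd %in% c("CO2", "CHO3", "HCO3")
    if (is_co2) next
    # uptake is the negative direction of a boundary drain with coefficient -1;
    # orient by the metabolite coefficient so producer-style drains also work
    coef <- net$reactions$stoichiometry[[i]][[1]]
    if (coef < 0) {
      net$reactions$lower_bound[i] <- max(net$reactions$lower_bound[i], -uptake_limit)
    } else {
      net$reactions$upper_bound[i] <- min(net$reactions$upper_bound[i], uptake_limit)
    }
  }
  validate_network(net)
}

#' Add irreversible sink (drain) reactions for metabolites
#'
#' One drain reaction per listed metabolite, with deterministic ids
#' `SK_<metabolite>`, stoichiometry -1 on the metabolite and bounds
#' `[0, 1000]`. Used to probe whether a model can synthesise each member of
#' a growth-essential metabolite set. Duplicate ids in the list collapse to
#' a single sink with a warning; a sink that already exists is left as is.
#'
#' @param net a [metabolic_network()].
#' @param metabolite_ids metabolites to drain.
#' @return the extended network.
#' @export
add_sink_reactions <- function(net, metabolite_ids) {
  if (!length(metabolite_ids)) return(net)
  if (anyDuplicated(metabolite_ids)) {
    warning("duplicate metabolite ids in sink list; collapsing")
    metabolite_ids <- unique(metabolite_ids)
  }
  miss <- setdiff(metabolite_ids, net$metabolites$id)
  if (length(miss))
    stop("unknown metabolite id(s): ", paste(miss, collapse = ", "))
  ids <- paste0("SK_", metabolite_ids)
  new <- !ids %in% net$reactions$id
  if (!any(new)) return(net)
  add <- data.frame(id = ids[new], lower_bound = 0, upper_bound = 1000,
                    subsystem = "Sink", gpr = "", stringsAsFactors = FALSE)
  add$stoichiometry <- lapply(metabolite_ids[new], function(m)
    stats::setNames(-1, m))
  metabolic_network(net$metabolites, rbind(net$reactions, add),
                    genes = net$genes, objective = net$objective)
}

#' Sink reaction ids for a metabolite list
#'
#' @param metabolite_ids metabolite ids.
#' @return the deterministic sink ids (`SK_<metabolite>`).
#' @export
sink_ids <- function(metabolite_ids) paste0("SK_", unique(metabolite_ids))

#' Flux-consistent subnetwork
#'
#' Returns the subnetwork of reactions able to carry a flux of magnitude at
#' least `tol` in some feasible steady state (both directions are probed via
#' flux variability analysis). Pruning is iterated to a fixed point, so the
#' result is transitively complete: running the function on its own output
#' changes nothing.
#'
#' @param net a [metabolic_network()].
#' @param tol activity tolerance (default 1e-6, the global reaction-activity
#'   threshold used throughout the package).
#' @return the consistent subnetwork (possibly with zero reactions).
#' @export
flux_consistent_subnetwork <- function(net, tol = 1e-6) {
  if (!nrow(net$reactions)) stop("empty network")
  cur <- net
  repeat {
    if (!nrow(cur$reactions)) break
    n <- nrow(cur$reactions)
    S <- stoich_matrix(cur)
    lb <- cur$reactions$lower_bound
    ub <- cur$reactions$upper_bound
    # fast path: a few whole-network LPs; any feasible solution certifies
    # every reaction it moves above tol as consistent, leaving only the
    # remainder for per-reaction variability analysis
    keep <- rep(FALSE, n)
    dirs <- list(rep(1, n), rep(-1, n),
                 rep_len(c(1, -1), n), rep_len(c(-1, 1, 1), n))
    for (d in dirs) {
      res <- lp_solve(d, S, rep(0, nrow(S)), lb = lb, ub = ub)
      if (res$status != "optimal")
        stop("network infeasible: no steady state satisfies the bounds")
      keep <- keep | abs(res$x) >= tol
    }
    rest <- which(!keep)
    if (length(rest)) {
      rng <- fva(cur, cur$reactions$id[rest])
      keep[rest] <- rng$max >= tol | rng$min <= -tol
    }
    if (all(keep)) break
    if (!any(keep)) {
      cur$reactions <- cur$reactions[0, , drop = FALSE]
      break
    }
    cur <- subnetwork(cur, cur$reactions$id[keep])
  }
  cur
}
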