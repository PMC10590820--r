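#' Construct a metabolic network
#'
#' The central container of the package: a stoichiometric model with reaction
#' bounds (mmol gDW^-1 h^-1), gene-protein-reaction (GPR) rules, subsystem
#' labels and metabolite formulas. Metabolites and reactions are stored in
#' canonical (lexicographic) id order so that derived matrices are
#' reproducible regardless of input format or construction order.
#'
#' @param metabolites data.frame with columns `id`, `formula`, `compartment`.
#' @param reactions data.frame with columns `id`, `lower_bound`, `upper_bound`,
#'   `subsystem`, `gpr`, and a list column `stoichiometry` of named numeric
#'   vectors (metabolite id -> coefficient).
#' @param genes character vector of gene ids; genes referenced by GPR rules
#'   are added automatically.
#' @param objective optional id of an objective (e.g. biomass-like) reaction.
#' @return object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, reactions, genes = character(0),
                              objective = NULL) {
  stopifnot(all(c("id", "formula", "compartment") %in% names(metabolites)),
            all(c("id", "lower_bound", "upper_bound", "subsystem", "gpr",
                  "stoichiometry") %in% names(reactions)))
  metabolites <- metabolites[order(metabolites$id, method = "radix"), , drop = FALSE]
  reactions <- reactions[order(reactions$id, method = "radix"), , drop = FALSE]
  rownames(metabolites) <- rownames(reactions) <- NULL
  gpr_gene_union <- unique(unlist(lapply(reactions$gpr, function(r)
    gpr_genes(parse_gpr(r)))))
  genes <- sort(unique(c(genes, gpr_gene_union)), method = "radix")
  net <- structure(list(metabolites = metabolites, reactions = reactions,
                        genes = genes, objective = objective),
                   class = "metabolic_network")
  validate_network(net)
  net
}

#' Validate a metabolic network's invariants
#'
#' Checks that stoichiometries reference only declared metabolites, that
#' `lower_bound <= upper_bound` everywhere, and that the objective (if set)
#' exists. Called on construction; exported for use after manual edits.
#'
#' @param net a [metabolic_network()].
#' @return `net`, invisibly; errors describe the offending element.
#' @export
validate_network <- function(net) {
  for (i in seq_len(nrow(net$reactions))) {
    st <- net$reactions$stoichiometry[[i]]
    if (!length(st)) stop("reaction '", net$reactions$id[i], "' has empty stoichiometry")
    bad <- setdiff(names(st), net$metabolites$id)
    if (length(bad))
      stop("reaction '", net$reactions$id[i],
           "' references undeclared metabolite(s): ", paste(bad, collapse = ", "))
  }
  bad <- net$reactions$lower_bound > net$reactions$upper_bound + 1e-12
  if (any(bad))
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(net$reactions$id[bad], collapse = ", "))
  if (anyDuplicated(net$reactions$id))
    stop("duplicate reaction ids")
  if (anyDuplicated(net$metabolites$id))
    stop("duplicate metabolite ids")
  if (!is.null(net$objective) && !net$objective %in% net$reactions$id)
    stop("objective reaction '", net$objective, "' not in network")
  invisible(net)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites, ", length(x$genes), " genes\n", sep = "")
  if (!is.null(x$objective)) cat("objective: ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a network
#'
#' @param net a [metabolic_network()].
#' @return dense matrix S (metabolites x reactions), dimnames set.
#' @export
stoich_matrix <- function(net) {
  S <- matrix(0, nrow(net$metabolites), nrow(net$reactions),
              dimnames = list(net$metabolites$id, net$reactions$id))
  for (i in seq_len(nrow(net$reactions))) {
    st <- net$reactions$stoichiometry[[i]]
    S[names(st), i] <- st
  }
  S
}

#' Restrict a network to a reaction subset
#'
#' Keeps the named reactions and every metabolite they reference. The parent's
#' declared gene space is retained (a context model lives in the same measured
#' gene space as its parent).
#'
#' @param net a [metabolic_network()].
#' @param reaction_ids reactions to keep.
#' @return a new [metabolic_network()].
#' @export
subnetwork <- function(net, reaction_ids) {
  missing_rxn <- setdiff(reaction_ids, net$reactions$id)
  if (length(missing_rxn))
    stop("unknown reaction(s): ", paste(missing_rxn, collapse = ", "))
  rx <- net$reactions[net$reactions$id %in% reaction_ids, , drop = FALSE]
  used <- unique(unlist(lapply(rx$stoichiometry, names)))
  mets <- net$metabolites[net$metabolites$id %in% used, , drop = FALSE]
  obj <- if (!is.null(net$objective) && net$objective %in% rx$id) net$objective
  metabolic_network(mets, rx, genes = net$genes, objective = obj)
}

#' Set the bounds of one reaction
#'
#' @param net a [metabolic_network()].
#' @param reaction_id reaction to change.
#' @param lb,ub new bounds; `NULL` leaves a bound unchanged.
#' @return the modified network.
#' @export
set_bounds <- function(net, reaction_id, lb = NULL, ub = NULL) {
  idx <- match(reaction_id, net$reactions$id)
  if (any(is.na(idx))) stop("unknown reaction: ",
                            paste(reaction_id[is.na(idx)], collapse = ", "))
  if (!is.null(lb)) net$reactions$lower_bound[idx] <- lb
  if (!is.null(ub)) net$reactions$upper_bound[idx] <- ub
  validate_network(net)
}

#' Identify exchange (boundary) reactions
#'
#' A reaction is treated as an exchange if exactly one metabolite participates
#' in it - the usual boundary-drain convention.
#'
#' @param net a [metabolic_network()].
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(net) {
  n_met <- vapply(net$reactions$stoichiometry, length, integer(1))
  net$reactions$id[n_met == 1L]
}

# genes catalyzing a set of reactions (union over GPR rules)
reaction_genes <- function(net, reaction_ids) {
  idx <- match(reaction_ids, net$reactions$id)
  if (any(is.na(idx))) stop("unknown reaction(s)")
  unique(unlist(lapply(net$reactions$gpr[idx], function(r) gpr_genes(parse_gpr(r)))))
}

# reactions whose GPR mentions any of the given genes
reactions_of_genes <- function(net, genes) {
  hit <- vapply(net$reactions$gpr, function(r)
    length(intersect(gpr_genes(parse_gpr(r)), genes)) > 0, logical(1))
  net$reactions$id[hit]
}
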