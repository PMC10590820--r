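#' E-flux bounds from a single expression sample
#'
#' Scales each reaction's flux capacity in proportion to the expression of
#' its catalyzing genes: `b = b_max * rexp / max(rexp)` where `rexp` is the
#' GPR-evaluated reaction expression. Reversible reactions get `(-b, b)`,
#' irreversible ones `(0, b)`. Reactions without expression data keep their
#' default bounds. The linear map to the per-sample maximum is the package's
#' choice of the (otherwise unspecified) scaling function.
#'
#' @param net a [metabolic_network()].
#' @param gene_values named numeric per-gene expression for one sample.
#' @param b_max maximum bound magnitude (default 1000, the model default).
#' @return the re-bounded network.
#' @export
eflux_bounds <- function(net, gene_values, b_max = 1000) {
  rexp <- map_expression_to_reactions(net, gene_values)
  mx <- suppressWarnings(max(rexp, na.rm = TRUE))
  if (!is.finite(mx) || mx <= 0)
    stop("all-zero or missing expression: cannot scale bounds")
  for (i in seq_len(nrow(net$reactions))) {
    e <- rexp[net$reactions$id[i]]
    if (is.na(e)) next
    b <- b_max * max(e, 0) / mx
    if (net$reactions$lower_bound[i] < 0) {
      net$reactions$lower_bound[i] <- -b
    } else {
      net$reactions$lower_bound[i] <- 0
    }
    net$reactions$upper_bound[i] <- b
  }
  validate_network(net)
}

#' Single-gene knockout
#'
#' Re-evaluates every reaction's GPR with the gene deleted; reactions whose
#' rule can no longer be satisfied get both bounds set to zero. Reactions
#' with an isozyme (`or`) covering the gene are unaffected; knockouts are
#' idempotent.
#'
#' @param net a [metabolic_network()].
#' @param gene gene id (or several) to delete.
#' @return the knocked-out network.
#' @export
gene_knockout <- function(net, gene) {
  unknown <- setdiff(gene, net$genes)
  if (length(unknown)) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  for (i in seq_len(nrow(net$reactions))) {
    ast <- parse_gpr(net$reactions$gpr[i])
    if (is.null(ast)) next
    if (!eval_gpr_bool(ast, gene)) {
      net$reactions$lower_bound[i] <- 0
      net$reactions$upper_bound[i] <- 0
    }
  }
  net
}

#' Quantile normalization to the average-rank reference distribution
#'
#' Columns are forced onto the common distribution given by the mean of the
#' column-sorted values (delegated to `limma::normalizeQuantiles`).
#'
#' @param mat numeric matrix (features x samples).
#' @return normalized matrix.
#' @export
quantile_normalize <- function(mat) {
  if (!requireNamespace("limma", quietly = TRUE))
    stop("quantile_normalize requires the limma package")
  out <- limma::normalizeQuantiles(as.matrix(mat))
  dimnames(out) <- dimnames(mat)
  out
}

#' Gene essentiality screen on normal-tissue expression
#'
#' For each normal-tissue sample, builds an E-flux model, measures the FBA
#' growth rate before and after deleting each candidate gene, and records
#' the growth-rate ratio (clamped to `[0, 1]`; shrinking bounds cannot raise
#' an LP maximum). A gene is non-essential iff its ratio equals 1 (within
#' `tol`) in at least `ceiling(frac * n_samples)` usable samples. Samples
#' with zero baseline growth are skipped for ratios (logged).
#'
#' @param normal_expr numeric matrix, genes x samples.
#' @param net a [metabolic_network()] with an objective (biomass-like drain).
#' @param biomass_id objective reaction id (default `net$objective`).
#' @param genes candidate genes (default all model genes present in the
#'   matrix).
#' @param frac fraction-of-samples rule for non-essentiality (default 1/3).
#' @param quantile logical, quantile-normalize the matrix first (default
#'   `TRUE`).
#' @param tol ratio tolerance for "unchanged growth".
#' @return data.frame `gene`, `n_samples`, `n_ratio_one`, `mean_ratio`,
#'   `nonessential`; the per-sample ratio matrix is attached as
#'   `attr(, "ratios")`.
#' @export
essentiality_screen <- function(normal_expr, net, biomass_id = net$objective,
                                genes = NULL, frac = 1 / 3, quantile = TRUE,
                                tol = 1e-6) {
  if (is.null(biomass_id)) stop("network has no objective reaction")
  if (quantile) normal_expr <- quantile_normalize(normal_expr)
  genes <- genes %||% intersect(net$genes, rownames(normal_expr))
  ns <- ncol(normal_expr)
  ratios <- matrix(NA_real_, length(genes), ns,
                   dimnames = list(genes, colnames(normal_expr)))
  usable <- 0L
  for (j in seq_len(ns)) {
    gv <- stats::setNames(normal_expr[, j], rownames(normal_expr))
    netj <- eflux_bounds(net, gv)
    g0 <- tryCatch(fba_maximize(netj, biomass_id), error = function(e) 0)
    if (!is.finite(g0) || g0 < tol) {
      message("essentiality_screen: sample ", j, " has zero baseline growth; skipped")
      next
    }
    usable <- usable + 1L
    for (k in seq_along(genes)) {
      netko <- gene_knockout(netj, genes[k])
      # an infeasible knockout model cannot grow at all
      g1 <- tryCatch(fba_maximize(netko, biomass_id), error = function(e) 0)
      ratios[k, j] <- min(max(g1 / g0, 0), 1)
    }
  }
  need <- ceiling(frac * usable)
  n_one <- rowSums(!is.na(ratios) & ratios >= 1 - tol)
  out <- data.frame(gene = genes, n_samples = usable, n_ratio_one = n_one,
                    mean_ratio = rowMeans(ratios, na.rm = TRUE),
                    nonessential = n_one >= need, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ratios") <- ratios
  out
}

# floored log2 fold-change of a correlation against a baseline
corr_log2fc <- function(post, baseline, floor = 1e-3) {
  log2(max(post, floor) / max(baseline, floor))
}

#' In-silico knockout screen against a transition
#'
#' For each candidate gene: delete it from the later-stage model, re-estimate
#' the flux state, and record the correlation with the initial-stage state
#' over the perturbed reactions and its log2 fold-change versus the
#' transition baseline. Candidates should be pre-filtered to non-essential
#' genes catalyzing perturbed reactions.
#'
#' @param later_net later-stage [metabolic_network()].
#' @param candidates candidate gene ids.
#' @param initial_state initial-stage flux state.
#' @param perturbed perturbed reaction ids.
#' @param exp_later later-stage reaction expression array (sampling evaluator).
#' @param baseline transition baseline correlation.
#' @inheritParams evaluate_modulated
#' @param corr_floor floor applied to correlations before the log2
#'   fold-change (keeps the ratio defined near zero).
#' @return data.frame ranked by descending correlation: `gene`,
#'   `n_reactions_hit`, `correlation`, `log2fc`.
#' @export
knockout_screen <- function(later_net, candidates, initial_state, perturbed,
                            exp_later = NULL, baseline,
                            mode = c("sample", "project"), seed = 1L,
                            sampler = list(), corr_floor = 1e-3) {
  mode <- match.arg(mode)
  ref <- if (inherits(initial_state, "flux_state")) initial_state$flux else initial_state
  candidates <- sort(unique(candidates), method = "radix")
  res <- lapply(candidates, function(g) {
    netko <- gene_knockout(later_net, g)
    hit <- sum(netko$reactions$upper_bound == 0 & netko$reactions$lower_bound == 0 &
               !(later_net$reactions$upper_bound == 0 &
                 later_net$reactions$lower_bound == 0))
    cc <- evaluate_modulated(netko, exp_later, perturbed, ref, mode = mode,
                             seed = derive_seed(seed, "ko", g), sampler = sampler)
    data.frame(gene = g, n_reactions_hit = hit, correlation = cc,
               log2fc = if (is.finite(cc)) corr_log2fc(cc, baseline, corr_floor)
                        else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$correlation, out$gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply a drug to a model as fractional bound inhibition
#'
#' Every reaction whose GPR rule mentions any target gene of the drug has
#' both bounds scaled by `(1 - inhibition)`. Membership (not boolean GPR
#' evaluation) is used deliberately: partial inhibition must also dampen
#' reactions protected by isozymes, unlike a knockout.
#'
#' @param net a [metabolic_network()].
#' @param drug a list/row with `targets` (character vector of gene ids); see
#'   [read_drug_table()].
#' @param inhibition fraction in (0, 1].
#' @return the inhibited network.
#' @export
apply_drug <- function(net, drug, inhibition) {
  if (!is.numeric(inhibition) || inhibition <= 0 || inhibition > 1)
    stop("inhibition must be in (0, 1]")
  targets <- if (is.list(drug)) drug$targets else drug
  hit <- reactions_of_genes(net, targets)
  for (r in hit) {
    i <- match(r, net$reactions$id)
    net$reactions$lower_bound[i] <- net$reactions$lower_bound[i] * (1 - inhibition)
    net$reactions$upper_bound[i] <- net$reactions$upper_bound[i] * (1 - inhibition)
  }
  net
}

#' Inhibition-response curve of a drug
#'
#' Correlation with the initial-stage state at percentage inhibitions from
#' 10% to 100%, plus the minimal level whose correlation is within
#' `plateau_tol` of the curve's plateau (maximum).
#'
#' @inheritParams knockout_screen
#' @param drug a drug record (list with `targets`).
#' @param levels inhibition fractions to scan.
#' @param plateau_tol tolerance for "at the plateau" (default 0.01).
#' @return list with `curve` (data.frame `inhibition`, `correlation`) and
#'   `minimal_level`.
#' @export
inhibition_scan <- function(later_net, drug, initial_state, perturbed,
                            exp_later = NULL, levels = seq(0.1, 1, by = 0.1),
                            plateau_tol = 0.01,
                            mode = c("sample", "project"), seed = 1L,
                            sampler = list()) {
  mode <- match.arg(mode)
  ref <- if (inherits(initial_state, "flux_state")) initial_state$flux else initial_state
  cc <- vapply(levels, function(f) {
    netd <- apply_drug(later_net, drug, f)
    evaluate_modulated(netd, exp_later, perturbed, ref, mode = mode,
                       seed = derive_seed(seed, "inh", round(100 * f)),
                       sampler = sampler)
  }, numeric(1))
  curve <- data.frame(inhibition = levels, correlation = cc)
  ok <- is.finite(cc)
  minimal <- if (any(ok)) {
    plateau <- max(cc[ok])
    min(levels[ok & cc >= plateau - plateau_tol])
  } else NA_real_
  list(curve = curve, minimal_level = minimal)
}

#' Drug-repurposing screen against a transition
#'
#' Screens inhibitor-class drugs with at least one target mapping to model
#' reactions at a fixed inhibition level (default 50%, the level at which
#' the inhibition-response curves plateau). Reports the post-drug correlation
#' with the initial-stage state, its log2 fold-change against the baseline,
#' the single-/multi-target annotation, and whether the drug passes the
#' `log2FC > fc_cutoff` filter.
#'
#' @inheritParams knockout_screen
#' @param drug_table data.frame from [read_drug_table()]: `drug_id`,
#'   `drug_name`, `action`, `targets` (list column).
#' @param inhibition inhibition fraction (default 0.5).
#' @param fc_cutoff log2 fold-change filter threshold (default 2).
#' @return data.frame ranked by descending correlation with columns
#'   `drug_id`, `drug_name`, `n_targets`, `n_mapped_reactions`, `multi_target`,
#'   `correlation`, `log2fc`, `pass_filter`.
#' @export
drug_screen <- function(later_net, drug_table, initial_state, perturbed,
                        exp_later = NULL, baseline, inhibition = 0.5,
                        fc_cutoff = 2, mode = c("sample", "project"),
                        seed = 1L, sampler = list(), corr_floor = 1e-3) {
  mode <- match.arg(mode)
  ref <- if (inherits(initial_state, "flux_state")) initial_state$flux else initial_state
  if (!nrow(drug_table))
    return(data.frame(drug_id = character(0), drug_name = character(0),
                      n_targets = integer(0), n_mapped_reactions = integer(0),
                      multi_target = logical(0), correlation = numeric(0),
                      log2fc = numeric(0), pass_filter = logical(0)))
  rows <- lapply(seq_len(nrow(drug_table)), function(i) {
    rec <- drug_table[i, ]
    targets <- rec$targets[[1]]
    if (!isTRUE(grepl("inhibitor", tolower(rec$action)))) {
      message("drug_screen: skipping non-inhibitor record '", rec$drug_id, "'")
      return(NULL)
    }
    mapped <- reactions_of_genes(later_net, targets)
    if (!length(mapped)) return(NULL)
    netd <- apply_drug(later_net, list(targets = targets), inhibition)
    cc <- evaluate_modulated(netd, exp_later, perturbed, ref, mode = mode,
                             seed = derive_seed(seed, "drug", rec$drug_id),
                             sampler = sampler)
    fc <- if (is.finite(cc)) corr_log2fc(cc, baseline, corr_floor) else NA_real_
    data.frame(drug_id = rec$drug_id, drug_name = rec$drug_name,
               n_targets = length(targets), n_mapped_reactions = length(mapped),
               multi_target = length(targets) > 1, correlation = cc,
               log2fc = fc, pass_filter = is.finite(fc) && fc > fc_cutoff,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(drug_screen(later_net, drug_table[0, ], initial_state,
                                        perturbed, exp_later, baseline))
  out <- do.call(rbind, rows)
  out <- out[order(-out$correlation, out$drug_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standardised IC50 (GDSC-style z-score)
#'
#' `z = (x - mu) / sigma` with `mu` and the population `sigma` taken over the
#' IC50 values of all screened cell lines. Negative z means the queried cell
#' line is more sensitive than average. The formula as sometimes printed uses
#' the variance in the denominator; `denominator = "var"` reproduces that
#' strict form for audit, but the standard z-score is the default.
#'
#' @param ic50 IC50 of the drug in the cell line of interest.
#' @param ic50_all IC50 values over all cell lines (including the queried one).
#' @param denominator `"sd"` (standard, default) or `"var"` (strict printed
#'   form).
#' @return the z-score.
#' @export
gdsc_zscore <- function(ic50, ic50_all, denominator = c("sd", "var")) {
  denominator <- match.arg(denominator)
  mu <- mean(ic50_all)
  sigma <- sqrt(mean((ic50_all - mu)^2))   # population sd
  den <- if (denominator == "sd") sigma else sigma^2
  if (den == 0) stop("zero variance in IC50 vector")
  (ic50 - mu) / den
}

#' Pathway overlap values of a drug
#'
#' For every subsystem containing at least one reaction targeted by the drug
#' (GPR membership of any target gene), the ratio of targeted reactions to
#' the subsystem's total reaction count.
#'
#' @param drug drug record (list with `targets`) or character vector of
#'   target gene ids.
#' @param net a [metabolic_network()].
#' @return data.frame `subsystem`, `targeted`, `size`, `overlap_value`.
#' @export
drug_pathway_overlap <- function(drug, net) {
  targets <- if (is.list(drug)) drug$targets else drug
  hit <- reactions_of_genes(net, targets)
  subs <- net$reactions$subsystem
  subs[is.na(subs) | !nzchar(subs)] <- "unassigned"
  hit_subs <- unique(subs[net$reactions$id %in% hit])
  out <- do.call(rbind, lapply(hit_subs, function(s) {
    inset <- subs == s
    k <- sum(inset & net$reactions$id %in% hit)
    data.frame(subsystem = s, targeted = k, size = sum(inset),
               overlap_value = k / sum(inset), stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(subsystem = character(0), targeted = integer(0),
                      size = integer(0), overlap_value = numeric(0)))
  out[order(-out$overlap_value, out$subsystem), , drop = FALSE]
}

#' Read / write a drug-target table
#'
#' TSV with columns `drug_id`, `drug_name`, `action`, `target_gene_ids`
#' (semicolon-separated). The in-memory form carries the targets as a list
#' column `targets`.
#'
#' @param path TSV file.
#' @return data.frame with list column `targets`.
#' @export
read_drug_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "drug_name", "action", "target_gene_ids")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("drug table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$targets <- lapply(strsplit(df$target_gene_ids, ";", fixed = TRUE), trimws)
  if (any(!vapply(df$targets, length, integer(1))))
    stop("drug record without targets")
  df
}

#' @rdname read_drug_table
#' @param drug_table data.frame with `targets` list column.
#' @export
write_drug_table <- function(drug_table, path) {
  df <- drug_table
  df$target_gene_ids <- vapply(df$targets, paste, character(1), collapse = ";")
  df$targets <- NULL
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an IC50 table
#'
#' TSV with columns `drug_id`, `cell_line`, `ic50`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_ic50_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "cell_line", "ic50")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("IC50 table missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}
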