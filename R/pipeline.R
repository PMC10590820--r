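#' Pipeline configuration
#'
#' Assembles all tunables of the end-to-end analysis with their canonical
#' defaults: carbon-source uptake cap 10 mmol gDW^-1 h^-1, activity tolerance
#' 1e-6, activation flux 1e-3, extraction method iMAT with threshold scheme
#' Th1, sampling at 2 x reactions points for stage states, fold cut-off 2,
#' module-search cut-offs 0.001 (internal) / 0.01 (external), drug inhibition
#' 0.5, functionality randomisation iter 1000. `eval_n_points` (default 500)
#' is the sampling budget of the per-candidate re-evaluations in the module
#' search and the intervention screens, where a Pearson correlation over a
#' small perturbed set needs more samples than the stage-state default.
#'
#' @param ... overrides of any default (unknown keys are an error).
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    method = "iMAT", scheme = "Th1",
    uptake_limit = 10, activity_tol = 1e-6, eps = 1e-3,
    n_points_multiplier = 2, fold_cutoff = 2,
    internal_cutoff = 0.001, external_cutoff = 0.01,
    n_seeds = 20L, inhibition = 0.5, fc_cutoff = 2,
    iter = 1000L, evaluator = "sample", n_warmup = NULL,
    eval_n_points = 500L, seed = 1L, outdir = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  utils::modifyList(cfg, over)
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Values are parsed as numbers where possible, otherwise kept as strings.
#'
#' @param path configuration file.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  do.call(pipeline_config, stats::setNames(vals, keys))
}

# per-stage expression arrays on reactions (log10 scale), restricted to model genes
stage_reaction_expression <- function(net, merged) {
  lapply(colnames(merged), function(s) {
    gv <- stats::setNames(merged[, s], rownames(merged))
    map_expression_to_reactions(net, gv)
  })
}

extract_context <- function(net, exp, cfg) {
  th <- compute_thresholds(exp, cfg$method, cfg$scheme)
  switch(cfg$method,
    iMAT = imat_extract(net, exp, th$lower, th$upper, eps = cfg$eps,
                        tol = cfg$activity_tol),
    FASTCORE = {
      core <- names(exp)[!is.na(exp) & exp >= th$lower]
      fastcore_extract(net, intersect(core, net$reactions$id), tol = cfg$eps)
    },
    INIT = init_extract(net, init_weights(exp, th$lower), eps = cfg$eps,
                        tol = cfg$activity_tol))
}

#' Run the full transition analysis end to end
#'
#' Orchestrates: expression preprocessing (presence filter, imputation,
#' replicate merge, log10), model conditioning (carbon bounds, biomass
#' removal, sinks, flux-consistency), per-stage context-model extraction,
#' flux sampling with expression-correlated state selection, functionality
#' scoring, transition-perturbation detection with subsystem enrichment,
#' greedy module search, essentiality filtering, knockout and drug screens.
#' Every stochastic stage gets a seed derived deterministically from the
#' master seed, so reruns with the same config are reproducible. Stages with
#' missing inputs (no drug table, no normal-tissue matrix) are skipped with a
#' warning. If `cfg$outdir` is set, stage outputs are written as TSV/JSON and
#' a manifest records the configuration echo and completed stages.
#'
#' @param net the parent [metabolic_network()] (generic model).
#' @param expression a [stage_expression()] (replicates of ordered stages).
#' @param essential_mets metabolite ids whose sinks define the functionality
#'   score.
#' @param cfg a [pipeline_config()].
#' @param drug_table optional drug-target table (see [read_drug_table()]).
#' @param normal_expression optional genes x samples matrix for the
#'   essentiality filter.
#' @param significance logical: run the functionality randomisation test
#'   (expensive; default `FALSE`).
#' @return list with elements `merged`, `conditioned`, `models`, `states`,
#'   `functionality`, `transitions` (per transition: report, enrichment,
#'   strategies, knockouts, drugs), `essentiality`, `manifest`.
#' @export
run_pipeline <- function(net, expression, essential_mets,
                         cfg = pipeline_config(), drug_table = NULL,
                         normal_expression = NULL, significance = FALSE) {
  manifest <- list(config = cfg[setdiff(names(cfg), "outdir")],
                   started = format(Sys.time(), tz = "UTC"),
                   stages = character(0))
  done <- function(s) manifest$stages <<- c(manifest$stages, s)

  # 1. preprocess expression
  m <- filter_proteins(expression)
  m <- impute_expression(m)
  merged <- collapse_and_normalize(m)
  merged <- merged[intersect(rownames(merged), net$genes), , drop = FALSE]
  done("preprocess")

  # 2. condition the model
  cond <- fix_carbon_bounds(net, cfg$uptake_limit)
  if (!is.null(cond$objective)) {
    keep <- setdiff(cond$reactions$id, cond$objective)
    cond$objective <- NULL
    cond <- subnetwork(cond, keep)
  }
  cond <- add_sink_reactions(cond, essential_mets)
  cond <- flux_consistent_subnetwork(cond, cfg$activity_tol)
  sinks <- intersect(sink_ids(essential_mets), cond$reactions$id)
  done("condition")

  # 3. reaction expression + extraction per stage
  stages <- colnames(merged)
  rexp <- stage_reaction_expression(cond, merged)
  names(rexp) <- stages
  models <- lapply(stages, function(s)
    extract_context(cond, rexp[[s]], cfg))
  names(models) <- stages
  done("extract")

  # 4. sampling + optimal states
  sampler <- list()
  if (!is.null(cfg$n_warmup)) sampler$n_warmup <- as.integer(cfg$n_warmup)
  states <- lapply(stages, function(s) {
    mod <- models[[s]]
    sm <- do.call(sample_fluxes,
                  c(list(net = mod,
                         n_points = ceiling(cfg$n_points_multiplier *
                                            nrow(mod$reactions)),
                         seed = derive_seed(cfg$seed, "sample", s)), sampler))
    select_optimal_state(sm, rexp[[s]])
  })
  names(states) <- stages
  done("sample")

  # 5. functionality
  functionality <- lapply(stages, function(s) {
    if (significance)
      functionality_significance(cond, models[[s]], sinks,
                                 iter = cfg$iter,
                                 seed = derive_seed(cfg$seed, "fsig", s),
                                 activity_tol = cfg$activity_tol)
    else functionality_score(models[[s]], sinks, cfg$activity_tol)
  })
  names(functionality) <- stages
  done("functionality")

  # 6. essentiality (optional)
  essentiality <- NULL
  nonessential <- net$genes   # without a normal-tissue matrix, no gene is excluded
  if (!is.null(normal_expression)) {
    ess_net <- fix_carbon_bounds(net, cfg$uptake_limit)
    essentiality <- essentiality_screen(normal_expression, ess_net)
    nonessential <- essentiality$gene[essentiality$nonessential]
    done("essentiality")
  } else {
    warning("no normal-tissue matrix: essentiality stage skipped")
  }

  # 7. per-transition analyses
  eval_sampler <- sampler
  if (!is.null(cfg$eval_n_points))
    eval_sampler$n_points <- as.integer(cfg$eval_n_points)
  transitions <- list()
  for (t in seq_len(length(stages) - 1L)) {
    s0 <- stages[t]; s1 <- stages[t + 1L]
    rep_t <- perturbed_reactions(states[[s0]], states[[s1]],
                                 fold_cutoff = cfg$fold_cutoff,
                                 eps = cfg$activity_tol)
    enr <- subsystem_enrichment(rep_t$perturbed,
                                subnetwork(cond, rep_t$common))
    later <- models[[s1]]
    pert_in_model <- intersect(rep_t$perturbed, later$reactions$id)
    strategies <- list(); ko <- NULL; drugs <- NULL
    if (length(pert_in_model) >= 3 && !is.na(rep_t$baseline_correlation)) {
      strategies <- greedy_module_search(
        later, states[[s0]], pert_in_model, rexp[[s1]],
        internal_cutoff = cfg$internal_cutoff,
        external_cutoff = cfg$external_cutoff,
        n_seeds = cfg$n_seeds, mode = cfg$evaluator,
        seed = derive_seed(cfg$seed, "mod", t), sampler = eval_sampler)
      cand <- intersect(reaction_genes(later, pert_in_model), nonessential)
      if (length(cand))
        ko <- knockout_screen(later, cand, states[[s0]], pert_in_model,
                              rexp[[s1]], rep_t$baseline_correlation,
                              mode = cfg$evaluator,
                              seed = derive_seed(cfg$seed, "ko", t),
                              sampler = eval_sampler)
      if (!is.null(drug_table) && nrow(drug_table)) {
        drugs <- drug_screen(later, drug_table, states[[s0]], pert_in_model,
                             rexp[[s1]], rep_t$baseline_correlation,
                             inhibition = cfg$inhibition,
                             fc_cutoff = cfg$fc_cutoff, mode = cfg$evaluator,
                             seed = derive_seed(cfg$seed, "drug", t),
                             sampler = eval_sampler)
      } else {
        warning("no drug table: drug stage skipped for transition ", t)
      }
    }
    target_scores <- vapply(strategies, targetability, numeric(1),
                            nonessential = nonessential, net = later)
    transitions[[t]] <- list(initial = s0, later = s1, report = rep_t,
                             enrichment = enr, strategies = strategies,
                             targetability = target_scores,
                             knockouts = ko, drugs = drugs)
  }
  done("transitions")
  manifest$finished <- format(Sys.time(), tz = "UTC")

  out <- list(merged = merged, conditioned = cond, models = models,
              states = states, functionality = functionality,
              transitions = transitions, essentiality = essentiality,
              nonessential = nonessential, manifest = manifest)
  if (!is.null(cfg$outdir)) write_pipeline_outputs(out, cfg$outdir)
  out
}

# serialize the main stage outputs; called when cfg$outdir is set
write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  utils::write.table(out$merged, file.path(outdir, "merged_expression.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  for (s in names(out$states)) {
    st <- out$states[[s]]
    tsv(data.frame(reaction = names(st$flux), flux = unname(st$flux)),
        paste0("flux_state_", s, ".tsv"))
    write_model_json(out$models[[s]],
                     file.path(outdir, paste0("model_", s, ".json")),
                     provenance = out$models[[s]]$provenance)
  }
  for (t in seq_along(out$transitions)) {
    tr <- out$transitions[[t]]
    tsv(data.frame(reaction = tr$report$perturbed),
        paste0("perturbed_t", t, ".tsv"))
    tsv(tr$enrichment, paste0("enrichment_t", t, ".tsv"))
    if (length(tr$strategies)) {
      tsv(data.frame(
        strategy = seq_along(tr$strategies),
        reactions = vapply(tr$strategies, function(s)
          paste(s$reactions, collapse = ";"), character(1)),
        correlation = vapply(tr$strategies, `[[`, numeric(1), "correlation"),
        levels = vapply(tr$strategies, `[[`, numeric(1), "levels"),
        targetability = tr$targetability),
        paste0("strategies_t", t, ".tsv"))
    }
    if (!is.null(tr$knockouts)) tsv(tr$knockouts, paste0("knockouts_t", t, ".tsv"))
    if (!is.null(tr$drugs)) tsv(tr$drugs, paste0("drugs_t", t, ".tsv"))
  }
  if (!is.null(out$essentiality)) tsv(out$essentiality, "essentiality.tsv")
  jsonlite::write_json(out$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
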