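#' Generate a toy flux-consistent metabolic network
#'
#' Builds a compact network that exercises every pipeline feature: a glucose
#' uptake/transport funnel, a linear carbon core (last step a reversible
#' isomerase, one complex-GPR step, one isozyme step), a hub metabolite
#' feeding `n_branch` independently variable secretion branches (two of them
#' reversible), CO2/bicarbonate/water handling with proper formulas (so the
#' carbon-source bound rule has real work and real exemptions), and a
#' biomass-like drain reached only through the core, giving planted essential
#' genes. Branches 1-4 form the plantable module: each carries the shared
#' driver gene `g_drv` in complex with a branch-specific gene `mg<i>`.
#' Subsystems: Transport, Exchange/demand, Core carbon, Branch metabolism A,
#' Branch metabolism B; each contains reversible and irreversible members.
#'
#' The topology is deterministic given the size parameters; `seed` only
#' jitters branch capacities, so identical seeds give identical networks.
#'
#' @param n_core length of the linear core chain (>= 4).
#' @param n_branch number of hub branches (>= 6; branches 1-4 are the module).
#' @param seed integer seed.
#' @return list with `network` (a [metabolic_network()]), `module` (reaction
#'   ids of the planted module), `module_genes`, `driver_gene`,
#'   `essential_genes`, `essential_mets` (toy growth-essential metabolite
#'   set), `orphan_genes` (declared genes absent from every GPR).
#' @export
make_network <- function(n_core = 4L, n_branch = 15L, seed = 1L) {
  if (n_core < 4L || n_branch < 6L)
    stop("network too small to be flux-consistent with all features ",
         "(need n_core >= 4, n_branch >= 6)")
  n_decoy <- n_branch - 4L
  # decoy branches run at narrow mandatory levels (housekeeping demand);
  # phenotypic contrast is carried by the wide-capacity module branches
  lvl <- with_seed(seed, round(runif(n_branch, 0.08, 0.15), 3))

  # only branches 5, 6, 7 and 9 route through an explicit branch metabolite;
  # 5-7 are drained by native sink reactions (the growth-essential set), 9 by
  # an exchange. The other branches drain directly, which avoids duplicating
  # every branch flux in a mirror exchange
  met_branches <- intersect(c(5L, 6L, 7L, 8L, 9L), seq_len(n_branch))
  sink_branches <- intersect(c(5L, 6L, 7L), met_branches)
  rev_branches <- intersect(c(8L, 9L), met_branches)
  mets <- data.frame(
    id = c("glc_e", "glc_c", paste0("cm", seq_len(n_core), "_c"),
           paste0("bm", met_branches, "_c"),
           "co2_c", "co2_e", "hco3_c", "hco3_e", "h2o_c", "h2o_e", "bio_c"),
    formula = c("C6H12O6", "C6H12O6", rep("C6H10O5", n_core),
                rep("C3H6O3", length(met_branches)),
                "CO2", "CO2", "HCO3", "HCO3", "H2O", "H2O", "C10H16N5O13P3"),
    compartment = c("e", "c", rep("c", n_core),
                    rep("c", length(met_branches)),
                    "c", "e", "c", "e", "c", "e", "c"),
    stringsAsFactors = FALSE)

  hub <- paste0("cm", n_core, "_c")
  rx <- list()
  add <- function(id, st, lb, ub, sub, gpr = "") {
    row <- data.frame(id = id, lower_bound = lb, upper_bound = ub,
                      subsystem = sub, gpr = gpr, stringsAsFactors = FALSE)
    row$stoichiometry <- list(st)
    rx[[length(rx) + 1L]] <<- row
  }

  # glucose consumption runs near saturation (mandatory uptake >= 8): the
  # backbone flux is then stable across flux states and phenotypic contrast
  # concentrates in the branches, where the module is planted
  add("EX_glc", c(glc_e = -1), -1000, -8, "Exchange/demand")
  add("T_glc", c(glc_e = -1, glc_c = 1), 0, 1000, "Transport", "tg1")
  add("C1", c(glc_c = -1, cm1_c = 1, h2o_c = 0.1), 0, 1000, "Core carbon", "cg1")
  add("C2", c(cm1_c = -1, cm2_c = 1, co2_c = 0.1), 0, 1000, "Core carbon", "cg2")
  add("C3", c(cm2_c = -1, cm3_c = 1), 0, 1000, "Core carbon", "cg3a and cg3b")
  for (k in seq(4, n_core)) {
    st <- stats::setNames(c(-1, 1), paste0("cm", c(k - 1, k), "_c"))
    # last core step: reversible isomerase with isozymes
    add(paste0("C", k), st, if (k == n_core) -1000 else 0, 1000,
        "Core carbon", if (k == n_core) "cg4a or cg4b" else paste0("cg", k))
  }
  dual <- 0L
  for (i in seq_len(n_branch)) {
    bm <- paste0("bm", i, "_c")
    sub <- if (i <= ceiling(n_branch / 2)) "Branch metabolism A" else "Branch metabolism B"
    gpr <- if (i <= 4) {
      paste0("g_drv and mg", i)
    } else if (i %% 2 == 1) {
      paste0("bg", i)
    } else {
      dual <- dual + 1L
      paste0("bg", i, "a or bg", i, "b")
    }
    # reversible flags sit on metabolite-carrying branches, where reversal is
    # blocked by mass balance and cannot inject noise carbon; their mandatory
    # level is enforced downstream, on the secretion reaction
    rev_branch <- i %in% rev_branches
    direct <- !(i %in% met_branches)
    st <- if (direct) stats::setNames(-1, hub) else
      stats::setNames(c(-1, 1), c(hub, bm))
    if (i <= 4) {
      # module branch: free up to a capacity that binds at full activation
      # (4 x 1.8 plus the decoy demand fits inside the uptake budget)
      add(paste0("BR", i), st, 0, 1.8, sub, gpr)
    } else {
      lo <- if (rev_branch) -1.8 * lvl[i] else lvl[i]
      add(paste0("BR", i), st, lo, 1.8 * lvl[i], sub, gpr)
    }
    # secretion-only drains: glucose stays the sole carbon entry, so branch
    # genes cannot become growth-limiting. Sink-carrying metabolites are
    # drained by their (native) sink reaction alone; reversible branches by a
    # narrow mandatory secretion that pins their level
    if (i %in% sink_branches)
      add(paste0("SK_", bm), stats::setNames(-1, bm), 0, 1000, "Exchange/demand")
    else if (!direct)
      add(paste0("EX_bm", i), stats::setNames(-1, bm),
          if (rev_branch) lvl[i] else 0,
          if (rev_branch) 1.8 * lvl[i] else 1000, "Exchange/demand")
  }
  # ungated overflow drains on the hub: absorb whatever carbon the branches
  # do not take, so every branch configuration is feasible; two parallel
  # drains keep the flux-space volume balanced between module-on and
  # module-off configurations
  for (k in 1:2)
    add(paste0("OVF", k), stats::setNames(-1, hub), 0, 4, "Exchange/demand",
        gpr = paste0("og", k))
  add("BIO", stats::setNames(c(-1, 1), c(hub, "bio_c")), 0, 1000, "Core carbon")
  add("DM_bio", c(bio_c = -1), 0, 1000, "Exchange/demand")
  # byproduct handling: small stoichiometric yield and a modest uptake
  # allowance keep these side fluxes an order of magnitude below the branches
  add("T_h2o", c(h2o_c = -1, h2o_e = 1), -1000, 1000, "Transport")
  add("EX_h2o", c(h2o_e = -1), 0, 1000, "Exchange/demand")
  add("T_co2", c(co2_c = -1, co2_e = 1), 0, 1000, "Transport")
  add("EX_co2", c(co2_e = -1), 0, 1000, "Exchange/demand")
  # carbonate conversion runs at a narrow mandatory level: the byproduct
  # loop is then determined by the (stable) backbone, not by chain noise
  add("HCO3F", c(co2_c = -1, h2o_c = -1, hco3_c = 1), 0.05, 0.09, "Core carbon")
  add("T_hco3", c(hco3_c = -1, hco3_e = 1), -1000, 1000, "Transport")
  add("EX_hco3", c(hco3_e = -1), 0, 1000, "Exchange/demand")

  reactions <- do.call(rbind, rx)
  orphans <- c("xg1", "xg2")
  net <- metabolic_network(mets, reactions, genes = orphans,
                           objective = "DM_bio")
  list(network = net,
       module = paste0("BR", 1:4),
       module_genes = c("g_drv", paste0("mg", 1:4)),
       driver_gene = "g_drv",
       essential_genes = c("tg1", "cg1", "cg2", "cg3a", "cg3b",
                           if (9L %in% rev_branches) "bg9"),
       essential_mets = paste0("bm", sink_branches, "_c"),
       orphan_genes = orphans)
}

#' Generate stage-wise replicate expression with a planted module shift
#'
#' Baseline abundances are log-normal (meanlog = log 100, sdlog = 1, a
#' proteomic-intensity-like scale) and constant across stages up to
#' multiplicative log-normal noise of the stated coefficient of variation.
#' Genes of the planted module are multiplied by `effect` at each consecutive
#' stage (stage 2 = effect x stage 1, stage 3 = effect^2 x stage 1), so the
#' between-stage fold-change of the planted genes is `effect` by
#' construction. Missingness (~`missing_frac`) is injected missing-at-random
#' plus a low-abundance bias into background genes only (the planted signal
#' stays observed, keeping the ground truth well defined), and three extra
#' non-model entities exercise the presence-filter edge cases: absent
#' everywhere; one observation per stage; present in 2/3 replicates of one
#' stage only.
#'
#' @param net_info result of [make_network()] (or a list with `network`,
#'   `module_genes`, `essential_genes`).
#' @param effect fold-change of module-gene abundance between consecutive
#'   stages (default 4).
#' @param noise_cv multiplicative noise coefficient of variation (default 0.1).
#' @param missing_frac target missingness among background cells (default 0.05).
#' @param stages stage labels, in order.
#' @param n_reps replicates per stage (default 3).
#' @param seed integer seed.
#' @return a [stage_expression()] with `stages x n_reps` columns.
#' @export
make_stage_expression <- function(net_info, effect = 4, noise_cv = 0.1,
                                  missing_frac = 0.05,
                                  stages = c("monolayer", "moruloid", "blastuloid"),
                                  n_reps = 3L, seed = 1L) {
  net <- net_info$network
  genes <- net$genes
  module_genes <- net_info$module_genes
  protected <- union(module_genes, net_info$essential_genes %||% character(0))
  sdlog_noise <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    base <- stats::setNames(rlnorm(length(genes), meanlog = log(100), sdlog = 1),
                            genes)
    # plant the module at a low initial abundance so the stated fold shift
    # sweeps its reactions from the bottom to the top of the expression range
    base[module_genes] <- 100 * exp(-2.1)
    # overflow genes sit near the background centre with a small gradient:
    # the drains absorb slack whenever the module is not called for, and the
    # gradient fixes the order in which they fill, at every stage alike
    og <- sort(grep("^og", genes, value = TRUE))
    base[og] <- 100 * 0.85^(seq_along(og) - 1)
    cols <- as.vector(outer(seq_len(n_reps), stages,
                            function(r, s) paste0(s, "_r", r)))
    stage_of <- rep(stages, each = n_reps)
    vals <- matrix(NA_real_, length(genes), length(cols),
                   dimnames = list(genes, cols))
    for (j in seq_along(cols)) {
      mult <- ifelse(genes %in% module_genes,
                     effect^(match(stage_of[j], stages) - 1), 1)
      vals[, j] <- base * mult * rlnorm(length(genes), 0, sdlog_noise)
    }
    # missingness: MAR plus a low-abundance-biased component, background only
    bg <- !(genes %in% protected)
    if (missing_frac > 0 && any(bg)) {
      lowness <- rank(-base) / length(base)        # 1 = lowest abundance
      p_miss <- missing_frac * (0.5 + lowness)
      for (j in seq_along(cols)) {
        drop <- bg & (runif(length(genes)) < p_miss)
        vals[drop, j] <- NA_real_
      }
    }
    edge <- matrix(NA_real_, 3, length(cols),
                   dimnames = list(c("edge_absent", "edge_sparse", "edge_half"),
                                   cols))
    edge["edge_sparse", match(stages, stage_of)] <- 50          # 1 of 3 per stage
    edge["edge_half", which(stage_of == stages[1])[1:2]] <- 80  # 2 of 3, stage 1
    stage_expression(rbind(vals, edge), stage_of)
  })
}

#' Generate a toy drug-target table with one true positive
#'
#' One drug (`D_true`) targets exactly the genes of the planted module;
#' `n_decoys` decoys target 1-2 random non-module genes each. All records are
#' inhibitor-class.
#'
#' @param net_info result of [make_network()].
#' @param n_decoys number of decoy drugs (default 5).
#' @param seed integer seed.
#' @return data.frame in the [read_drug_table()] layout (with `targets` list
#'   column).
#' @export
make_drug_table <- function(net_info, n_decoys = 5L, seed = 1L) {
  net <- net_info$network
  module_genes <- net_info$module_genes
  pool <- setdiff(grep("^bg|^cg4", net$genes, value = TRUE),
                  net_info$essential_genes %||% character(0))
  with_seed(seed, {
    decoy_targets <- lapply(seq_len(n_decoys), function(i)
      sample(pool, sample(1:2, 1)))
    df <- data.frame(
      drug_id = c("D_true", if (n_decoys) paste0("D_decoy", seq_len(n_decoys))),
      drug_name = c("true positive", if (n_decoys) paste0("decoy ", seq_len(n_decoys))),
      action = "inhibitor", stringsAsFactors = FALSE)
    df$targets <- c(list(module_genes), decoy_targets)
    df$target_gene_ids <- vapply(df$targets, paste, character(1), collapse = ";")
    df
  })
}

#' Generate a toy normal-tissue expression matrix
#'
#' Log-normal gene x sample abundances, strictly positive, covering every
#' model gene - a stand-in for a normal-tissue RNA compendium used by the
#' essentiality filter.
#'
#' @param net_info result of [make_network()].
#' @param n_samples number of samples (default 12).
#' @param seed integer seed.
#' @return numeric matrix genes x samples.
#' @export
make_normal_expression <- function(net_info, n_samples = 12L, seed = 1L) {
  genes <- net_info$network$genes
  with_seed(seed, {
    matrix(rlnorm(length(genes) * n_samples, log(50), 0.6),
           nrow = length(genes),
           dimnames = list(genes, paste0("N", seq_len(n_samples))))
  })
}

#' Generate a toy IC50 table
#'
#' Log-normal IC50 values for each drug over `n_lines` cell lines; the first
#' cell line (`CL1`) plays the role of the line of interest.
#'
#' @param drug_table result of [make_drug_table()].
#' @param n_lines number of cell lines (default 20).
#' @param seed integer seed.
#' @return data.frame `drug_id`, `cell_line`, `ic50`.
#' @export
make_ic50_table <- function(drug_table, n_lines = 20L, seed = 1L) {
  with_seed(seed, {
    do.call(rbind, lapply(drug_table$drug_id, function(d)
      data.frame(drug_id = d, cell_line = paste0("CL", seq_len(n_lines)),
                 ic50 = rlnorm(n_lines, log(10), 0.8),
                 stringsAsFactors = FALSE)))
  })
}

#' Bundle a complete synthetic scenario
#'
#' All inputs of the pipeline at toy scale, with planted ground truth: the
#' network with its plantable module and essential genes, three-stage
#' replicate expression with the module shifted by `effect` per transition,
#' a drug table whose true positive targets the module, a normal-tissue
#' matrix, and an IC50 table.
#'
#' @param seed master seed; sub-generators get deterministically derived
#'   seeds.
#' @param effect,noise_cv,missing_frac see [make_stage_expression()].
#' @param n_core,n_branch see [make_network()].
#' @param n_decoys see [make_drug_table()].
#' @return list with components `network`, `module`, `module_genes`,
#'   `driver_gene`, `essential_genes`, `essential_mets`, `orphan_genes`,
#'   `expression`, `drug_table`, `normal_expression`, `ic50`, `seed`.
#' @export
make_scenario <- function(seed = 1L, effect = 4, noise_cv = 0.1,
                          missing_frac = 0.05, n_core = 4L, n_branch = 15L,
                          n_decoys = 5L) {
  info <- make_network(n_core, n_branch, seed = derive_seed(seed, "net"))
  info$expression <- make_stage_expression(
    info, effect = effect, noise_cv = noise_cv, missing_frac = missing_frac,
    seed = derive_seed(seed, "expr"))
  info$drug_table <- make_drug_table(info, n_decoys = n_decoys,
                                     seed = derive_seed(seed, "drug"))
  info$normal_expression <- make_normal_expression(
    info, seed = derive_seed(seed, "normal"))
  info$ic50 <- make_ic50_table(info$drug_table, seed = derive_seed(seed, "ic50"))
  info$seed <- seed
  info
}
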