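test_that("E-flux scales bounds linearly and anchors at the sample maximum", {
  net <- branched_network()
  gv <- c(ga = 10, gb1 = 5, gb2 = 2, gd = 0)
  out <- eflux_bounds(net, gv, b_max = 1000)
  ub <- stats::setNames(out$reactions$upper_bound, out$reactions$id)
  lb <- stats::setNames(out$reactions$lower_bound, out$reactions$id)
  expect_equal(ub[["R1"]], 1000)          # max-expression anchor
  expect_equal(lb[["R1"]], 0)             # irreversible keeps lb = 0
  expect_equal(ub[["R2"]], 1000 * 5 / 10) # isozyme max, linear scaling
  expect_equal(ub[["RD"]], 0)
  expect_equal(ub[["EX_B"]], 1000)        # no GPR -> untouched
  expect_equal(lb[["EX_C"]], -5)          # reversible exchange untouched
  # halving a gene's expression halves its sole reaction's bound
  gv2 <- gv; gv2["gb1"] <- 2.5; gv2["gb2"] <- 1
  out2 <- eflux_bounds(net, gv2, b_max = 1000)
  expect_equal(out2$reactions$upper_bound[out2$reactions$id == "R2"],
               ub[["R2"]] / 2)
  # reversible GPR reaction gets a symmetric box
  net3 <- chain_network()
  net3 <- set_bounds(net3, "R1", lb = -100)
  out3 <- eflux_bounds(net3, c(g1 = 4, g2 = 4, g3 = 1), b_max = 50)
  i <- match("R1", out3$reactions$id)
  expect_equal(out3$reactions$lower_bound[i], -50)
  expect_equal(out3$reactions$upper_bound[i], 50)
  expect_error(eflux_bounds(net, c(ga = 0, gb1 = 0, gb2 = 0, gd = 0)),
               "all-zero")
})

test_that("gene knockout disables complexes but not isozymes, idempotently", {
  net <- branched_network()
  ko <- gene_knockout(net, "ga")
  i <- match("R1", ko$reactions$id)
  expect_equal(ko$reactions$upper_bound[i], 0)
  j <- match("R2", ko$reactions$id)
  expect_equal(ko$reactions$upper_bound[j], 8)      # isozyme survives
  ko1 <- gene_knockout(net, "gb1")
  expect_equal(ko1$reactions$upper_bound[match("R2", ko1$reactions$id)], 8)
  ko2 <- gene_knockout(net, c("gb1", "gb2"))
  expect_equal(ko2$reactions$upper_bound[match("R2", ko2$reactions$id)], 0)
  expect_equal(gene_knockout(ko, "ga"), ko)          # idempotent
  expect_error(gene_knockout(net, "ghost"), "unknown gene")
})

test_that("essentiality screen recovers planted essential genes exactly", {
  info <- make_network(seed = 8)
  net <- fix_carbon_bounds(info$network)
  normal <- make_normal_expression(info, n_samples = 6, seed = 2)
  res <- essentiality_screen(normal, net, genes = net$genes, quantile = TRUE)
  ratios <- attr(res, "ratios")
  expect_true(all(ratios >= 0 & ratios <= 1 + 1e-9, na.rm = TRUE))
  found_essential <- res$gene[!res$nonessential]
  expect_setequal(found_essential, info$essential_genes)
  # genes absent from every GPR never change growth
  orphan <- res[res$gene %in% info$orphan_genes, ]
  expect_true(all(orphan$nonessential))
  expect_true(all(abs(ratios[info$orphan_genes, ] - 1) < 1e-9, na.rm = TRUE))
})

test_that("drug application scales bounds of GPR-member reactions", {
  net <- branched_network()
  half <- apply_drug(net, list(targets = "gb1"), 0.5)
  i <- match("R2", half$reactions$id)
  expect_equal(half$reactions$upper_bound[i], 4)     # isozymes dampened too
  full <- apply_drug(net, list(targets = "ga"), 1)
  j <- match("R1", full$reactions$id)
  expect_equal(full$reactions$upper_bound[j], 0)
  # 100% inhibition of a single-gene rule == knockout for that reaction
  ko <- gene_knockout(net, "ga")
  expect_equal(full$reactions[j, c("lower_bound", "upper_bound")],
               ko$reactions[j, c("lower_bound", "upper_bound")])
  # drugs with disjoint targets commute
  d1 <- list(targets = "ga"); d2 <- list(targets = "gd")
  ab <- apply_drug(apply_drug(net, d1, 0.3), d2, 0.6)
  ba <- apply_drug(apply_drug(net, d2, 0.6), d1, 0.3)
  expect_equal(ab$reactions, ba$reactions)
  expect_error(apply_drug(net, d1, 0), "inhibition")
  expect_error(apply_drug(net, d1, 1.2), "inhibition")
})

test_that("GDSC z-scores use the population sd (variance mode for audit)", {
  expect_equal(gdsc_zscore(3, c(1, 2, 3)), 1.224745, tolerance = 1e-6)
  expect_equal(gdsc_zscore(2, c(1, 2, 3)), 0)
  mu <- mean(c(1, 2, 3)); sig <- sqrt(mean((c(1, 2, 3) - mu)^2))
  expect_equal(gdsc_zscore(mu + sig, c(1, 2, 3)), 1)
  expect_equal(gdsc_zscore(3, c(1, 2, 3), denominator = "var"),
               1 / sig^2 * 1)
  expect_error(gdsc_zscore(1, c(2, 2, 2)), "zero variance")
})

test_that("drug pathway overlap is the targeted share of each subsystem", {
  net <- branched_network()
  ov <- drug_pathway_overlap(list(targets = c("gb1")), net)
  expect_equal(ov$overlap_value[ov$subsystem == "Route2"], 1)   # 1 of 1
  info <- make_network(seed = 4)
  ov2 <- drug_pathway_overlap(list(targets = info$module_genes),
                              info$network)
  expect_true(all(ov2$overlap_value > 0 & ov2$overlap_value <= 1))
  k <- sum(ov2$targeted)
  expect_equal(k, length(reactions_of_genes(info$network, info$module_genes)))
  empty <- drug_pathway_overlap(list(targets = "ghost_gene"), net)
  expect_equal(nrow(empty), 0)
})

test_that("drug tables round-trip through TSV and screen inputs validate", {
  info <- make_network(seed = 4)
  tab <- make_drug_table(info, n_decoys = 3, seed = 5)
  path <- tempfile(fileext = ".tsv")
  write_drug_table(tab, path)
  back <- read_drug_table(path)
  expect_equal(back$drug_id, tab$drug_id)
  expect_equal(back$targets, tab$targets)
  expect_error(suppressWarnings(read_drug_table(tempfile())),
               "cannot open|missing")
  # empty drug table gives an empty, well-formed screen result
  net <- flux_consistent_subnetwork(fix_carbon_bounds(info$network))
  res <- drug_screen(net, tab[0, ], stats::setNames(1:3, c("BR1", "BR2", "BR3")),
                     c("BR1", "BR2", "BR3"), NULL, baseline = 0.1)
  expect_equal(nrow(res), 0)
})

test_that("growth-rate ratios never exceed one (bound shrinking lemma)", {
  info <- make_network(seed = 12)
  net <- fix_carbon_bounds(info$network)
  gv <- stats::setNames(rep(5, length(net$genes)), net$genes)
  netj <- eflux_bounds(net, gv)
  g0 <- fba_maximize(netj, "DM_bio")
  for (g in c("cg4a", "bg5", info$driver_gene)) {
    g1 <- tryCatch(fba_maximize(gene_knockout(netj, g), "DM_bio"),
                   error = function(e) 0)
    expect_lte(g1, g0 + 1e-9)
  }
})
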