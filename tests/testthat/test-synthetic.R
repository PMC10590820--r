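test_that("generated networks are reproducible and flux-consistent as built", {
  a <- make_network(seed = 42)
  b <- make_network(seed = 42)
  expect_equal(a$network$reactions, b$network$reactions)
  cons <- flux_consistent_subnetwork(a$network)
  expect_equal(nrow(cons$reactions), nrow(a$network$reactions))
  expect_error(make_network(n_core = 2, n_branch = 3), "too small")
})

test_that("generated networks carry the advertised structural features", {
  info <- make_network(seed = 3)
  net <- info$network
  expect_gte(length(unique(net$reactions$subsystem)), 4)
  # module reactions all carry GPRs with the shared driver gene
  idx <- match(info$module, net$reactions$id)
  expect_true(all(grepl(info$driver_gene, net$reactions$gpr[idx])))
  # carbon formulas parse with at least one carbon on non-cofactor metabolites
  core_mets <- grep("^cm|^bm|^glc", net$metabolites$id, value = TRUE)
  ccount <- vapply(net$metabolites$formula[match(core_mets, net$metabolites$id)],
                   carbon_count, integer(1))
  expect_true(all(ccount >= 1))
  # at least one reversible and one irreversible reaction per subsystem
  rev <- net$reactions$lower_bound < 0
  for (s in unique(net$reactions$subsystem)) {
    inset <- net$reactions$subsystem == s
    expect_true(any(rev[inset]), label = paste("reversible in", s))
    expect_true(any(!rev[inset]), label = paste("irreversible in", s))
  }
  # essential metabolites exist and their sinks are native
  expect_true(all(info$essential_mets %in% net$metabolites$id))
  expect_true(all(sink_ids(info$essential_mets) %in% net$reactions$id))
})

test_that("stage expression plants the stated fold shift with noise and NAs", {
  info <- make_network(seed = 2)
  m <- make_stage_expression(info, effect = 4, noise_cv = 0.1, seed = 9)
  expect_s3_class(m, "stage_expression")
  expect_equal(ncol(m$values), 9)
  expect_equal(length(unique(m$stages)), 3)
  expect_true(all(m$values > 0, na.rm = TRUE))
  # module genes shift ~4-fold per transition (noise CV 0.1)
  merged <- collapse_and_normalize(impute_expression(filter_proteins(m)),
                                   log_base = NA)
  for (g in info$module_genes) {
    expect_gt(merged[g, 2] / merged[g, 1], 2.5)
    expect_gt(merged[g, 3] / merged[g, 2], 2.5)
  }
  # the filter edge-case rows behave as designed
  filt <- filter_proteins(m)
  expect_false("edge_absent" %in% rownames(filt$values))
  expect_false("edge_sparse" %in% rownames(filt$values))
  expect_true("edge_half" %in% rownames(filt$values))
  # with a 4-fold effect and CV 0.1 every planted gene passes |log2FC| >= 1
  s1 <- m$values[info$module_genes, m$stages == m$stage_levels[1]]
  s2 <- m$values[info$module_genes, m$stages == m$stage_levels[2]]
  de <- differential_expression(s1, s2)
  expect_true(all(abs(de$log2fc) >= 1))
  expect_true(all(de$direction == "up"))
})

test_that("a null effect yields a calibrated differential-expression rate", {
  info <- make_network(seed = 2)
  m <- make_stage_expression(info, effect = 1, noise_cv = 0.1,
                             missing_frac = 0, seed = 33)
  s1 <- m$values[, m$stages == m$stage_levels[1]]
  s2 <- m$values[, m$stages == m$stage_levels[2]]
  de <- differential_expression(s1, s2)
  # no gene moves 2-fold when the planted effect is absent
  expect_equal(sum(de$direction != "ns"), 0)
  # raw p-values are roughly uniform: the sub-0.05 share stays near alpha
  expect_lt(mean(de$p < 0.05), 0.25)
})

test_that("zero missingness makes imputation the identity", {
  info <- make_network(seed = 2)
  m <- make_stage_expression(info, missing_frac = 0, seed = 5)
  body <- m$values[!grepl("^edge", rownames(m$values)), ]
  expect_false(anyNA(body))
  filt <- filter_proteins(m)
  imp <- impute_expression(filt)
  keep <- !grepl("^edge", rownames(filt$values))
  expect_equal(imp$values[keep, ], filt$values[keep, ])
})

test_that("drug tables plant one true positive and disjoint decoys", {
  info <- make_network(seed = 6)
  tab <- make_drug_table(info, n_decoys = 4, seed = 7)
  expect_equal(nrow(tab), 5)
  expect_setequal(tab$targets[[1]], info$module_genes)
  for (k in 2:5)
    expect_length(intersect(tab$targets[[k]], info$module_genes), 0)
  expect_true(all(tab$action == "inhibitor"))
  single <- make_drug_table(info, n_decoys = 0, seed = 7)
  expect_equal(nrow(single), 1)
})

test_that("scenario bundles are seed-deterministic", {
  a <- make_scenario(seed = 5)
  b <- make_scenario(seed = 5)
  expect_equal(a$expression$values, b$expression$values)
  expect_equal(a$drug_table$target_gene_ids, b$drug_table$target_gene_ids)
  expect_equal(a$normal_expression, b$normal_expression)
  expect_equal(a$ic50$ic50, b$ic50$ic50)
})
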