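mk_state <- function(...) {
  v <- c(...)
  structure(list(flux = v, correlation = NA, sample_index = 1L, seed = 1L),
            class = "flux_state")
}

test_that("the two-fold rule is inclusive, floored, and sign-aware", {
  a <- mk_state(r1 = 1, r2 = 1, r3 = 1e-9, r4 = 2, r5 = -3, r6 = 1)
  b <- mk_state(r1 = 2, r2 = 1.5, r3 = 0, r4 = 4.2, r5 = 3, r6 = 1)
  rep <- perturbed_reactions(a, b)
  expect_true("r1" %in% rep$perturbed)      # exactly two-fold, inclusive
  expect_false("r2" %in% rep$perturbed)     # 1.5-fold
  expect_false("r3" %in% rep$perturbed)     # both below the noise floor
  expect_true("r4" %in% rep$perturbed)
  expect_true("r5" %in% rep$perturbed)      # sign flip at equal magnitude
  expect_false("r6" %in% rep$perturbed)
  expect_equal(unname(rep$log2_ratio["r1"]), 1)
})

test_that("perturbation is symmetric in the stage order", {
  set.seed(8)
  v1 <- stats::setNames(runif(20, 0, 5), paste0("r", 1:20))
  v2 <- stats::setNames(runif(20, 0, 5), paste0("r", 1:20))
  fwd <- perturbed_reactions(v1, v2)
  bwd <- perturbed_reactions(v2, v1)
  expect_setequal(fwd$perturbed, bwd$perturbed)
  expect_equal(fwd$log2_ratio, -bwd$log2_ratio)
})

test_that("baseline correlation equals the direct Pearson formula", {
  set.seed(13)
  rxn <- paste0("r", 1:10)
  a <- stats::setNames(rnorm(10), rxn)
  b <- 0.4 * a + stats::setNames(rnorm(10, sd = 0.5), rxn)
  got <- baseline_correlation(a, b, rxn)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got, manual)
  expect_equal(baseline_correlation(a, a, rxn), 1)
  expect_equal(baseline_correlation(a, -a, rxn), -1)
  expect_error(baseline_correlation(a, b, rxn[1:2]), ">= 3")
  expect_error(baseline_correlation(stats::setNames(rep(1, 10), rxn), b, rxn),
               "variance")
})

test_that("hypergeometric enrichment matches exact combinatorial arithmetic", {
  # N = 10 reactions, one subsystem of size K = 4; n = 5 perturbed hit all 4
  mets <- data.frame(id = "A_c", formula = "C", compartment = "c",
                     stringsAsFactors = FALSE)
  rx <- data.frame(id = sprintf("r%02d", 1:10),
                   lower_bound = -10, upper_bound = 10,
                   subsystem = rep(c("S1", "S2"), c(4, 6)), gpr = "",
                   stringsAsFactors = FALSE)
  rx$stoichiometry <- rep(list(c(A_c = 1)), 10)
  rx$stoichiometry[6:10] <- rep(list(c(A_c = -1)), 5)
  net <- metabolic_network(mets, rx)
  perturbed <- c(sprintf("r%02d", 1:4), "r05")
  enr <- subsystem_enrichment(perturbed, net)
  p_exact <- choose(4, 4) * choose(6, 1) / choose(10, 5)   # = 6/252
  expect_equal(enr$p[enr$subsystem == "S1"], p_exact)
  expect_equal(enr$overlap[enr$subsystem == "S1"], 4)
  expect_true(enr$significant[enr$subsystem == "S1"])
  # overlap counts add to n when subsystems partition the universe
  expect_equal(sum(enr$overlap), 5)
  # invariant to subsystem ordering
  net2 <- net
  net2$reactions$subsystem <- rev(net2$reactions$subsystem)
  enr2 <- subsystem_enrichment(sprintf("r%02d", 6:10), net2)
  expect_equal(enr2$p[enr2$subsystem == "S1"], p_exact)
})

test_that("enrichment p values are calibrated under uniform draws", {
  mets <- data.frame(id = "A_c", formula = "C", compartment = "c",
                     stringsAsFactors = FALSE)
  n_rxn <- 40
  rx <- data.frame(id = sprintf("r%02d", 1:n_rxn),
                   lower_bound = 0, upper_bound = 10,
                   subsystem = rep(c("S1", "S2", "S3", "S4"), each = 10),
                   gpr = "", stringsAsFactors = FALSE)
  rx$stoichiometry <- rep(list(c(A_c = -1)), n_rxn)
  net <- metabolic_network(mets, rx)
  set.seed(31)
  ps <- replicate(500, {
    hit <- sample(net$reactions$id, 8)
    subsystem_enrichment(hit, net)$p[1]   # smallest p of the draw
  })
  # under the null the smallest of 4 p-values exceeds its nominal level:
  # false-positive rate at 0.05 must stay below ~4 * 0.05 (selection effect)
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps < 0.5), 0.3)          # and p is not degenerate at 1
})
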