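test_that("threshold schemes are computed from the array, never hard-coded", {
  exp <- stats::setNames(as.numeric(1:100), paste0("r", 1:100))
  th <- compute_thresholds(exp, "iMAT", "Th1")
  expect_equal(th$lower, 1)      # array minimum
  expect_equal(th$upper, 91)     # smallest value of the top decile
  th2 <- compute_thresholds(exp, "iMAT", "Th2")
  expect_equal(th2$lower, mean(exp) - sd(exp))
  expect_equal(th2$upper, mean(exp) + sd(exp))
  expect_equal(compute_thresholds(exp, "FASTCORE", "Th1")$lower, 91)
  expect_equal(compute_thresholds(exp, "FASTCORE", "Th2")$lower, 1)
  expect_equal(compute_thresholds(exp, "INIT", "Th1")$lower, 91)
  # top-decile boundary uses a ceiling on the scored count
  exp15 <- stats::setNames(as.numeric(1:15), paste0("r", 1:15))
  expect_equal(compute_thresholds(exp15, "iMAT", "Th1")$upper, 14)  # ceil(1.5)=2nd largest
  expect_error(compute_thresholds(exp[1:5], "iMAT", "Th1"), "at least 10")
  expect_warning(compute_thresholds(stats::setNames(rep(2, 12), paste0("r", 1:12)),
                                    "iMAT", "Th1"), "constant")
})

test_that("iMAT objective equals exhaustive enumeration on a small fixture", {
  net <- branched_network()
  cons <- flux_consistent_subnetwork(net)
  ids <- cons$reactions$id
  # R1 high, R2 low, others unscored
  exp <- stats::setNames(rep(NA_real_, length(ids)), ids)
  exp["R1"] <- 10; exp["R2"] <- 1; exp["EX_B"] <- 5
  cm <- imat_extract(cons, exp, lower = 2, upper = 8, eps = 1e-3)
  # enumeration oracle: all activity patterns of (high active?, low off?)
  S <- stoich_matrix(cons)
  lb <- cons$reactions$lower_bound; ub <- cons$reactions$upper_bound
  eps <- 1e-3
  best <- -1
  for (hi_on in c(0, 1)) for (lo_off in c(0, 1)) {
    l2 <- lb; u2 <- ub
    i1 <- match("R1", ids); i2 <- match("R2", ids)
    if (hi_on) l2[i1] <- max(l2[i1], eps)
    if (lo_off) { l2[i2] <- 0; u2[i2] <- 0 }
    ok <- lp_solve(numeric(length(ids)), S, rep(0, nrow(S)),
                   lb = l2, ub = u2)$status == "optimal"
    if (ok) best <- max(best, hi_on + lo_off)
  }
  expect_equal(cm$provenance$objective, best)
  expect_equal(best, 2)             # both goals achievable here
  expect_true("R1" %in% cm$reactions$id)
  expect_false("R2" %in% cm$reactions$id)
  # every context model is flux-consistent
  again <- flux_consistent_subnetwork(cm)
  expect_setequal(again$reactions$id, cm$reactions$id)
})

test_that("iMAT with an empty high set can return a minimal or empty model", {
  net <- flux_consistent_subnetwork(branched_network())
  ids <- net$reactions$id
  exp <- stats::setNames(rep(1, length(ids)), ids)   # everything low
  cm <- imat_extract(net, exp, lower = 5, upper = 50)
  expect_equal(nrow(cm$reactions), 0)
})

test_that("FASTCORE output contains the core and is minimal on a fixture", {
  net <- flux_consistent_subnetwork(make_network(seed = 3)$network)
  core <- c("BR1", "C1")
  cm <- fastcore_extract(net, core)
  expect_true(all(core %in% cm$reactions$id))
  again <- flux_consistent_subnetwork(cm)
  expect_setequal(again$reactions$id, cm$reactions$id)

  # brute-force minimal support on a small consistent fixture
  small <- flux_consistent_subnetwork(branched_network())
  core2 <- "R1"
  cm2 <- fastcore_extract(small, core2)
  expect_true(all(core2 %in% cm2$reactions$id))
  ids <- small$reactions$id
  noncore <- setdiff(ids, core2)
  minimal <- Inf
  for (k in 0:length(noncore)) {
    for (sub in if (k == 0) list(character(0)) else
         asplit(utils::combn(noncore, k), 2)) {
      cand <- tryCatch(subnetwork(small, c(core2, unlist(sub))),
                       error = function(e) NULL)
      if (is.null(cand)) next
      ok <- tryCatch({
        rng <- fva(cand, core2)
        all(rng$max >= 1e-3 | rng$min <= -1e-3)
      }, error = function(e) FALSE)
      if (ok) minimal <- min(minimal, k)
    }
    if (is.finite(minimal)) break
  }
  expect_lte(nrow(cm2$reactions), minimal + 1 + 1)   # core + support, small slack
  # chain: supporting a middle reaction pulls in the whole chain
  chain <- chain_network()
  cm3 <- fastcore_extract(chain, "R1")
  expect_setequal(cm3$reactions$id, c("EX_A", "R1", "EX_B"))
  # empty core -> empty model
  expect_equal(nrow(fastcore_extract(chain, character(0))$reactions), 0)
  expect_error(fastcore_extract(chain, "nope"), "not in network")
})

test_that("INIT weights follow the 5*log2(expression/threshold) rule", {
  exp <- c(r1 = 4, r2 = 2, r3 = NA)
  w <- init_weights(exp, threshold = 2)
  expect_equal(unname(w["r1"]), 5)        # 5 * log2(2)
  expect_equal(unname(w["r2"]), 0)
  expect_equal(unname(w["r3"]), -2)       # no expression data
  expect_error(init_weights(exp, 0), "positive")
})

test_that("INIT extraction beats random reaction subsets on a small fixture", {
  net <- flux_consistent_subnetwork(branched_network())
  ids <- net$reactions$id
  w <- stats::setNames(rep(-2, length(ids)), ids)
  w["R1"] <- 6; w["EX_B"] <- 3; w["R2"] <- -4
  cm <- init_extract(net, w)
  expect_true(all(c("R1", "EX_B") %in% cm$reactions$id))
  expect_false("R2" %in% cm$reactions$id)
  got <- sum(w[cm$reactions$id])
  set.seed(9)
  for (k in 1:30) {
    keep <- ids[runif(length(ids)) < 0.5]
    if (!length(keep)) next
    cand <- tryCatch(flux_consistent_subnetwork(subnetwork(net, keep)),
                     error = function(e) NULL)
    if (is.null(cand) || !nrow(cand$reactions)) next
    expect_lte(sum(w[cand$reactions$id]), got + 1e-9)
  }
})
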