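# A controlled two-stage setting built from the synthetic generator: the
# initial state is the moruloid-like optimum (module off), the later model the
# same network, so clamping behaviour can be checked deterministically.
local_search_fixture <- function(seed = 11) {
  info <- make_network(seed = seed)
  net <- flux_consistent_subnetwork(fix_carbon_bounds(info$network))
  list(info = info, net = net)
}

test_that("clamping to a reference flux follows the sign-split bound rule", {
  net <- chain_network()
  neg <- clamp_to_reference(net, "EX_A", -5)
  i <- match("EX_A", neg$reactions$id)
  expect_equal(c(neg$reactions$lower_bound[i], neg$reactions$upper_bound[i]),
               c(-5, 0))
  pos <- clamp_to_reference(net, "R1", 3)
  i <- match("R1", pos$reactions$id)
  expect_equal(c(pos$reactions$lower_bound[i], pos$reactions$upper_bound[i]),
               c(0, 3))
  zer <- clamp_to_reference(net, "R1", 0)
  i <- match("R1", zer$reactions$id)
  expect_equal(c(zer$reactions$lower_bound[i], zer$reactions$upper_bound[i]),
               c(0, 0))
  # idempotence
  expect_equal(clamp_to_reference(pos, "R1", 3), pos)
  expect_error(clamp_to_reference(net, "nope", 1), "unknown reaction")
})

test_that("an infeasible clamp is rejected with the -Inf sentinel", {
  fx <- local_search_fixture()
  net <- fx$net
  # forcing the mandatory-uptake network to carry zero through the only
  # glucose transporter is infeasible
  netm <- set_bounds(net, "T_glc", lb = 0, ub = 0)
  expect_message(
    cc <- evaluate_modulated(netm, NULL, c("BR1", "BR2", "BR3"),
                             stats::setNames(rep(1, 3), c("BR1", "BR2", "BR3")),
                             mode = "project"),
    "infeasible")
  expect_identical(cc, -Inf)
})

test_that("clamping every perturbed reaction to the reference restores it", {
  fx <- local_search_fixture()
  net <- fx$net
  module <- fx$info$module
  ref <- stats::setNames(c(0.1, 0.2, 0.15, 0.1, 3, 2),
                         c(module, "OVF1", "OVF2"))
  netm <- net
  for (r in names(ref)) netm <- clamp_to_reference(netm, r, ref[[r]])
  cc <- evaluate_modulated(netm, NULL, names(ref), ref, mode = "project")
  expect_gt(cc, 0.95)
})

test_that("the single-modulation scan is sorted and input-order invariant", {
  fx <- local_search_fixture()
  net <- fx$net
  module <- fx$info$module
  pert <- c(module, "OVF1", "OVF2")
  ref <- stats::setNames(c(0.1, 0.2, 0.15, 0.1, 3.5, 2), pert)
  exp_arr <- map_expression_to_reactions(
    net, stats::setNames(rep(2, length(net$genes)), net$genes))
  exp_arr[module] <- 3   # later stage wants the module on
  scan <- single_modulation_scan(net, ref, pert, exp_arr, mode = "sample",
                                 seed = 5, sampler = list(n_points = 150))
  expect_equal(order(-scan$correlation), seq_len(nrow(scan)))
  scan2 <- single_modulation_scan(net, ref, rev(pert), exp_arr, mode = "sample",
                                  seed = 5, sampler = list(n_points = 150))
  expect_equal(scan, scan2)
})

test_that("greedy search traces are monotone with per-step gain >= cutoff", {
  fx <- local_search_fixture()
  net <- fx$net
  module <- fx$info$module
  pert <- c(module, "OVF1", "OVF2")
  ref <- stats::setNames(c(0.1, 0.2, 0.15, 0.1, 3.5, 2), pert)
  exp_arr <- map_expression_to_reactions(
    net, stats::setNames(rep(2, length(net$genes)), net$genes))
  exp_arr[module] <- 3
  strategies <- greedy_module_search(net, ref, pert, exp_arr, n_seeds = 3,
                                     mode = "sample", seed = 7,
                                     sampler = list(n_points = 150))
  expect_gt(length(strategies), 0)
  for (s in strategies) {
    expect_true(all(diff(s$trace) >= 0.001 - 1e-12))
    expect_equal(s$correlation, max(s$trace))
    expect_true(all(s$reactions %in% pert))
    expect_equal(length(s$reactions), length(s$trace))
  }
})

test_that("an infinite internal cut-off collapses every strategy to its seed", {
  fx <- local_search_fixture()
  net <- fx$net
  pert <- c(fx$info$module, "OVF1", "OVF2")
  ref <- stats::setNames(c(0.1, 0.2, 0.15, 0.1, 3.5, 2), pert)
  exp_arr <- map_expression_to_reactions(
    net, stats::setNames(rep(2, length(net$genes)), net$genes))
  exp_arr[fx$info$module] <- 3
  strategies <- greedy_module_search(net, ref, pert, exp_arr, n_seeds = 2,
                                     internal_cutoff = Inf,
                                     mode = "sample", seed = 7,
                                     sampler = list(n_points = 100))
  expect_gt(length(strategies), 0)
  for (s in strategies) expect_equal(s$reactions, s$seed_reaction)
})

test_that("looser internal cut-offs give larger modules (calibration pattern)", {
  fx <- local_search_fixture()
  net <- fx$net
  pert <- c(fx$info$module, "OVF1", "OVF2")
  ref <- stats::setNames(c(0.1, 0.2, 0.15, 0.1, 3.5, 2), pert)
  exp_arr <- map_expression_to_reactions(
    net, stats::setNames(rep(2, length(net$genes)), net$genes))
  exp_arr[fx$info$module] <- 3
  sizes <- vapply(c(1e-4, 0.2), function(cut) {
    st <- greedy_module_search(net, ref, pert, exp_arr, n_seeds = 2,
                               internal_cutoff = cut, mode = "sample",
                               seed = 17, sampler = list(n_points = 120))
    mean(vapply(st, function(s) length(s$reactions), numeric(1)))
  }, numeric(1))
  expect_gte(sizes[1], sizes[2])
})

test_that("targetability is the non-essential share of the strategy's genes", {
  net <- branched_network()   # R1: ga; R2: gb1 or gb2; RD: gd
  strat <- structure(list(reactions = c("R1", "R2", "RD")),
                     class = "modulation_strategy")
  expect_equal(targetability(strat, c("ga", "gb1", "gb2"), net), 75)
  expect_equal(targetability(strat, c("ga", "gb1", "gb2", "gd"), net), 100)
  expect_equal(targetability(strat, character(0), net), 0)
  expect_message(
    val <- targetability(structure(list(reactions = "EX_A"),
                                   class = "modulation_strategy"),
                         "ga", net),
    "no gene")
  expect_true(is.na(val))
})
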