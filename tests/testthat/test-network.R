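test_that("constructor enforces the container invariants", {
  net <- chain_network()
  expect_s3_class(net, "metabolic_network")
  expect_equal(net$reactions$id, sort(net$reactions$id))   # canonical order
  expect_setequal(net$genes, c("g1", "g2", "g3"))          # GPR genes collected

  bad <- net
  bad$reactions$stoichiometry[[1]] <- c(ghost_c = -1)
  expect_error(validate_network(bad), "undeclared metabolite")
  bad2 <- net
  bad2$reactions$lower_bound[1] <- 5
  bad2$reactions$upper_bound[1] <- -5
  expect_error(validate_network(bad2), "lower_bound")
})

test_that("JSON and SBML encodings of the same fixture load identically", {
  jpath <- system.file("extdata", "toy_model.json", package = "fluxmod")
  xpath <- system.file("extdata", "toy_model.xml", package = "fluxmod")
  nj <- load_model(jpath)
  nx <- load_model(xpath)
  expect_equal(nrow(nj$reactions), 3)
  expect_equal(nrow(nj$metabolites), 2)
  expect_equal(nj$metabolites, nx$metabolites)
  expect_equal(nj$genes, nx$genes)
  expect_equal(nj$reactions$id, nx$reactions$id)
  expect_equal(nj$reactions$lower_bound, nx$reactions$lower_bound)
  expect_equal(nj$reactions$upper_bound, nx$reactions$upper_bound)
  expect_equal(nj$reactions$subsystem, nx$reactions$subsystem)
  expect_equal(nj$reactions$gpr, nx$reactions$gpr)
  for (i in seq_len(3))
    expect_equal(sort(names(nj$reactions$stoichiometry[[i]])),
                 sort(names(nx$reactions$stoichiometry[[i]])))
})

test_that("JSON writer round-trips a network", {
  net <- branched_network()
  path <- tempfile(fileext = ".json")
  write_model_json(net, path, provenance = list(method = "none"))
  back <- read_model_json(path)
  expect_equal(back$reactions$id, net$reactions$id)
  expect_equal(back$reactions$gpr, net$reactions$gpr)
  expect_equal(back$reactions$lower_bound, net$reactions$lower_bound)
  expect_equal(stoich_matrix(back), stoich_matrix(net))
})

test_that("malformed model files raise parse errors naming the problem", {
  p <- tempfile(fileext = ".json")
  writeLines('{"metabolites": []}', p)
  expect_error(read_model_json(p), "missing")
  p2 <- tempfile(fileext = ".xml")
  writeLines("<sbml>", p2)
  expect_error(read_model_sbml(p2), "malformed")
  expect_error(load_model(tempfile(fileext = ".json")), "not found")
})

test_that("exchange reactions are the single-metabolite boundary drains", {
  net <- branched_network()
  expect_setequal(exchange_reactions(net), c("EX_A", "EX_B", "EX_C"))
})

test_that("carbon-source bounds: capped for carbon, exempt for CO2/HCO3/water", {
  mets <- data.frame(
    id = c("glc_e", "co2_e", "hco3_e", "h2o_e", "mys_e"),
    formula = c("C6H12O6", "CO2", "HCO3", "H2O", NA),
    compartment = "e", stringsAsFactors = FALSE)
  rx <- data.frame(id = paste0("EX_", c("glc", "co2", "hco3", "h2o", "mys")),
                   lower_bound = -1000, upper_bound = 1000,
                   subsystem = "Exchange", gpr = "", stringsAsFactors = FALSE)
  rx$stoichiometry <- lapply(mets$id, function(m) stats::setNames(-1, m))
  net <- metabolic_network(mets, rx)
  expect_warning(out <- fix_carbon_bounds(net), "no parseable formula")
  lb <- stats::setNames(out$reactions$lower_bound, out$reactions$id)
  expect_equal(lb[["EX_glc"]], -10)      # carbon source capped
  expect_equal(lb[["EX_co2"]], -1000)    # exempt
  expect_equal(lb[["EX_hco3"]], -1000)   # exempt
  expect_equal(lb[["EX_h2o"]], -1000)    # no carbon
  expect_equal(lb[["EX_mys"]], -1000)    # unparseable -> treated as non-carbon
  # idempotence
  out2 <- suppressWarnings(fix_carbon_bounds(out))
  expect_equal(out2$reactions, out$reactions)
})

test_that("sink reactions are added deterministically and idempotently", {
  net <- chain_network()
  out <- add_sink_reactions(net, c("A_c", "B_c"))
  expect_true(all(c("SK_A_c", "SK_B_c") %in% out$reactions$id))
  i <- match("SK_A_c", out$reactions$id)
  expect_equal(out$reactions$stoichiometry[[i]], c(A_c = -1))
  expect_equal(out$reactions$lower_bound[i], 0)
  expect_warning(out2 <- add_sink_reactions(net, c("A_c", "A_c")), "duplicate")
  expect_equal(sum(out2$reactions$id == "SK_A_c"), 1)
  expect_equal(add_sink_reactions(net, character(0)), net)
  expect_error(add_sink_reactions(net, "nope_c"), "nope_c")
})

test_that("flux-consistent subnetwork matches the scipy FVA oracle", {
  net <- branched_network()
  cons <- flux_consistent_subnetwork(net)
  expect_setequal(cons$reactions$id, scipy_consistent_set(net))
  expect_false("RD" %in% cons$reactions$id)   # dead-end removed
  # fixed point: running again changes nothing
  cons2 <- flux_consistent_subnetwork(cons)
  expect_equal(cons2$reactions$id, cons$reactions$id)
  # fully coupled network with exchanges is retained whole
  chain <- chain_network()
  expect_equal(nrow(flux_consistent_subnetwork(chain)$reactions), 3)
})

test_that("formula parsing counts elements and carbons", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6, H = 12, O = 6),
               ignore_attr = TRUE)
  expect_equal(carbon_count("H2O"), 0L)
  expect_equal(carbon_count("HCO3"), 1L)
  expect_equal(carbon_count("C10H16N5O13P3"), 10L)
  expect_error(parse_formula("c6h12"), "cannot parse")
})
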