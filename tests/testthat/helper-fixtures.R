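# Small networks built in code, shared across test files.

# linear chain with a capped bottleneck:
# A is imported (up to `cap`), converted to B, B secreted freely
chain_network <- function(cap = 10) {
  mets <- data.frame(id = c("A_c", "B_c"),
                     formula = c("C3H6O3", "C3H4O3"),
                     compartment = "c", stringsAsFactors = FALSE)
  rx <- data.frame(id = c("EX_A", "R1", "EX_B"),
                   lower_bound = c(-cap, 0, 0),
                   upper_bound = c(0, 1000, 1000),
                   subsystem = c("Exchange", "Core", "Exchange"),
                   gpr = c("", "g1 and (g2 or g3)", ""),
                   stringsAsFactors = FALSE)
  rx$stoichiometry <- list(c(A_c = -1), c(A_c = -1, B_c = 1), c(B_c = -1))
  metabolic_network(mets, rx)
}

# A imported, split into two parallel routes (R1 gene ga; R2 isozymes), each
# secreted; a dead-end branch D with no drain; a free exchange pair on C
branched_network <- function() {
  mets <- data.frame(
    id = c("A_c", "B_c", "C_c", "D_c"),
    formula = c("C6H12O6", "C3H6O3", "C3H6O3", "C3H6O3"),
    compartment = "c", stringsAsFactors = FALSE)
  rx <- data.frame(
    id = c("EX_A", "R1", "R2", "RD", "EX_B", "EX_C"),
    lower_bound = c(-10, 0, 0, 0, 0, -5),
    upper_bound = c(0, 8, 8, 10, 1000, 1000),
    subsystem = c("Exchange", "Route1", "Route2", "Dead", "Exchange", "Exchange"),
    gpr = c("", "ga", "gb1 or gb2", "gd", "", ""),
    stringsAsFactors = FALSE)
  rx$stoichiometry <- list(
    c(A_c = -1), c(A_c = -1, B_c = 1), c(A_c = -1, C_c = 1),
    c(A_c = -1, D_c = 1), c(B_c = -1), c(C_c = -1))
  metabolic_network(mets, rx)
}

# solve an LP with scipy.optimize.linprog through the system python;
# independent oracle for the package's own simplex
scipy_lp <- function(obj, A, b, lb, ub, maximize = TRUE) {
  A <- unname(as.matrix(A))
  req <- list(obj = unname(obj),
              A = lapply(seq_len(nrow(A)), function(i) A[i, ]),
              b = b, lb = unname(lb), ub = unname(ub), maximize = maximize)
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  jsonlite::write_json(req, fin, auto_unbox = FALSE, digits = NA)
  code <- paste(
    "import json, sys, numpy as np",
    "from scipy.optimize import linprog",
    sprintf("q = json.load(open('%s'))", fin),
    "A = np.array(q['A']) if len(q['A']) else np.zeros((0, len(q['obj'])))",
    "c = np.array(q['obj'])",
    "if q['maximize'][0]: c = -c",
    "bounds = list(zip(q['lb'], q['ub']))",
    "res = linprog(c, A_eq=A, b_eq=q['b'], bounds=bounds, method='highs')",
    "obj = None if res.fun is None else (-res.fun if q['maximize'][0] else res.fun)",
    sprintf("json.dump({'status': int(res.status), 'objective': obj}, open('%s','w'))", fout),
    sep = "\n")
  script <- tempfile(fileext = ".py")
  writeLines(code, script)
  rc <- system2("python", script, stdout = FALSE, stderr = FALSE)
  if (rc != 0) stop("python oracle failed")
  jsonlite::read_json(fout)
}

# brute-force FVA oracle via scipy on every reaction of a network
scipy_consistent_set <- function(net, tol = 1e-6) {
  S <- stoich_matrix(net)
  keep <- logical(nrow(net$reactions))
  for (i in seq_len(nrow(net$reactions))) {
    obj <- numeric(ncol(S)); obj[i] <- 1
    hi <- scipy_lp(obj, S, rep(0, nrow(S)), net$reactions$lower_bound,
                   net$reactions$upper_bound, maximize = TRUE)
    lo <- scipy_lp(obj, S, rep(0, nrow(S)), net$reactions$lower_bound,
                   net$reactions$upper_bound, maximize = FALSE)
    keep[i] <- (hi$status == 0 && hi$objective >= tol) ||
               (lo$status == 0 && lo$objective <= -tol)
  }
  net$reactions$id[keep]
}
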