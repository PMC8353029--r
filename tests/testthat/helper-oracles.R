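# Independent references for the LP/FBA engine.
#
# 1. brute_force_lp(): vertex enumeration. Every vertex of
#    {v : S v = 0, lb <= v <= ub} has n - rank(S) coordinates at a bound;
#    enumerate all bound assignments, solve the remaining square system and
#    keep feasible candidates. Exact but exponential: tiny problems only.
# 2. scipy_lp_batch(): scipy.optimize.linprog (HiGGS) through the system
#    python, one process for a whole batch of problems.

brute_force_lp <- function(obj, S, lb, ub, maximize = FALSE, tol = 1e-7) {
  n <- ncol(S)
  qr_rows <- qr(t(S))
  r <- qr_rows$rank
  Sr <- S[sort(qr_rows$pivot[seq_len(r)]), , drop = FALSE]
  n_fix <- n - r
  best <- NULL
  if (n_fix == 0) {
    v <- rep(0, n)
    if (all(v >= lb - tol & v <= ub + tol)) best <- sum(obj * v)
    return(list(value = best, v = v))
  }
  best_v <- NULL
  for (fix_set in utils::combn(n, n_fix, simplify = FALSE)) {
    free_set <- setdiff(seq_len(n), fix_set)
    B <- Sr[, free_set, drop = FALSE]
    qb <- qr(B)
    if (qb$rank < r) next
    for (mask in 0:(2^n_fix - 1)) {
      at_ub <- as.logical(bitwAnd(mask, 2^(seq_len(n_fix) - 1)))
      v <- numeric(n)
      v[fix_set] <- ifelse(at_ub, ub[fix_set], lb[fix_set])
      rhs <- -Sr[, fix_set, drop = FALSE] %*% v[fix_set]
      v[free_set] <- qr.solve(qb, rhs)
      if (max(abs(S %*% v)) > tol) next
      if (any(v < lb - tol | v > ub + tol)) next
      val <- sum(obj * v)
      if (is.null(best) || (maximize && val > best) || (!maximize && val < best)) {
        best <- val; best_v <- v
      }
    }
  }
  list(value = best, v = best_v)
}

# enumerate the total |v| of every optimal vertex (objective within rel_tol
# of the optimum); used to certify pFBA minimality
brute_force_optimal_vertices <- function(obj, S, lb, ub, maximize = FALSE,
                                         tol = 1e-7, rel_tol = 1e-9) {
  opt <- brute_force_lp(obj, S, lb, ub, maximize, tol)
  if (is.null(opt$value)) return(list(value = NULL, total_flux = numeric(0)))
  n <- ncol(S)
  r <- qr(t(S))$rank
  Sr <- S[sort(qr(t(S))$pivot[seq_len(r)]), , drop = FALSE]
  n_fix <- n - r
  totals <- numeric(0)
  for (fix_set in utils::combn(n, n_fix, simplify = FALSE)) {
    free_set <- setdiff(seq_len(n), fix_set)
    qb <- qr(Sr[, free_set, drop = FALSE])
    if (qb$rank < r) next
    for (mask in 0:(2^n_fix - 1)) {
      at_ub <- as.logical(bitwAnd(mask, 2^(seq_len(n_fix) - 1)))
      v <- numeric(n)
      v[fix_set] <- ifelse(at_ub, ub[fix_set], lb[fix_set])
      rhs <- -Sr[, fix_set, drop = FALSE] %*% v[fix_set]
      v[free_set] <- qr.solve(qb, rhs)
      if (max(abs(S %*% v)) > tol) next
      if (any(v < lb - tol | v > ub + tol)) next
      val <- sum(obj * v)
      if (abs(val - opt$value) <= rel_tol * max(1, abs(opt$value)))
        totals <- c(totals, sum(abs(v)))
    }
  }
  list(value = opt$value, total_flux = totals)
}

scipy_available <- function() {
  nzchar(Sys.which("python")) &&
    system2("python", c("-c", shQuote("import scipy.optimize")),
            stdout = FALSE, stderr = FALSE) == 0
}

# problems: list of list(obj, S, lb, ub, maximize); returns numeric vector of
# optimal objective values (NA where infeasible)
scipy_lp_batch <- function(problems) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  payload <- lapply(problems, function(p) list(
    c = as.numeric(p$obj), A = unname(apply(p$S, 1, as.numeric, simplify = FALSE)),
    lb = as.numeric(p$lb), ub = as.numeric(p$ub),
    maximize = isTRUE(p$maximize)))
  jsonlite::write_json(payload, infile, digits = NA, auto_unbox = TRUE)
  script <- paste(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "probs = json.load(open(sys.argv[1]))",
    "out = []",
    "for p in probs:",
    "    c = np.array(p['c'], float)",
    "    A = np.array(p['A'], float)",
    "    sign = -1.0 if p['maximize'] else 1.0",
    "    res = linprog(sign * c, A_eq=A, b_eq=np.zeros(A.shape[0]),",
    "                  bounds=list(zip(p['lb'], p['ub'])), method='highs')",
    "    out.append(sign * res.fun if res.status == 0 else None)",
    "json.dump(out, open(sys.argv[2], 'w'))",
    sep = "\n")
  status <- system2("python", c("-c", shQuote(script), shQuote(infile),
                                shQuote(outfile)))
  if (status != 0) stop("python/scipy oracle failed")
  vals <- jsonlite::read_json(outfile)
  vapply(vals, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)
}

# small random metabolic-style network: a chain of metabolites with random
# extra internal links and exchange reactions; always feasible (all bounds
# straddle or touch zero)
random_network <- function(n_mets = 4, n_internal = 5, seed = 1) {
  withr::with_seed(seed, {
    mets <- paste0("M", seq_len(n_mets))
    rxns <- list()
    # exchanges for first and last metabolite (+ a random extra one)
    ex_mets <- unique(c(1, n_mets, sample(n_mets, 1)))
    for (i in ex_mets)
      rxns[[length(rxns) + 1]] <- reaction(
        paste0("EX_", mets[i]), stoichiometry = stats::setNames(-1, mets[i]),
        lower_bound = -round(stats::runif(1, 0.5, 3), 2), upper_bound = 1000,
        gene_associated = FALSE)
    for (k in seq_len(n_internal)) {
      pair <- sample(n_mets, 2)
      coef <- sample(1:2, 2, replace = TRUE)
      st <- stats::setNames(c(-coef[1], coef[2]), mets[pair])
      rev <- stats::runif(1) < 0.4
      rxns[[length(rxns) + 1]] <- reaction(
        paste0("R", k), stoichiometry = st,
        lower_bound = if (rev) -1000 else 0, upper_bound = 1000)
    }
    obj_rxn <- paste0("EX_", mets[n_mets])
    stoichiometric_model(lapply(mets, metabolite), rxns,
                         objective = stats::setNames(1, obj_rxn))
  })
}

toy_chain_model <- function() {
  stoichiometric_model(
    list(metabolite("A", compartment = "extracellular"),
         metabolite("B", compartment = "extracellular")),
    list(reaction("EX_A", stoichiometry = c(A = -1), lower_bound = -1,
                  upper_bound = 1000, gene_associated = FALSE),
         reaction("v1", stoichiometry = c(A = -1, B = 1)),
         reaction("EX_B", stoichiometry = c(B = -1), lower_bound = 0,
                  upper_bound = 1000, gene_associated = FALSE)),
    objective = c(EX_B = 1))
}

# two equivalent parallel routes A -> B; pFBA must route through one only
toy_diamond_model <- function() {
  stoichiometric_model(
    list(metabolite("A"), metabolite("B")),
    list(reaction("EX_A", stoichiometry = c(A = -1), lower_bound = -1,
                  upper_bound = 1000, gene_associated = FALSE),
         reaction("p1", stoichiometry = c(A = -1, B = 1)),
         reaction("p2", stoichiometry = c(A = -1, B = 1)),
         reaction("EX_B", stoichiometry = c(B = -1), lower_bound = 0,
                  upper_bound = 1000, gene_associated = FALSE)),
    objective = c(EX_B = 1))
}

phase1_constraints <- function(phb = 1.63, maintenance = 7.5) {
  constraint_set(fixed_fluxes = c(BIOMASS = 0, DM_phb = phb),
                 bound_overrides = list(ATPM = c(maintenance, 1000)))
}
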