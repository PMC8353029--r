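test_that("a single-path toy network carries its uptake bound", {
  m <- toy_chain_model()
  sol <- solve_fba(m, c(EX_B = 1), "max")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 1.0, tolerance = 1e-9)
  expect_equal(production_rate(sol, m, "B"), 1.0, tolerance = 1e-9)
})

test_that("accumulation-phase pins force succinate uptake 3.26 on the core model", {
  m <- build_core_model()
  sol <- solve_fba(m, c(EX_succ = 1), "max", phase1_constraints())
  expect_equal(sol$status, "optimal")
  expect_equal(-sol$fluxes[["EX_succ"]], 3.26, tolerance = 1e-6)
})

test_that("an unsatisfiable maintenance demand is reported infeasible", {
  m <- build_core_model()
  cons <- constraint_set(
    fixed_fluxes = c(BIOMASS = 0, DM_phb = 1.63),
    bound_overrides = list(ATPM = c(7.5, 1000), EX_succ = c(0, 0)))
  sol <- solve_fba(m, c(EX_succ = 1), "max", cons)
  expect_equal(sol$status, "infeasible")
})

test_that("unknown reaction ids in objective or constraints are lookup errors", {
  m <- toy_chain_model()
  expect_error(solve_fba(m, c(NOPE = 1), "max"), "unknown reaction")
  expect_error(solve_fba(m, c(EX_B = 1), "max",
                         constraint_set(fixed_fluxes = c(NOPE = 1))),
               "unknown reaction")
  expect_error(production_rate(solve_fba(m, c(EX_B = 1), "max"), m, "NOPE"),
               "unknown metabolite")
})

test_that("pFBA routes parallel paths through a single branch", {
  m <- toy_diamond_model()
  sol <- pfba(m, c(EX_B = 1), "max")
  expect_equal(sol$objective_value, 1.0, tolerance = 1e-9)
  branch <- abs(c(sol$fluxes[["p1"]], sol$fluxes[["p2"]]))
  expect_equal(sort(branch), c(0, 1), tolerance = 1e-9)
  # total |v| is minimal: uptake 1 + one branch 1 + export 1
  expect_equal(sol$total_flux, 3, tolerance = 1e-8)
})

test_that("pFBA never worsens the primary objective", {
  m <- build_core_model()
  for (cons in list(phase1_constraints(),
                    constraint_set(fixed_fluxes = c(BIOMASS = 0.232, DM_phb = 0.169)))) {
    a <- solve_fba(m, c(EX_succ = 1), "max", cons)
    b <- pfba(m, c(EX_succ = 1), "max", cons)
    expect_equal(b$objective_value, a$objective_value, tolerance = 1e-9)
  }
})

test_that("pFBA total flux is minimal over enumerated optimal vertices", {
  m <- toy_diamond_model()
  S <- stoich_matrix(m)
  b <- model_bounds(m)
  obj <- c(EX_A = 0, p1 = 0, p2 = 0, EX_B = 1)
  enum <- brute_force_optimal_vertices(obj, S, b[, "lower"], b[, "upper"],
                                       maximize = TRUE)
  sol <- pfba(m, c(EX_B = 1), "max")
  expect_true(length(enum$total_flux) >= 1)
  expect_lte(sol$total_flux, min(enum$total_flux) + 1e-7)
})

test_that("active reactions honour gene association and tolerance", {
  m <- build_core_model()
  sol <- pfba(m, c(EX_succ = 1), "max", phase1_constraints())
  act <- active_reactions(sol, m)
  # citrate synthase idle in the accumulation phase
  expect_false("CS" %in% act)
  # exchanges and pseudo-reactions never counted
  expect_length(intersect(act, c("EX_succ", "DM_phb", "ATPM", "BIOMASS")), 0)
  # tolerance larger than every flux empties the set
  expect_length(active_reactions(sol, m, tol = 1e6), 0)
  # all-zero solution has no active reactions
  zero <- solve_fba(build_core_model(core_model_params(maintenance_atp = 0)),
                    c(EX_succ = 1), "max",
                    constraint_set(fixed_fluxes = c(BIOMASS = 0, DM_phb = 0)))
  expect_length(active_reactions(zero, build_core_model()), 0)
})

test_that("production equals consumption for internal metabolites at steady state", {
  m <- build_core_model()
  sol <- pfba(m, c(EX_succ = 1), "max",
              constraint_set(fixed_fluxes = c(BIOMASS = 0.232, DM_phb = 0.169)))
  for (met in c("accoa_c", "nadh_c", "atp_c", "mal_c", "oaa_c")) {
    prod <- production_rate(sol, m, met)
    cons <- -sum(vapply(m$reactions, function(r) {
      coef <- r$stoichiometry[met]
      if (is.na(coef)) 0 else min(coef * sol$fluxes[[r$id]], 0)
    }, 0))
    expect_equal(prod, cons, tolerance = 1e-8, info = met)
  }
})

test_that("solver agrees with vertex enumeration on random small networks", {
  for (seed in 1:20) {
    m <- random_network(n_mets = 4, n_internal = 5, seed = seed)
    S <- stoich_matrix(m)
    b <- model_bounds(m)
    # cap the big bounds so enumeration stays exact and vertices finite
    ub <- pmin(b[, "upper"], 10)
    lb <- pmax(b[, "lower"], -10)
    obj <- stats::setNames(numeric(ncol(S)), colnames(S))
    obj[names(m$objective)] <- m$objective
    ref <- brute_force_lp(obj, S, lb, ub, maximize = TRUE)
    cons <- constraint_set(bound_overrides = stats::setNames(
      lapply(colnames(S), function(id) c(lb[[id]], ub[[id]])), colnames(S)))
    sol <- solve_fba(m, m$objective, "max", cons)
    if (is.null(ref$value)) {
      expect_equal(sol$status, "infeasible", info = seed)
    } else {
      expect_equal(sol$status, "optimal", info = seed)
      expect_equal(sol$objective_value, ref$value, tolerance = 1e-6, info = seed)
    }
  }
})

test_that("solver agrees with an external LP reference", {
  expect_true(scipy_available())
  probs <- list()
  sols <- numeric(0)
  m <- build_core_model()
  S <- stoich_matrix(m)
  bounds <- phbflux:::apply_constraints(m, phase1_constraints())
  obj <- stats::setNames(numeric(ncol(S)), colnames(S)); obj["EX_succ"] <- 1
  probs[[1]] <- list(obj = obj, S = S, lb = bounds[, "lower"],
                     ub = bounds[, "upper"], maximize = TRUE)
  sols[1] <- solve_fba(m, c(EX_succ = 1), "max", phase1_constraints())$objective_value
  for (seed in 1:20) {
    rm_ <- random_network(n_mets = 4, n_internal = 5, seed = seed)
    Sr <- stoich_matrix(rm_)
    br <- model_bounds(rm_)
    objr <- stats::setNames(numeric(ncol(Sr)), colnames(Sr))
    objr[names(rm_$objective)] <- rm_$objective
    probs[[seed + 1]] <- list(obj = objr, S = Sr, lb = br[, "lower"],
                              ub = br[, "upper"], maximize = TRUE)
    sols[seed + 1] <- solve_fba(rm_, rm_$objective, "max")$objective_value
  }
  ref <- scipy_lp_batch(probs)
  expect_equal(sols, ref, tolerance = 1e-6)
})

test_that("minimal uptake is monotone in each pinned demand", {
  m <- build_core_model()
  uptake_at <- function(growth, phb, maint) {
    sol <- solve_fba(m, c(EX_succ = 1), "max", constraint_set(
      fixed_fluxes = c(BIOMASS = growth, DM_phb = phb),
      bound_overrides = list(ATPM = c(maint, 1000))))
    -sol$fluxes[["EX_succ"]]
  }
  u_phb <- vapply(c(0, 0.5, 1, 1.63, 2.5), function(p) uptake_at(0, p, 7.5), 0)
  expect_true(all(diff(u_phb) >= -1e-9))
  u_mu <- vapply(c(0, 0.1, 0.2, 0.3), function(g) uptake_at(g, 0.169, 7.5), 0)
  expect_true(all(diff(u_mu) >= -1e-9))
  u_maint <- vapply(c(0, 5, 10, 20, 40), function(a) uptake_at(0, 1.63, a), 0)
  expect_true(all(diff(u_maint) >= -1e-9))
})

test_that("doubling all pinned demands doubles minimal uptake", {
  m <- build_core_model(core_model_params(maintenance_atp = 0))
  uptake_at <- function(growth, phb, maint) {
    sol <- solve_fba(m, c(EX_succ = 1), "max", constraint_set(
      fixed_fluxes = c(BIOMASS = growth, DM_phb = phb),
      bound_overrides = list(ATPM = c(maint, 1000))))
    -sol$fluxes[["EX_succ"]]
  }
  u1 <- uptake_at(0.1, 0.2, 4)
  u2 <- uptake_at(0.2, 0.4, 8)
  expect_equal(u2, 2 * u1, tolerance = 1e-8)
})

test_that("flux solutions export as TSV and JSON", {
  m <- build_core_model()
  sol <- pfba(m, c(EX_succ = 1), "max", phase1_constraints())
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_flux_solution(sol, m, tsv = tsv, json = js)
  tab <- read.delim(tsv)
  expect_identical(tab$reaction, names(sol$fluxes))
  rep <- jsonlite::read_json(js)
  expect_identical(rep$status, "optimal")
  expect_identical(rep$n_active_enzymes, 10L)
})
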