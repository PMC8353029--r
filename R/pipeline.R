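#' Default reaction-id mapping for phase analyses
#'
#' Names the model reactions that play the four special roles of the
#' two-phase analysis. Defaults fit the built-in core model; supply a
#' different mapping for an imported genome-scale model.
#'
#' @param growth Biomass (growth) reaction id.
#' @param phb PHB drain reaction id (sink or synthase — equal at steady state).
#' @param uptake Substrate exchange reaction id (negative flux = uptake).
#' @param maintenance ATP maintenance reaction id.
#' @param tca_marker Reaction whose flux flags TCA-cycle activity.
#' @return Named list of reaction ids.
#' @export
phase_config <- function(growth = "BIOMASS", phb = "DM_phb",
                         uptake = "EX_succ", maintenance = "ATPM",
                         tca_marker = "CS") {
  list(growth = growth, phb = phb, uptake = uptake,
       maintenance = maintenance, tca_marker = tca_marker)
}

#' Specify a physiological phase for FBA
#'
#' @param name `"accumulation"` (growth-arrested PHB burst; growth rate must
#'   be 0) or `"exponential"`.
#' @param growth_rate Specific growth rate to pin, h^-1.
#' @param phb_molar_rate Specific PHB production rate to pin,
#'   mmol gDW^-1 h^-1.
#' @param maintenance_atp Lower bound on the ATP maintenance flux,
#'   mmol gDW^-1 h^-1.
#' @return An object of class `"phb_phase_spec"`. The objective is always
#'   minimisation of substrate uptake.
#' @export
phase_spec <- function(name = c("accumulation", "exponential"),
                       growth_rate, phb_molar_rate,
                       maintenance_atp = MAINTENANCE_ATP_DEFAULT) {
  name <- match.arg(name)
  if (name == "accumulation" && growth_rate != 0)
    stop("the accumulation phase is growth-arrested: growth_rate must be 0")
  if (growth_rate < 0 || phb_molar_rate < 0 || maintenance_atp < 0)
    stop("rates must be non-negative")
  structure(list(name = name, growth_rate = growth_rate,
                 phb_molar_rate = phb_molar_rate,
                 maintenance_atp = maintenance_atp),
            class = "phb_phase_spec")
}

#' Run one phase: pin measured rates, minimise substrate uptake
#'
#' Pins the growth and PHB fluxes to the measured values, imposes the
#' maintenance ATP lower bound, minimises succinate uptake, and resolves the
#' degenerate optimum by parsimonious FBA. If the constraint set is
#' infeasible, each pin is relaxed in turn to diagnose which one binds.
#'
#' @param model A `"phb_model"`.
#' @param spec A [phase_spec()].
#' @param config A [phase_config()] naming the special reactions.
#' @param tol Active-flux tolerance, mmol gDW^-1 h^-1.
#' @return An object of class `"phb_phase_report"`: `spec`, `status`,
#'   `predicted_uptake` (magnitude), `acetyl_coa_rate`, `n_active_enzymes`
#'   (solution-dependent; see [active_reactions()]), `tca_active`, `fluxes`,
#'   `active_enzymes`, and `diagnostics` when infeasible.
#' @export
run_phase <- function(model, spec, config = phase_config(), tol = 1e-6) {
  if (!inherits(spec, "phb_phase_spec")) stop("spec must be a phase_spec()")
  need <- unlist(config[c("growth", "phb", "uptake", "maintenance")])
  missing <- setdiff(need, names(model$reactions))
  if (length(missing))
    stop("model lacks configured reaction(s): ", paste(missing, collapse = ", "))

  pins <- stats::setNames(c(spec$growth_rate, spec$phb_molar_rate),
                          c(config$growth, config$phb))
  maint_ub <- max(model$reactions[[config$maintenance]]$upper_bound,
                  spec$maintenance_atp)
  cons <- constraint_set(
    fixed_fluxes = pins,
    bound_overrides = stats::setNames(list(c(spec$maintenance_atp, maint_ub)),
                                      config$maintenance))
  objective <- stats::setNames(1, config$uptake)
  sol <- pfba(model, objective, "max", cons) # uptake is negative: max = min magnitude

  if (sol$status != "optimal") {
    diag <- phase_diagnostics(model, spec, config, cons, objective)
    return(structure(list(spec = spec, status = sol$status,
                          predicted_uptake = NA_real_,
                          acetyl_coa_rate = NA_real_,
                          n_active_enzymes = NA_integer_,
                          tca_active = NA, fluxes = NULL,
                          diagnostics = diag),
                     class = "phb_phase_report"))
  }

  accoa <- intersect(c("accoa_c", "accoa"), names(model$metabolites))
  act <- active_reactions(sol, model, tol)
  structure(list(
    spec = spec, status = sol$status,
    predicted_uptake = max(0, -sol$fluxes[[config$uptake]]),
    acetyl_coa_rate = if (length(accoa))
      production_rate(sol, model, accoa[1]) else NA_real_,
    n_active_enzymes = length(act),
    tca_active = if (config$tca_marker %in% names(model$reactions))
      abs(sol$fluxes[[config$tca_marker]]) > tol else NA,
    fluxes = sol$fluxes,
    active_enzymes = act,
    diagnostics = NULL),
    class = "phb_phase_report")
}

# relax one pin at a time; report which relaxation restores feasibility
phase_diagnostics <- function(model, spec, config, cons, objective) {
  relaxations <- list(
    growth = constraint_set(cons$fixed_fluxes[names(cons$fixed_fluxes) != config$growth],
                            cons$bound_overrides),
    phb = constraint_set(cons$fixed_fluxes[names(cons$fixed_fluxes) != config$phb],
                         cons$bound_overrides),
    maintenance = constraint_set(
      cons$fixed_fluxes,
      stats::setNames(list(c(0, model$reactions[[config$maintenance]]$upper_bound)),
                      config$maintenance))
  )
  feasible_when_relaxed <- vapply(relaxations, function(cs)
    solve_fba(model, objective, "max", cs)$status == "optimal", TRUE)
  list(binding_pins = names(relaxations)[feasible_when_relaxed])
}

#' @export
print.phb_phase_report <- function(x, ...) {
  cat(sprintf("Phase '%s' (mu = %g, q_PHB = %g, maintenance >= %g): %s\n",
              x$spec$name, x$spec$growth_rate, x$spec$phb_molar_rate,
              x$spec$maintenance_atp, x$status))
  if (x$status == "optimal") {
    cat(sprintf("  predicted uptake   : %.3f mmol g-DW^-1 h^-1\n", x$predicted_uptake))
    cat(sprintf("  acetyl-CoA synthesis: %.3f mmol g-DW^-1 h^-1\n", x$acetyl_coa_rate))
    cat(sprintf("  active enzymes     : %d (pFBA solution; solution-dependent)\n",
                x$n_active_enzymes))
    cat(sprintf("  TCA cycle active   : %s\n", x$tca_active))
  } else if (!is.null(x$diagnostics)) {
    cat("  feasibility restored by relaxing:",
        paste(x$diagnostics$binding_pins, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare two phase reports
#'
#' @param r1,r2 Optimal `"phb_phase_report"` objects (conventionally the
#'   accumulation and exponential phase).
#' @return List with per-phase uptake and acetyl-CoA rates, active-enzyme
#'   counts and set differences, and the PHB-rate ratio r1/r2.
#' @export
compare_phases <- function(r1, r2) {
  if (r1$status != "optimal" || r2$status != "optimal")
    stop("both phase reports must be optimal")
  list(
    phases = c(r1$spec$name, r2$spec$name),
    predicted_uptake = c(r1$predicted_uptake, r2$predicted_uptake),
    acetyl_coa_rate = c(r1$acetyl_coa_rate, r2$acetyl_coa_rate),
    n_active_enzymes = c(r1$n_active_enzymes, r2$n_active_enzymes),
    enzymes_only_in_1 = setdiff(r1$active_enzymes, r2$active_enzymes),
    enzymes_only_in_2 = setdiff(r2$active_enzymes, r1$active_enzymes),
    phb_rate_ratio = if (r2$spec$phb_molar_rate > 0)
      r1$spec$phb_molar_rate / r2$spec$phb_molar_rate else NA_real_)
}

#' Full two-phase analysis from a batch time series
#'
#' Chains the whole pipeline: rate estimation from the time series
#' (growth-rate regression on the exponential window, yield regression,
#' accumulation rate from the first sampling interval), construction of the
#' two phase specifications, FBA of each phase, and a phase comparison.
#'
#' @param series A `"phb_timeseries"` (or path to one; see
#'   [read_batch_timeseries()]).
#' @param model A `"phb_model"`; default is the built-in core model.
#' @param window Exponential-window override passed to [estimate_rates()].
#' @param phb_content PHB content (mg/g) for the exponential-phase
#'   production rate; `NULL` = mean measured content over the window.
#' @param maintenance_atp Maintenance ATP lower bound for both phases.
#' @param config A [phase_config()].
#' @return An object of class `"phb_analysis"` with elements `kinetics`
#'   (the [estimate_rates()] result plus `accumulation_rate`), `phase1`,
#'   `phase2`, and `comparison`.
#' @export
run_full_analysis <- function(series, model = build_core_model(),
                              window = "auto", phb_content = NULL,
                              maintenance_atp = MAINTENANCE_ATP_DEFAULT,
                              config = phase_config()) {
  if (is.character(series)) series <- read_batch_timeseries(series)
  if (!inherits(series, "phb_timeseries")) series <- batch_timeseries(series)

  rates <- tryCatch(estimate_rates(series, window, phb_content),
                    error = function(e) stop("kinetics stage: ",
                                             conditionMessage(e), call. = FALSE))
  acc <- accumulation_rate(series$phb_content[1], series$phb_content[2],
                           series$time[2] - series$time[1])

  spec1 <- phase_spec("accumulation", 0, acc, maintenance_atp)
  spec2 <- phase_spec("exponential", rates$mu, rates$q_phb_molar, maintenance_atp)
  p1 <- tryCatch(run_phase(model, spec1, config),
                 error = function(e) stop("phase I stage: ",
                                          conditionMessage(e), call. = FALSE))
  p2 <- tryCatch(run_phase(model, spec2, config),
                 error = function(e) stop("phase II stage: ",
                                          conditionMessage(e), call. = FALSE))
  cmp <- if (p1$status == "optimal" && p2$status == "optimal")
    compare_phases(p1, p2) else NULL

  structure(list(kinetics = c(unclass(rates), list(accumulation_rate = acc)),
                 phase1 = p1, phase2 = p2, comparison = cmp),
            class = "phb_analysis")
}

#' @export
print.phb_analysis <- function(x, ...) {
  k <- x$kinetics
  cat("== Kinetics ==\n")
  cat(sprintf("mu = %.4f +/- %.4f h^-1 | Y_XS = %.1f +/- %.1f g-DW/mol | q_s = %.2f mmol/gDW/h\n",
              k$mu, k$mu_se, k$yield_xs, k$yield_se, k$q_s))
  cat(sprintf("q_PHB = %.1f mg/gDW/h (%.3f mmol/gDW/h) | accumulation rate = %.3f mmol/gDW/h\n",
              k$q_phb_mass, k$q_phb_molar, k$accumulation_rate))
  cat("== Phase I (accumulation) ==\n"); print(x$phase1)
  cat("== Phase II (exponential) ==\n"); print(x$phase2)
  if (!is.null(x$comparison))
    cat(sprintf("PHB-rate ratio (I/II) = %.2f; enzymes %d vs %d\n",
                x$comparison$phb_rate_ratio, x$comparison$n_active_enzymes[1],
                x$comparison$n_active_enzymes[2]))
  invisible(x)
}

#' Write an analysis report to JSON
#'
#' @param analysis A `"phb_analysis"`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_analysis_json <- function(analysis, path) {
  strip <- function(p) list(
    phase = p$spec$name, status = p$status,
    growth_rate = p$spec$growth_rate, phb_molar_rate = p$spec$phb_molar_rate,
    maintenance_atp = p$spec$maintenance_atp,
    predicted_uptake = p$predicted_uptake,
    acetyl_coa_rate = p$acetyl_coa_rate,
    n_active_enzymes = p$n_active_enzymes,
    n_active_enzymes_note = "pFBA solution; FBA optima are degenerate, counts are solution-dependent",
    tca_active = p$tca_active,
    fluxes = as.list(p$fluxes))
  out <- list(kinetics = analysis$kinetics,
              phase1 = strip(analysis$phase1),
              phase2 = strip(analysis$phase2),
              comparison = analysis$comparison)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
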