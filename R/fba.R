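#' Constraint set for an FBA problem
#'
#' @param fixed_fluxes Named numeric vector: reaction id to pinned flux value
#'   (implemented as lower = upper bound overrides).
#' @param bound_overrides Named list: reaction id to `c(lower, upper)`.
#' @return An object of class `"phb_constraints"`.
#' @export
constraint_set <- function(fixed_fluxes = numeric(0), bound_overrides = list()) {
  if (length(bound_overrides)) {
    ok <- vapply(bound_overrides, function(b) length(b) == 2L && b[1] <= b[2], TRUE)
    if (!all(ok)) stop("each bound override must be c(lower, upper) with lower <= upper")
  }
  structure(list(fixed_fluxes = fixed_fluxes, bound_overrides = bound_overrides),
            class = "phb_constraints")
}

apply_constraints <- function(model, constraints) {
  bounds <- model_bounds(model)
  if (is.null(constraints)) return(bounds)
  unknown <- setdiff(c(names(constraints$fixed_fluxes),
                       names(constraints$bound_overrides)),
                     rownames(bounds))
  if (length(unknown))
    stop("constraints reference unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  for (id in names(constraints$bound_overrides)) {
    bounds[id, ] <- constraints$bound_overrides[[id]]
  }
  for (id in names(constraints$fixed_fluxes)) {
    v <- constraints$fixed_fluxes[[id]]
    bounds[id, ] <- c(v, v)
  }
  bounds
}

#' Solve a flux balance analysis problem
#'
#' Optimises a linear objective over the steady-state flux cone
#' \{v : S v = 0, lb <= v <= ub\} of the model, with optional equality pins
#' and bound overrides.
#'
#' @param model A `"phb_model"`.
#' @param objective Named numeric vector of objective coefficients per
#'   reaction id; defaults to the model's stored objective.
#' @param direction `"max"` or `"min"`.
#' @param constraints A [constraint_set()] or `NULL`.
#' @return An object of class `"phb_flux_solution"` with fields `status`
#'   (`"optimal"`, `"infeasible"` or `"unbounded"`), `objective_value` and
#'   `fluxes` (named vector over all reactions).
#' @export
solve_fba <- function(model, objective = model$objective,
                      direction = c("max", "min"), constraints = NULL) {
  direction <- match.arg(direction)
  if (!length(objective)) stop("no objective given and model stores none")
  unknown <- setdiff(names(objective), names(model$reactions))
  if (length(unknown))
    stop("objective references unknown reaction(s): ", paste(unknown, collapse = ", "))
  S <- stoich_matrix(model)
  bounds <- apply_constraints(model, constraints)
  obj <- stats::setNames(numeric(ncol(S)), colnames(S))
  obj[names(objective)] <- objective
  res <- solve_lp(obj, S, rep(0, nrow(S)), bounds[, "lower"], bounds[, "upper"],
                  maximize = direction == "max")
  fluxes <- if (is.null(res$x)) NULL else stats::setNames(res$x, colnames(S))
  structure(list(status = res$status,
                 objective_value = res$value,
                 fluxes = fluxes),
            class = "phb_flux_solution")
}

#' @export
print.phb_flux_solution <- function(x, ...) {
  cat("FBA solution:", x$status)
  if (x$status == "optimal") cat(", objective", format(x$objective_value))
  cat("\n")
  invisible(x)
}

#' Parsimonious FBA
#'
#' Resolves the degeneracy of the FBA optimum: among flux vectors attaining
#' the optimal objective value (held fixed as an equality), returns one
#' minimising the total absolute flux, with each flux split into non-negative
#' forward and reverse parts. FBA optima are typically degenerate, so
#' flux-level summaries (active reaction sets in particular) should be read
#' from a pFBA solution, and even then remain solution-dependent.
#'
#' @inheritParams solve_fba
#' @return A `"phb_flux_solution"`; `objective_value` is the primary (FBA)
#'   objective value, which pFBA never worsens.
#' @export
pfba <- function(model, objective = model$objective,
                 direction = c("max", "min"), constraints = NULL) {
  direction <- match.arg(direction)
  base <- solve_fba(model, objective, direction, constraints)
  if (base$status != "optimal") return(base)
  S <- stoich_matrix(model)
  bounds <- apply_constraints(model, constraints)
  n <- ncol(S)
  obj_full <- stats::setNames(numeric(n), colnames(S))
  obj_full[names(objective)] <- objective

  # v = p - q, p, q >= 0; minimise sum(p + q) s.t. S(p-q)=0, lb<=p-q<=ub,
  # c'(p-q) = z*.  The primary optimum is held as an equality row.
  A_eq <- rbind(cbind(S, -S), c(obj_full, -obj_full))
  b_eq <- c(rep(0, nrow(S)), base$objective_value)
  lb <- pmax(bounds[, "lower"], -LP_BIG)
  ub <- pmin(bounds[, "upper"], LP_BIG)
  # split bounds so that p - q always lies in [lb, ub]: a strictly forward
  # reaction keeps its positive lower bound on p, a strictly reverse one on q
  res <- solve_lp(rep(1, 2 * n), A_eq, b_eq,
                  lb = c(pmax(lb, 0), pmax(-ub, 0)),
                  ub = c(pmax(ub, 0), pmax(-lb, 0)),
                  maximize = FALSE)
  if (res$status != "optimal") {
    warning("pFBA stage infeasible at solver tolerance; returning the FBA vertex")
    return(base)
  }
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  structure(list(status = "optimal",
                 objective_value = base$objective_value,
                 fluxes = stats::setNames(v, colnames(S)),
                 total_flux = sum(abs(v))),
            class = "phb_flux_solution")
}

#' Active gene-associated reactions of a flux solution
#'
#' The set of enzyme-catalysed (gene-associated) reactions carrying flux
#' above a tolerance. Because FBA optima are degenerate, this set depends on
#' which optimal vertex the solver returned; use it on a [pfba()] solution
#' and treat counts as solution-dependent.
#'
#' @param solution An optimal `"phb_flux_solution"`.
#' @param model The model it was solved on.
#' @param tol Absolute flux threshold, mmol gDW^-1 h^-1. Default `1e-6`
#'   (LP solver noise floor).
#' @return Character vector of reaction ids.
#' @export
active_reactions <- function(solution, model, tol = 1e-6) {
  if (solution$status != "optimal") stop("solution is not optimal")
  gene <- vapply(model$reactions, `[[`, TRUE, "gene_associated")
  ids <- names(model$reactions)[gene]
  ids[abs(solution$fluxes[ids]) > tol]
}

#' Production rate of a metabolite in a flux solution
#'
#' Sums coefficient-times-flux over all reaction sides that produce the
#' metabolite (a negative coefficient traversed in reverse produces too).
#' At steady state production equals consumption.
#'
#' @param solution An optimal `"phb_flux_solution"`.
#' @param model The model it was solved on.
#' @param metabolite_id Metabolite id, e.g. `"accoa_c"`.
#' @return Production rate, mmol gDW^-1 h^-1.
#' @export
production_rate <- function(solution, model, metabolite_id) {
  if (!metabolite_id %in% names(model$metabolites))
    stop("unknown metabolite: ", metabolite_id)
  if (solution$status != "optimal") stop("solution is not optimal")
  total <- 0
  for (r in model$reactions) {
    coef <- r$stoichiometry[metabolite_id]
    if (is.na(coef)) next
    total <- total + max(coef * solution$fluxes[[r$id]], 0)
  }
  unname(total)
}

#' Export a flux solution
#'
#' Writes a two-column tab-separated table (reaction id, flux) and/or a JSON
#' report with status, objective value and the active gene-associated
#' reaction count.
#'
#' @param solution A `"phb_flux_solution"`.
#' @param model The model it was solved on.
#' @param tsv,json Output paths (either may be `NULL`).
#' @param tol Active-flux tolerance passed to [active_reactions()].
#' @return Invisibly, the paths written.
#' @export
write_flux_solution <- function(solution, model, tsv = NULL, json = NULL,
                                tol = 1e-6) {
  written <- character(0)
  if (!is.null(tsv)) {
    utils::write.table(
      data.frame(reaction = names(solution$fluxes), flux = unname(solution$fluxes)),
      tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, tsv)
  }
  if (!is.null(json)) {
    rep <- list(status = solution$status,
                objective_value = solution$objective_value,
                n_active_enzymes = if (solution$status == "optimal")
                  length(active_reactions(solution, model, tol)) else NA,
                fluxes = as.list(solution$fluxes))
    jsonlite::write_json(rep, json, auto_unbox = TRUE, digits = NA)
    written <- c(written, json)
  }
  invisible(written)
}
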