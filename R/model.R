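#' Create a metabolite
#'
#' Metabolites are the nodes of the stoichiometric network. Formulas are
#' elemental compositions over C, H, O, N, P and S (neutral-molecule
#' convention) and are only needed for mass-balance checking.
#'
#' @param id Short unique identifier, e.g. `"succ_c"`.
#' @param name Human-readable name.
#' @param compartment `"cytosol"` or `"extracellular"`.
#' @param formula Named integer vector of element counts (subset of
#'   C, H, O, N, P, S), or `NULL` if unknown.
#' @param charge Integer formal charge, or `NULL`.
#' @return An object of class `"phb_metabolite"`.
#' @export
metabolite <- function(id, name = id, compartment = c("cytosol", "extracellular"),
                       formula = NULL, charge = NULL) {
  compartment <- match.arg(compartment)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.null(formula)) {
    formula <- formula[formula != 0]
    storage.mode(formula) <- "double"
    bad <- setdiff(names(formula), c("C", "H", "O", "N", "P", "S"))
    if (length(bad)) stop("unsupported elements in formula for '", id, "': ",
                          paste(bad, collapse = ", "))
    if (any(formula < 0)) stop("negative element count in formula for '", id, "'")
  }
  structure(list(id = id, name = name, compartment = compartment,
                 formula = formula, charge = charge),
            class = "phb_metabolite")
}

#' Create a reaction
#'
#' @param id Short unique identifier, e.g. `"PDH"`.
#' @param name Human-readable name.
#' @param stoichiometry Named numeric vector, metabolite id to signed
#'   coefficient; negative = consumed, positive = produced.
#' @param lower_bound,upper_bound Flux bounds in mmol gDW^-1 h^-1 (the biomass
#'   reaction is in h^-1).
#' @param gene_associated `TRUE` for enzyme-catalysed reactions, `FALSE` for
#'   exchanges, sinks, diffusion and maintenance pseudo-reactions.
#' @param subsystem Optional subsystem label.
#' @return An object of class `"phb_reaction"`.
#' @export
reaction <- function(id, name = id, stoichiometry, lower_bound = 0,
                     upper_bound = 1000, gene_associated = TRUE,
                     subsystem = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoichiometry) == 0L)
    stop("reaction '", id, "' has empty stoichiometry")
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop("stoichiometry of '", id, "' must be a named vector")
  if (anyDuplicated(names(stoichiometry)))
    stop("duplicate metabolite in stoichiometry of '", id, "'")
  if (lower_bound > upper_bound)
    stop("reaction '", id, "': lower_bound > upper_bound")
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gene_associated = isTRUE(gene_associated),
                 subsystem = subsystem),
            class = "phb_reaction")
}

#' Assemble a stoichiometric model
#'
#' Validates referential integrity: every metabolite referenced by a reaction
#' must be declared, ids must be unique, and exchange reactions (single-
#' metabolite boundary pseudo-reactions) are identified structurally.
#'
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects.
#' @param objective Named numeric vector, reaction id to objective coefficient
#'   (may be empty).
#' @return An object of class `"phb_model"`.
#' @export
stoichiometric_model <- function(metabolites, reactions, objective = numeric(0)) {
  met_ids <- vapply(metabolites, `[[`, "", "id")
  rxn_ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(met_ids)) stop("duplicate metabolite ids: ",
                                   paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids: ",
                                   paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  for (r in reactions) {
    missing <- setdiff(names(r$stoichiometry), met_ids)
    if (length(missing))
      stop("reaction '", r$id, "' references undeclared metabolite(s): ",
           paste(missing, collapse = ", "))
  }
  if (length(objective)) {
    missing <- setdiff(names(objective), rxn_ids)
    if (length(missing))
      stop("objective references unknown reaction(s): ", paste(missing, collapse = ", "))
  }
  structure(list(metabolites = stats::setNames(metabolites, met_ids),
                 reactions = stats::setNames(reactions, rxn_ids),
                 objective = objective),
            class = "phb_model")
}

#' @export
print.phb_model <- function(x, ...) {
  cat("Stoichiometric model:", length(x$metabolites), "metabolites,",
      length(x$reactions), "reactions\n")
  if (length(x$objective))
    cat("Objective:", paste(sprintf("%+g %s", x$objective, names(x$objective)),
                            collapse = " "), "\n")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model A `"phb_model"`.
#' @return Dense numeric matrix S (metabolites x reactions), with dimnames.
#' @export
stoich_matrix <- function(model) {
  met_ids <- names(model$metabolites)
  rxn_ids <- names(model$reactions)
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (r in model$reactions) S[names(r$stoichiometry), r$id] <- r$stoichiometry
  S
}

#' Is a reaction an exchange reaction?
#'
#' Exchange reactions are boundary pseudo-reactions touching exactly one
#' metabolite; by convention negative flux denotes uptake.
#'
#' @param rxn A `"phb_reaction"`.
#' @return Logical scalar.
#' @export
is_exchange <- function(rxn) length(rxn$stoichiometry) == 1L

#' Reaction bounds of a model
#'
#' @param model A `"phb_model"`.
#' @return Two-column matrix (lower, upper) with reaction ids as rownames.
#' @export
model_bounds <- function(model) {
  cbind(lower = vapply(model$reactions, `[[`, 0, "lower_bound"),
        upper = vapply(model$reactions, `[[`, 0, "upper_bound"))
}

format_stoich <- function(st) {
  side <- function(v, sgn) {
    v <- v[sign(v) == sgn]
    if (!length(v)) return("")
    paste(sprintf("%s %s", sub("^1 ", "", format(abs(v), trim = TRUE)), names(v)),
          collapse = " + ")
  }
  paste(side(st, -1), "-->", side(st, 1))
}

#' Export a model as two tab-separated tables
#'
#' Writes `<prefix>_metabolites.txt` (id, name, compartment, formula) and
#' `<prefix>_reactions.txt` (id, name, stoichiometry text, lower and upper
#' bound, gene flag).
#'
#' @param model A `"phb_model"`.
#' @param prefix Path prefix for the two files.
#' @return Invisibly, the two file paths.
#' @export
write_model_tables <- function(model, prefix) {
  fmt_formula <- function(f) {
    if (is.null(f)) return("")
    paste0(names(f), ifelse(f == 1, "", f), collapse = "")
  }
  mets <- data.frame(
    id = names(model$metabolites),
    name = vapply(model$metabolites, `[[`, "", "name"),
    compartment = vapply(model$metabolites, `[[`, "", "compartment"),
    formula = vapply(model$metabolites, function(m) fmt_formula(m$formula), ""),
    row.names = NULL, check.names = FALSE)
  rxns <- data.frame(
    id = names(model$reactions),
    name = vapply(model$reactions, `[[`, "", "name"),
    equation = vapply(model$reactions, function(r) format_stoich(r$stoichiometry), ""),
    lower_bound = vapply(model$reactions, `[[`, 0, "lower_bound"),
    upper_bound = vapply(model$reactions, `[[`, 0, "upper_bound"),
    gene_associated = vapply(model$reactions, `[[`, TRUE, "gene_associated"),
    row.names = NULL, check.names = FALSE)
  paths <- paste0(prefix, c("_metabolites.txt", "_reactions.txt"))
  utils::write.table(mets, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rxns, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
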