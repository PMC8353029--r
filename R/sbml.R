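# SBML import/export. Writes Level 3 Version 1 with the flux-balance
# constraints (fbc, version 2) extension; reads both Level 3 + FBC and
# Level 2 (flux bounds from kinetic-law LOWER_BOUND/UPPER_BOUND parameters).

SBML_NS  <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS   <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

format_formula <- function(f) {
  if (is.null(f) || !length(f)) return(NULL)
  ord <- c("C", "H", "N", "O", "P", "S")
  f <- f[order(match(names(f), ord))]
  paste0(names(f), ifelse(f == 1, "", f), collapse = "")
}

parse_formula <- function(txt) {
  if (is.null(txt) || is.na(txt) || !nzchar(txt)) return(NULL)
  parts <- regmatches(txt, gregexpr("[A-Z][a-z]?[0-9]*\\.?[0-9]*", txt))[[1]]
  el <- sub("^([A-Z][a-z]?).*$", "\\1", parts)
  ct <- sub("^[A-Z][a-z]?", "", parts)
  ct <- ifelse(nzchar(ct), as.numeric(ct), 1)
  f <- stats::setNames(ct, el)
  f <- tapply(f, names(f), sum)
  if (any(!names(f) %in% c("C", "H", "O", "N", "P", "S"))) return(NULL)
  stats::setNames(as.numeric(f), names(f))
}

# attribute lookup ignoring namespace prefixes
attr_any <- function(node, local) {
  a <- xml2::xml_attrs(node)
  hit <- which(names(a) == local | endsWith(names(a), paste0(":", local)))
  if (!length(hit)) NA_character_ else unname(a[hit[1]])
}

#' Write a model to SBML
#'
#' Serialises the model as SBML Level 3 Version 1 with the FBC (version 2)
#' extension: species carry chemical formulas and charges, reactions carry
#' flux bounds as global parameters, gene-associated reactions carry a
#' one-gene-per-reaction product association, and the model objective is
#' written as the active FBC objective (maximisation sense).
#'
#' @param model A `"phb_model"` with at least one reaction.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sbml <- function(model, path) {
  if (!inherits(model, "phb_model")) stop("model must be a phb_model")
  if (!length(model$reactions)) stop("cannot write an empty model (no reactions)")
  comp_id <- c(cytosol = "c", extracellular = "e")

  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mod <- xml2::xml_add_child(doc, "model", id = "phbflux_model",
                             "fbc:strict" = "true")

  locomp <- xml2::xml_add_child(mod, "listOfCompartments")
  for (cid in unique(comp_id[vapply(model$metabolites, `[[`, "", "compartment")]))
    xml2::xml_add_child(locomp, "compartment", id = cid, constant = "true")

  losp <- xml2::xml_add_child(mod, "listOfSpecies")
  for (met in model$metabolites) {
    sp <- xml2::xml_add_child(losp, "species", id = met$id, name = met$name,
                              compartment = comp_id[[met$compartment]],
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    ff <- format_formula(met$formula)
    if (!is.null(ff)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", ff)
    if (!is.null(met$charge)) xml2::xml_set_attr(sp, "fbc:charge",
                                                 as.character(met$charge))
  }

  bounds <- model_bounds(model)
  uniq <- sort(unique(c(bounds)))
  par_id <- sprintf("bnd_%d", seq_along(uniq))
  bound_par <- function(v) par_id[match(v, uniq)]
  lopar <- xml2::xml_add_child(mod, "listOfParameters")
  for (i in seq_along(uniq))
    xml2::xml_add_child(lopar, "parameter", id = par_id[i],
                        value = format(uniq[i], digits = 17),
                        constant = "true")

  gene_rxns <- names(model$reactions)[vapply(model$reactions, `[[`, TRUE,
                                             "gene_associated")]
  lorx <- xml2::xml_add_child(mod, "listOfReactions")
  for (r in model$reactions) {
    rx <- xml2::xml_add_child(
      lorx, "reaction", id = r$id, name = r$name,
      reversible = tolower(r$lower_bound < 0), fast = "false",
      "fbc:lowerFluxBound" = bound_par(r$lower_bound),
      "fbc:upperFluxBound" = bound_par(r$upper_bound))
    reac <- r$stoichiometry[r$stoichiometry < 0]
    prod <- r$stoichiometry[r$stoichiometry > 0]
    if (length(reac)) {
      lo <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in seq_along(reac))
        xml2::xml_add_child(lo, "speciesReference", species = names(reac)[i],
                            stoichiometry = format(-reac[i], digits = 17),
                            constant = "true")
    }
    if (length(prod)) {
      lo <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in seq_along(prod))
        xml2::xml_add_child(lo, "speciesReference", species = names(prod)[i],
                            stoichiometry = format(prod[i], digits = 17),
                            constant = "true")
    }
    if (r$gene_associated) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      xml2::xml_add_child(gpa, "fbc:geneProductRef",
                          "fbc:geneProduct" = paste0("G_", r$id))
    }
  }

  if (length(gene_rxns)) {
    logp <- xml2::xml_add_child(mod, "fbc:listOfGeneProducts")
    for (id in gene_rxns)
      xml2::xml_add_child(logp, "fbc:geneProduct", "fbc:id" = paste0("G_", id),
                          "fbc:label" = id)
  }

  if (length(model$objective)) {
    loob <- xml2::xml_add_child(mod, "fbc:listOfObjectives",
                                "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(loob, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lofo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    for (i in seq_along(model$objective))
      xml2::xml_add_child(lofo, "fbc:fluxObjective",
                          "fbc:reaction" = names(model$objective)[i],
                          "fbc:coefficient" = format(model$objective[i],
                                                     digits = 17))
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a model from SBML
#'
#' Reads SBML Level 3 (flux bounds and objective from the FBC extension) or
#' Level 2 (bounds from `LOWER_BOUND`/`UPPER_BOUND` kinetic-law parameters).
#' Identifiers are preserved verbatim. Reactions without declared bounds get
#' defaults, (-1000, 1000) if the `reversible` attribute allows reversal and
#' (0, 1000) otherwise, with a warning. A reaction is marked gene-associated
#' if it carries an FBC gene-product association (or a GENE_ASSOCIATION
#' note); with neither annotation, every non-boundary reaction is assumed
#' enzymatic.
#'
#' @param path Path to an SBML file.
#' @return A `"phb_model"`.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML: ", conditionMessage(e)))
  find <- function(node, what)
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", what))
  mod <- find(doc, "model")
  if (!length(mod)) stop("malformed SBML: no <model> element")
  mod <- mod[[1]]

  comps <- find(mod, "compartment")
  comp_kind <- stats::setNames(rep("cytosol", length(comps)),
                               vapply(comps, attr_any, "", "id"))
  for (i in seq_along(comps)) {
    nm <- paste(attr_any(comps[[i]], "id"), attr_any(comps[[i]], "name"))
    if (grepl("(^| )e( |$)|extra|external|boundary", nm, ignore.case = TRUE))
      comp_kind[i] <- "extracellular"
  }

  mets <- lapply(find(mod, "species"), function(sp) {
    id <- attr_any(sp, "id")
    if (is.na(id)) stop("malformed SBML: species without id")
    comp <- attr_any(sp, "compartment")
    ch <- attr_any(sp, "charge")
    metabolite(id,
               name = if (is.na(attr_any(sp, "name"))) id else attr_any(sp, "name"),
               compartment = if (!is.na(comp) && comp %in% names(comp_kind))
                 comp_kind[[comp]] else "cytosol",
               formula = parse_formula(attr_any(sp, "chemicalFormula")),
               charge = if (is.na(ch)) NULL else as.integer(ch))
  })

  pars <- find(mod, "listOfParameters")
  par_val <- numeric(0)
  if (length(pars)) {
    pnodes <- xml2::xml_find_all(pars[[1]], "./*[local-name()='parameter']")
    par_val <- stats::setNames(as.numeric(vapply(pnodes, attr_any, "", "value")),
                               vapply(pnodes, attr_any, "", "id"))
  }

  any_gpa <- FALSE
  rxn_nodes <- find(mod, "reaction")
  rxns <- lapply(rxn_nodes, function(rx) {
    id <- attr_any(rx, "id")
    if (is.na(id)) stop("malformed SBML: reaction without id")
    side <- function(tag, sgn) {
      refs <- xml2::xml_find_all(
        rx, sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']", tag))
      if (!length(refs)) return(numeric(0))
      st <- vapply(refs, function(s) {
        v <- attr_any(s, "stoichiometry")
        if (is.na(v)) 1 else as.numeric(v)
      }, 0)
      stats::setNames(sgn * st, vapply(refs, attr_any, "", "species"))
    }
    st <- c(side("listOfReactants", -1), side("listOfProducts", 1))
    if (anyDuplicated(names(st))) {
      st <- tapply(st, names(st), sum)
      st <- stats::setNames(as.numeric(st), names(st))
      st <- st[st != 0]
    }
    if (!length(st)) stop("malformed SBML: reaction '", id, "' has no species")

    rev_attr <- attr_any(rx, "reversible")
    reversible <- is.na(rev_attr) || tolower(rev_attr) == "true"
    lbref <- attr_any(rx, "lowerFluxBound")
    ubref <- attr_any(rx, "upperFluxBound")
    lb <- if (!is.na(lbref) && lbref %in% names(par_val)) par_val[[lbref]] else NA
    ub <- if (!is.na(ubref) && ubref %in% names(par_val)) par_val[[ubref]] else NA
    if (is.na(lb) || is.na(ub)) {
      # Level 2 fallback: kinetic-law parameters
      kl <- xml2::xml_find_all(
        rx, "./*[local-name()='kineticLaw']//*[local-name()='parameter']")
      if (length(kl)) {
        kid <- vapply(kl, attr_any, "", "id")
        kv <- as.numeric(vapply(kl, attr_any, "", "value"))
        if (is.na(lb) && "LOWER_BOUND" %in% kid) lb <- kv[match("LOWER_BOUND", kid)]
        if (is.na(ub) && "UPPER_BOUND" %in% kid) ub <- kv[match("UPPER_BOUND", kid)]
      }
    }
    if (is.na(lb) || is.na(ub)) {
      warning("reaction '", id, "': no declared bounds, using defaults",
              call. = FALSE)
      if (is.na(lb)) lb <- if (reversible) -1000 else 0
      if (is.na(ub)) ub <- 1000
    }

    gpa <- xml2::xml_find_all(rx, "./*[local-name()='geneProductAssociation']")
    notes <- xml2::xml_text(xml2::xml_find_all(rx, "./*[local-name()='notes']"))
    has_gene_note <- any(grepl("GENE_?ASSOCIATION *[:=] *[^ <]", notes))
    if (length(gpa) || has_gene_note) any_gpa <<- TRUE
    reaction(id,
             name = if (is.na(attr_any(rx, "name"))) id else attr_any(rx, "name"),
             stoichiometry = st, lower_bound = lb, upper_bound = ub,
             gene_associated = length(gpa) > 0 || has_gene_note)
  })

  # models without any gene annotation: assume non-boundary reactions enzymatic
  if (!any_gpa) {
    rxns <- lapply(rxns, function(r) {
      r$gene_associated <- !(length(r$stoichiometry) == 1L ||
                               grepl("^(EX_|DM_|SK_)|biomass|maintenance|ATPM",
                                     r$id, ignore.case = TRUE))
      r
    })
  }

  objective <- numeric(0)
  fobj <- find(mod, "fluxObjective")
  if (length(fobj)) {
    objective <- stats::setNames(
      vapply(fobj, function(f) {
        v <- attr_any(f, "coefficient"); if (is.na(v)) 1 else as.numeric(v)
      }, 0),
      vapply(fobj, attr_any, "", "reaction"))
  }
  stoichiometric_model(mets, rxns, objective)
}
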