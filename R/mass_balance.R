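#' Check elemental balance of a model's reactions
#'
#' Sums element counts (coefficient times formula) over each reaction.
#' Boundary and pseudo-reactions — exchanges, sinks/demands, biomass and ATP
#' maintenance — are skipped, as are reactions involving a metabolite without
#' a formula (with a warning).
#'
#' @param model A `"phb_model"`.
#' @param elements Elements to check; default C, H, O, N, P, S.
#' @param tol Absolute imbalance below which a reaction counts as balanced.
#' @return Data frame with columns `reaction`, `element`, `imbalance`; zero
#'   rows iff every checked reaction is balanced.
#' @export
check_mass_balance <- function(model, elements = c("C", "H", "O", "N", "P", "S"),
                               tol = 1e-9) {
  skip_ids <- grepl("^(EX_|DM_|SK_)", names(model$reactions)) |
    names(model$reactions) %in% c("BIOMASS", "ATPM")
  out <- list()
  for (r in model$reactions[!skip_ids]) {
    if (is_exchange(r)) next
    mets <- model$metabolites[names(r$stoichiometry)]
    has_formula <- !vapply(mets, function(m) is.null(m$formula), TRUE)
    if (!all(has_formula)) {
      warning("reaction '", r$id, "' skipped: no formula for ",
              paste(names(mets)[!has_formula], collapse = ", "), call. = FALSE)
      next
    }
    bal <- stats::setNames(numeric(length(elements)), elements)
    for (i in seq_along(mets)) {
      f <- mets[[i]]$formula
      f <- f[names(f) %in% elements]
      if (length(f)) bal[names(f)] <- bal[names(f)] + r$stoichiometry[i] * f
    }
    off <- abs(bal) > tol
    if (any(off))
      out[[r$id]] <- data.frame(reaction = r$id, element = names(bal)[off],
                                imbalance = unname(bal[off]))
  }
  if (!length(out))
    return(data.frame(reaction = character(0), element = character(0),
                      imbalance = numeric(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
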