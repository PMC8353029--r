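#' Molar mass used to convert PHB mass rates to molar rates
#'
#' Grams per mole of 3-hydroxybutyrate monomer incorporated into the polymer
#' (monomer minus the water lost on polymerisation), as used throughout the
#' rate conversions.
#' @export
PHB_MONOMER_MOLAR_MASS <- 96

#' Non-growth ATP maintenance demand
#'
#' Default maintenance ATP requirement of succinate-grown *Paracoccus
#' denitrificans*, mmol ATP gDW^-1 h^-1, derived from chemostat maintenance
#' substrate uptake via Pirt's relation.
#' @export
MAINTENANCE_ATP_DEFAULT <- 7.5

#' Parameters of the built-in core model
#'
#' The core model covers the succinate-to-PHB route and the TCA cycle of
#' *P. denitrificans* central carbon metabolism. Several choices are not
#' fixed by experiment and are exposed here.
#'
#' @param po_ratio ATP synthesised per NADH oxidised by the (lumped)
#'   respiratory chain; must be > 0. Default 1.5.
#' @param me_cofactor Cofactor reduced by malic enzyme, `"NADPH"` (default) or
#'   `"NADH"`.
#' @param include_transhydrogenase Include a reversible NADH/NADPH
#'   transhydrogenase so the malic-enzyme cofactor choice never blocks NADPH
#'   supply to acetoacetyl-CoA reductase. Default `TRUE`.
#' @param maintenance_atp Lower bound of the ATP maintenance reaction,
#'   mmol gDW^-1 h^-1; must be >= 0. Default [MAINTENANCE_ATP_DEFAULT].
#' @param biomass_demands Named numeric vector of precursor demands of the
#'   biomass pseudo-reaction, mmol per gDW. Defaults are generic heterotroph
#'   values (a calibration, not a measured composition): acetyl-CoA 3.7,
#'   oxaloacetate 1.8, 2-oxoglutarate 1.1, pyruvate 2.9, NADPH 11 and a
#'   growth-associated ATP demand of 40.
#' @return An object of class `"phb_core_params"`.
#' @export
core_model_params <- function(po_ratio = 1.5,
                              me_cofactor = c("NADPH", "NADH"),
                              include_transhydrogenase = TRUE,
                              maintenance_atp = MAINTENANCE_ATP_DEFAULT,
                              biomass_demands = c(accoa_c = 3.7, oaa_c = 1.8,
                                                  akg_c = 1.1, pyr_c = 2.9,
                                                  nadph_c = 11, atp_c = 40)) {
  me_cofactor <- match.arg(me_cofactor)
  if (!is.numeric(po_ratio) || length(po_ratio) != 1L || po_ratio <= 0)
    stop("po_ratio must be a positive number")
  if (!is.numeric(maintenance_atp) || length(maintenance_atp) != 1L ||
      maintenance_atp < 0)
    stop("maintenance_atp must be >= 0")
  if (any(biomass_demands < 0)) stop("biomass_demands must be non-negative")
  structure(list(po_ratio = po_ratio, me_cofactor = me_cofactor,
                 include_transhydrogenase = isTRUE(include_transhydrogenase),
                 maintenance_atp = maintenance_atp,
                 biomass_demands = biomass_demands),
            class = "phb_core_params")
}

core_metabolites <- function() {
  # neutral-molecule formulas; CoA thioesters carry the full CoA composition
  coa  <- c(C = 21, H = 36, N = 7, O = 16, P = 3, S = 1)
  acyl <- function(C, H, O) {
    f <- coa; f["C"] <- f["C"] + C; f["H"] <- f["H"] - 1 + H; f["O"] <- f["O"] + O; f
  }
  nad  <- c(C = 21, H = 27, N = 7, O = 14, P = 2)
  nadh <- nad; nadh["H"] <- nadh["H"] + 2
  list(
    metabolite("succ_e", "succinate (external)", "extracellular", c(C = 4, H = 6, O = 4)),
    metabolite("o2_e", "oxygen (external)", "extracellular", c(O = 2)),
    metabolite("co2_e", "carbon dioxide (external)", "extracellular", c(C = 1, O = 2)),
    metabolite("h2o_e", "water (external)", "extracellular", c(H = 2, O = 1)),
    metabolite("succ_c", "succinate", "cytosol", c(C = 4, H = 6, O = 4)),
    metabolite("fum_c", "fumarate", "cytosol", c(C = 4, H = 4, O = 4)),
    metabolite("mal_c", "(S)-malate", "cytosol", c(C = 4, H = 6, O = 5)),
    metabolite("oaa_c", "oxaloacetate", "cytosol", c(C = 4, H = 4, O = 5)),
    metabolite("pyr_c", "pyruvate", "cytosol", c(C = 3, H = 4, O = 3)),
    metabolite("cit_c", "citrate", "cytosol", c(C = 6, H = 8, O = 7)),
    metabolite("icit_c", "isocitrate", "cytosol", c(C = 6, H = 8, O = 7)),
    metabolite("akg_c", "2-oxoglutarate", "cytosol", c(C = 5, H = 6, O = 5)),
    metabolite("succoa_c", "succinyl-CoA", "cytosol", acyl(4, 5, 3)),
    metabolite("coa_c", "coenzyme A", "cytosol", coa),
    metabolite("accoa_c", "acetyl-CoA", "cytosol", acyl(2, 3, 1)),
    metabolite("aacoa_c", "acetoacetyl-CoA", "cytosol", acyl(4, 5, 2)),
    metabolite("hbcoa_c", "(R)-3-hydroxybutyryl-CoA", "cytosol", acyl(4, 7, 2)),
    metabolite("phb_c", "PHB monomer unit", "cytosol", c(C = 4, H = 6, O = 2)),
    metabolite("nad_c", "NAD+", "cytosol", nad),
    metabolite("nadh_c", "NADH", "cytosol", nadh),
    metabolite("nadp_c", "NADP+", "cytosol", c(C = 21, H = 28, N = 7, O = 17, P = 3)),
    metabolite("nadph_c", "NADPH", "cytosol", c(C = 21, H = 30, N = 7, O = 17, P = 3)),
    metabolite("atp_c", "ATP", "cytosol", c(C = 10, H = 16, N = 5, O = 13, P = 3)),
    metabolite("adp_c", "ADP", "cytosol", c(C = 10, H = 15, N = 5, O = 10, P = 2)),
    metabolite("pi_c", "orthophosphate", "cytosol", c(H = 3, O = 4, P = 1)),
    metabolite("o2_c", "oxygen", "cytosol", c(O = 2)),
    metabolite("co2_c", "carbon dioxide", "cytosol", c(C = 1, O = 2)),
    metabolite("h2o_c", "water", "cytosol", c(H = 2, O = 1))
  )
}

#' Build the built-in core metabolic model
#'
#' Constructs a stoichiometric model of the succinate-to-PHB route in
#' *P. denitrificans*: succinate uptake, the TCA-cycle reactions, malic
#' enzyme and pyruvate dehydrogenase feeding acetyl-CoA, the three-step PHB
#' pathway (beta-ketothiolase *phaA*, acetoacetyl-CoA reductase *phaB*, PHB
#' synthase *phaC*) with a PHB sink, a lumped respiratory chain
#' (NADH + 1/2 O2 + P/O ADP -> P/O ATP), ATP maintenance bounded below, and a
#' biomass pseudo-reaction draining the configured precursors.
#'
#' Redox bookkeeping is deliberately coarse: succinate dehydrogenase is
#' written against NAD rather than a separate quinone pool, and oxidative
#' phosphorylation is a single reaction parameterised by the P/O ratio.
#' Carbon stoichiometry is exact; every gene-associated reaction is
#' elementally balanced (see [check_mass_balance()]).
#'
#' @param params A [core_model_params()] object.
#' @return A `"phb_model"` whose objective is succinate-uptake minimisation
#'   (maximise the `EX_succ` exchange flux, uptake being negative).
#' @export
build_core_model <- function(params = core_model_params()) {
  if (!inherits(params, "phb_core_params"))
    stop("params must be created by core_model_params()")
  po <- params$po_ratio
  me_red <- if (params$me_cofactor == "NADPH") c(nadp_c = -1, nadph_c = 1)
            else c(nad_c = -1, nadh_c = 1)

  rxns <- list(
    reaction("EX_succ", "succinate exchange", c(succ_e = -1), -1000, 1000,
             gene_associated = FALSE, subsystem = "exchange"),
    reaction("EX_o2", "O2 exchange", c(o2_e = -1), -1000, 1000,
             gene_associated = FALSE, subsystem = "exchange"),
    reaction("EX_co2", "CO2 exchange", c(co2_e = -1), -1000, 1000,
             gene_associated = FALSE, subsystem = "exchange"),
    reaction("EX_h2o", "H2O exchange", c(h2o_e = -1), -1000, 1000,
             gene_associated = FALSE, subsystem = "exchange"),
    reaction("SUCCt", "succinate transport", c(succ_e = -1, succ_c = 1),
             0, 1000, subsystem = "transport"),
    reaction("O2t", "O2 diffusion", c(o2_e = -1, o2_c = 1), -1000, 1000,
             gene_associated = FALSE, subsystem = "transport"),
    reaction("CO2t", "CO2 diffusion", c(co2_c = -1, co2_e = 1), -1000, 1000,
             gene_associated = FALSE, subsystem = "transport"),
    reaction("H2Ot", "H2O diffusion", c(h2o_c = -1, h2o_e = 1), -1000, 1000,
             gene_associated = FALSE, subsystem = "transport"),
    reaction("SDH", "succinate dehydrogenase (lumped to NAD)",
             c(succ_c = -1, nad_c = -1, fum_c = 1, nadh_c = 1),
             0, 1000, subsystem = "TCA"),
    reaction("FUM", "fumarase", c(fum_c = -1, h2o_c = -1, mal_c = 1),
             0, 1000, subsystem = "TCA"),
    reaction("MDH", "malate dehydrogenase",
             c(mal_c = -1, nad_c = -1, oaa_c = 1, nadh_c = 1),
             0, 1000, subsystem = "TCA"),
    reaction("ME", "malic enzyme",
             c(mal_c = -1, pyr_c = 1, co2_c = 1) |> c(me_red),
             0, 1000, subsystem = "anaplerosis"),
    reaction("PDH", "pyruvate dehydrogenase",
             c(pyr_c = -1, coa_c = -1, nad_c = -1,
               accoa_c = 1, co2_c = 1, nadh_c = 1),
             0, 1000, subsystem = "central"),
    reaction("CS", "citrate synthase",
             c(accoa_c = -1, oaa_c = -1, h2o_c = -1, cit_c = 1, coa_c = 1),
             0, 1000, subsystem = "TCA"),
    reaction("ACONT", "aconitase", c(cit_c = -1, icit_c = 1), 0, 1000,
             subsystem = "TCA"),
    reaction("ICDH", "isocitrate dehydrogenase (NADP)",
             c(icit_c = -1, nadp_c = -1, akg_c = 1, co2_c = 1, nadph_c = 1),
             0, 1000, subsystem = "TCA"),
    reaction("OGDH", "2-oxoglutarate dehydrogenase",
             c(akg_c = -1, coa_c = -1, nad_c = -1,
               succoa_c = 1, co2_c = 1, nadh_c = 1),
             0, 1000, subsystem = "TCA"),
    reaction("SCS", "succinyl-CoA synthetase",
             c(succoa_c = -1, adp_c = -1, pi_c = -1,
               succ_c = 1, coa_c = 1, atp_c = 1),
             0, 1000, subsystem = "TCA"),
    reaction("PHAA", "beta-ketothiolase (phaA)",
             c(accoa_c = -2, aacoa_c = 1, coa_c = 1), 0, 1000,
             subsystem = "PHB"),
    reaction("PHAB", "acetoacetyl-CoA reductase (phaB)",
             c(aacoa_c = -1, nadph_c = -1, hbcoa_c = 1, nadp_c = 1),
             0, 1000, subsystem = "PHB"),
    reaction("PHAC", "PHB synthase (phaC)",
             c(hbcoa_c = -1, phb_c = 1, coa_c = 1), 0, 1000,
             subsystem = "PHB"),
    reaction("DM_phb", "PHB sink (polymer accumulation)", c(phb_c = -1),
             0, 1000, gene_associated = FALSE, subsystem = "sink"),
    reaction("RESP", "respiratory chain (lumped)",
             c(nadh_c = -1, o2_c = -0.5, adp_c = -po, pi_c = -po,
               nad_c = 1, atp_c = po, h2o_c = 1 + po),
             0, 1000, subsystem = "energy"),
    reaction("ATPM", "ATP maintenance",
             c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1),
             params$maintenance_atp, 1000, gene_associated = FALSE,
             subsystem = "energy"),
    reaction("BIOMASS", "biomass pseudo-reaction",
             biomass_stoich(params$biomass_demands),
             0, 1000, gene_associated = FALSE, subsystem = "biomass")
  )
  if (params$include_transhydrogenase)
    rxns <- c(rxns, list(
      reaction("THD", "transhydrogenase",
               c(nadh_c = -1, nadp_c = -1, nad_c = 1, nadph_c = 1),
               -1000, 1000, subsystem = "energy")))

  stoichiometric_model(core_metabolites(), rxns, objective = c(EX_succ = 1))
}

# biomass drains precursors and regenerates the carrier pools; no biomass
# species is tracked (the reaction's flux IS the growth rate, h^-1)
biomass_stoich <- function(d) {
  st <- -d
  if (!is.na(d["accoa_c"]) && d["accoa_c"] > 0)
    st <- c(st, coa_c = unname(d["accoa_c"]))
  if (!is.na(d["nadph_c"]) && d["nadph_c"] > 0)
    st <- c(st, nadp_c = unname(d["nadph_c"]))
  if (!is.na(d["atp_c"]) && d["atp_c"] > 0)
    st <- c(st, adp_c = unname(d["atp_c"]), pi_c = unname(d["atp_c"]),
            h2o_c = -unname(d["atp_c"]))
  st
}
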