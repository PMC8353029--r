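Package: phbflux
Title: Flux Balance Analysis of PHB Synthesis in Succinate-Grown Paracoccus denitrificans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates batch-culture growth kinetics (specific growth rate,
    biomass yield on succinate, specific substrate uptake and PHB production
    rates) from time series of dry weight, poly(3-hydroxybutyrate) content and
    residual succinate, and predicts metabolic flux distributions by flux
    balance analysis (FBA) of a stoichiometric model of central carbon
    metabolism in Paracoccus denitrificans. Supports two physiological phases:
    growth-arrested PHB accumulation and exponential growth with constant PHB
    content. Includes a built-in core model of the succinate-to-PHB route,
    SBML (Level 3 + FBC, Level 2) import/export, parsimonious FBA for
    degeneracy resolution, Pirt maintenance-energy regression, and a
    batch-culture simulator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    stats,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
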