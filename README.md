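# phbflux

Quantitative analysis of poly(3-hydroxybutyrate) (PHB) synthesis in
*Paracoccus denitrificans* growing on succinate: physiological rate
estimation from batch-culture time series, and flux balance analysis (FBA)
of a stoichiometric model of central carbon metabolism under the two
physiological phases such cultures exhibit — a growth-arrested PHB
accumulation burst right after inoculation, and exponential growth with a
constant fractional PHB content.

It is aimed at microbial physiologists and metabolic modellers who want a
reproducible route from raw batch measurements (dry weight, PHB content,
residual substrate) to intracellular flux predictions.

## What it computes

**Kinetics.** From a time series $x(t)$ (dry weight, g L⁻¹), $w(t)$ (PHB
content, mg g⁻¹) and $s(t)$ (succinate, mM):

- specific growth rate $\mu$ — slope of $\ln x$ vs $t$ on the exponential
  window (lag-aware automatic selection, or explicit indices);
- biomass yield $Y_{XS}$ — slope of $x$ vs consumed succinate (g-DW mol⁻¹);
- specific uptake $q_s = 1000\,\mu/Y_{XS}$ (mmol g-DW⁻¹ h⁻¹);
- specific PHB production $q_{PHB} = \mu w$, and the molar equivalent using
  the 96 g mol⁻¹ monomer mass;
- the zero-growth accumulation rate $\Delta w/(\Delta t \cdot 96)$;
- Pirt maintenance regression $q_s = \mu/Y_{max} + m_s$.

**Flux balance analysis.** A built-in, elementally balanced core model of
the succinate→PHB route (TCA cycle, malic enzyme, pyruvate dehydrogenase,
*phaA/phaB/phaC*, lumped respiration, ATP maintenance, biomass drain) is
solved as a linear program: measured growth and PHB rates are pinned,
maintenance ATP is bounded below, succinate uptake is minimised, and the
degenerate optimum is resolved by parsimonious FBA (minimal total flux).
Genome-scale models can be supplied as SBML (Level 3 + FBC, or Level 2).

**Synthetic data.** A batch-culture simulator with the same structure the
estimators assume (hard lag, exponential growth, yield-coupled substrate,
PHB burst, replicate Gaussian noise) supports parameter-recovery studies.

## Worked example

```r
library(phbflux)

ts <- read_batch_timeseries(system.file("extdata", "table1_batch.csv",
                                        package = "phbflux"))
rates <- estimate_rates(ts, window = 3:9, phb_content = 70)
rates
#> mu      = 0.2355 +/- 0.0242 h^-1 (window: points 3-9, R^2 = 0.9499)
#> Y_XS    = 47.9 +/- 2.2 g-DW mol^-1
#> q_s     = 4.92 mmol g-DW^-1 h^-1
#> q_PHB   = 16.5 mg g-DW^-1 h^-1 = 0.172 mmol g-DW^-1 h^-1 (content 70.0 mg/g)
```

The packaged series is the duplicate-culture batch experiment: cells grow
at ~0.23 h⁻¹, form ~48 g dry weight per mole of succinate, and therefore
take up ~4.9 mmol succinate g-DW⁻¹ h⁻¹ while producing PHB at ~16 mg
g-DW⁻¹ h⁻¹ (7% of new biomass is polymer).

```r
m <- build_core_model()

# growth-arrested accumulation: PHB content 0 -> 78.4 mg/g in 30 min
acc <- accumulation_rate(0, 78.4, 0.5)     # 1.63 mmol g-DW^-1 h^-1
p1 <- run_phase(m, phase_spec("accumulation", 0, 1.63, 7.5))
p1
#> Phase 'accumulation' (mu = 0, q_PHB = 1.63, maintenance >= 7.5): optimal
#>   predicted uptake   : 3.260 mmol g-DW^-1 h^-1
#>   acetyl-CoA synthesis: 3.260 mmol g-DW^-1 h^-1
#>   active enzymes     : 10 (pFBA solution; solution-dependent)
#>   TCA cycle active   : FALSE

p2 <- run_phase(m, phase_spec("exponential", rates$mu, rates$q_phb_molar, 7.5))
compare_phases(p1, p2)$enzymes_only_in_2
#> [1] "MDH"   "CS"    "ACONT" "ICDH"  "OGDH"  "SCS"
```

The numbers say: with growth pinned to zero, every PHB monomer costs two
acetyl-CoA and every acetyl-CoA one succinate, so minimal uptake and
acetyl-CoA synthesis are both exactly 2 × 1.63 = 3.26 mmol g-DW⁻¹ h⁻¹ —
and the NADH generated on that route already covers maintenance ATP, so
the parsimonious solution leaves the whole oxidative TCA branch idle.
During exponential growth the biomass demand switches the cycle on, which
is what drains the acetyl-CoA pool and throttles PHB synthesis (the
thiolase is bimolecular in acetyl-CoA: `thiolase_sensitivity(4)` = 16).

`run_full_analysis()` chains all of the above from a CSV to a JSON report;
`inst/scripts/phbflux.R` wraps the same functions as a command-line tool
(`rates`, `phase`, `analyze`, `build-model`, `simulate`).

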