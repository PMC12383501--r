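# mtctrends

Climate-driven **tropicalization** of pelagic fisheries: as oceans warm,
warm-water species take up a growing share of the catch while cold-water
species recede. `mtctrends` quantifies that signal from year-by-species
catch biomass tables, the way fisheries ecologists analyse multidecadal
tuna/billfish/shark catch series split into western and eastern ocean
sectors. It is aimed at community ecologists and fisheries scientists who
have (i) a catch matrix, (ii) a species thermal-preference table, and
(iii) optional annual environmental series (SST, boundary-current
transport), and want the full indicator suite with reproducible seeds.

## The statistics at its core

* **Mean Temperature of the Catch.** For year *y*,
  `MTC_y = Σ_i T_i C_{i,y} / Σ_i C_{i,y}`, where `T_i` is species *i*'s
  preferred temperature (°C) and `C_{i,y}` its catch biomass. Species are
  classed *warm* or *cold* against the mean preference of the assemblage
  (strictly above = warm).
* **Trend models.** OLS of MTC/SST/transport on year; a penalized cubic
  regression spline (k = 5, GCV-selected λ) as the nonlinear alternative,
  retained only when it beats the line on adjusted R², AIC *and* BIC;
  ANCOVA (`value ~ year × region`) for slope differences; leave-one-species-out
  sensitivity of the MTC slope; and time-lagged (0–4 yr) driver models
  selected by minimum AIC, maximum R², and slope significance.
* **Composition workflow.** Hellinger transform
  `√(C_{i,y}/Σ_i C_{i,y})`; a multivariate regression tree on year
  (cross-validated size) cutting the series into compositional regimes;
  PCoA of the Hellinger distance matrix; total beta diversity
  `BD_total = SS_total/(n−1)` decomposed into species (SCBD) and year
  (YCBD) contributions with a 999-permutation test; and temporal
  beta-diversity indices per year pair, partitioning the percentage
  difference `D = (B+C)/(2A+B+C)` into loss (`B̄`) and gain (`C̄`) shares
  with a paired *t* test of `C̄ − B̄`.

A seeded synthetic-data generator (`scenario_params()`,
`tropicalization_scenario()`, `null_scenario()`) emulates the stylised
fishery — 41 years, 29 species, a few dominant taxa, planted warm-ward
share shift, linear-plus-noise environmental series — so every stage is
testable without external databases.

## Worked example

```r
library(mtctrends)
params <- scenario_params(seed = 2024)                 # 41 yr x 29 species
scenario <- tropicalization_scenario(params, planted_mtc_slope = 0.012)
mtc <- compute_mtc(scenario$catch, scenario$table)
fit_linear_trend(mtc)
#> trend_fit: slope 0.012043 /yr (SE 0.000828, p = 2.39e-17), r2 = 0.844,
#>            adj r2 = 0.840, AIC = -106.79, n = 41
```

The fitted slope, 0.0120 °C/yr, recovers the planted tropicalization rate:
catches warm by about 0.12 °C per decade. Composition analysis on the same
scenario:

```r
h <- hellinger_transform(scenario$catch)
fit_mrt(h, seed = 2024)
#> mrt_result: 4 group(s); splits at 1998.5, 2011.5, 2012.5
beta_decompose(h)
#> beta_div_result: SStotal = 0.097061, BDtotal = 0.0024265 (n = 41)
tbi_gain_loss_test(tbi_pairwise(scenario$catch))
#> tbi_test over 820 pairs: mean(C' - B') = 0.1070, direction gains
#>          (t = 38.003, p = 5.921e-183)
```

The tree cuts the series into compositional regimes (here an early/late
break at 1998/99), total beta diversity is modest (composition drifts
rather than jumps), and across all 820 year pairs biomass **gains**
dominate losses — the tropicalization fingerprint. Lagged driver models
(`fit_lagged(to_anomaly(mtc), to_anomaly(scenario$sst))`) report
slope/SE/p/R²/AIC per lag with the three selection criteria named
separately.

The full pipeline, including CSV outputs shaped like the standard trend /
sensitivity / lag tables plus a JSON run manifest, runs from a YAML or
JSON config:

```r
run_pipeline(list(output_dir = "out", seed = 1,
                  simulate = list(kind = "tropicalization",
                                  params = list(n_years = 41, n_species = 29))))
```

or from the command line:
`Rscript -e 'mtctrends::mtc_cli()' all config.yaml`.

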