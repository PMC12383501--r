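---
title: "Methods: catch-based tropicalization indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: catch-based tropicalization indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtctrends)
```

## The model and its assumptions

`mtctrends` treats a fishery's annual catch composition as a sample of the
underlying pelagic community filtered through fishing effort. Its central
statistic, the Mean Temperature of the Catch,

$$\mathrm{MTC}_y = \frac{\sum_i T_i\, C_{i,y}}{\sum_i C_{i,y}},$$

is the biomass-weighted mean of species' preferred temperatures $T_i$ in
year $y$. It rises when warm-affinity species contribute a growing biomass
share. The key assumptions are that (i) each species can be summarised by a
single scalar thermal preference, (ii) catch tonnage is an acceptable proxy
for relative availability (this confounds fleet behaviour with ecology —
the leave-one-species-out sensitivity analysis exists precisely to probe
whether one heavily marketed species drives the trend), and (iii) species
identities are stable across the series (group-level catch categories are
excluded at ingestion).

Warm/cold classification uses the arithmetic mean preference of the
supplied table as threshold, with *strictly above = warm* (a tie is cold).
The threshold is always recomputed from the table rather than hard-coded,
so the conventional 24.03 °C value for the 29-species South Atlantic
assemblage emerges when that table is supplied, and other assemblages work
unchanged.

## Tunable parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| spline basis dimension `k` | `fit_spline_trend` | 5 | small series (≈41 yr); caps flexibility at gentle curvature |
| smoothing λ | `fit_spline_trend` | GCV | classical criterion for penalized regression splines; REML is a documented alternative not implemented to keep the GCV-vs-grid contract exact |
| lag range | `fit_lagged` | 0–4 yr | plausible community response delays to SST / transport forcing |
| `common_sample` | `fit_lagged` | FALSE | each lag uses its maximal overlap (matching common reporting practice); TRUE forces one aligned sample so AIC compares identical data |
| MRT `max_size` | `fit_mrt` | min(10, n−1) | regimes in a 41-year series; data-capped for short series |
| CV folds / type | `fit_mrt` | 10, contiguous blocks | block folds respect serial structure of time-ordered rows; random folds are an option, seeded |
| size rule | `fit_mrt` | min-CV | 1-SE available; the literature on tree-size choice uses both |
| `n_perm` | `ycbd_permutation_test` | 999 | convention; p floor 1/1000 |
| significance α | throughout | 0.05 | two-sided; no multiple-testing correction across lags or sensitivity rows, by design fidelity to standard practice |

## What the synthetic generator emulates — and what it does not

`scenario_params()` states a stylised South Atlantic pelagic fishery:
41 years, 29 species, thermal preferences uniform on 10–29 °C with 16/29
above the table mean, geometric rank-abundance (ratio 0.5, so four taxa
carry >90 % of biomass), midpoint annual total 300,000 t growing 1.6 %/yr
(matching a rise from ≈220,000 t to ≈410,000 t over four decades),
log-normal multiplicative catch noise (sd 0.1), SST warming 0.008 °C/yr
about 23.7 °C with 0.1 °C noise, and boundary-current transport
strengthening 0.366 Sv/yr about −22 Sv with 4 Sv noise (magnitudes chosen
so trend/noise variance shares resemble the reported fits). The
tropicalization scenario plants a log-share trend $+g$ on warm and $-g$ on
cold species, with $g$ calibrated by root finding so the noise-free MTC
path has OLS slope exactly the requested value (default 0.012 °C/yr).

The generator does **not** emulate: spatial structure beyond the two-sector
split, gear/fleet dynamics and effort shifts, autocorrelated environmental
noise, species interactions, or recruitment variability. A green test on
synthetic data therefore establishes that the estimators recover planted
first-order structure under i.i.d. log-normal noise — not that the method
is robust to fleet-behaviour confounding or serially correlated residuals.

Seeding: one master seed expands into per-component substreams via a string
hash, so regenerating the catch matrix is unaffected by whether the
environmental series were also drawn, and all streams stay below $2^{31}$.

## Numerical choices

* **Spline machinery.** The cubic-regression-spline basis and its
  second-derivative penalty matrix come from `mgcv::smoothCon`; the ridge
  solve, GCV profile, effective degrees of freedom (trace of the smoother
  matrix) and information criteria are computed in-package. The penalty
  null space is the straight lines, so λ → ∞ reproduces the OLS line
  (verified to sup-norm 1e−6) and λ = 0 the unpenalized basis regression.
  AIC/BIC use the Gaussian log-likelihood with `edf + 1` parameters, the
  same convention `stats::AIC` applies to `lm`, so linear and spline fits
  are comparable.
* **Degenerate inputs.** A constant series gets `r2 = 0`, `p = 1` (rather
  than 0/0); zero-catch years yield `NA` MTC, never 0; zero biomass rows
  stay zero through the Hellinger transform with a warning; a constant
  matrix gives `BDtotal = 0` with contributions flagged `NA`; a
  zero-variance gain/loss difference returns an exact-equality report
  without a *t* statistic.
* **Tie-breaks.** Thermal ties classify cold (strict "above" rule). Equal
  MRT split reductions break toward the earliest year; equal CV errors
  toward the smaller tree.
* **Model structure choice.** The spline replaces the line only when it
  wins adjusted R², AIC *and* BIC simultaneously — when criteria disagree
  the line is kept, privileging parsimony and cross-study comparability.
* **Percent slope change** in the sensitivity table is signed,
  $100(\beta_{-i}-\beta)/|\beta|$, so a sign flip exceeds −100 %.

## Open design points, decided

* **MRT predictor.** Only year is used as the explanatory variable
  (chronological partitioning); reported regime groupings in this
  literature are contiguous year blocks, and a single ordered predictor
  makes the exhaustive-search oracle feasible. Flagged prominently: the
  tree cannot discover non-chronological groupings.
* **Warm-species proportion.** Implemented primarily as a biomass share
  (consistent with the biomass-weighted MTC framework); a species-count
  share is emitted as a secondary output since the literature is ambiguous
  about which is regressed on time.
* **Beta diversity input.** `BDtotal` defaults to the Hellinger-transformed
  matrix (the workflow's sequencing implies it); every function also
  accepts raw biomass, making the alternative reading one call away.
* **Lag-model samples.** Per-lag maximal overlap by default with a
  `common_sample` switch; AIC ordering across lags is only formally valid
  under the common sample, and both are reported.
* **Paired gains/losses test.** Pairing is across year pairs (each pair
  contributes one $\bar B$, $\bar C$); a species-level pairing variant is
  out of scope.
* **Permutation-null caveat.** The YCBD column-shuffle null is exactly
  invariant for matrices with independent cells (e.g. raw catches under the
  null generator). After Hellinger row-normalisation the rows are
  internally dependent and permutation p-values are slightly non-uniform —
  detectable at 500 replicates — which is a property of the classical test
  itself, not of this implementation; uniformity checks therefore run on
  the raw null matrix.

## Known limitations

Plain OLS inference throughout (no autocorrelation-robust errors); no
effort standardisation; no replacement/richness partition of beta
diversity; no multiple-testing correction; thermal preferences are taken
as given, never re-derived from distribution ranges. All empirical claims
above are computed by the test suite or the worked examples — the vignette
asserts nothing the code does not reproduce.
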