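---
title: "Probabilistic risk assessment of drinking-water contaminants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic risk assessment of drinking-water contaminants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwrisk)
```

## The problem and the model

Groundwater supplies that serve as the primary drinking-water source can
carry chemical contaminants — nitrate from septic systems and fertilizers,
fluoride from mineral dissolution, trace metals, and bulk salinity from
seawater intrusion — whose health relevance depends not on a single
concentration but on the *distribution* of doses a population actually
ingests. `dwrisk` implements the standard non-carcinogenic risk-assessment
chain for the drinking-water ingestion route:

* **Exposure** (chronic daily intake): `Exp = C · Iw / BW`, in mg per kg
  body weight per day, where `C` is the contaminant concentration (mg/L),
  `Iw` the daily water intake (L/day) and `BW` the body weight (kg).
* **Hazard quotient**: `HQ = Exp / RfD`, with `RfD` the USEPA chronic oral
  reference dose. `HQ < 1` indicates an exposure unlikely to cause
  appreciable non-carcinogenic harm; the fraction of simulated trials with
  `HQ > 1` is the exceedance probability.

Uncertainty and population variability are propagated by Monte Carlo
simulation: each iteration draws an independent triple `(C, Iw, BW)` and
computes the resulting dose. The defaults follow common risk-assessment
practice for this setting:

| quantity | model | default | units |
|---|---|---|---|
| concentration `C` | lognormal, moment-matched to the survey mean/SD | per parameter | mg/L |
| intake `Iw`, adults | uniform | 0.5–2 | L/day |
| intake `Iw`, children 1–3 | uniform | 0.25–1.0 | L/day |
| body weight, adult male | lognormal, median/P95 | 80 / 100 | kg |
| body weight, adult female | lognormal, median/P95 | 65 / 85 | kg |
| body weight, child 1–3 | lognormal, median/P95 | 12.5 / 20 | kg |
| iterations | — | 100,000 | — |

Only the *range* of daily consumption is reported for the population
groups, so intake is modelled as uniform over that range — the
minimal-assumption reading; a triangular alternative is available
(`triangular_spec()`) for sensitivity analyses. Body weights reported as
"median m, 95th percentile q" map exactly onto a lognormal via
`mu = ln m`, `sigma = ln(q/m)/z0.95`.

## Parameterizing concentrations from summary statistics

When only per-parameter summary tables are available (the usual situation
for published surveys), `lognormal_from_mean_sd()` matches the lognormal's
analytic moments to the reported mean and SD:

```{r}
no3 <- lognormal_from_mean_sd(112, 74)   # nitrate, mg/L
c(meanlog = no3$meanlog, sdlog = no3$sdlog, median = dist_median(no3))
```

The implied median (93.4 mg/L) can be compared against the survey's
reported median (93 mg/L) as a consistency check. Moment matching is the
package's deliberate stand-in for fitting raw well data; it is also the
main source of residual discrepancy when comparing against analyses that
fit the raw measurements — summary-derived quantiles inherit the summary's
information loss, which is why desk-scale reproductions should be read
with a 20 % band on quantiles rather than to the printed digit. When raw
(possibly left-censored) values are available, `fit_lognormal()` fits the
log-moments after censor substitution; censored-likelihood (Tobit-style)
fitting is out of scope.

Microgram-per-litre parameters are converted to mg/L on spec construction
(factor 1e-3), so all exposure arithmetic is in mg/kg/day.

## Censoring and screening policy

Left-censored measurements (reported as below a detection limit) carry the
detection limit as their value plus a `censored` flag. Summaries
substitute limit/2 by default — the common environmental convention —
with full-limit and zero substitution selectable. A parameter censored in
*every* well is flagged all-censored and excluded from exposure
assessment: no distribution can be defended for a chemical never
quantified, and its dose is bounded above by the detection limit anyway.

Guideline screening flags a parameter whose mean is *strictly* above the
WHO guideline value; boundary equality does not flag, and a parameter
without a guideline yields an explicit "not screenable" status. One
shipped guideline value (Mn, 0.8 on a µg/L row) is stored exactly as
printed in the source survey although its magnitude is inconsistent with
WHO practice; it is annotated rather than silently corrected, so screening
against it is conservative.

## The synthetic survey generator

The generator (`generate_wells()`) emulates the study conditions of a
115-well stratified municipal survey: 30/34/18/22/11 wells across five
governorates, independent lognormal marginals per parameter matched to the
target mean/SD, six trace metals (Al, As, Cd, Co, Ni, Pb) censored in
every well at their detection limits, and two single-well point-source
detections (PO4 at 72 mg/L, Cu at 18 µg/L). Design choices where the
emulated survey is silent:

* **Independence.** Parameters are sampled independently across wells and
  across each other. Real wells are spatially autocorrelated and major
  ions co-vary strongly (Cl–Na under seawater intrusion), so passing tests
  on synthetic data demonstrate the pipeline's arithmetic, not robustness
  to correlated inputs.
* **Stratum assignment** is deterministic: wells fill governorates in
  contiguous blocks sized by the configured counts. No spatial gradient is
  modelled.
* **Clipping** to the target [min, max] is off by default because clipping
  shifts the matched moments; moment-recovery checks therefore run
  unclipped.
* **Detection limits for the point-source parameters** are not reported in
  the emulated survey; the generator uses synthetic defaults (PO4
  0.01 mg/L, Cu 0.1 µg/L) for the censored balance of those wells.

A fixed seed makes the generated table byte-identical across runs.

## Numerical choices

* Empirical quantiles use linear interpolation between order statistics
  (`stats::quantile` type 7), the convention of the spreadsheet-style
  Monte Carlo tools this workflow descends from; the estimator is
  selectable in `percentile_table()`.
* Draws are inverse-CDF transforms of a seeded uniform stream. This makes
  cross-scenario comparisons with a shared seed *common-random-number*
  comparisons: the concentration draws coincide exactly, so
  `relative_exposure()` isolates the scenario parameters (intake, body
  weight) from sampling noise.
* `HQ` percentiles are computed from the HQ draws but are, by monotonicity
  of the division, exactly the exposure percentiles divided by the RfD;
  the identity is asserted internally at every call.
* Exceedance uses a strict `>`; ties count as non-exceeding. A binomial
  standard error accompanies every exceedance estimate.
* Degenerate inputs are explicit: `sd = 0` produces a flagged point mass
  (used for single-detection point sources, where one observation cannot
  support a distribution), and a point mass at zero is admitted as
  `lognormal_spec(-Inf, 0)`.
* The Ag reference dose ships as the standard USEPA IRIS value
  5.0e-3 mg/kg/day, with a message on load and a config override.

## Open modelling questions, resolved

* Concentrations are fit **pooled over all wells**, not stratified by
  governorate — the per-stratum sample sizes (11–34) are too small to
  support 17 separate stratified fits, and the assessment question is
  population-wide.
* The reported ~18.7 % exposure increase for adult women is not
  reproducible from the stated scenario parameters: the body-weight median
  ratio 80/65 implies ~ +23 % at the median (the package computes ≈ +23 %),
  and P95-weight logic ~ +17.6 %. `relative_exposure()` reports the
  computed value; the discrepancy is documented, not forced.
* Alternate intake benchmarks (WHO/EFSA nitrate ADI 3.7 mg/kg/day, EFSA
  fluoride adequate intake 0.05 mg/kg/day — the latter covering *all*
  exposure sources, not just water) are reported alongside the USEPA RfDs,
  never substituted for them.

## Problem sizes and limitations

The test suite and the reproduction script run every simulation at the
assessment's native size of 100,000 iterations, where Monte Carlo noise on
the reported quantiles is below 1 % — negligible against the 20 % band
that summary-based parameterization warrants. Generator moment-recovery
checks use 200,000 synthetic wells, the size at which a 1 % relative band
on the SD of a heavy-tailed lognormal is a ≥3-sigma statement.

Out of scope by design: carcinogenic (slope-factor) risk, hazard-index
summation across chemicals, dermal and inhalation routes, dietary/soil/dust
ingestion, spatial interpolation and source attribution, and
censored-likelihood distribution fitting. Exposure estimates here cover the
drinking-water route only and therefore bound total intake from below.
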