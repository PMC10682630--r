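# dwrisk

Probabilistic human-health risk assessment of drinking-water contaminants,
built around a 115-well groundwater survey of the Gaza Strip, where
municipal groundwater is the main drinking-water source and is contaminated
by both natural inputs (seawater intrusion, fluoride-bearing minerals) and
anthropogenic ones (septic-tank nitrate, point-source phosphate).

The package is for environmental-health analysts who have per-parameter
summary statistics (or well-level measurements) of a water supply and want:

1. **Guideline screening** — which parameters' mean concentrations exceed
   WHO drinking-water guideline values;
2. **Probabilistic exposure** — Monte Carlo chronic daily intake through
   drinking water,

   `Exp_i = C_i × I_w / BW`  (mg per kg body weight per day),

   with the concentration `C_i` (mg/L) lognormal, the intake `I_w` (L/day)
   uniform over the reported consumption range, and the body weight `BW`
   (kg) lognormal, all sampled independently;
3. **Risk characterization** — hazard quotients against USEPA chronic oral
   reference doses,

   `HQ_i = Exp_i / RfD_o,i`,

   with `HQ < 1` indicating non-risky exposure, plus exceedance
   probabilities `Pr(Exp > threshold)` against the RfD and alternate
   benchmarks (WHO/EFSA nitrate ADI 3.7 mg/kg/day, EFSA fluoride adequate
   intake 0.05 mg/kg/day), for three population groups: adult male, adult
   female and children aged 1–3.

A synthetic well-measurement generator emulates the survey itself
(115 wells stratified 30/34/18/22/11 across five governorates, lognormal
marginals matched to each parameter's mean/SD, six fully left-censored
trace metals, single-well point-source detections of PO4 and Cu), so the
whole pipeline is testable without the raw field data.

## Worked example

```r
library(dwrisk)

tab <- gaza_summary(quiet = TRUE)                 # packaged survey summaries
no3 <- conc_spec_from_row(tab[tab$parameter == "NO3", ])  # lognormal, mg/L
dist_median(no3)
#> [1] 93.44556        # implied median, consistent with the surveyed 93 mg/L

sc <- default_scenarios()
ex <- sample_exposure(no3, sc$adult_male, n_iter = 1e5, seed = 1,
                      parameter = "NO3")
signif(ex$summary, 3)
#>   mean     sd    p25    p50    p75    p90    p95    p99
#>  1.760  1.410  0.835  1.380  2.240  3.440  4.440  7.050
```

The adult-male nitrate intake has a median of about 1.4 mg/kg/day —
close to the 1.6 mg/kg/day reference dose — and a long upper tail.

```r
hq <- hazard_quotient(ex, rfd = 1.6)
hq$summary[["p50"]]
#> [1] 0.8608345       # median HQ just below 1
100 * exceedance_probability(ex, 1.6)$fraction
#> [1] 41.841          # % of trials above the reference dose

relative_exposure(sc$adult_male, sc$child_1_3, no3, n_iter = 1e5, seed = 1)
#> [1] 219.2639        # children's median intake ~220 % above adult males'
```

The full pipeline (screening, three scenarios, exposure and HQ tables,
exceedance report, provenance log) runs in one call:

```r
res <- run_pipeline(run_config(n_iter = 1e5, seed = 42, out_dir = "report"))
```

or from a shell via the bundled script:

```sh
exec/dwrisk report --iterations 100000 --seed 42 --out report
exec/dwrisk screen
exec/dwrisk generate --out wells.csv --seed 1
```

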