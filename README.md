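# plaqmir

Statistical pipeline for circulating-microRNA biomarker studies of
lipid-rich coronary plaques.

Lipid-rich coronary lesions — plaques whose near-infrared spectroscopy
lipid core burden index over the worst 4 mm segment (maxLCBI<sub>4mm</sub>)
reaches **324.7** — predict future coronary events, but finding them
requires invasive imaging. Studies of this design ask whether circulating
plasma miRNAs, measured by qPCR on a fixed panel (177 assays plus spike-in
and no-template controls), discriminate patients with and without such
plaques. `plaqmir` implements that entire analysis as a tested, reusable R
package for biostatisticians working with small case–control qPCR panels:

- **Cq quality control** — no-template-control detection rule
  (`Cq ≤ NTC − 5`), spike-in deviation checks, hemolysis indicator
  `Cq(miR-23a-3p) − Cq(miR-451a)`;
- **global-mean normalization** —
  `ΔCq = mean Cq of always-detected assays − assay Cq` per sample, with an
  80% detection filter, limit-of-detection imputation at the per-assay
  minimum, and a NormFinder-style reference-stability ranking;
- **univariable screen** — Shapiro–Wilk-routed Welch t / Mann–Whitney U
  tests with Benjamini–Hochberg FDR control, chi-square baseline
  comparisons, Spearman dependence;
- **elastic-net penalized logistic regression** — the core model,

  minimize (1/n) Σ<sub>i</sub> [log(1+e<sup>η<sub>i</sub></sup>) − y<sub>i</sub>η<sub>i</sub>] + λ(α‖β‖₁ + (1−α)/2 ‖β‖₂²),  α = 0.9,

  fitted by an in-package IRLS + cyclic coordinate-descent solver (Rcpp)
  with warm-started penalty paths, KKT certificates, and λ selected by
  stratified tenfold cross-validation repeated ten times, minimizing the
  averaged held-out binomial deviance;
- **bootstrap stability selection** — the full fitting procedure repeated
  on resampled cohorts; each variable reported by its percent presence
  (nonzero coefficient) across B resamples with its full-data odds ratio;
- **cross-validated ROC/AUC** with DeLong confidence intervals for a
  single-miR model versus a traditional lipid panel;
- a **synthetic-cohort generator** reproducing the study conditions
  (47 patients, lipid-rich prevalence 23/47, per-group maxLCBI moments
  153.0 (91.0) / 427.0 (85.8), ~160 of 177 assays passing detection,
  planted miR effects with calibratable odds ratios), so everything is
  testable without patient-level data.

## Worked example

```r
library(plaqmir)

cohort <- simulate_cohort(sim_config(seed = 42))   # 47 x 177 synthetic cohort
cfg    <- run_config(seed = 42, n_bootstrap = 200, bootstrap_cv_repeats = 2)
report <- run_pipeline(cohort$cq, cohort$patients, cfg)
report
#> <plq_report>
#>   retained assays: 160 | screen smallest adjusted p: 0.000
#>   top miR: hsa-miR-sim-101 (100.0% bootstrap presence, OR 25.98)
#>   AUC hsa-miR-sim-101: 0.84 (0.72-0.96) | lipid panel: 0.38 (0.21-0.55)

top_table(report$stability_mirs, 5)
#> # A tibble: 5 × 3
#>   variable        odds_ratio percent_presence
#>   <chr>                <dbl>            <dbl>
#> 1 hsa-miR-sim-101    26.0               100
#> 2 hsa-miR-sim-125     0.0950             99
#> 3 hsa-miR-sim-055     2.39               67.5
#> 4 hsa-miR-sim-061     0.487              66.5
#> 5 hsa-miR-sim-073     1.58               62.5

cohort$truth$planted$assay
#> [1] "hsa-miR-sim-101"
```

Reading the output: 160 of the 177 simulated assays pass the 80% detection
filter, mirroring the emulated panel. The generator planted one true effect
(`hsa-miR-sim-101`, a 0.9-Cq downshift in lipid-rich patients), and the
bootstrap stability ranking recovers it at rank 1: its coefficient stayed
nonzero in 100% of the 200 resamples, with a full-data odds ratio above 1
(higher abundance → higher odds of a lipid-rich plaque, 25.98 per ΔCq unit
at this seed's strong draw). The single-miR model's cross-validated AUC of
0.84 (DeLong 95% CI 0.72–0.96) beats the traditional lipid panel, whose
lipids are simulated independently of the outcome (AUC 0.38, i.e.
chance-level). Diagnostics chain in tidyverse style: `tidy()`, `glance()`
and `autoplot()` work on fits, CV curves, stability reports and ROC
results, and `write_report()` emits every table as TSV.

A thin command-line wrapper with `simulate`, `qc`, `normalize`, `screen`,
`fit`, `stabsel`, `roc` and `report` subcommands lives at
`inst/cli/plaqmir.R`.

See `vignettes/plaqmir-methods.Rmd` for the model, its assumptions, every
tunable parameter, and what the synthetic cohort does and does not emulate.

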