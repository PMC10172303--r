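---
title: "Statistical methods behind plaqmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind plaqmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaqmir)
```

## The problem

Lipid-rich coronary plaques — lesions whose near-infrared spectroscopy lipid
core burden index over the worst 4 mm segment (maxLCBI~4mm~, range 0–1000)
reaches at least 324.7 — carry an elevated risk of future myocardial
infarction, but identifying them requires invasive intracoronary imaging.
`plaqmir` implements the complete statistical workflow for asking whether
circulating plasma microRNAs, quantified by a fixed qPCR panel, discriminate
patients with and without such plaques in a small case–control cohort:
quality control and normalization of raw quantification cycles (Cq),
univariable screening with multiplicity control, penalized multivariable
selection with resampling-based uncertainty, and cross-validated predictive
evaluation. Because patient-level data for studies of this design are
typically available only on request, the package ships a synthetic-cohort
generator with the same statistical structure, so every stage is exercised
and tested end to end without any external data.

## From raw Cq to analysis-ready values

**Detection against the no-template control.** A reaction is trusted only if
its Cq undercuts the assay's negative-control background by a margin
(default 5 cycles), read inclusively: `Cq <= NTC - 5` stays detected. The
margin is configurable (`ntc_margin_cq`).

**Sample QC.** Spike-in RNAs (UniSp2/4/5 for extraction, UniSp6 for reverse
transcription, UniSp3 for qPCR) are added at fixed amounts; a sample is
flagged when any spike-in deviates from the cohort median by more than 2 Cq
(configurable). Hemolysis is screened by
`Cq(miR-23a-3p) - Cq(miR-451a)` — miR-451a is strongly enriched in
erythrocytes — with the conventional warn level above 5 ΔCq and failure
above 7. Failing samples are excluded and logged; they are never imputed.
The thresholds are vendor conventions rather than settled science, which is
why all three live in `run_config()`.

**Detection filter.** Target assays detected in at least 80% of samples
(boundary inclusive) enter the analysis; spike-ins never do.

**Global-mean normalization.** The per-sample reference is the mean Cq over
all target assays detected in *every* sample, and

$$\Delta Cq_{ij} = \overline{Cq}_i^{\,\text{(global)}} - Cq_{ij},$$

so larger values mean higher abundance and any additive per-sample technical
offset cancels exactly — a property the test suite checks to machine
precision. A NormFinder-style stability ranking (below) is computed to
*verify* that the global mean is a defensible reference, but the global mean
remains the normalizer regardless of the ranking.

**Limit-of-detection imputation.** Undetected cells of a retained assay
receive the assay's lowest measured concentration, i.e. its minimum observed
ΔCq. Imputation happens on the normalized scale: imputing raw Cq (per-assay
maximum) and normalizing afterwards would inject each sample's technical
offset into the imputed cells. Whether "lowest measured concentration"
should be cohort-internal or assay-specification-based is not decidable from
the study design; the cohort-internal minimum was chosen.

**Reference stability.** The ranking follows the NormFinder variance
decomposition: expression values are centered per sample across the $k$
candidates, intragroup variances are estimated with the correction
$\hat\sigma^2 = (v - \sum_l v_l / (k(k-1))) / (1 - 2/k)$ (floored at zero),
the intergroup difference of group means is shrunken by its estimated
signal-to-noise ratio, and the stability value is
$|\tilde d| + \sqrt{\hat\sigma_1^2/n_1 + \hat\sigma_2^2/n_2}$ — lower is
more stable. Both the grouped and an ungrouped variant are reported; the
grouped value drives the ranking. The decomposition needs at least three
candidates and three samples per group.

## Univariable screening

Each retained assay is compared between outcome groups. Normality is
screened per group by Shapiro–Wilk at level 0.05 (constant vectors, where
the test is undefined, route directly to the rank test); if either group
rejects, the Mann–Whitney U test is used, otherwise a t test — Welch by
default, since equal variances are an unnecessary assumption at this sample
size (`welch_t = FALSE` restores the pooled test). The Mann–Whitney p-value
is exact (full enumeration of group assignments, ties handled by half
counts) when the smaller group has at most 8 observations, and otherwise
uses the tie-corrected normal approximation without continuity correction.
Benjamini–Hochberg adjustment is applied across all retained assays at an
FDR of 0.05. Baseline characteristics are compared the same way, with
binary variables tested by Pearson chi-square *without* continuity
correction — the variant that reproduces published two-group frequency
comparisons of this design at the printed precision. Dependence among
selected markers is summarized by Spearman rank correlation.

## Penalized multivariable model

The core model is elastic-net penalized logistic regression. With predictors
standardized to mean zero and population (1/n) unit variance, the package
minimizes

$$\frac{1}{n}\sum_i \left[\log(1 + e^{\eta_i}) - y_i \eta_i\right]
  + \lambda\left(\alpha \lVert\beta\rVert_1 +
  \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\right),
  \qquad \eta = \beta_0 + X\beta,$$

with the intercept unpenalized. The default mixing parameter is
$\alpha = 0.9$ — a model much closer to the lasso than to ridge, so weak
predictors are set exactly to zero (odds ratio exactly 1) while the small
ridge component keeps correlated predictors stable. Coefficients are
reported on the original predictor scale, so $e^{\beta_j}$ is the odds
ratio of a lipid-rich plaque per unit increase of variable $j$ (per ΔCq
unit for a miRNA).

The solver is an outer iteratively-reweighted quadratic approximation
(weights $p(1-p)$, working response) with inner cyclic coordinate descent
and soft-thresholding, warm-started along a descending 100-point
log-spaced penalty path from the data-derived ceiling
$\lambda_{\max} = \max_j |n^{-1}\sum_i x_{ij}(y_i - \bar y)| / \alpha$ down
to $0.01\,\lambda_{\max}$ — conventional path defaults for the $p > n$
regime, both configurable. Numerical choices: coordinate updates iterate to
a $10^{-9}$ change tolerance (relaxed to $10^{-8}$ inside cross-validation)
within a $10^5$-sweep budget; active-set cycling between full sweeps; the
linear predictor is capped at $\pm 30$ and IRLS weights floored at
$10^{-5}$ as divergence guards under separation; $\lambda_{\max}$ carries a
$1 + 10^{-10}$ relative guard so the first path point yields an exactly
zero coefficient vector despite floating-point round trips. Every returned
fit satisfies a Karush–Kuhn–Tucker certificate at $10^{-6}$
(`enet_kkt()`), and the test suite additionally pins the solver to an
unpenalized Newton fit at $\lambda = 0$, to a derivative-free minimizer of
the same objective at $\lambda > 0$, and to glmnet along the path.

**Penalty selection.** Tenfold cross-validation repeated ten times: each
repeat partitions the cohort into stratified folds (at 47 samples,
unstratified folds can lose an outcome class; stratification is the one
deviation from plain random folds, and fold counts reduce automatically if
a class is rarer than the fold count), computes for every penalty the mean
across folds of the held-out binomial deviance ($-2\times$ mean held-out
log-likelihood), and the selected $\lambda^\*$ minimizes the pointwise
average of the ten repeat curves, ties resolving to the more penalized end.
The grid is computed once from the full design so curves are comparable
across folds and repeats.

**Bootstrap stability.** The *entire* fitting procedure — grid, repeated
cross-validation, refit at the selected penalty — is repeated on bootstrap
resamples (default $B = 1000$); each variable's uncertainty is summarized
as the percentage of resamples in which its coefficient stayed nonzero.
Resamples that lose an outcome class (or produce a constant predictor) are
redrawn with a bounded, logged retry. Because a full penalty re-selection
per resample is expensive, `bootstrap_cv_repeats` provides a fast mode with
fewer repeats per resample; the faithful mode (equal to `cv_repeats`) is
the default. Rankings break ties by the larger absolute full-data
coefficient, then variable name, so reruns are reproducible. Two predictor
sets are fitted: the retained miRNAs alone, and the miRNAs plus 14
established cardiovascular risk factors (age, BMI, smoking, treated
hypertension, diabetes, hyperlipidemia, CVD heredity, previous CVD, total
cholesterol, LDL-C, HDL-C, triglycerides, the derived LDL/HDL ratio, and
lipoprotein(a)), standardized jointly with the miRNAs.

One note on conventions: descriptions of the elastic net sometimes state
the mixing parameter with the opposite orientation (an "$\alpha$" of 0.1
denoting the ridge share). `plaqmir` uses the glmnet convention throughout:
$\alpha = 1$ is the lasso, and the default 0.9 means 90% lasso.

## Predictive evaluation

The discriminative value of a selected marker is estimated by stratified
tenfold cross-validation repeated ten times: in each repeat every sample
receives the held-out predicted probability from an unpenalized
maximum-likelihood logistic fit on the training folds, and the final score
is the per-sample mean over repeats (the scheme is pinned in
`run_config()`; the study design this emulates states only
"cross-validation"). Training splits with separation fall back to a lightly
ridge-stabilized fit, which is logged. The ROC curve comes from a threshold
sweep, the AUC equals the tie-corrected rank statistic $U/(n_1 n_0)$, and
the 95% confidence interval uses the DeLong placement-value variance on the
pooled out-of-fold scores — an approximation, since a CI method for
*cross-validated* scores is not uniquely defined. A five-variable
traditional lipid panel (LDL-C, HDL-C, triglycerides, LDL/HDL,
lipoprotein(a)) serves as the comparison model.

## The synthetic cohort

`simulate_cohort()` emulates the data structure the analysis assumes, with
defaults fixed at the emulated study's conditions:

| Parameter | Default | Meaning |
|---|---|---|
| `n_samples` | 47 | cohort size |
| `group_prevalence` | 23/47 | lipid-rich component weight |
| `lcbi_means`, `lcbi_sds` | (153.0, 427.0), (91.0, 85.8) | per-group maxLCBI~4mm~ moments |
| `n_assays` | 177 | target assays on the panel |
| `frac_low_detection` | 17/177 | assays placed just above the limit of detection |
| `assay_baseline_range` | [22, 35] Cq | per-assay baseline abundance |
| `sample_offset_sd` | 0.5 Cq | per-sample technical offset |
| `noise_sd` | 0.8 Cq | per-reaction noise |
| `lod_cq` | 40 | limit of detection |
| `n_planted`, `planted_shift_cq` | 1, 0.9 | planted case effects |

maxLCBI~4mm~ is drawn from per-group zero-truncated normals and the label
re-derived from the 324.7 threshold, so label and value are always
consistent (re-thresholding pulls the expected label prevalence slightly
below the component weight — the tests check against the closed-form
adjusted expectation). Cq values are additive:
$Cq_{ij} = a_j + b_i + \delta_j g_i + \varepsilon_{ij}$, treating Cq as a
log2-scale abundance proxy so planted effects act linearly on the
normalized scale. Planted assays shift *down* in cases (lower Cq = more
abundant). Under the equal-variance two-class Gaussian model the implied
per-unit logistic coefficient is $\delta/\sigma^2$ with
$\sigma^2 = $ `noise_sd`$^2$ on the normalized scale, which
`plant_effect_or()` inverts to calibrate a target odds ratio. The within-
assay noise level is a free parameter, not an estimate — the emulated
design does not report one — and the hemolysis pair's baselines are pinned
near 24/23 Cq so the ΔCq indicator behaves like real non-hemolysed plasma.
Covariates are drawn independently from reported-style marginals (binary by
prevalence, continuous by mean ± SD with structural floors, e.g. HDL-C
bounded away from zero so the LDL/HDL ratio exists).

What the generator does *not* emulate: correlation among miRNAs beyond the
shared sample offset, covariate–covariate and covariate–outcome dependence,
assay-specific variance heterogeneity, plate or batch structure, and
NIRS-physics detail behind maxLCBI~4mm~. Passing tests therefore certify
the statistical machinery — calibration under the null, recovery of planted
effects, exactness of the algebraic invariants — not biological claims
about real cohorts.

## Problem sizes used by the tests and the acceptance script

Simulation-backed checks run at sizes chosen to give the relevant binomial
bounds real power while keeping a laptop-scale footprint: parameter
recovery uses 20 replicates of a 150-sample, 24-assay cohort with one
planted effect of twice the noise SD and $B = 200$ bootstrap resamples with
a single CV repeat per resample on a 50-point path; null calibration uses
30 replicates of the
default 47 × 177 cohort; the scaled faithful end-to-end run uses the
default cohort with $B = 200$ and two CV repeats per resample. The
acceptance script mirrors the scaled run and additionally recomputes the
six published 2 × 2 baseline comparisons from their printed counts.

Two empirical notes the tests encode deliberately: under a global null,
argmin-based penalty selection leaves the most-penalized decile of the path
in roughly a quarter of replicates (repeated `cv.glmnet` reproduces the
same selections on identical draws — a property of minimizing a flat,
noisy deviance curve, not an implementation artifact), and with 160
independent tests the Benjamini–Hochberg step-up makes at least one false
discovery in about 5% of null cohorts, exactly its design guarantee. The
corresponding tests assert these oracle-confirmed rates with binomial
slack rather than idealized ones.

## Known limitations

- The hemolysis and spike-in rules are vendor conventions; real QC
  pipelines may use different indicators or cut-offs.
- The DeLong interval on pooled out-of-fold scores ignores the dependence
  induced by cross-validation; it is reported as the conventional
  approximation.
- Bootstrap selection percentages inherit the penalty-selection noise of
  the fast mode when `bootstrap_cv_repeats < cv_repeats`.
- With 47 samples, stratified tenfold cross-validation leaves 4–5 samples
  per fold; fold-level deviance estimates are accordingly coarse, which is
  precisely why the repeat-averaged curve is used.
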