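# lymphodose

Dose-response modelling of **severe radiation-induced lymphopenia (SRIL)**
from the radiation dose received by circulating blood during fractionated
thoracic radiotherapy.

Circulating lymphocytes are exquisitely radiosensitive. Over a 25-30
fraction course, the blood pool sweeps through the treatment field during
every beam-on window, accumulating a heterogeneous dose that no
treatment-planning export records directly. The absolute lymphocyte count
(ALC) falls roughly exponentially during treatment; when it drops below
500 cells/uL (CTCAE v5.0 grade >= 3), the patient has SRIL — an outcome
associated with worse survival and blunted immunotherapy response.
`lymphodose` is for medical physicists and outcome modellers who want to
estimate blood dose from standard organ DVHs and model SRIL risk from it.

## What the package implements

**Blood-dose simulation.** A Monte Carlo renewal Markov compartment model:
blood parcels occupy compartments (lungs, heart, great vessels, liver, an
out-of-field remainder — an editable JSON config) in proportion to their
blood volume, dwell exponential transit times, and during each fraction's
beam delivery time (BDT) accrue dose sampled from the organ's per-fraction
differential DVH, one voxel-dose draw per organ visit. The output is the
whole-blood differential DVH and its metrics (mean dose, gEUD, D_n%,
V_nGy).

**The LKB NTCP model.** The blood DVH is reduced to a generalized
equivalent uniform dose,

    gEUD(a) = (sum_i v_i * D_i^a)^(1/a),

and SRIL probability follows a probit dose-response,

    NTCP = Phi((gEUD - D50) / (m * D50)),

with D50 the dose at 50% risk, m the slope, and a the volume-effect
exponent. All three parameters are fitted by maximum likelihood
(Nelder-Mead on the Bernoulli negative log-likelihood, 42-point restart
grid, log-space positivity), freely or with `a` held fixed, with
percentile-bootstrap 95% confidence intervals.

**Validation and calibration.** ROC AUC (Mann-Whitney form), Brier score,
outcome-stratified k-fold cross-validation, a chi-square goodness-of-fit
test on mean-blood-dose bins, calibration deciles with Wilson 95%
intervals, a LOWESS calibration curve, calibration slope/intercept from a
logistic fit of outcomes on logit predictions, and frozen-parameter
external validation for cross-modality transfer.

**Cohort statistics and synthetic data.** CTCAE lymphopenia grading,
ALC exponential-decay kinetics, logistic regression with odds ratios,
median dichotomization, Bonferroni adjustment, ANOVA by grade; plus a
synthetic cohort generator with known ground truth that emulates
photon-like (broad low-dose bath) and proton-like (steep fall-off)
blood-dose distributions, so the entire pipeline is testable without
patient data.

## Worked example

Generate a photon-like cohort of 94 patients with known truth
(D50 = 7.44 Gy, m = 0.42, a = 2), fit the LKB model, and evaluate it:

```r
library(lymphodose)

truth  <- truth_spec(lkb = lkb_params(7.44, 0.42, 2))
photon <- generate_cohort(94, modality_profile("photon_like"), truth, seed = 1)
coh    <- as_lkb_cohort(photon)

fit <- fit_lkb(coh, n_boot = 200, seed = 1)
print(fit)
#> LKB probit NTCP fit
#>   D50 = 7.576 Gy, m = 0.453, a = 2.500
#>   NLL = 49.9923; converged: TRUE; identifiable: TRUE; restarts: 42
#>   bootstrap 95% CIs:
#>   parameter        lo         hi
#> 1       d50 5.9452277 10.1770634
#> 2         m 0.2998215  0.7621742
#> 3         a 1.6557610  7.2856207

probs <- ntcp_probit(cohort_geud(coh, fit$params$a), fit$params)
roc_auc(probs, coh$outcomes)                 # 0.793
brier_score(probs, coh$outcomes)             # 0.180
chisq_gof(coh, fit$params)[c("chi2", "p")]   # chi2 0.070, p 0.966
stratified_kfold_cv(coh, k = 5, seed = 2)$mean_auc   # 0.771

fit_alc_decay(split(photon$alc[c("day", "alc")], photon$alc$id))
#> lambda = 0.0667 / day, half-time 10.39 days
```

Reading the numbers: the fit recovers the generating parameters within
their (wide, strongly correlated) confidence intervals — the (D50, a) pair
sits on a flat likelihood ridge, so expect a broad interval on `a`. An AUC
near 0.8 and a goodness-of-fit chi-square near zero (p ~ 1) indicate good
discrimination and bin-level calibration; the ALC decay fit returns the
cohort-average exponential rate, here a ~10-day half-time.

The full pipeline (two-modality synthesis, photon fit, evaluation, and
cross-modality external validation with calibration slope/intercept) runs
as one call:

```r
bundle <- run_pipeline(run_config(seed = 1, out_dir = "out", fix_a = 19.85))
```

A thin command-line dispatcher with subcommands `synth`, `simulate-blood`,
`fit`, `evaluate`, `validate-external` and `report` is installed at
`inst/cli/lymphodose.R`.

See `vignettes/blood-dose-ntcp.Rmd` for the model assumptions, numerical
choices, and what the synthetic cohorts do and do not emulate.

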