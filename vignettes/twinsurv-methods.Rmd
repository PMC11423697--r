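---
title: "Survival EWAS and risk prediction in twin cohorts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival EWAS and risk prediction in twin cohorts: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`twinsurv` implements a survival epigenome-wide association (EWAS) and risk
prediction workflow for twin cohorts in which a rare malignancy competes with
death. This vignette is the package's account of the science: the models and
their assumptions, the parameters that matter, what the synthetic generator
does and does not emulate, and the design decisions taken where more than one
reasonable choice existed.

## The analytical problem

The workflow targets register-based twin studies in which blood DNA
methylation (Illumina-450K-style beta-values in [0, 1]) is measured once at
study entry and individuals are followed for incidence of a rare cancer —
on the order of 3% of subjects over ~15 years — while a substantial fraction
die of other causes first. Three features shape every stage:

1. **Twin pairing.** Members of a pair are correlated in methylation and
   share unmeasured confounders (germline genotype, early environment).
   Pairing is exploited (matched cotwin analyses, intraclass correlations)
   and must be respected wherever independence is assumed (robust variance,
   resampling).
2. **Competing risk of death.** Association is therefore read on two scales:
   the cause-specific hazard (Cox, deaths censored) and the subdistribution
   hazard (Fine-Gray, deaths retained in the risk set with
   inverse-probability-of-censoring weights).
3. **Genome-scale multiplicity with very few events.** Hundreds of thousands
   of tests against a few dozen events force both FDR control and a
   conservative fixed p-value rule applied on both scales simultaneously.

## Models

### Preparation of model inputs

Missing beta-values (missing completely at random, up to a few percent) are
imputed per CpG by ordinary least squares on sex, age at blood sampling,
zygosity, data-set label and the three measured cell fractions (monocytes,
lymphocytes, eosinophils); imputed values are clamped to [0, 1] and observed
cells are never touched. The completed matrix is then adjusted per CpG by a
linear mixed model with the same fixed effects plus random intercepts for
sample plate and array position, fitted by REML (`lme4`); the conditional
residual (observed minus fixed-effect fit minus predicted random effects) is
standardized to sample SD one (denominator `n - 1`; the convention had to be
fixed, and the sample SD is the common one). These standardized residuals
are the inputs of every downstream model. Exposure for the causal contrast
is the residual dichotomized at zero, with a residual of exactly zero
assigned to the "high" group — an arbitrary but fixed boundary convention.

Two numerical policies are worth stating. A mixed-model fit that fails to
converge for a CpG falls back to the fixed-effects-only least-squares fit,
with a warning naming the CpGs affected; a singular (zero) variance
component, common when batch effects are weak, is accepted as a valid
boundary fit. And because the REML residual uses shrunken (BLUP) random
effects, re-residualizing the output moves it only marginally (order 1e-3 at
desk scale) rather than reproducing it exactly: shrinkage deliberately
leaves a small share of batch-level signal in the residual.

### The dual-model screen

For each CpG the standardized residual enters, alone, a Cox model and a
Fine-Gray model of time since blood sampling to malignancy, both with a
cluster-sandwich variance aggregating score residuals within twin pairs.
No further covariates enter: residualization already removed them (a
covariate-adjusted variant would be a trivial extension of the same loop).
"Cox frailty with robust variance" is implemented as the marginal Cox model
with pair-robust standard errors — the reproducible reading of that pairing
of terms — with a shared gamma-frailty fit available behind the `frailty`
flag. Ties are handled by Efron's method in the Cox fits and Breslow's
within the weighted Fine-Gray fit, the standard choice for IPCW
subdistribution estimation; the Fine-Gray censoring weights come from the
overall (not covariate-stratified) Kaplan-Meier estimator of censoring.

Benjamini-Hochberg adjustment is applied separately per scale across all
CpGs, and a CpG is significant when FDR < 0.05 on **both** scales and both
unadjusted p-values fall below the dual threshold (1e-7 by default). That
fixed threshold is calibrated to a ~450,000-site screen; at the desk scales
of the simulations it is exposed as configuration and relaxed
proportionally (e.g. 1e-3 with tens of CpGs), which changes the stringency,
not the logic. Proportional hazards are then checked only on the
significant set (Grambsch-Therneau scaled Schoenfeld score test,
Kaplan-Meier time transform by default), and markers failing it at the 0.05
level are excluded from the validated set.

### Causal contrast, twin correlations and the matched analysis

The average causal exposure effect is a ratio of standardized risks at a
fixed horizon (5 years by default): a Fine-Gray model with the binary
exposure is fitted, the baseline cumulative subdistribution hazard is
estimated by the weighted Breslow estimator, each subject's model-based
cumulative incidence at the horizon is evaluated under exposure forced high
and forced low, and the two counterfactual risks are averaged over the
cohort before taking their ratio. This standardization (G-computation)
estimator is the package's realization of causal effect estimation on the
subdistribution model; structural-nested G-estimation proper is out of
scope. Uncertainty comes from a nonparametric bootstrap that resamples
**pairs**, never individuals (500 replicates by default, percentile CI; the
p-value uses a normal approximation on the log ratio, since no significance
convention is otherwise implied).

Within-pair similarity is quantified by the double-entry Pearson
correlation per zygosity — the standard twin-methylation ICC — with
Fisher-z intervals using the number of pairs as the effective sample size.
Under the polygenic (ADCE) variance-components model the MZ correlation
upper-bounds heritability, and it is reported as exactly that bound, not as
a biometric decomposition. The matched cotwin analysis fits pair-stratified
Cox models (a separate baseline hazard per pair), so only event-containing,
covariate-discordant pairs contribute; it removes confounding shared within
pairs at the price of discarding all between-pair information, which is why
the unmatched regression is always reported alongside.

### The predictor

Candidates for the predictor are the CpGs passing the dual unadjusted-p
rule. The model is an L1-penalized Cox regression (glmnet) with sex and age
at blood sampling exempt from the penalty, so they are always in the model.
The smoothness parameter is chosen per fit by 10-fold cross-validation with
folds assigned by pair, under the rule "largest lambda whose CV deviance
lies within half a standard error of the minimum" — the within-k-SE family
with k = 0.5, which is how the "minimizer plus half a standard error"
prescription is read here; the literal alternative (adding half the SE to
the minimizing lambda as a number) is implemented behind a flag for
sensitivity. Stability selection runs 1,000 replicates (100 in the
simulations) of this procedure on random half-samples drawn **by pair**,
and CpGs selected in strictly more than 80% of replicates form the
predictor; replicates whose half-sample holds too few events are redrawn
and counted. The selected set is refit as an ordinary multivariable Cox
model with pair-robust standard errors, whose linear predictor is the risk
score.

Validation uses pair-blocked 5-fold cross-validation: out-of-fold risk
scores are pooled and scored by Harrell's C and by the time-varying AUC,
always against the basic sex + age model fitted on the same folds. The
time-varying AUC is the cumulative-cases / dynamic-controls estimator with
inverse-probability-of-censoring weights from the Kaplan-Meier estimator of
censoring; subjects dead of the competing cause by the horizon are retained
as controls (the cause-specific cumulative/dynamic convention — one of
several defensible conventions, fixed and documented here). External
validation refits the selected CpGs (plus sex and age) on the external
cohort without re-estimating the selection, drops and logs model CpGs
absent from the external array, and reports per-CpG and combined Harrell's
C against the basic model.

## The synthetic twin generator

Because the motivating data class is access-restricted registry data, the
package ships a seeded generator that reproduces the statistical structure
the analysis assumes; it is first-class, tested code, and all acceptance
checks run on it.

* **Within-pair correlation.** Each CpG's latent signal is a pair-shared
  plus an individual standard-normal component, mixed so the within-pair
  correlation is exactly `icc_mz` (default 0.34, a representative upper end
  of observed MZ correlations for disease-associated CpGs) or `icc_dz`
  (default 0.17, consistent with additive-genetic sharing and no shared
  environment). The config exposes the ICCs directly rather than A/C/E
  shares because only the ICCs are interpreted downstream.
* **Beta scale.** Latent signals map to beta-values through a clamped
  affine transform into [0.05, 0.95] (per-CpG mean in [0.15, 0.85], scale
  in [0.03, 0.08]), keeping the [0, 1] invariant testable while distorting
  correlations negligibly. Plate shifts (twin pairs share a plate, as on
  real arrays) and random per-CpG loadings on centred cell fractions are
  added on the beta scale; both are removed again by residualization.
* **Event law.** Cause-1 (malignancy) times follow a proportional
  subdistribution hazards mixture: the total cause-1 probability for linear
  predictor eta is `1 - (1 - p)^exp(eta)` with
  `p = 1 - exp(-base_rate_cause1 * admin_censor_years)`, and the
  conditional time distribution uses rate `3 / admin_censor_years`, placing
  ~95% of eventual cause-1 mass inside follow-up. This indirect
  construction makes the planted sHR and the counterfactual cumulative
  incidences exactly known (`true_cause1_cif()`), so recovery and
  G-computation tests have closed-form truth; a cause-specific-hazards
  generator would not give that. Cause-2 (death) times are independent
  exponentials (default 0.03/year, ~36% mortality over 15 years, plausible
  for an elderly twin panel), and administrative censoring falls at 15
  years. The default cause-1 base rate (0.0013/year) was set so that the
  *marginal* malignancy fraction under the default causal architecture —
  five causal CpGs with sHRs 0.58-1.60 per SD, the observed range for
  screened markers — lands near the motivating 3% (~31 events per ~1,085
  subjects); the causal effects inflate the marginal rate above the
  baseline via the expectation of `exp(eta)`.
* **Missingness** is missing-completely-at-random at 2.7% by default.
* **One seed** governs everything, with per-stage sub-streams derived
  deterministically, so a cohort is byte-identical under a fixed seed.
* **Pair-level outcome dependence** beyond the methylation path is off by
  default (`pair_frailty_sd = 0`): the real within-pair correlation of
  outcome times is unknown, so the generator leaves it as an explicit,
  default-off parameter.

What the generator does **not** emulate: array chemistry and probe types,
QC failures, non-MCAR missingness, cell-type deconvolution error,
age-dependent mortality, delayed entry, and real LD-like correlation
between CpGs (sites are independent given the pair structure). Passing
tests therefore demonstrate statistical correctness of the estimators under
the assumed structure, not robustness to those real-data pathologies.

## Numerical choices and known limitations

* All fits are deterministic given their inputs; every source of
  randomness (generation, subsampling, folds, bootstrap) takes an explicit
  seed, and reruns of the full pipeline are hash-identical.
* Monotone partial likelihoods (perfect separation, common in tiny strata
  and rare-event subsets) are flagged on the fit object rather than raised,
  and the corresponding warnings are muffled inside loops where they are
  expected behaviour.
* With ~150 events at n = 5,000, Cox-type estimators show the usual mild
  rare-event attenuation of the log (s)HR toward zero (about -0.03 to
  -0.04 for a planted log 2); it vanishes by n = 200,000. The same
  attenuation propagates to the G-computation ratio. It is a property of
  partial-likelihood estimation at low event counts, not of the generator.
* Cluster-robust Wald tails are mildly liberal when events are very few;
  the FDR-calibration simulation therefore uses screens with ~200 events
  (300 pairs at a raised event rate), where Benjamini-Hochberg control
  holds. At genome scale the dual 1e-7 rule adds a second guard precisely
  because of this tail sensitivity.
* The AUC bootstrap CI resamples pairs and is off by default (`n_boot = 0`)
  because the point estimator is what validation compares; the asymptotic
  variance of the weighted two-sample statistic is not implemented.
* Problem sizes in the shipped tests and the acceptance script are chosen
  as desk-scale study conditions: cohorts of 120-2,500 pairs, screens of
  20-200 CpGs, 100 stability replicates, 10-30 simulation replicates per
  recovery check. They are stated here as the package's own simulation
  design.

## Session

```{r}
library(twinsurv)
cohort_config(n_pairs = 50, n_cpgs = 20, n_causal = 1,
              causal_log_shr = log(2), seed = 1)
```
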