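# twinsurv

Survival epigenome-wide association analysis and risk prediction for twin
cohorts with a rare malignancy outcome and competing risk of death.

## The problem

Register-based twin studies measure blood DNA methylation (CpG beta-values
in [0, 1]) once at study entry and follow individuals for decades, during
which a small fraction (~3%) develop a hematopoietic malignancy and many die
of other causes first. Finding methylation markers of future malignancy in
such data requires, simultaneously: per-CpG time-to-event regression on two
scales — the cause-specific hazard (Cox; HR) and the subdistribution hazard
(Fine–Gray; sHR, where deaths remain in the risk set with Kaplan–Meier
censoring weights) — with variance estimates robust to twin-pair clustering;
genome-scale multiple-testing control (Benjamini–Hochberg FDR plus a dual
unadjusted-p rule on both scales) and a scaled-Schoenfeld proportional-
hazards filter; causal risk contrasts by G-computation on the Fine–Gray
model (average of counterfactual 5-year cumulative incidences under
exposure forced high vs low, pair-bootstrap uncertainty); twin-design
quantities (double-entry intraclass correlations by zygosity, whose MZ
value upper-bounds heritability under the polygenic model, and matched
case–cotwin stratified Cox analyses); and a stability-selected LASSO-Cox
predictor with sex and age forced in, chosen by the "within half a standard
error" cross-validation rule on half-samples drawn by pair, validated with
pair-blocked cross-validated Harrell's C and IPCW time-varying AUC, plus an
external-cohort protocol that tolerates missing array sites.

Because the motivating registry data are access-restricted, the package
also ships a seeded synthetic twin-cohort generator with the matching
statistical structure: ACE-style within-pair CpG correlation (MZ/DZ),
plate and cell-composition effects, MCAR missingness, and event times drawn
from a proportional subdistribution hazards law with closed-form truth
(`true_cause1_cif()`), so every estimator is testable end to end.

## Worked example

```r
library(twinsurv)

cfg <- cohort_config(n_pairs = 300, n_cpgs = 50, n_causal = 2,
                     causal_log_shr = log(c(2.5, 0.5)),
                     base_rate_cause1 = 0.004, seed = 42)
sim <- simulate_cohort(cfg)
sim
#> Synthetic twin cohort: 600 individuals (300 pairs), 50 CpGs
#>   events: 360 censored, 49 malignancy, 191 death
#>   causal CpGs: 2; missing cells: 2.72%

complete <- impute_missing(sim$methylation, sim$phenotypes)
resid    <- residualize(complete, sim$phenotypes)

scan <- run_ewas(resid, sim$outcomes, sim$phenotypes,
                 ewas_config(dual_p_threshold = 1e-3))  # desk-scale threshold
scan
#> EWAS screen: 50 CpGs, 49 events; 2 significant, 2 passing the PH filter
#>     cpg_id     hr      hr_p    shr     shr_p    fdr_hr   fdr_shr   ph_p ...
#> 1 cg000019 2.1767 1.636e-08 2.2016 1.980e-08 8.178e-07 9.901e-07 0.1392
#> 2 cg000037 0.5123 9.741e-05 0.5128 1.096e-04 2.435e-03 2.739e-03 0.1126

markers <- select_markers(scan)   # both planted causal CpGs, nothing else
```

Both reported sites are the planted causal CpGs (true sHR 2.5 and 0.5 per
SD); `hr`/`shr` are their per-SD hazard and subdistribution hazard ratios,
and the PH test does not reject proportionality for either. The causal risk
ratio at 5 years for the first marker, with pair-bootstrap CI:

```r
expo <- dichotomize(resid)
ate_risk_ratio(expo[, markers[1]], sim$outcomes$time, sim$outcomes$event,
               sim$phenotypes$pair_id, horizon = 5, n_boot = 200, seed = 7)
#> G-computation ATE risk ratio at 5 years: 3.068 (95% CI 1.845-5.623, p = 0.000454)
#>   counterfactual risks: high 0.0925, low 0.0302 (200 pair-bootstrap reps)
```

i.e. subjects with high methylation at this site carry about three times
the 5-year malignancy risk of those with low methylation. Predictive value
of the two markers together, by pair-blocked cross-validation against the
basic sex + age model:

```r
cross_validate(markers, resid, sim$outcomes, sim$phenotypes,
               k = 5, horizons = c(3, 5, 8), seed = 9)
#> 5-fold pair-blocked cross-validation
#>   Harrell's C: full model 0.741, basic (sex + age) 0.480
#>   time-varying AUC (full | basic):
#>       3.0 yr: 0.762 | 0.463
#>       5.0 yr: 0.717 | 0.470
#>       8.0 yr: 0.743 | 0.482
```

The basic model sits at chance (the generator gives sex and age no effect
by default); the methylation markers lift discrimination to C ≈ 0.74.
`run_pipeline()` chains all stages — simulate/load, preprocess, EWAS,
causal/twin analyses, predictor, external validation — writing fixed-format
CSV/TSV outputs and an MD5 manifest; reruns with the same config and seed
are hash-identical.

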