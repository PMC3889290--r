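# curemix

Survival analysis for oncology cohorts that contain **long-term survivors**,
built around the Weibull mixture cure model, together with the
immunohistochemistry (IHC) agreement/association battery used in
tissue-microarray biomarker studies.

## Who this is for

Biostatisticians and clinical researchers analysing resected-cancer cohorts
(the motivating setting is gastric and esophagogastric-junction
adenocarcinoma with HER-family IHC scoring) where a substantial fraction of
patients never experience the event. In that setting the Cox model's
proportional-hazards assumption typically fails and a parametric mixture is
the natural choice: the population divides into a *cured* fraction and a
*susceptible* fraction with parametric survival.

## The model

Population survival is a two-component mixture

S(t) = π + (1 − π) · exp(−(t/λ)^k)

with cure fraction π (the late-time plateau of the survival curve), Weibull
shape k and scale λ (months); k = 1 degenerates to the exponential. The
population hazard h(t) = (1 − π) f_W(t) / S(t) decays to zero as the
at-risk pool becomes dominated by cured patients. Fitting is by maximum
likelihood under right censoring,

ℓ = Σ δ_i log[(1 − π) f_W(t_i)] + (1 − δ_i) log[π + (1 − π) S_W(t_i)],

on unconstrained transforms (logit π, log k, log λ) with a deterministic
multi-start grid; the cure-fraction CI is delta-method on the logit scale
with a profile-likelihood fallback. A companion regression places linear
predictors on logit(π_i) and/or log(λ_i) with a shared shape.

The IHC side implements the standard 0/1+ = negative vs 2+/3+ = positive
dichotomization, pairwise 2×2 cross-tabs with Cohen's kappa and the
*uncorrected* McNemar test, Pearson chi-square association tests, and
positivity-by-stage tables. A synthetic cohort generator draws correlated
binary markers with prescribed marginals and pairwise kappa (closed-form
inversion of the kappa formula) and cure-mixture survival under accrual
censoring, including a fully constrained 201-patient study-replica cohort.

## Worked example

```r
library(curemix)

cohort   <- study_replica_cohort(seed = 2026)   # 201 synthetic patients
analyzed <- exclude_postoperative_deaths(cohort)

fit <- fit_mle(analyzed$time_months, analyzed$event, "weibull_cure")
fit
#> <parametric_fit> weibull_cure: n = 189 (86 events)
#>   cure fraction pi = 0.508, shape k = 1.569, scale lambda = 13.29 months
#>   loglik = -401.273, AIC = 808.55, converged: TRUE

cure_fraction_ci(fit)
#>  estimate     lower     upper
#> 0.5076121 0.4294678 0.5853861
```

About half the synthetic cohort is modelled as cured — the survival curve
plateaus near 0.51 — and the 95 % interval spans roughly 0.43–0.59. The AIC
ranking shows why the mixture is needed:

```r
fits <- lapply(c("exponential", "weibull", "weibull_cure"), function(m)
  fit_mle(analyzed$time_months, analyzed$event, m))
model_compare_aic(fits)
#>          model n_par  loglik    aic delta_aic
#> 1 weibull_cure     3 -401.27 808.55     0.000
#> 2  exponential     1 -415.78 833.55    25.006
#> 3      weibull     2 -415.52 835.04    26.494
```

Marker agreement, e.g. HER2 membrane vs HER3 cytoplasm:

```r
tab <- crosstab(marker_call(cohort, "her2_membrane"),
                marker_call(cohort, "her3_cytoplasm"))
cohen_kappa(tab)                  # 0.102  (weak chance-corrected agreement)
mcnemar_test(tab)$p.value         # < 0.001 (marginal rates 17 % vs 62 % differ)
```

End-to-end bundles (`run_concordance_report()`, `run_survival_report()`)
write the pairwise-agreement, positivity, KM, goodness-of-fit, hazard and
regression tables as TSV/JSON plus a digest manifest.

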