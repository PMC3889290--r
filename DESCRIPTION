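Package: curemix
Title: Weibull Mixture Cure Survival Models and IHC Marker Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for survival analysis of oncology cohorts containing
    long-term survivors, built around the Weibull mixture cure model: maximum
    likelihood fitting with right censoring, cure-fraction confidence
    intervals, population hazard, AIC model comparison, and goodness-of-fit
    against the Kaplan-Meier estimate.  A companion covariate regression
    places linear predictors on the logit cure fraction and/or the log
    Weibull scale.  An immunohistochemistry toolkit dichotomizes ordinal
    0-3+ staining scores and runs the agreement/association battery
    (Cohen's kappa, McNemar, Pearson chi-square, positivity-by-stage
    tables).  A synthetic cohort generator emulates a gastric-cancer
    tissue-microarray study - covariate marginals, marker positivity with
    prescribed pairwise kappa, and cure-mixture survival under accrual
    censoring - so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
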