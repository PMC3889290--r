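# Pipeline orchestration: end-to-end concordance and survival report
# bundles.  TSV/JSON files are the contract; every emitted table traces to a
# machine-readable file listed (with digest) in the run manifest.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  path
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  path
}

# manifest: seed/config, input digest, and an md5 inventory of the outputs
.write_manifest <- function(out_dir, inputs, config, outputs, seed = NULL) {
  manifest <- list(
    package = "curemix",
    version = as.character(utils::packageVersion("curemix")),
    seed = seed,
    config = config,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  .write_json(manifest, file.path(out_dir, "manifest.json"))
}

.resolve_cohort <- function(cohort) {
  if (inherits(cohort, "cohort")) return(list(cohort = cohort, path = NULL))
  list(cohort = read_cohort(cohort), path = cohort)
}

#' Run the full marker concordance/association report
#'
#' Emits a pairwise agreement TSV (all informative marker pairs: cross-tab
#' cells, Cohen's kappa, uncorrected McNemar), a positivity-by-stage TSV,
#' an association-battery JSON, a cohort validation JSON, and a manifest
#' with input/output digests.
#'
#' @param cohort a `cohort` or a path readable by [read_cohort()].
#' @param out_dir output directory (created if needed).
#' @param config list: `markers` (default: all informative markers),
#'   `covariates` for the battery, `age_cutoff`.
#' @return named character vector of written file paths, invisibly; the
#'   computed tables are returned in attribute `"results"`.
#' @export
run_concordance_report <- function(cohort, out_dir, config = list()) {
  src <- .resolve_cohort(cohort)
  ch <- src$cohort
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  markers <- config$markers %||% setdiff(marker_columns(), "her3_membrane")
  markers <- intersect(markers, names(ch))
  if (length(markers) < 2L)
    warning("fewer than two markers present: pairwise section empty",
            call. = FALSE)

  files <- character(0)
  pairwise <- if (length(markers) >= 2L) agreement_battery(ch, markers)
              else data.frame()
  files["pairwise"] <- .write_tsv(pairwise,
                                  file.path(out_dir, "pairwise_agreement.tsv"))

  pos <- do.call(rbind, lapply(markers, function(m) {
    r <- positivity_by_stage(ch, m)$rates
    cbind(marker = m, r)
  }))
  files["positivity"] <- .write_tsv(pos,
                                    file.path(out_dir, "positivity_by_stage.tsv"))

  assoc <- lapply(markers, function(m) {
    b <- association_battery(ch, m,
                             covariates = config$covariates %||%
                               c("age", "lauren", "pt", "pn", "stage_group"),
                             age_cutoff = config$age_cutoff)
    b$results
  })
  names(assoc) <- markers
  files["associations"] <- .write_json(assoc,
                                       file.path(out_dir, "associations.json"))
  files["validation"] <- .write_json(
    attr(ch, "validation") %||% list(n_rows = nrow(ch),
                                     provenance = attr(ch, "provenance")),
    file.path(out_dir, "cohort_validation.json"))
  files["manifest"] <- .write_manifest(
    out_dir, inputs = as.list(src$path), config = config,
    outputs = as.list(files))
  structure(invisible(files),
            results = list(pairwise = pairwise, positivity = pos,
                           associations = assoc))
}

# default covariate specification mirroring the published adjusted model:
# age, surgical radicality, surgery type (location proxy), Lauren histology,
# adjuvant therapy, TNM stage group, and the informative receptors
.default_regression_spec <- function() {
  list(age = list(type = "continuous"),
       radicality = list(type = "categorical", ref = "R0"),
       location = list(type = "categorical", ref = "stomach"),
       lauren = list(type = "categorical", ref = "intestinal"),
       adjuvant = list(type = "categorical", ref = "surgery_alone"),
       stage_group = list(type = "categorical", ref = "g0_I_II"),
       her2_membrane = list(type = "binary"),
       her3_cytoplasm = list(type = "binary"))
}

#' Run the full survival analysis report
#'
#' Excludes postoperative deaths, fits the exponential, Weibull and
#' Weibull-mixture-cure models, and emits: the Kaplan-Meier step function,
#' KM-versus-model overlay pairs per model, parametric and smoothed hazard
#' curves, the cure fraction with CI, the AIC ranking, the cure-regression
#' forest table, and a manifest.
#'
#' @param cohort a `cohort` or a path readable by [read_cohort()].
#' @param out_dir output directory.
#' @param config list: `bandwidth` (hazard smoothing, months), `level`
#'   (CI level), `regression` (covariate spec for [build_design()], `NULL`
#'   for the default adjusted model, `NA` to skip), `links`.
#' @return named character vector of written files, invisibly; computed
#'   objects in attribute `"results"`.
#' @export
run_survival_report <- function(cohort, out_dir, config = list()) {
  src <- .resolve_cohort(cohort)
  ch0 <- src$cohort
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ch <- exclude_postoperative_deaths(ch0)
  times <- ch$time_months; events <- ch$event
  if (sum(events == 1, na.rm = TRUE) == 0L)
    stop("no events after postoperative exclusions", call. = FALSE)

  files <- character(0)
  km <- km_fit(times, events)
  files["km"] <- .write_tsv(
    data.frame(time = km$time, n_risk = km$n_risk, n_event = km$n_event,
               n_censor = km$n_censor, survival = km$surv,
               variance = km$variance, lower = km$lower, upper = km$upper),
    file.path(out_dir, "km_curve.tsv"))

  fits <- list(
    exponential = fit_mle(times, events, "exponential"),
    weibull = fit_mle(times, events, "weibull"),
    weibull_cure = fit_mle(times, events, "weibull_cure"))
  level <- config$level %||% 0.95
  ci <- cure_fraction_ci(fits$weibull_cure, level = level,
                         times = times, events = events)
  fit_report <- list(
    n_total = nrow(ch0), n_excluded_postop = nrow(ch0) - nrow(ch),
    n_analyzed = nrow(ch), n_events = sum(events == 1),
    n_censored = sum(events == 0),
    median_followup_months = median_followup_reverse_km(times, events),
    cure_fraction = list(estimate = unname(ci["estimate"]),
                         lower = unname(ci["lower"]),
                         upper = unname(ci["upper"]),
                         level = level, method = attr(ci, "method")),
    models = lapply(fits, function(f)
      list(model = f$model, pi = f$params$pi, shape = f$params$shape,
           scale = f$params$scale, loglik = f$loglik, aic = f$aic,
           converged = f$converged)))
  files["fits"] <- .write_json(fit_report, file.path(out_dir, "fits.json"))
  files["aic"] <- .write_tsv(model_compare_aic(fits),
                             file.path(out_dir, "aic_ranking.tsv"))

  gof <- do.call(rbind, lapply(fits, function(f) {
    g <- gof_pairs(km, f)
    if (nrow(g)) cbind(model = f$model, g) else NULL
  }))
  files["gof"] <- .write_tsv(gof, file.path(out_dir, "gof_pairs.tsv"))

  grid <- seq(0, max(times), length.out = 200L)
  haz <- data.frame(
    time = grid,
    parametric = cure_hazard(grid, fits$weibull_cure$params),
    smoothed = smoothed_hazard(km, bandwidth = config$bandwidth %||% 3,
                               grid = grid)$hazard)
  files["hazard"] <- .write_tsv(haz, file.path(out_dir, "hazard_curves.tsv"))

  regression <- config$regression %||% .default_regression_spec()
  if (!identical(regression, NA) && length(regression)) {
    des <- build_design(ch, regression)
    reg <- fit_cure_regression(des, links = config$links %||% c("cure", "scale"),
                               level = level)
    files["regression"] <- .write_tsv(suppressWarnings(summarize_fit(reg)),
                                      file.path(out_dir, "regression_forest.tsv"))
  } else reg <- NULL

  files["manifest"] <- .write_manifest(
    out_dir, inputs = as.list(src$path), config = config,
    outputs = as.list(files))
  structure(invisible(files),
            results = list(km = km, fits = fits, cure_fraction_ci = ci,
                           report = fit_report, regression = reg))
}
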