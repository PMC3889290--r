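# Nonparametric survival: Kaplan-Meier product-limit curve (via
# survival::survfit), reverse-KM follow-up, kernel-smoothed empirical hazard.

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] for a single group and repackages the step
#' function with Greenwood variance.  Ties are handled the standard way:
#' deaths precede censorings at the same time.
#'
#' @param times non-negative follow-up times (months).
#' @param events 0/1 event indicators (1 = death).
#' @param conf_level confidence level for the pointwise interval.
#' @param conf_type `"plain"` (Greenwood, default) or `"log-log"`.
#' @return object of class `km_curve`: list with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, `variance` (Greenwood), `lower`,
#'   `upper`, `n`, `n_events`.
#' @export
km_fit <- function(times, events, conf_level = 0.95, conf_type = "plain") {
  if (length(times) == 0L) stop("empty input", call. = FALSE)
  if (length(times) != length(events))
    stop("times and events differ in length", call. = FALSE)
  if (any(times < 0, na.rm = TRUE)) stop("negative times", call. = FALSE)
  conf_type <- match.arg(conf_type, c("plain", "log-log"))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = conf_type, conf.int = conf_level)
  structure(list(
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    n_censor = sf$n.censor, surv = sf$surv,
    variance = (sf$std.err * sf$surv)^2,
    lower = sf$lower, upper = sf$upper,
    n = length(times), n_events = sum(events == 1),
    conf_level = conf_level, conf_type = conf_type),
    class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d, last time = %.2f, S(last) = %.3f\n",
              x$n, x$n_events, max(x$time), x$surv[length(x$surv)]))
  invisible(x)
}

#' Event times of a Kaplan-Meier curve
#' @param curve a `km_curve`.
#' @return numeric vector of times with at least one event.
#' @export
km_event_times <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  curve$time[curve$n_event > 0]
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step-function value; before the first step the estimate
#' is 1, beyond the last observed time the last value is carried forward.
#'
#' @param curve a `km_curve`.
#' @param t non-negative times.
#' @return survival probabilities.
#' @export
km_eval <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  if (any(t < 0)) stop("negative evaluation times", call. = FALSE)
  sf <- stats::stepfun(curve$time, c(1, curve$surv), right = FALSE)
  sf(t)
}

#' Median follow-up by reverse Kaplan-Meier
#'
#' KM median of the censoring distribution: the event indicator is inverted
#' so that censorings are the "events".  The standard estimator of median
#' follow-up under right censoring.
#'
#' @param times follow-up times (months).
#' @param events 0/1 event indicators.
#' @return median follow-up in months, or `NA` with a warning when the
#'   censoring survival never crosses 0.5 (e.g. no censored records).
#' @export
median_followup_reverse_km <- function(times, events) {
  if (all(events == 1)) {
    warning("no censored observations: median follow-up undefined",
            call. = FALSE)
    return(NA_real_)
  }
  sf <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  med <- unname(stats::quantile(sf, probs = 0.5)$quantile)
  if (is.na(med))
    warning("censoring survival never crosses 0.5: median follow-up undefined",
            call. = FALSE)
  med
}

# Epanechnikov CDF on [-1, 1]
.epan_cdf <- function(x) {
  x <- pmin(pmax(x, -1), 1)
  0.5 + 0.75 * x - 0.25 * x^3
}

#' Kernel-smoothed empirical hazard
#'
#' Epanechnikov smoothing of the Nelson-Aalen increments \eqn{d_i/n_i} over
#' a time grid, with per-kernel renormalization near the t = 0 boundary so
#' that each increment keeps unit mass.
#'
#' @param curve a `km_curve`.
#' @param bandwidth kernel half-width in months (default 3).
#' @param grid evaluation times; default 200 points over the observed range.
#' @return object of class `hazard_curve`: data.frame with columns `time`
#'   and `hazard`, attributes `bandwidth` and `na_mass` (total Nelson-Aalen
#'   mass).  Grid points outside the observed range get hazard 0 with a
#'   warning.
#' @export
smoothed_hazard <- function(curve, bandwidth = 3, grid = NULL) {
  stopifnot(inherits(curve, "km_curve"))
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be positive", call. = FALSE)
  tmax <- max(curve$time)
  if (is.null(grid)) grid <- seq(0, tmax, length.out = 200L)
  if (any(grid < 0) || any(grid > tmax))
    warning("grid extends outside the observed time range: hazard set to 0 there",
            call. = FALSE)
  ev <- curve$n_event > 0
  et <- curve$time[ev]
  inc <- curve$n_event[ev] / curve$n_risk[ev]   # Nelson-Aalen increments
  h <- numeric(length(grid))
  if (length(et)) {
    # weight of kernel i retained on [0, Inf): renormalize by it
    w <- .epan_cdf(1) - .epan_cdf(-pmin(et / bandwidth, 1))
    for (i in seq_along(et)) {
      u <- (grid - et[i]) / bandwidth
      k <- ifelse(abs(u) < 1, 0.75 * (1 - u^2) / bandwidth, 0)
      h <- h + inc[i] * k / w[i]
    }
  }
  h[grid < 0 | grid > tmax] <- 0
  structure(data.frame(time = grid, hazard = h),
            class = c("hazard_curve", "data.frame"),
            bandwidth = bandwidth, na_mass = sum(inc))
}
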