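# Parametric survival with long-term survivors: exponential, Weibull, and
# Weibull mixture cure models fitted by maximum likelihood under right
# censoring.  Parameterization throughout: S_W(t) = exp(-(t/scale)^shape),
# population survival S(t) = pi + (1 - pi) * S_W(t).

#' Mixture cure model parameters
#'
#' @param pi cure fraction in \[0, 1): the long-term survivor proportion and
#'   the asymptote of the population survival curve.
#' @param shape Weibull shape k (> 0); k = 1 degenerates to the exponential.
#' @param scale Weibull scale lambda in months (> 0).
#' @return object of class `cure_params`.
#' @export
cure_params <- function(pi = 0, shape = 1, scale) {
  stopifnot(is.numeric(pi), pi >= 0, pi <= 1,
            is.numeric(shape), shape > 0,
            is.numeric(scale), scale > 0)
  structure(list(pi = pi, shape = shape, scale = scale), class = "cure_params")
}

#' Population survival of the Weibull mixture cure model
#'
#' \eqn{S(t) = \pi + (1-\pi)\exp(-(t/\lambda)^k)}: starts at 1, decreases,
#' and plateaus at the cure fraction \eqn{\pi}.
#'
#' @param t non-negative times (months).
#' @param params a `cure_params`.
#' @return survival probabilities.
#' @export
cure_survival <- function(t, params) {
  stopifnot(inherits(params, "cure_params"))
  if (any(t < 0)) stop("negative times", call. = FALSE)
  params$pi + (1 - params$pi) *
    stats::pweibull(t, params$shape, params$scale, lower.tail = FALSE)
}

#' Population hazard of the Weibull mixture cure model
#'
#' \eqn{h(t) = (1-\pi) f_W(t) / S(t)}.  With \eqn{\pi > 0} the hazard decays
#' to zero at late times as the at-risk pool becomes dominated by cured
#' subjects; with \eqn{\pi = 0, k = 1} it is the constant \eqn{1/\lambda}.
#'
#' @inheritParams cure_survival
#' @return hazard rates per month.
#' @export
cure_hazard <- function(t, params) {
  stopifnot(inherits(params, "cure_params"))
  (1 - params$pi) * stats::dweibull(t, params$shape, params$scale) /
    cure_survival(t, params)
}

#' Negative log-likelihood for right-censored parametric survival
#'
#' \deqn{-\ell = -\sum_i \delta_i \log[(1-\pi) f_W(t_i)] +
#'   (1-\delta_i)\log[\pi + (1-\pi) S_W(t_i)]}
#' At \eqn{\pi = 0} this reduces exactly to the plain Weibull censored
#' log-likelihood, and at \eqn{k = 1} the Weibull terms reduce to
#' exponential terms.
#'
#' @param params a `cure_params` (use `pi = 0` for non-cure models,
#'   `shape = 1` for the exponential).
#' @param times follow-up times; events must have `t > 0`.
#' @param events 0/1 indicators.
#' @param model one of `"weibull_cure"`, `"weibull"`, `"exponential"`
#'   (consistency check on `params` only; the formula is shared).
#' @return the negative log-likelihood (finite for interior parameters).
#' @export
neg_loglik <- function(params, times, events,
                       model = c("weibull_cure", "weibull", "exponential")) {
  model <- match.arg(model)
  stopifnot(inherits(params, "cure_params"), length(times) == length(events))
  if (model != "weibull_cure" && params$pi != 0)
    stop("non-cure model requires pi = 0", call. = FALSE)
  if (model == "exponential" && params$shape != 1)
    stop("exponential model requires shape = 1", call. = FALSE)
  d <- events == 1
  if (any(times[d] <= 0))
    stop("event recorded at t <= 0: density undefined", call. = FALSE)
  ll_event <- if (any(d)) {
    if (params$pi >= 1) return(Inf)
    sum(log1p(-params$pi) +
        stats::dweibull(times[d], params$shape, params$scale, log = TRUE))
  } else 0
  sw <- stats::pweibull(times[!d], params$shape, params$scale,
                        lower.tail = FALSE)
  ll_cens <- sum(log(params$pi + (1 - params$pi) * sw))
  -(ll_event + ll_cens)
}

# --- transform helpers (unconstrained optimization scale) ---------------

.theta_to_params <- function(theta, model) {
  switch(model,
    weibull_cure = cure_params(pi = stats::plogis(theta[1]),
                               shape = exp(theta[2]), scale = exp(theta[3])),
    weibull      = cure_params(pi = 0, shape = exp(theta[1]),
                               scale = exp(theta[2])),
    exponential  = cure_params(pi = 0, shape = 1, scale = exp(theta[1])))
}

.param_names <- function(model) {
  switch(model,
    weibull_cure = c("logit_pi", "log_shape", "log_scale"),
    weibull      = c("log_shape", "log_scale"),
    exponential  = "log_scale")
}

# deterministic multi-start grid around a KM-informed center
.start_grid <- function(times, events, model, init, n_starts) {
  km <- km_fit(times, events)
  pi0 <- min(max(km$surv[length(km$surv)], 0.01), 0.95)
  et <- times[events == 1]
  lam0 <- if (length(et)) stats::median(et) else stats::median(times)
  lam0 <- max(lam0, 1e-3)
  base <- switch(model,
    weibull_cure = c(stats::qlogis(pi0), 0, log(lam0)),
    weibull      = c(0, log(lam0)),
    exponential  = log(lam0))
  starts <- list(base)
  jitter <- switch(model,
    weibull_cure = list(c(-1, 0, 0), c(1, 0.4, 0.5), c(0, -0.4, -0.5),
                        c(0.5, 0.4, -0.3)),
    weibull      = list(c(0.4, 0.5), c(-0.4, -0.5), c(0.7, 0)),
    exponential  = list(0.7, -0.7))
  starts <- c(starts, lapply(jitter, function(j) base + j))
  if (!is.null(init)) {
    th0 <- switch(model,
      weibull_cure = c(stats::qlogis(min(max(init$pi, 1e-6), 1 - 1e-6)),
                       log(init$shape), log(init$scale)),
      weibull      = c(log(init$shape), log(init$scale)),
      exponential  = log(init$scale))
    starts <- c(list(th0), starts)
  }
  starts[seq_len(min(length(starts), max(n_starts, 1)))]
}

#' Fit a parametric survival model by maximum likelihood
#'
#' Unconstrained optimization on transformed parameters (logit cure
#' fraction, log shape, log scale) with a deterministic multi-start grid
#' informed by the Kaplan-Meier plateau (mixture likelihoods can be
#' multi-modal).  The covariance is the inverse of the numerically
#' differentiated observed information on the transformed scale.
#'
#' @param times follow-up times (months).
#' @param events 0/1 indicators.
#' @param model `"weibull_cure"`, `"weibull"` or `"exponential"`.
#' @param init optional `cure_params` used as an extra start.
#' @param config list of controls: `n_starts` (default 5), `min_n` (default
#'   10), `reltol` (default 1e-10).
#' @return object of class `parametric_fit`: model id, `params`
#'   (`cure_params` on the natural scale), `loglik`, `aic`, `cov`
#'   (transformed scale), `converged`, `n`, `n_events`.
#' @export
fit_mle <- function(times, events, model = c("weibull_cure", "weibull",
                                             "exponential"),
                    init = NULL, config = list()) {
  model <- match.arg(model)
  min_n <- config$min_n %||% 10L
  if (length(times) < min_n)
    stop("fewer than ", min_n, " records", call. = FALSE)
  if (length(times) != length(events))
    stop("times and events differ in length", call. = FALSE)
  if (sum(events == 1) == 0L) {
    if (model != "weibull_cure")
      stop("no events: ", model, " model cannot be fitted", call. = FALSE)
    warning("all records censored: cure fraction at the pi = 1 boundary",
            call. = FALSE)
    return(structure(list(
      model = model, params = cure_params(pi = 1 - 1e-12, shape = 1,
                                          scale = stats::median(times)),
      boundary = TRUE, loglik = 0, aic = 2 * 3, cov = NULL,
      converged = FALSE, n = length(times), n_events = 0L),
      class = "parametric_fit"))
  }
  obj <- function(theta) {
    # guard optimizer excursions where exp() under/overflows
    if (any(!is.finite(theta)) || any(abs(theta) > 200)) return(1e12)
    p <- .theta_to_params(theta, model)
    v <- suppressWarnings(neg_loglik(p, times, events, model = model))
    if (!is.finite(v)) 1e12 else v
  }
  starts <- .start_grid(times, events, model, init,
                        config$n_starts %||% 5L)
  best <- NULL
  for (s in starts) {
    op <- tryCatch(
      stats::optim(s, obj, method = "BFGS",
                   control = list(reltol = config$reltol %||% 1e-10,
                                  maxit = 500L)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value - 1e-12) best <- op
  }
  if (is.null(best)) stop("optimization failed for all starts", call. = FALSE)
  theta <- best$par
  hess <- tryCatch(stats::optimHess(theta, obj), error = function(e) NULL)
  cov <- if (!is.null(hess))
    tryCatch(solve(hess), error = function(e) NULL) else NULL
  if (!is.null(cov)) {
    dimnames(cov) <- list(.param_names(model), .param_names(model))
    if (any(!is.finite(cov)) || any(diag(cov) < 0)) cov <- NULL
  }
  npar <- length(theta)
  structure(list(
    model = model, params = .theta_to_params(theta, model),
    theta = stats::setNames(theta, .param_names(model)),
    loglik = -best$value, aic = 2 * npar + 2 * best$value,
    cov = cov, converged = best$convergence == 0,
    n = length(times), n_events = sum(events == 1),
    boundary = FALSE),
    class = "parametric_fit")
}

#' @export
print.parametric_fit <- function(x, ...) {
  cat(sprintf("<parametric_fit> %s: n = %d (%d events)\n", x$model, x$n,
              x$n_events))
  cat(sprintf("  cure fraction pi = %.3f, shape k = %.3f, scale lambda = %.2f months\n",
              x$params$pi, x$params$shape, x$params$scale))
  cat(sprintf("  loglik = %.3f, AIC = %.2f, converged: %s\n", x$loglik, x$aic,
              x$converged))
  invisible(x)
}

#' Survival function implied by a fitted parametric model
#' @param fit a `parametric_fit`.
#' @param t non-negative times.
#' @return survival probabilities.
#' @export
model_survival <- function(fit, t) {
  stopifnot(inherits(fit, "parametric_fit"))
  cure_survival(t, fit$params)
}

# profile-likelihood CI for logit(pi) used when the Hessian is unusable
.profile_pi_ci <- function(fit, times, events, level) {
  thr <- stats::qchisq(level, 1) / 2
  lp_hat <- fit$theta[["logit_pi"]]
  prof <- function(lp) {
    obj <- function(kl) {
      if (any(!is.finite(kl)) || any(abs(kl) > 200)) return(1e12)
      v <- suppressWarnings(
        neg_loglik(.theta_to_params(c(lp, kl), "weibull_cure"), times, events))
      if (!is.finite(v)) 1e12 else v
    }
    op <- stats::optim(fit$theta[c("log_shape", "log_scale")], obj,
                       method = "BFGS")
    (-op$value) - fit$loglik + thr   # > 0 inside the interval
  }
  lo <- tryCatch(stats::uniroot(prof, c(lp_hat - 8, lp_hat))$root,
                 error = function(e) -Inf)
  hi <- tryCatch(stats::uniroot(prof, c(lp_hat, lp_hat + 8))$root,
                 error = function(e) Inf)
  stats::plogis(c(lo, hi))
}

#' Confidence interval for the cure fraction
#'
#' Delta-method interval on the logit scale, back-transformed so the bounds
#' stay inside (0, 1).  Falls back to a profile-likelihood interval when the
#' observed information is singular or ill-conditioned.
#'
#' @param fit a converged `parametric_fit` with `model = "weibull_cure"`.
#' @param level confidence level (default 0.95); `level = 0` degenerates to
#'   the point estimate.
#' @param times,events the data, needed only for the profile fallback.
#' @return named numeric: `estimate`, `lower`, `upper`, with attribute
#'   `method` (`"wald_logit"` or `"profile"`).
#' @export
cure_fraction_ci <- function(fit, level = 0.95, times = NULL, events = NULL) {
  stopifnot(inherits(fit, "parametric_fit"))
  if (fit$model != "weibull_cure")
    stop("cure_fraction_ci requires a weibull_cure fit", call. = FALSE)
  if (!isTRUE(fit$converged))
    stop("fit did not converge", call. = FALSE)
  est <- fit$params$pi
  z <- stats::qnorm(1 - (1 - level) / 2)
  se_ok <- !is.null(fit$cov) && is.finite(fit$cov["logit_pi", "logit_pi"]) &&
    fit$cov["logit_pi", "logit_pi"] > 0
  if (se_ok) {
    se <- sqrt(fit$cov["logit_pi", "logit_pi"])
    lp <- fit$theta[["logit_pi"]]
    ci <- stats::plogis(c(lp - z * se, lp + z * se))
    method <- "wald_logit"
  } else {
    if (is.null(times))
      stop("singular covariance: supply times/events for the profile fallback",
           call. = FALSE)
    ci <- .profile_pi_ci(fit, times, events, level)
    method <- "profile"
  }
  structure(c(estimate = est, lower = unname(ci[1]), upper = unname(ci[2])),
            method = method)
}

#' Rank fitted models by AIC
#'
#' @param fits list of `parametric_fit` objects fitted to the same data.
#' @return data.frame sorted by AIC ascending with a `delta_aic` column.
#' @export
model_compare_aic <- function(fits) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "parametric_fit")))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  ne <- vapply(fits, `[[`, numeric(1), "n_events")
  if (length(unique(ns)) > 1L || length(unique(ne)) > 1L)
    stop("fits are not on identical data (n or event counts differ)",
         call. = FALSE)
  df <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    n_par = vapply(fits, function(f) length(f$theta), numeric(1)),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    stringsAsFactors = FALSE)
  df <- df[order(df$aic), , drop = FALSE]
  df$delta_aic <- df$aic - df$aic[1]
  rownames(df) <- NULL
  df
}

#' Pair Kaplan-Meier and model survival for goodness-of-fit display
#'
#' Evaluates both estimates at the KM event times; suitable for overlay
#' curves and KM-versus-model scatter diagnostics.
#'
#' @param km_curve a `km_curve`.
#' @param fit a converged `parametric_fit`.
#' @return data.frame with `time`, `s_km`, `s_model`; attribute
#'   `max_abs_diff` summarizes the largest discrepancy.
#' @export
gof_pairs <- function(km_curve, fit) {
  stopifnot(inherits(km_curve, "km_curve"), inherits(fit, "parametric_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  et <- km_event_times(km_curve)
  out <- data.frame(time = et, s_km = km_eval(km_curve, et),
                    s_model = model_survival(fit, et))
  attr(out, "max_abs_diff") <- if (nrow(out)) max(abs(out$s_km - out$s_model))
                               else NA_real_
  out
}
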