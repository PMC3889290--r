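# helper: simulate right-censored data from the mixture cure model
sim_cure <- function(n, pi, shape, scale, cens_upper = 60, seed = 1) {
  cfg <- synthetic_config(n = n, pi = pi, shape = shape, scale = scale,
                          censoring = list(type = "accrual", accrual = cens_upper,
                                           horizon = cens_upper),
                          seed = seed)
  simulate_survival(cfg)
}

test_that("closed-form survival and hazard identities", {
  p <- cure_params(pi = 0.5, shape = 1.5, scale = 20)
  expect_equal(cure_survival(0, p), 1)
  expect_equal(cure_survival(1e6, p), 0.5, tolerance = 1e-12)
  expect_equal(cure_survival(10, cure_params(0, 1, 10)), exp(-1),
               tolerance = 1e-12)
  expect_error(cure_survival(-1, p), "negative")
  # exponential special case: constant hazard 1/lambda
  expect_equal(cure_hazard(c(1, 5, 20), cure_params(0, 1, 10)),
               rep(1 / 10, 3), tolerance = 1e-12)
  # cured plateau: hazard decays to zero
  expect_lt(cure_hazard(500, p), 1e-8)
  # survival is non-increasing
  tt <- seq(0, 100, by = 0.5)
  expect_true(all(diff(cure_survival(tt, p)) <= 0))
})

test_that("S(t) = exp(-integral of h) by quadrature for the mixture model", {
  p <- cure_params(pi = 0.4, shape = 1.8, scale = 15)
  for (t in c(2, 10, 30, 60)) {
    H <- integrate(function(u) cure_hazard(u, p), 0, t,
                   rel.tol = 1e-10)$value
    expect_equal(exp(-H), cure_survival(t, p), tolerance = 1e-6)
  }
})

test_that("likelihood boundary reductions are exact", {
  set.seed(8)
  for (i in 1:100) {
    n <- 30
    times <- rweibull(n, runif(1, 0.7, 2), runif(1, 5, 30)) + 0.01
    events <- rbinom(n, 1, 0.6)
    k <- runif(1, 0.5, 2.5); lam <- runif(1, 5, 40)
    # cure model at pi = 0 is the plain Weibull censored likelihood
    expect_equal(
      neg_loglik(cure_params(0, k, lam), times, events, "weibull_cure"),
      neg_loglik(cure_params(0, k, lam), times, events, "weibull"),
      tolerance = 1e-10)
    # Weibull at k = 1 is the exponential likelihood, in closed form
    d <- sum(events); ll_exp <- d * log(1 / lam) - sum(times) / lam
    expect_equal(neg_loglik(cure_params(0, 1, lam), times, events, "weibull"),
                 -ll_exp, tolerance = 1e-10)
    expect_equal(
      neg_loglik(cure_params(0, 1, lam), times, events, "exponential"),
      -ll_exp, tolerance = 1e-10)
  }
})

test_that("likelihood edge cases: all-censored boundary, t = 0 event, validation", {
  times <- c(1, 2, 3); cens <- c(0L, 0L, 0L)
  expect_equal(neg_loglik(cure_params(1, 1.5, 10), times, cens), 0)
  expect_error(neg_loglik(cure_params(0.5, 0.8, 10), c(0, 1), c(1L, 1L)),
               "t <= 0")
  expect_error(neg_loglik(cure_params(0.3, 1, 10), times, cens, "weibull"),
               "pi = 0")
})

test_that("neg_loglik agrees with an independent direct implementation", {
  # independent oracle: literal sum over records from the written-out
  # formula (log-density expanded by hand), no shared code path
  oracle <- function(pi, k, lam, times, events) {
    tot <- 0
    for (i in seq_along(times)) {
      sw <- exp(-(times[i] / lam)^k)
      log_fw <- log(k / lam) + (k - 1) * log(times[i] / lam) -
        (times[i] / lam)^k
      tot <- tot + if (events[i] == 1) log(1 - pi) + log_fw
                   else log(pi + (1 - pi) * sw)
    }
    -tot
  }
  set.seed(13)
  times <- rweibull(40, 1.3, 18) + 0.05
  events <- rbinom(40, 1, 0.5)
  for (i in 1:100) {
    pi <- runif(1, 0, 0.9); k <- runif(1, 0.4, 3); lam <- runif(1, 2, 50)
    expect_equal(neg_loglik(cure_params(pi, k, lam), times, events),
                 oracle(pi, k, lam, times, events), tolerance = 1e-9)
  }
})

test_that("MLE recovers generating parameters and matches survreg on reductions", {
  sim <- sim_cure(2000, pi = 0.5, shape = 1.5, scale = 20, cens_upper = 60,
                  seed = 202)
  fit <- fit_mle(sim$time, sim$event, "weibull_cure")
  expect_true(fit$converged)
  se <- sqrt(diag(fit$cov))
  expect_lt(abs(fit$theta[["logit_pi"]] - qlogis(0.5)),
            3 * se[["logit_pi"]])
  expect_lt(abs(fit$theta[["log_shape"]] - log(1.5)), 3 * se[["log_shape"]])
  expect_lt(abs(fit$theta[["log_scale"]] - log(20)), 3 * se[["log_scale"]])
  # plain Weibull fit matches the survreg oracle on the same data
  wb <- fit_mle(sim$time, sim$event, "weibull")
  sr <- survival::survreg(survival::Surv(time, event) ~ 1, data = sim,
                          dist = "weibull")
  expect_equal(wb$params$scale, unname(exp(sr$coefficients)), tolerance = 1e-4)
  expect_equal(wb$params$shape, 1 / sr$scale, tolerance = 1e-4)
  expect_equal(wb$loglik, sr$loglik[1], tolerance = 1e-6)
})

test_that("Weibull fit on exponential data estimates shape near 1", {
  set.seed(30)
  n <- 1500
  t0 <- rexp(n, 1 / 15); cen <- runif(n, 0, 60)
  obs <- pmin(t0, cen); ev <- as.integer(t0 <= cen)
  fit <- fit_mle(obs, ev, "weibull")
  se_k <- sqrt(fit$cov["log_shape", "log_shape"])
  expect_lt(abs(fit$theta[["log_shape"]]), 2 * se_k)
})

test_that("duplicating the dataset leaves estimates fixed and halves variances", {
  sim <- sim_cure(400, 0.5, 1.5, 18, seed = 77)
  f1 <- fit_mle(sim$time, sim$event, "weibull_cure")
  f2 <- fit_mle(rep(sim$time, 2), rep(sim$event, 2), "weibull_cure")
  expect_equal(f2$params$pi, f1$params$pi, tolerance = 1e-4)
  expect_equal(f2$params$shape, f1$params$shape, tolerance = 1e-4)
  expect_equal(diag(f2$cov), diag(f1$cov) / 2, tolerance = 0.02)
})

test_that("fit is invariant to record order and equivariant to time rescaling", {
  sim <- sim_cure(500, 0.45, 1.4, 16, seed = 55)
  f <- fit_mle(sim$time, sim$event, "weibull_cure")
  perm <- sample(nrow(sim))
  fp <- fit_mle(sim$time[perm], sim$event[perm], "weibull_cure")
  expect_equal(fp$theta, f$theta, tolerance = 1e-5)
  fs <- fit_mle(sim$time * 12, sim$event, "weibull_cure")  # months -> years*144
  expect_equal(fs$params$pi, f$params$pi, tolerance = 1e-4)
  expect_equal(fs$params$shape, f$params$shape, tolerance = 1e-4)
  expect_equal(fs$params$scale, f$params$scale * 12, tolerance = 1e-3)
})

test_that("fit_mle guards: floor, no events, all-censored boundary", {
  expect_error(fit_mle(1:5, rep(1, 5), "weibull"), "fewer than")
  expect_error(fit_mle(1:20, rep(0L, 20), "weibull"), "no events")
  expect_warning(bf <- fit_mle(1:20 + 0.5, rep(0L, 20), "weibull_cure"),
                 "boundary")
  expect_false(bf$converged)
  expect_gt(bf$params$pi, 0.999)
})

test_that("cure fraction CI: consistency, level-0 degeneracy, profile fallback agrees", {
  sim <- sim_cure(4000, 0.5, 1.5, 18, seed = 91)
  fit <- fit_mle(sim$time, sim$event, "weibull_cure")
  ci <- cure_fraction_ci(fit)
  expect_lt(ci["lower"], 0.5); expect_gt(ci["upper"], 0.5)
  expect_lt(ci["upper"] - ci["lower"], 0.06)  # large-n interval is narrow
  ci0 <- cure_fraction_ci(fit, level = 0)
  expect_equal(unname(ci0["lower"]), unname(ci0["estimate"]), tolerance = 1e-9)
  # profile interval is close to Wald at this n
  fit_noc <- fit; fit_noc$cov <- NULL
  cip <- cure_fraction_ci(fit_noc, times = sim$time, events = sim$event)
  expect_equal(attr(cip, "method"), "profile")
  expect_equal(unname(cip["lower"]), unname(ci["lower"]), tolerance = 0.02)
  expect_equal(unname(cip["upper"]), unname(ci["upper"]), tolerance = 0.02)
  expect_error(cure_fraction_ci(fit_mle(sim$time, sim$event, "weibull")),
               "weibull_cure")
})

test_that("AIC comparison ranks the generating model first on cured data", {
  sim <- sim_cure(2000, 0.5, 1.5, 20, seed = 404)
  fits <- lapply(c("exponential", "weibull", "weibull_cure"), function(m)
    fit_mle(sim$time, sim$event, m))
  cmp <- model_compare_aic(fits)
  expect_equal(cmp$model[1], "weibull_cure")
  expect_true(all(diff(cmp$aic) >= 0))
  expect_equal(cmp$delta_aic[1], 0)
  # pure exponential data: exponential within 2 AIC of Weibull
  set.seed(61); t0 <- rexp(2000, 1 / 15); cen <- runif(2000, 0, 60)
  obs <- pmin(t0, cen); ev <- as.integer(t0 <= cen)
  f_e <- fit_mle(obs, ev, "exponential"); f_w <- fit_mle(obs, ev, "weibull")
  expect_lt(f_e$aic - f_w$aic, 2)
  # mismatched data refuse to rank
  other <- fit_mle(obs[1:500], ev[1:500], "weibull")
  expect_error(model_compare_aic(list(f_e, other)), "identical data")
  expect_equal(nrow(model_compare_aic(list(f_e))), 1L)
})

test_that("goodness-of-fit pairs: self-consistency and misspecification gap", {
  sim <- sim_cure(10000, 0.5, 1.5, 18, seed = 500)
  km <- km_fit(sim$time, sim$event)
  fc <- fit_mle(sim$time, sim$event, "weibull_cure")
  fe <- fit_mle(sim$time, sim$event, "exponential")
  gc <- gof_pairs(km, fc); ge <- gof_pairs(km, fe)
  expect_lt(attr(gc, "max_abs_diff"), 0.03)
  expect_gt(attr(ge, "max_abs_diff"), attr(gc, "max_abs_diff"))
  empty_km <- km_fit(c(1, 2), c(0, 0))
  expect_equal(nrow(gof_pairs(empty_km, fc)), 0L)
})
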