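# Covariate regression for the Weibull mixture cure model: linear
# predictors on logit(pi_i) and/or log(lambda_i), shared shape k.

#' Build a regression design from a cohort
#'
#' Treatment (reference-level) coding for categorical covariates; records
#' with any missing covariate, time or event are dropped with a message.
#'
#' @param cohort a `cohort`.
#' @param covariates named list describing covariates.  Each element is a
#'   list with `type` (`"continuous"`, `"binary"` or `"categorical"`) and,
#'   for categoricals, `ref` (reference level).  The element name is either
#'   a cohort column, `"age"` (continuous by default), `"stage_group"`
#'   (derived via [assign_stage_group()]), or one of [marker_columns()]
#'   (entered as the dichotomized call).
#' @param standardize logical: center/scale continuous covariates.
#' @return list with `X` (design matrix without intercept), `times`,
#'   `events`, `n_dropped`, and `term_map` (column -> covariate).
#' @export
build_design <- function(cohort, covariates, standardize = FALSE) {
  stopifnot(inherits(cohort, "cohort"), length(covariates) >= 1L,
            !is.null(names(covariates)))
  n <- nrow(cohort)
  cols <- list(); term_map <- character(0)
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    type <- cv$type %||% "categorical"
    v <- if (nm == "stage_group") assign_stage_group(cohort$stage)
         else if (nm %in% marker_columns()) marker_call(cohort, nm)
         else if (nm %in% names(cohort)) cohort[[nm]]
         else stop("unknown covariate '", nm, "'", call. = FALSE)
    if (type == "continuous") {
      x <- as.numeric(v)
      if (standardize) x <- as.numeric(scale(x))
      cols[[nm]] <- matrix(x, ncol = 1, dimnames = list(NULL, nm))
      term_map[nm] <- nm
    } else if (type == "binary") {
      x <- if (is.logical(v)) as.numeric(v) else as.numeric(factor(v)) - 1
      cols[[nm]] <- matrix(x, ncol = 1, dimnames = list(NULL, nm))
      term_map[nm] <- nm
    } else {
      f <- factor(v)
      if (!is.null(cv$ref)) {
        if (!cv$ref %in% levels(f))
          stop("reference level '", cv$ref, "' absent for '", nm, "'",
               call. = FALSE)
        f <- stats::relevel(f, cv$ref)
      }
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      # model.matrix drops NA rows; rebuild aligned with NAs kept
      mm_full <- matrix(NA_real_, nrow = n, ncol = nlevels(f) - 1,
                        dimnames = list(NULL,
                                        paste0(nm, "_", levels(f)[-1])))
      ok <- !is.na(f)
      for (j in seq_len(ncol(mm_full)))
        mm_full[ok, j] <- as.numeric(f[ok] == levels(f)[j + 1])
      cols[[nm]] <- mm_full
      term_map[colnames(mm_full)] <- nm
    }
  }
  X <- do.call(cbind, cols)
  keep <- stats::complete.cases(X) & !is.na(cohort$time_months) &
    !is.na(cohort$event)
  n_dropped <- sum(!keep)
  if (n_dropped)
    message(sprintf("build_design: dropped %d record(s) with missing values",
                    n_dropped))
  X <- X[keep, , drop = FALSE]
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)] - 1L]
    stop("collinear design columns: ", paste(aliased, collapse = ", "),
         call. = FALSE)
  }
  list(X = X, times = cohort$time_months[keep],
       events = as.integer(cohort$event[keep]),
       n_dropped = n_dropped, term_map = term_map)
}

# negative log-likelihood of the covariate mixture-cure model
# theta = (log_k, beta_pi (if "cure" linked, incl. intercept),
#          beta_scale (if "scale" linked, incl. intercept))
.reg_negll <- function(theta, X1, times, events, links) {
  if (any(!is.finite(theta)) || any(abs(theta) > 200)) return(1e12)
  p <- ncol(X1)
  k <- exp(theta[1])
  i <- 2L
  if ("cure" %in% links) {
    eta_pi <- drop(X1 %*% theta[i:(i + p - 1)]); i <- i + p
  } else {
    eta_pi <- rep(theta[i], length(times)); i <- i + 1L
  }
  if ("scale" %in% links) {
    eta_lam <- drop(X1 %*% theta[i:(i + p - 1)])
  } else {
    eta_lam <- rep(theta[i], length(times))
  }
  pi_i <- stats::plogis(eta_pi)
  lam <- exp(eta_lam)
  d <- events == 1
  ll <- suppressWarnings(
    sum(log1p(-pi_i[d]) +
          stats::dweibull(times[d], k, lam[d], log = TRUE)) +
      sum(log(pi_i[!d] + (1 - pi_i[!d]) *
                stats::pweibull(times[!d], k, lam[!d], lower.tail = FALSE))))
  if (!is.finite(ll)) return(1e12)
  -ll
}

.reg_par_names <- function(X, links) {
  nm <- "log_shape"
  cn <- c("(Intercept)", colnames(X))
  if ("cure" %in% links) nm <- c(nm, paste0("cure.", cn))
  else nm <- c(nm, "cure.(Intercept)")
  if ("scale" %in% links) nm <- c(nm, paste0("scale.", cn))
  else nm <- c(nm, "scale.(Intercept)")
  nm
}

#' Fit the mixture-cure regression
#'
#' Maximizes the mixture-cure likelihood with
#' \eqn{\mathrm{logit}(\pi_i) = x_i^\top\beta_\pi} and/or
#' \eqn{\log(\lambda_i) = x_i^\top\beta_\lambda} (per `links`), and a shared
#' Weibull shape.  With an intercept-only design this reduces exactly to
#' [fit_mle()] with `model = "weibull_cure"`.
#'
#' @param design output of [build_design()] (or a compatible list).
#' @param links character subset of `c("cure", "scale")`: which parameters
#'   receive the covariates.  Non-linked parameters keep an intercept.
#' @param level confidence level for the Wald intervals.
#' @param config list of controls: `reltol` (default 1e-10), `maxit`.
#' @return object of class `cure_regression_fit`: `coefficients`
#'   (data.frame: term, link, estimate, se, lower, upper, p.value),
#'   `loglik`, `aic`, `converged`, `links`, `shape`, `n`, `n_events`.
#' @export
fit_cure_regression <- function(design, links = c("cure", "scale"),
                                level = 0.95, config = list()) {
  links <- match.arg(links, c("cure", "scale"), several.ok = TRUE)
  X <- as.matrix(design$X)
  times <- design$times; events <- design$events
  if (sum(events == 1) == 0L) stop("no events", call. = FALSE)
  if (qr(cbind(1, X))$rank < ncol(X) + 1L)
    stop("design is not full rank", call. = FALSE)
  X1 <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X1)

  # init from the intercept-only mixture fit, betas at zero
  base <- fit_mle(times, events, "weibull_cure")
  th0 <- base$theta
  init <- log(base$params$shape)
  init <- c(init,
            if ("cure" %in% links) c(th0[["logit_pi"]], rep(0, p - 1))
            else th0[["logit_pi"]])
  init <- c(init,
            if ("scale" %in% links) c(th0[["log_scale"]], rep(0, p - 1))
            else th0[["log_scale"]])

  obj <- function(theta) .reg_negll(theta, X1, times, events, links)
  op <- stats::optim(init, obj, method = "BFGS",
                     control = list(reltol = config$reltol %||% 1e-10,
                                    maxit = config$maxit %||% 1000L))
  theta <- op$par
  nms <- .reg_par_names(X, links)
  names(theta) <- nms
  hess <- tryCatch(stats::optimHess(theta, obj), error = function(e) NULL)
  cov <- if (!is.null(hess)) tryCatch(solve(hess), error = function(e) NULL)
         else NULL
  se <- rep(NA_real_, length(theta))
  if (!is.null(cov)) {
    v <- diag(cov)
    se[v > 0 & is.finite(v)] <- sqrt(v[v > 0 & is.finite(v)])
  }
  # separation guard: runaway cure-link coefficients
  cure_idx <- grepl("^cure\\.", nms) & nms != "cure.(Intercept)"
  if (any(abs(theta[cure_idx]) > 10, na.rm = TRUE))
    warning("possible separation in the cure part (|coefficient| > 10); ",
            "Wald intervals unreliable for the flagged term(s)",
            call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  coefs <- data.frame(
    term = nms, link = sub("\\..*$", "", sub("^log_shape$", "shape", nms)),
    estimate = unname(theta), se = se,
    lower = unname(theta) - z * se, upper = unname(theta) + z * se,
    p.value = 2 * stats::pnorm(-abs(unname(theta) / se)),
    stringsAsFactors = FALSE)
  structure(list(
    coefficients = coefs, theta = theta, cov = cov,
    loglik = -op$value, aic = 2 * length(theta) + 2 * op$value,
    converged = op$convergence == 0, links = links,
    shape = exp(theta[[1]]), n = length(times),
    n_events = sum(events == 1),
    term_map = design$term_map, level = level),
    class = "cure_regression_fit")
}

#' @export
print.cure_regression_fit <- function(x, ...) {
  cat(sprintf("<cure_regression_fit> links: %s; n = %d (%d events); shape k = %.3f\n",
              paste(x$links, collapse = "+"), x$n, x$n_events, x$shape))
  cat(sprintf("  loglik = %.3f, AIC = %.2f, converged: %s\n",
              x$loglik, x$aic, x$converged))
  print(summarize_fit(x), digits = 3)
  invisible(x)
}

#' Forest-style coefficient table
#'
#' One row per term and linked parameter: estimate, Wald CI and p-value,
#' with the display-formatted p.  A non-converged fit is still summarized
#' but carries a prominent warning flag column.
#'
#' @param fit a `cure_regression_fit`.
#' @return data.frame suitable for a forest plot or TSV export.
#' @export
summarize_fit <- function(fit) {
  stopifnot(inherits(fit, "cure_regression_fit"))
  out <- fit$coefficients
  out$p.display <- format_pvalue(out$p.value)
  out$flag <- if (isTRUE(fit$converged)) "" else "NOT CONVERGED"
  if (!isTRUE(fit$converged))
    warning("summarizing a non-converged fit", call. = FALSE)
  out
}

#' Covariate-level significance calls from a cure regression
#'
#' A covariate is "flagged" when any of its design columns has a Wald CI
#' excluding 0 on any linked parameter (intercepts and the shape are never
#' flagged).
#'
#' @param fit a `cure_regression_fit`.
#' @return named logical vector, one entry per covariate.
#' @export
flagged_covariates <- function(fit) {
  stopifnot(inherits(fit, "cure_regression_fit"))
  cf <- fit$coefficients
  cf <- cf[!grepl("Intercept", cf$term) & cf$term != "log_shape", ,
           drop = FALSE]
  col <- sub("^(cure|scale)\\.", "", cf$term)
  covar <- unname(fit$term_map[col])
  sig <- !is.na(cf$lower) & !is.na(cf$upper) & (cf$lower > 0 | cf$upper < 0)
  tapply(sig, covar, any)[unique(covar)]
}
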