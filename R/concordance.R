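# Marker agreement and association battery: 2x2 cross-tabulation, Cohen's
# kappa, McNemar (uncorrected), Pearson chi-square, positivity-by-stage.

#' Cross-tabulate two binary marker call vectors
#'
#' Pairs with either value missing are dropped (pairwise complete cases).
#' The cells are ordered (pos,pos), (pos,neg) / (neg,pos), (neg,neg): rows
#' index the first marker, columns the second.
#'
#' @param calls_a,calls_b logical vectors of equal length, aligned by patient.
#' @param labels character(2): names of the two markers (for dimnames).
#' @return 2x2 integer matrix with attribute `n` (complete pairs); an
#'   all-missing input yields a zero table flagged with attribute
#'   `degenerate = TRUE` and a warning.
#' @export
crosstab <- function(calls_a, calls_b, labels = c("A", "B")) {
  if (length(calls_a) != length(calls_b))
    stop("call vectors differ in length (", length(calls_a), " vs ",
         length(calls_b), ")", call. = FALSE)
  keep <- !is.na(calls_a) & !is.na(calls_b)
  a <- calls_a[keep]; b <- calls_b[keep]
  m <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
              nrow = 2, byrow = TRUE,
              dimnames = stats::setNames(list(c("pos", "neg"), c("pos", "neg")),
                                         labels))
  attr(m, "n") <- sum(keep)
  if (sum(keep) == 0L) {
    warning("no complete pairs: degenerate empty table", call. = FALSE)
    attr(m, "degenerate") <- TRUE
  }
  m
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' observed agreement \eqn{p_o = (a+d)/n} and chance agreement \eqn{p_e}
#' from the marginal products.  Unweighted, on dichotomized calls.
#'
#' @param table 2x2 nonnegative count matrix (rows: first rater pos/neg,
#'   columns: second rater pos/neg).
#' @return numeric kappa in \[-1, 1\]; `NA` with attribute
#'   `degenerate = TRUE` when both margins are constant (\eqn{p_e = 1}).
#' @export
#' @examples
#' cohen_kappa(matrix(c(5, 12, 29, 152), 2, byrow = TRUE))  # 0.092
cohen_kappa <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0))
  storage.mode(table) <- "double"   # guard n^2 against integer overflow
  n <- sum(table)
  if (n == 0) stop("empty table", call. = FALSE)
  po <- (table[1, 1] + table[2, 2]) / n
  pe <- (sum(table[1, ]) * sum(table[, 1]) +
         sum(table[2, ]) * sum(table[, 2])) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    warning("both classifications constant (p_e = 1): kappa undefined",
            call. = FALSE)
    return(structure(NA_real_, degenerate = TRUE))
  }
  unname((po - pe) / (1 - pe))
}

#' McNemar test of marginal homogeneity (uncorrected)
#'
#' Statistic \eqn{(b - c)^2/(b + c)} on the discordant cells, without
#' continuity correction, referred to a chi-square with 1 df.  Depends only
#' on the off-diagonal cells.
#'
#' @param table 2x2 paired count matrix.
#' @return list with `statistic`, `p.value`, discordant counts `b`, `c`,
#'   and `degenerate` (`TRUE` when `b = c = 0`, reported as stat 0, p 1).
#' @export
#' @examples
#' mcnemar_test(matrix(c(5, 12, 29, 152), 2, byrow = TRUE))  # p = 0.008
mcnemar_test <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0))
  b <- table[1, 2]; cc <- table[2, 1]
  if (b + cc == 0) {
    warning("no discordant pairs: McNemar degenerate (stat 0, p 1)",
            call. = FALSE)
    return(list(statistic = 0, p.value = 1, b = b, c = cc, degenerate = TRUE))
  }
  ht <- stats::mcnemar.test(table, correct = FALSE)
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value),
       b = unname(b), c = unname(cc), degenerate = FALSE)
}

#' Pearson chi-square test of independence
#'
#' No continuity correction, no exact test.  Expected counts below 5 raise a
#' message, not an error (small strata are expected in stage tables).
#'
#' @param table r x c nonnegative count matrix.
#' @return list with `statistic`, `df`, `p.value`, `expected`, `table`.
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0))
  if (sum(table) == 0) stop("empty table", call. = FALSE)
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    lvl <- c(rownames(table)[rs == 0], colnames(table)[cs == 0])
    lvl <- lvl[!is.na(lvl)]
    stop("zero marginal for level(s): ",
         if (length(lvl)) paste(lvl, collapse = ", ") else "(unnamed)",
         call. = FALSE)
  }
  expected <- outer(rs, cs) / sum(table)
  if (min(expected) < 5)
    message(sprintf("chi-square: %d expected count(s) below 5 (min %.2f)",
                    sum(expected < 5), min(expected)))
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = unname(ht$p.value), expected = expected, table = table)
}

#' Marker positivity rates by TNM stage group
#'
#' One row per stage group: positives / non-missing denominator and the
#' percentage rounded to integer, plus the 2 x groups contingency table of
#' positive/negative counts.
#'
#' @param cohort a `cohort` with a `stage` column.
#' @param marker one of [marker_columns()].
#' @return list with `rates` (data.frame: group, positives, n, rate_pct) and
#'   `table` (2 x 3 matrix pos/neg by group).  Groups with denominator 0
#'   have `rate_pct = NA`.
#' @export
positivity_by_stage <- function(cohort, marker) {
  stopifnot(inherits(cohort, "cohort"))
  grp <- assign_stage_group(cohort$stage)
  call <- marker_call(cohort, marker)
  keep <- !is.na(grp) & !is.na(call)
  tab <- matrix(0L, nrow = 2, ncol = nlevels(grp),
                dimnames = list(c("pos", "neg"), levels(grp)))
  if (any(keep)) {
    t0 <- table(factor(ifelse(call[keep], "pos", "neg"), c("pos", "neg")),
                grp[keep])
    tab[, colnames(t0)] <- as.matrix(t0)
  }
  n <- colSums(tab)
  rates <- data.frame(group = colnames(tab), positives = tab["pos", ],
                      n = as.integer(n),
                      rate_pct = ifelse(n > 0, round(100 * tab["pos", ] / n), NA),
                      row.names = NULL, stringsAsFactors = FALSE)
  list(rates = rates, table = tab, marker = marker)
}

# build the default analysis factor for one clinicopathological covariate
.covariate_factor <- function(cohort, covariate, age_cutoff) {
  switch(covariate,
    age = factor(ifelse(cohort$age > age_cutoff,
                        sprintf("age>%s", age_cutoff),
                        sprintf("age<=%s", age_cutoff))),
    stage_group = assign_stage_group(cohort$stage),
    {
      if (!covariate %in% names(cohort))
        stop("cohort has no column '", covariate, "'", call. = FALSE)
      factor(cohort[[covariate]])
    })
}

#' Association battery: marker positivity vs clinicopathological covariates
#'
#' Runs a Pearson chi-square test of the dichotomized marker against each
#' categorical covariate.  Age is dichotomized at `age_cutoff` (default: the
#' cohort median).
#'
#' @param cohort a `cohort`.
#' @param marker one of [marker_columns()].
#' @param covariates character vector of covariates; `"age"` and
#'   `"stage_group"` receive their standard derivations, anything else must
#'   be a cohort column.
#' @param age_cutoff age threshold in years; `NULL` uses the cohort median.
#' @return list with `results` (data.frame: covariate, statistic, df,
#'   p.value, p.display) and `tables` (named list of contingency tables).
#' @export
association_battery <- function(cohort, marker,
                                covariates = c("age", "lauren", "pt", "pn",
                                               "stage_group"),
                                age_cutoff = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  call <- marker_call(cohort, marker)
  if (is.null(age_cutoff))
    age_cutoff <- stats::median(cohort$age, na.rm = TRUE)
  rows <- list(); tabs <- list()
  for (cv in covariates) {
    f <- droplevels(.covariate_factor(cohort, cv, age_cutoff))
    keep <- !is.na(call) & !is.na(f)
    f2 <- droplevels(f[keep])
    if (nlevels(f2) < 2L)
      stop("covariate '", cv, "' is constant (single level: ",
           paste(levels(f2), collapse = ""), ")", call. = FALSE)
    tab <- table(factor(ifelse(call[keep], "pos", "neg"), c("pos", "neg")), f2)
    res <- pearson_chi_square(as.matrix(tab))
    rows[[cv]] <- data.frame(covariate = cv, statistic = res$statistic,
                             df = res$df, p.value = res$p.value,
                             p.display = format_pvalue(res$p.value),
                             n = sum(keep), stringsAsFactors = FALSE)
    tabs[[cv]] <- res$table
  }
  list(results = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       tables = tabs, marker = marker, age_cutoff = age_cutoff)
}

#' Pairwise agreement battery across markers
#'
#' For every informative marker pair (all pairs of the supplied markers),
#' computes the 2x2 cross-tab on pairwise complete cases, Cohen's kappa and
#' the uncorrected McNemar test.
#'
#' @param cohort a `cohort`.
#' @param markers marker columns to pair; defaults to all informative
#'   markers (HER3 membrane excluded as near-absent).
#' @return data.frame, one row per pair, with cells (pp, pn, np, nn), n,
#'   kappa, McNemar statistic and p-value (raw and display-formatted).
#' @export
agreement_battery <- function(cohort,
                              markers = setdiff(marker_columns(),
                                                "her3_membrane")) {
  stopifnot(inherits(cohort, "cohort"), length(markers) >= 2L)
  calls <- lapply(markers, marker_call, cohort = cohort)
  names(calls) <- markers
  pairs <- utils::combn(markers, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    m1 <- pairs[1, j]; m2 <- pairs[2, j]
    tab <- crosstab(calls[[m1]], calls[[m2]], labels = c(m1, m2))
    mc <- if (tab[1, 2] + tab[2, 1] > 0) mcnemar_test(tab) else
      suppressWarnings(mcnemar_test(tab))
    data.frame(marker_a = m1, marker_b = m2,
               pp = tab[1, 1], pn = tab[1, 2], np = tab[2, 1], nn = tab[2, 2],
               n = attr(tab, "n"), kappa = cohen_kappa(tab),
               mcnemar_stat = mc$statistic, mcnemar_p = mc$p.value,
               mcnemar_p_display = format_pvalue(mc$p.value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
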