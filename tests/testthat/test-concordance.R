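test_that("crosstab drops incomplete pairs and orders cells pos-first", {
  a <- c(TRUE, TRUE, FALSE, NA, FALSE)
  b <- c(TRUE, FALSE, TRUE, TRUE, NA)
  tab <- crosstab(a, b)
  expect_equal(as.vector(t(tab)), c(1L, 1L, 1L, 0L))
  expect_equal(attr(tab, "n"), 3L)
  expect_error(crosstab(a, b[-1]), "length")
  expect_warning(t0 <- crosstab(c(TRUE, FALSE), c(NA, NA)), "degenerate")
  expect_true(isTRUE(attr(t0, "degenerate")))
  # identical vectors have empty off-diagonals
  v <- c(TRUE, FALSE, TRUE, TRUE)
  t1 <- crosstab(v, v)
  expect_equal(t1[1, 2] + t1[2, 1], 0L)
})

test_that("cohen_kappa matches hand values, the e1071 oracle, and its invariances", {
  expect_equal(cohen_kappa(matrix(c(10, 0, 0, 10), 2)), 1)
  expect_equal(round(cohen_kappa(as_2x2(list(pp = 5, pn = 12, np = 29,
                                             nn = 152))), 3), 0.092)
  set.seed(42)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    k <- cohen_kappa(tab)
    expect_equal(k, e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
    # transposition symmetry and integer-scaling invariance
    expect_equal(cohen_kappa(t(tab)), k, tolerance = 1e-12)
    expect_equal(cohen_kappa(tab * 7L), k, tolerance = 1e-12)
  }
  expect_warning(kd <- cohen_kappa(matrix(c(10, 0, 0, 0), 2)), "undefined")
  expect_true(is.na(kd))
})

test_that("kappa equals 1 exactly when and only when the off-diagonals vanish", {
  set.seed(7)
  for (i in 1:20) {
    cells <- rpois(4, 15) + 1
    tab <- matrix(cells, 2, byrow = TRUE)
    expect_equal(unname(cohen_kappa(tab) == 1),
                 unname(tab[1, 2] == 0 && tab[2, 1] == 0))
    expect_equal(cohen_kappa(matrix(c(cells[1], 0, 0, cells[4]), 2)), 1)
  }
})

test_that("uncorrected McNemar matches the hand statistic and stats oracle", {
  tab <- as_2x2(list(pp = 5, pn = 12, np = 29, nn = 152))
  mc <- mcnemar_test(tab)
  expect_equal(mc$statistic, (12 - 29)^2 / 41, tolerance = 1e-12)
  expect_equal(round(mc$statistic, 3), 7.049)
  expect_equal(round(mc$p.value, 3), 0.008)
  # invariant to the diagonal cells
  tab2 <- tab + diag(c(100, 500))
  expect_equal(mcnemar_test(tab2)$statistic, mc$statistic, tolerance = 1e-12)
  # symmetric discordance degenerates to stat 0 / p 1 only at b = c
  expect_equal(mcnemar_test(matrix(c(3, 7, 7, 9), 2))$p.value, 1)
  expect_warning(d <- mcnemar_test(matrix(c(5, 0, 0, 7), 2)), "degenerate")
  expect_true(d$degenerate)
  set.seed(11)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 12) + 1, 2)
    ht <- stats::mcnemar.test(tab, correct = FALSE)
    mc <- mcnemar_test(tab)
    expect_equal(mc$statistic, unname(ht$statistic), tolerance = 1e-12)
    expect_equal(mc$p.value, unname(ht$p.value), tolerance = 1e-12)
  }
})

test_that("pearson_chi_square: df-2 analytic tail, scaling law, zero-marginal error", {
  # for df = 2 the chi-square upper tail is exp(-stat/2)
  pp <- published_positivity()
  for (m in names(pp)) {
    res <- pearson_chi_square(positivity_matrix(pp[[m]]))
    expect_equal(res$df, 2)
    expect_equal(res$p.value, exp(-res$statistic / 2), tolerance = 1e-12)
  }
  # statistic scales linearly with an integer replication factor
  tab <- positivity_matrix(pp$her2_membrane)
  r1 <- pearson_chi_square(tab); r5 <- pearson_chi_square(tab * 5L)
  expect_equal(r5$statistic, 5 * r1$statistic, tolerance = 1e-10)
  # identical row proportions give stat 0, p 1
  flat <- rbind(c(10, 20, 30), c(10, 20, 30))
  expect_equal(pearson_chi_square(flat)$statistic, 0, tolerance = 1e-12)
  expect_equal(pearson_chi_square(flat)$p.value, 1)
  bad <- rbind(c(0, 0, 0), c(5, 5, 5)); rownames(bad) <- c("pos", "neg")
  expect_error(pearson_chi_square(bad), "zero marginal.*pos")
})

test_that("positivity_by_stage reproduces published rates on the replica", {
  ch <- study_replica_cohort(seed = 2)
  h3 <- positivity_by_stage(ch, "her3_cytoplasm")
  expect_equal(h3$rates$positives[h3$rates$group == "gIVM1"], 23)
  expect_equal(h3$rates$n[h3$rates$group == "gIVM1"], 30L)
  expect_equal(h3$rates$rate_pct[h3$rates$group == "gIVM1"], 77)
  # degenerate and saturated groups
  df <- data.frame(id = 1:4, time_months = 1, event = 0L,
                   stage = c("IA", "IA", "IVM1", "IVM1"),
                   her2_membrane = c(2L, 3L, NA, NA))
  p <- positivity_by_stage(as_cohort(df), "her2_membrane")
  expect_true(is.na(p$rates$rate_pct[p$rates$group == "gIVM1"]))
  expect_equal(p$rates$rate_pct[p$rates$group == "g0_I_II"], 100)
})

test_that("association battery is calibrated under independence and detects the replica enrichment", {
  # null: covariate independent of the marker by construction
  set.seed(314)
  pvals <- replicate(300, {
    df <- data.frame(id = seq_len(120), time_months = 1, event = 0L,
                     lauren = sample(c("intestinal", "diffuse"), 120, TRUE),
                     her2_membrane = sample(c(0L, 3L), 120, TRUE,
                                            prob = c(0.6, 0.4)))
    association_battery(as_cohort(df), "her2_membrane",
                        covariates = "lauren")$results$p.value
  })
  expect_gt(mean(pvals < 0.05), 0.01)
  expect_lt(mean(pvals < 0.05), 0.10)
  expect_gt(mean(pvals), 0.40); expect_lt(mean(pvals), 0.60)
  # replica: HER2 positivity enriched in intestinal histology
  ch <- study_replica_cohort(seed = 1)
  ab <- association_battery(ch, "her2_membrane", covariates = c("age", "lauren"))
  expect_lt(ab$results$p.value[ab$results$covariate == "lauren"], 0.05)
  tab <- ab$tables$lauren
  rate <- tab["pos", ] / colSums(tab)
  expect_gt(rate[["intestinal"]], max(rate[setdiff(colnames(tab), "intestinal")]))
  # constant covariate is a named hard error
  df <- tiny_cohort_df(); df$lauren <- "intestinal"
  expect_error(association_battery(as_cohort(df), "her2_membrane",
                                   covariates = "lauren"),
               "constant")
})

test_that("agreement battery emits one row per informative marker pair", {
  ch <- study_replica_cohort(seed = 5)
  bat <- agreement_battery(ch)
  expect_equal(nrow(bat), choose(6, 2))
  expect_true(all(bat$kappa <= 1))
  expect_true(all(bat$mcnemar_p >= 0 & bat$mcnemar_p <= 1))
  expect_true(all(bat$pp + bat$pn + bat$np + bat$nn == bat$n))
})
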