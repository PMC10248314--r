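test_that("confusion counts match hand tallies in both directions", {
  cc <- confusion_at_cutoff(c(0, 5, 2, 7), c(FALSE, TRUE, FALSE, TRUE), 4,
                            "at_or_above")
  expect_identical(unclass(cc)[c("tp", "fp", "tn", "fn")],
                   list(tp = 2L, fp = 0L, tn = 2L, fn = 0L))
  cc2 <- confusion_at_cutoff(c(45, 50), c(TRUE, FALSE), 45, "at_or_below")
  expect_identical(cc2$tp, 1L); expect_identical(cc2$tn, 1L)
  cc3 <- confusion_at_cutoff(c(1, 2, 3), c(TRUE, FALSE, TRUE), 10, "at_or_above")
  expect_identical(cc3$tp, 0L); expect_identical(cc3$fp, 0L)
  expect_error(confusion_at_cutoff(numeric(0), logical(0), 1), "empty")
  expect_error(confusion_at_cutoff(1:3, c(TRUE, FALSE), 1), "equal length")
})

test_that("classification metrics apply the standard formulas", {
  m <- classification_metrics(list(tp = 13L, fn = 7L, tn = 27L, fp = 3L))
  expect_equal(m$sensitivity, 0.65)
  expect_equal(m$specificity, 0.90)
  expect_equal(m$occ, 0.80)
  expect_equal(m$br_fail, 16 / 50)
  perfect <- classification_metrics(list(tp = 2L, tn = 2L, fp = 0L, fn = 0L))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "occ")]),
               c(sensitivity = 1, specificity = 1, occ = 1))
  blind <- classification_metrics(list(tp = 0L, fn = 10L, tn = 10L, fp = 0L))
  expect_equal(blind$sensitivity, 0)
  expect_equal(blind$specificity, 1)
  expect_error(classification_metrics(list(tp = 0L, fn = 0L, tn = 5L, fp = 5L)),
               "sensitivity undefined")
})

test_that("base rate of failure is criterion-free and direction-aware", {
  expect_equal(base_rate_fail(c(0, 1, 4, 6), 4, "at_or_above"), 0.5)
  expect_equal(base_rate_fail(c(5, 9), 1, "at_or_above"), 1.0)
  expect_equal(base_rate_fail(c(45, 50, 40), 45, "at_or_below"), 2 / 3)
  expect_error(base_rate_fail(numeric(0), 1), "empty")
})

test_that("cutoff sweeps are monotone: sens down, spec up, BR_Fail down", {
  set.seed(31)
  for (i in 1:10) {
    n <- 60
    truth <- runif(n) < 0.3
    scores <- round(rnorm(n, mean = ifelse(truth, 5, 2), sd = 2))
    tab <- roc_sweep(scores, truth, cutoffs = 0:8, "at_or_above")
    expect_true(all(diff(tab$sensitivity) <= 1e-12))
    expect_true(all(diff(tab$specificity) >= -1e-12))
    expect_true(all(diff(tab$br_fail) <= 1e-12))
    # OCC identity: occ = sens*prev + spec*(1-prev)
    prev <- mean(truth)
    expect_equal(tab$occ,
                 tab$sensitivity * prev + tab$specificity * (1 - prev))
  }
  one <- roc_sweep(c(1, 5), c(FALSE, TRUE), 3)
  expect_identical(nrow(one), 1L)
  expect_equal(one$occ, 1)
  expect_error(roc_sweep(c(1, 5), c(TRUE, TRUE), 3), "negative")
})

test_that("AUC equals the exhaustive pairwise oracle on all small cohorts", {
  expect_equal(auc_mann_whitney(c(3, 5, 5, 1, 5, 2),
                                c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$auc,
               7 / 9)
  set.seed(41)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    truth <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    scores <- sample(0:4, n, replace = TRUE)
    dirn <- sample(c("at_or_above", "at_or_below"), 1)
    expect_equal(auc_mann_whitney(scores, truth, dirn)$auc,
                 auc_pair_oracle(scores, truth, dirn))
  }
})

test_that("AUC equals trapezoidal ROC area and matches pROC on larger cohorts", {
  skip_if_not_installed("pROC")
  set.seed(43)
  for (i in 1:10) {
    n <- 80
    truth <- c(TRUE, FALSE, runif(n - 2) < 0.35)
    scores <- round(rnorm(n, ifelse(truth, 4, 2), 2), 1)
    est <- auc_mann_whitney(scores, truth, "at_or_above")
    expect_equal(est$auc, auc_trapezoid_oracle(scores, truth, "at_or_above"))
    proc <- pROC::roc(response = truth, predictor = scores,
                      direction = "<", quiet = TRUE)
    expect_equal(est$auc, as.numeric(pROC::auc(proc)))
  }
})

test_that("AUC degenerate and boundary behavior", {
  same <- c(1, 2, 3)
  expect_equal(auc_mann_whitney(c(same, same),
                                c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$auc,
               0.5)
  sep <- auc_mann_whitney(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$auc, 1.0)
  expect_lte(sep$ci_hi, 1.0)
  expect_error(auc_mann_whitney(1:3, c(TRUE, TRUE, TRUE)), "negative case")
})

test_that("likelihood ratios reproduce printed cross-range quotients", {
  expect_equal(fmt_prop(likelihood_ratio(36.3, 6.9), 2), 5.26)
  expect_equal(fmt_prop(likelihood_ratio(82.9, 6.9), 2), 12.01)
  expect_equal(likelihood_ratio(7, 7), 1)
  expect_error(likelihood_ratio(5, 0), "zero denominator")
})

test_that("range analysis recovers planted band-wise rates and LR identities", {
  set.seed(51)
  n_band <- c(Pass = 400, Borderline = 200, Fail = 150)
  bands <- rep(names(n_band), n_band)
  planted <- c(Pass = 0.05, Borderline = 0.25, Fail = 0.60)
  fails <- unlist(lapply(names(n_band), function(b) {
    k <- round(planted[[b]] * n_band[[b]])  # exact planted counts
    sample(rep(c(TRUE, FALSE), c(k, n_band[[b]] - k)))
  }))
  res <- range_br_analysis(bands, list(crit = fails))
  expect_equal(res$br$pass, 5); expect_equal(res$br$fail, 60)
  expect_equal(res$lr$f_over_p[1], 12)
  # multiplicativity F/P = F/B * B/P at full precision
  expect_equal(res$lr$f_over_p[1], res$lr$f_over_b[1] * res$lr$b_over_p[1])
  # identical rates across bands => all LRs 1
  flat <- range_br_analysis(rep(c("Pass", "Borderline", "Fail"), each = 10),
                            list(c1 = rep(c(TRUE, FALSE), 15)))
  expect_equal(unlist(flat$lr[flat$lr$criterion == "c1", -1]),
               c(b_over_p = 1, f_over_b = 1, f_over_p = 1))
  expect_error(range_br_analysis(rep("Pass", 5), list(c1 = rep(TRUE, 5))),
               "every band")
})

test_that("per-value LR profile is relative to the zero-score baseline", {
  scores <- c(0, 0, 0, 0, 1, 1, 2, 2)
  fails <- c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  prof <- value_lr_profile(scores, list(crit = fails))
  expect_equal(prof$br_crit, c(25, 50, 100))
  expect_equal(prof$lr_crit, c(1, 2, 4))
  expect_error(value_lr_profile(c(1, 2), list(crit = c(TRUE, FALSE))),
               "baseline")
})

test_that("Cohen's d conventions: average-variance default, pooled optional", {
  expect_equal(fmt_prop(cohens_d(284.5, 20.4, 237.8, 40.0), 2), 1.47)
  expect_equal(fmt_prop(cohens_d(284.5, 20.4, 265.1, 33.6), 2), 0.70)
  expect_equal(cohens_d(5, 1, 5, 2), 0)
  # pooled-by-df variant collapses to the same answer at equal n
  expect_equal(cohens_d(3, 2, 1, 2, pooled = TRUE, n1 = 10, n2 = 10),
               cohens_d(3, 2, 1, 2))
  expect_error(cohens_d(1, 0, 2, 1), "positive")
})

test_that("phi-squared identity and Pearson chi-square wrapper", {
  expect_equal(fmt_prop(phi_squared(90.0, 452), 3), 0.199)
  expect_equal(fmt_prop(phi_squared(29.6, 239), 3), 0.124)
  tab <- matrix(c(30, 10, 15, 25), 2)
  expect_equal(phi_squared(chi2_rxc(tab), sum(tab)),
               chi2_rxc(tab) / 80)
  # identical row distributions carry no association
  expect_equal(chi2_rxc(matrix(c(10, 20, 10, 20), 2)), 0)
  expect_error(chi2_rxc(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "zero margin")
})

test_that("display rounding is half away from zero", {
  expect_equal(fmt_prop(0.125, 2), 0.13)
  expect_equal(fmt_prop(-0.125, 2), -0.13)
  expect_equal(fmt_prop(2.5, 0), 3)
})
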