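test_that("normality gate accepts Gaussian and rejects skewed samples", {
  hits_normal <- 0
  hits_exp <- 0
  for (seed in 1:100) {
    set.seed(seed)
    if (ks_normality(rnorm(200))$is_normal) hits_normal <- hits_normal + 1
    if (!ks_normality(rexp(200))$is_normal) hits_exp <- hits_exp + 1
  }
  expect_gte(hits_normal, 90)
  expect_gte(hits_exp, 90)

  expect_false(ks_normality(rep(5, 10))$is_normal)  # zero variance
  expect_false(ks_normality(c(1, 2, 3, 4))$is_normal)  # below table range
  expect_error(ks_normality(c(1, 2, 3)), "at least 4")
})

test_that("two-group test switches correctly and matches known p-values", {
  # {1,2,3} vs {4,5,6}: U = 0, exact two-sided p = 2/20
  tt <- two_group_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$test_used, "mann_whitney")
  expect_true(tt$exact)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 0.1)

  # identical constant groups carry no evidence
  expect_equal(two_group_test(c(5, 5, 5), c(5, 5, 5))$p_value, 1)

  # normal route uses the Welch t-test
  set.seed(1)
  tt <- two_group_test(rnorm(10), rnorm(10), is_normal = TRUE)
  expect_equal(tt$test_used, "t_test")

  # ties or large samples fall back to the corrected normal approximation
  tt <- two_group_test(c(1, 2, 2, 3), c(2, 4, 5), is_normal = FALSE)
  expect_false(tt$exact)
  expect_error(two_group_test(1, c(2, 3)), "at least 2")
})

test_that("exact Mann-Whitney p equals the full-permutation oracle", {
  set.seed(77)
  for (i in 1:40) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    # continuous draws: ties almost surely absent
    a <- rnorm(n1)
    b <- rnorm(n2, mean = sample(c(0, 2), 1))
    p_pkg <- two_group_test(a, b)$p_value
    p_oracle <- oracle_mw_permutation(a, b)
    expect_equal(p_pkg, p_oracle, tolerance = 1e-12)
  }
})

test_that("AUC equals the normalised Mann-Whitney statistic", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    n_pos <- sample(2:(n - 2), 1)
    scores <- if (i %% 3 == 0) sample(1:8, n, replace = TRUE) else rnorm(n)
    labels <- rep("CMR", n)
    labels[sample(n, n_pos)] <- "PMR"
    rc <- roc_analysis(scores, labels)
    auc_oracle <- oracle_auc_pairs(scores, labels == "PMR")
    expect_equal(rc$auc, max(auc_oracle, 1 - auc_oracle), tolerance = 1e-12)
  }
})

test_that("ROC cutoff, orientation and accuracy behave as specified", {
  # perfect separation
  rc <- roc_analysis(c(1, 2, 3, 10, 11), c("CMR", "CMR", "CMR", "PMR", "PMR"))
  expect_equal(rc$auc, 1)
  expect_equal(rc$sensitivity, 100)
  expect_equal(rc$specificity, 100)
  expect_equal(rc$accuracy, 100)
  expect_equal(rc$orientation, "higher")

  # inverted separation flips the orientation, AUC stays >= 0.5
  rc <- roc_analysis(c(10, 11, 12, 1, 2), c("CMR", "CMR", "CMR", "PMR", "PMR"))
  expect_equal(rc$auc, 1)
  expect_equal(rc$orientation, "lower")
  expect_true(all(c(1, 2) <= rc$cutoff) && all(c(10, 11, 12) > rc$cutoff))

  # accuracy is always the prevalence-weighted mean of sens and spec
  set.seed(12)
  for (i in 1:25) {
    n <- sample(8:30, 1)
    scores <- rnorm(n)
    labels <- rep("CMR", n)
    labels[sample(n, sample(2:(n - 2), 1))] <- "PMR"
    rc <- roc_analysis(scores, labels)
    expect_equal(rc$accuracy_raw,
                 (rc$sensitivity_raw * rc$n_pos + rc$specificity_raw * rc$n_neg) /
                   (rc$n_pos + rc$n_neg), tolerance = 1e-12)
    expect_gte(rc$auc, 0.5)
  }

  expect_error(roc_analysis(1:5, rep("CMR", 5)), "both classes")
})

test_that("ROC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(60)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    scores <- round(rnorm(n), 2)
    labels <- rep("CMR", n)
    labels[sample(n, sample(3:(n - 3), 1))] <- "PMR"
    rc <- roc_analysis(scores, labels)
    ref <- pROC::roc(response = labels, predictor = scores,
                     levels = c("CMR", "PMR"), quiet = TRUE)
    expect_equal(rc$auc, max(as.numeric(ref$auc), 1 - as.numeric(ref$auc)),
                 tolerance = 1e-12)
  }
})

test_that("comparison plans draw only from their allowed sources", {
  plan <- comparison_plan("predict_interim")
  expect_equal(plan$sources, "f0")
  expect_equal(plan$label_col, "label_t1")
  expect_setequal(comparison_plan("assess_eot")$sources, c("f2", "d02", "d12"))

  # a predict_interim run never touches T1/T2 features: only baseline values
  # differ between groups yet nothing else is even looked at
  set.seed(5)
  ids <- sprintf("P%02d", 1:12)
  f <- do.call(rbind, lapply(0:2, function(tp)
    synth_feature_table(rnorm(12, mean = 100 + 50 * tp), ids, timepoint = tp)))
  # poison non-baseline values: if the plan touched them it would error
  f$value[f$timepoint > 0] <- NA
  man <- synth_manifest(ids, label_t1 = rep(c("CMR", "PMR"), each = 6))
  cmp <- run_comparisons(f, NULL, man, "predict_interim")
  expect_equal(nrow(cmp), 1L)
  expect_equal(cmp$source, "f0")
  expect_equal(cmp$n_cmr, 6L)
})

test_that("comparisons gate ROC on significance and report completeness", {
  set.seed(42)
  ids <- sprintf("P%02d", 1:18)
  lab <- c(rep("CMR", 15), rep("PMR", 3))
  # one strongly separated feature, one null feature
  v_sep <- c(rnorm(15, 100, 5), rnorm(3, 160, 5))
  v_null <- rnorm(18, 100, 5)
  f <- rbind(synth_feature_table(v_sep, ids, 2, "DV", 40),
             synth_feature_table(v_null, ids, 2, "ADCmean", 40))
  man <- synth_manifest(ids, label_t1 = lab, label_t2 = lab)
  cmp <- run_comparisons(f, NULL, man, "assess_eot")
  sep <- cmp[cmp$feature_name == "DV", ]
  nul <- cmp[cmp$feature_name == "ADCmean", ]
  expect_true(sep$significant)
  expect_gt(sep$auc, 0.9)
  expect_false(is.na(sep$cutoff))
  if (!nul$significant) expect_true(is.na(nul$auc))
  # medians/IQRs always present
  expect_false(any(is.na(cmp$median_cmr)))

  # SMD/PMD patients are excluded from the comparison
  lab2 <- c(rep("CMR", 13), "PMD", "PMD", rep("PMR", 3))
  man2 <- synth_manifest(ids, label_t1 = lab2, label_t2 = lab2)
  cmp2 <- run_comparisons(f, NULL, man2, "assess_eot")
  expect_equal(unique(cmp2$n_cmr), 13L)

  # a feature missing for one included patient is skipped with a reason
  f_missing <- f
  f_missing$value[f_missing$feature_name == "ADCmean" &
                    f_missing$patient_id == "P01"] <- NA
  cmp3 <- run_comparisons(f_missing, NULL, man, "assess_eot")
  expect_false("ADCmean" %in% cmp3$feature_name)
  comp <- attr(cmp3, "completeness")
  expect_equal(comp$feature_name, "ADCmean")
  expect_match(comp$reason, "P01")

  # single-class cohorts cannot be compared
  man_one <- synth_manifest(ids, label_t1 = rep("PMR", 18))
  expect_error(run_comparisons(f, NULL, man_one, "assess_eot"), "both CMR")
})
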