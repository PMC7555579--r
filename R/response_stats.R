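#' Normality gate for feature values
#'
#' Lilliefors-corrected Kolmogorov-Smirnov test against a normal
#' distribution with estimated mean and standard deviation. The Lilliefors
#' correction is used because the reference parameters are estimated from
#' the same sample. The decision at `alpha` drives the choice between the
#' Welch t-test and the Mann-Whitney U test downstream.
#'
#' A zero-variance sample is declared non-normal by convention. Samples of
#' exactly 4 values (below the Lilliefors table range) are treated as
#' non-normal — the conservative choice, routing them to the rank test.
#'
#' @param values Numeric sample, n >= 4.
#' @param alpha Decision level (default 0.05).
#' @return List with `p_value` and `is_normal`.
#' @export
ks_normality <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4L) stop("normality test needs at least 4 values")
  if (stats::sd(values) == 0)
    return(list(p_value = 0, is_normal = FALSE))
  if (n == 4L)
    return(list(p_value = NA_real_, is_normal = FALSE))
  p <- nortest::lillie.test(values)$p.value
  list(p_value = p, is_normal = p >= alpha)
}

#' Two-group location test
#'
#' Welch t-test when both groups passed the normality gate, otherwise the
#' two-sided Mann-Whitney U test. The U test is computed exactly (full null
#' enumeration) when the combined sample size is at most 14 and there are
#' no ties — the regime of the small responder groups this analysis
#' targets, where exactness matters — and by the normal approximation with
#' tie correction otherwise.
#'
#' @param group_a,group_b Numeric samples, each of size >= 2.
#' @param is_normal Logical: did both groups pass the normality gate?
#' @return List with `test_used` (`"t_test"` or `"mann_whitney"`),
#'   `p_value`, and the test statistic (`t` or `U` for group A).
#' @export
two_group_test <- function(group_a, group_b, is_normal = FALSE) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 finite values")
  if (isTRUE(is_normal)) {
    ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
    return(list(test_used = "t_test", p_value = ht$p.value,
                statistic = unname(ht$statistic)))
  }
  n <- length(group_a) + length(group_b)
  pooled <- c(group_a, group_b)
  if (stats::var(pooled) == 0)  # all values identical: no evidence either way
    return(list(test_used = "mann_whitney", p_value = 1,
                statistic = length(group_a) * length(group_b) / 2,
                exact = FALSE))
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- n <= 14L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = use_exact, correct = TRUE)
  )
  list(test_used = "mann_whitney", p_value = ht$p.value,
       statistic = unname(ht$statistic), exact = use_exact)
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Empirical ROC of a scalar feature for discriminating the positive class
#' (by default PMR, the poor responders) from the negative class. The
#' orientation — whether high or low values indicate the positive class —
#' is chosen per feature so that AUC >= 0.5, and is always reported, since
#' the discriminating direction genuinely differs between features
#' (e.g. diffusion volume rises with poor response while ADC percentiles
#' fall).
#'
#' AUC is the tie-corrected rank statistic (equal to U/(n1*n2) with half
#' credit for ties). Candidate cutoffs are midpoints between consecutive
#' distinct score values plus the two outer extremes; the reported cutoff
#' maximises Youden's J = sensitivity + specificity - 1, breaking ties
#' toward higher specificity. Sensitivity, specificity and accuracy are
#' reported in percent, rounded to the nearest integer for display with
#' unrounded values retained; accuracy is the prevalence-weighted mean of
#' sensitivity and specificity.
#'
#' @param scores Numeric feature values, one per patient.
#' @param labels Class labels parallel to `scores`.
#' @param positive Label of the positive class (default `"PMR"`).
#' @return List: `auc`, `cutoff`, `sensitivity`, `specificity`, `accuracy`
#'   (integer percent), `sensitivity_raw`, `specificity_raw`,
#'   `accuracy_raw` (unrounded percent), `orientation` (`"higher"` if
#'   scores >= cutoff call the positive class, else `"lower"`), `n_pos`,
#'   `n_neg`.
#' @export
roc_analysis <- function(scores, labels, positive = "PMR") {
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC needs both classes present")

  # tie-corrected AUC via ranks: P(score_pos > score_neg) + 0.5 P(equal)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  orientation <- "higher"
  s <- scores
  if (auc < 0.5) {
    orientation <- "lower"
    auc <- 1 - auc
    s <- -scores
  }

  u <- sort(unique(s))
  cuts <- c(u[1L] - 1, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  best <- NULL
  for (cut in cuts) {
    pred_pos <- s >= cut
    sens <- sum(pred_pos & pos) / n_pos
    spec <- sum(!pred_pos & !pos) / n_neg
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec + 1e-12)) {
      best <- list(cut = cut, sens = sens, spec = spec, j = j)
    }
  }
  acc <- (best$sens * n_pos + best$spec * n_neg) / (n_pos + n_neg)
  cutoff <- if (orientation == "lower") -best$cut else best$cut
  list(auc = auc, cutoff = cutoff,
       sensitivity = round(100 * best$sens),
       specificity = round(100 * best$spec),
       accuracy = round(100 * acc),
       sensitivity_raw = 100 * best$sens,
       specificity_raw = 100 * best$spec,
       accuracy_raw = 100 * acc,
       youden_j = best$j,
       orientation = orientation, n_pos = n_pos, n_neg = n_neg)
}

COMPARISON_MODES <- c("predict_interim", "predict_eot",
                      "assess_interim", "assess_eot")

#' Candidate feature sources and grouping label for a comparison mode
#'
#' Each analysis mode draws on a fixed set of feature sources:
#' * `predict_interim` — baseline features (`f0`) vs interim response;
#' * `predict_eot` — baseline (`f0`), interim (`f1`) and
#'   baseline-to-interim changes (`d01`) vs EOT response;
#' * `assess_interim` — interim features (`f1`) and `d01` vs interim
#'   response;
#' * `assess_eot` — EOT features (`f2`), baseline-to-EOT (`d02`) and
#'   interim-to-EOT (`d12`) changes vs EOT response.
#'
#' @param mode One of `"predict_interim"`, `"predict_eot"`,
#'   `"assess_interim"`, `"assess_eot"`.
#' @return List with `sources` (character: `f0`/`f1`/`f2`/`d01`/`d02`/`d12`)
#'   and `label_col` (`"label_t1"` or `"label_t2"`).
#' @export
comparison_plan <- function(mode) {
  mode <- match.arg(mode, COMPARISON_MODES)
  switch(mode,
    predict_interim = list(mode = mode, sources = "f0", label_col = "label_t1"),
    predict_eot = list(mode = mode, sources = c("f0", "f1", "d01"),
                       label_col = "label_t2"),
    assess_interim = list(mode = mode, sources = c("f1", "d01"),
                          label_col = "label_t1"),
    assess_eot = list(mode = mode, sources = c("f2", "d02", "d12"),
                      label_col = "label_t2"))
}

#' Run the CMR-vs-PMR comparisons for one analysis mode
#'
#' For every candidate feature (feature name x threshold x source allowed
#' by the mode's plan) the per-patient values of the complete (CMR) and
#' partial (PMR) responders are compared: the normality gate
#' ([ks_normality()], per group, both groups must pass and have n >= 5)
#' selects the test in [two_group_test()]; ROC statistics are computed only
#' for features significant at `alpha`. Group medians and interquartile
#' ranges are always reported. Patients labelled SMD or PMD at the mode's
#' timepoint are excluded from the comparison, as are features with any
#' missing value among the included patients (these are listed in the
#' completeness report).
#'
#' No multiple-testing correction is applied to the significance calls;
#' Benjamini-Hochberg q-values are reported as a supplementary column
#' (`q_value`) for reference only and play no role in feature selection.
#'
#' @param features Feature table ([extract_patient_features()] stacked).
#' @param deltas Delta table ([compute_deltas()]); may be `NULL` for
#'   `predict_interim`.
#' @param manifest A `cohort_manifest`.
#' @param mode Analysis mode, see [comparison_plan()].
#' @param alpha Significance level (default 0.05).
#' @param positive Positive class for ROC (default `"PMR"`).
#' @return Data.frame with one row per candidate feature: identification
#'   (`source`, `feature_name`, `threshold_percent`), group summaries
#'   (`median_cmr`, `q1_cmr`, `q3_cmr`, `median_pmr`, `q1_pmr`, `q3_pmr`,
#'   `n_cmr`, `n_pmr`), `test_used`, `p_value`, `q_value`, `significant`,
#'   and — where significant — `auc`, `cutoff`, `sensitivity`,
#'   `specificity`, `accuracy`, `orientation`. Attribute `completeness`
#'   holds a data.frame of skipped features with reasons.
#' @export
run_comparisons <- function(features, deltas, manifest, mode,
                            alpha = 0.05, positive = "PMR") {
  plan <- comparison_plan(mode)
  man <- as.data.frame(manifest)
  lab <- man[[plan$label_col]]
  keep <- lab %in% c("CMR", positive)
  ids <- man$patient_id[keep]
  lab <- lab[keep]
  if (length(unique(lab)) < 2L)
    stop(sprintf("mode %s: need both CMR and %s patients (have %s)",
                 mode, positive, paste(unique(lab), collapse = ", ")))

  value_table <- function(source) {
    if (startsWith(source, "f")) {
      tp <- as.integer(substr(source, 2L, 2L))
      df <- features[features$timepoint == tp, ]
      df$source <- source
      df[, c("patient_id", "source", "feature_name", "threshold_percent", "value")]
    } else {
      pr <- substr(source, 2L, 3L)
      if (is.null(deltas)) return(NULL)
      df <- deltas[deltas$pair == pr, ]
      df$source <- source
      df[, c("patient_id", "source", "feature_name", "threshold_percent", "value")]
    }
  }
  cand <- do.call(rbind, lapply(plan$sources, value_table))
  cand <- cand[cand$patient_id %in% ids, ]

  skipped <- list()
  rows <- list()
  combos <- unique(cand[, c("source", "feature_name", "threshold_percent")])
  combos <- combos[order(combos$source,
                         match(combos$feature_name, FEATURE_NAMES),
                         combos$threshold_percent), ]
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    sub <- cand[cand$source == cb$source &
                cand$feature_name == cb$feature_name &
                cand$threshold_percent == cb$threshold_percent, ]
    v <- sub$value[match(ids, sub$patient_id)]
    if (any(is.na(v))) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        source = cb$source, feature_name = cb$feature_name,
        threshold_percent = cb$threshold_percent,
        reason = sprintf("missing value for patient(s) %s",
                         paste(ids[is.na(v)], collapse = ", ")),
        stringsAsFactors = FALSE)
      next
    }
    g_cmr <- v[lab == "CMR"]
    g_pmr <- v[lab == positive]
    if (length(g_cmr) < 2L || length(g_pmr) < 2L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        source = cb$source, feature_name = cb$feature_name,
        threshold_percent = cb$threshold_percent,
        reason = "a group has fewer than 2 patients", stringsAsFactors = FALSE)
      next
    }
    normal_a <- length(g_cmr) >= 5L && ks_normality(g_cmr)$is_normal
    normal_b <- length(g_pmr) >= 5L && ks_normality(g_pmr)$is_normal
    tt <- two_group_test(g_cmr, g_pmr, is_normal = normal_a && normal_b)
    qs <- function(g) unname(stats::quantile(g, c(0.25, 0.5, 0.75), type = 7))
    qc <- qs(g_cmr); qp <- qs(g_pmr)
    row <- data.frame(
      source = cb$source, feature_name = cb$feature_name,
      threshold_percent = cb$threshold_percent,
      n_cmr = length(g_cmr), n_pmr = length(g_pmr),
      median_cmr = qc[2L], q1_cmr = qc[1L], q3_cmr = qc[3L],
      median_pmr = qp[2L], q1_pmr = qp[1L], q3_pmr = qp[3L],
      test_used = tt$test_used, p_value = tt$p_value,
      significant = is.finite(tt$p_value) && tt$p_value < alpha,
      auc = NA_real_, cutoff = NA_real_, sensitivity = NA_real_,
      specificity = NA_real_, accuracy = NA_real_,
      orientation = NA_character_, stringsAsFactors = FALSE)
    if (row$significant) {
      rc <- roc_analysis(v, lab, positive = positive)
      row$auc <- rc$auc; row$cutoff <- rc$cutoff
      row$sensitivity <- rc$sensitivity; row$specificity <- rc$specificity
      row$accuracy <- rc$accuracy; row$orientation <- rc$orientation
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stop(sprintf("mode %s: no complete candidate features", mode))
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$mode <- mode
  attr(out, "completeness") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(source = character(0), feature_name = character(0),
               threshold_percent = numeric(0), reason = character(0))
  out
}
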