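DEFAULT_THRESHOLDS <- c(5, 10, 20, 40, 60, 80)

FEATURE_NAMES <- c("DV", "ADCmean", "ADCsd", "ADCmd", "ADC5p", "ADC95p",
                   "ADCsk", "ADCkurt", "ADCentr")

#' Threshold-based segmentation of the high-b-value volume
#'
#' Selects every voxel whose intensity is at least `threshold_percent`% of
#' a per-volume reference intensity. This is the fully automatic "total
#' tumor load" segmentation: no mask editing, hole filling or
#' connected-component filtering is applied afterwards, so physiologically
#' hyperintense structures (brain, kidneys, spleen, activated bone marrow)
#' deliberately remain in the mask.
#'
#' The percentage reference is not standardised across vendor tools; the
#' default here is the robust maximum — the 99.9th percentile of positive
#' voxel intensities — which is insensitive to isolated hot voxels.
#' Alternatives: `"max"` (absolute maximum) and `"mean_sd"`
#' (mean + `k` standard deviations of positive voxels).
#'
#' @param volume An [image_volume] (typically the b = 800 s/mm^2 image).
#' @param threshold_percent Threshold in percent, in (0, 100].
#' @param reference Reference rule: `"p99.9"` (default), `"max"`, or
#'   `"mean_sd"`.
#' @param k Standard-deviation multiplier for `reference = "mean_sd"`.
#' @return A `threshold_mask`: list with `mask` (logical array),
#'   `threshold_percent`, `reference_intensity`, `reference_rule`.
#' @export
segment_threshold <- function(volume, threshold_percent,
                              reference = c("p99.9", "max", "mean_sd"),
                              k = 3) {
  stopifnot(inherits(volume, "image_volume"))
  reference <- match.arg(reference)
  if (!is.numeric(threshold_percent) || length(threshold_percent) != 1L ||
      threshold_percent <= 0 || threshold_percent > 100)
    stop("`threshold_percent` must be a single value in (0, 100]")
  pos <- volume$data[volume$data > 0]
  if (length(pos) == 0L)
    stop("cannot derive a reference intensity: volume has no positive voxels")
  ref <- switch(reference,
    "p99.9" = unname(stats::quantile(pos, 0.999, type = 7)),
    "max" = max(pos),
    "mean_sd" = mean(pos) + k * stats::sd(pos))
  mask <- volume$data >= (threshold_percent / 100) * ref
  structure(
    list(mask = mask, threshold_percent = threshold_percent,
         reference_intensity = ref, reference_rule = reference),
    class = "threshold_mask"
  )
}

#' @export
print.threshold_mask <- function(x, ...) {
  cat(sprintf("<threshold_mask> th = %g%% of %.4g (%s), %d voxels\n",
              x$threshold_percent, x$reference_intensity, x$reference_rule,
              sum(x$mask)))
  invisible(x)
}

#' Diffusion volume of a mask
#'
#' Total segmented volume in cm^3 by pure voxel counting:
#' `DV = n_voxels * dx * dy * dz / 1000`.
#'
#' @param mask A `threshold_mask` or logical array.
#' @param spacing Voxel spacing `(dx, dy, dz)` in mm.
#' @return Volume in cm^3 (0 for an empty mask).
#' @export
diffusion_volume <- function(mask, spacing) {
  m <- if (inherits(mask, "threshold_mask")) mask$mask else mask
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes in mm")
  sum(m) * prod(spacing) / 1000
}

#' First-order ADC histogram statistics over a mask
#'
#' Computes the eight ADC histogram features over the valid masked voxels:
#' arithmetic mean, sample standard deviation (n-1 denominator), median,
#' 5th and 95th percentiles (linear interpolation between order
#' statistics), Fisher-Pearson skewness, Fisher excess kurtosis (0 for a
#' normal distribution), and Shannon entropy in bits over a fixed-range
#' histogram. The entropy histogram uses `entropy_bins` equal-width bins
#' spanning `entropy_range` (default 1024 bins over 0..4000 x 1e-6 mm^2/s);
#' values outside the range are clamped into the edge bins. The fixed range
#' keeps entropy comparable across timepoints and patients.
#'
#' Moments use no small-sample bias correction: skewness is
#' `m3 / m2^(3/2)` and excess kurtosis `m4 / m2^2 - 3` with central moments
#' `m_k` averaged over n. Statistics that need more voxels than the mask
#' holds (sd: 2; skewness: 3; kurtosis: 4) — or any moment ratio on a
#' zero-variance sample — are returned as `NA` (undefined); the others are
#' still computed.
#'
#' @param adc An `adc_map` (from [compute_adc()] or [as_adc_map()]).
#' @param mask A `threshold_mask` or logical array on the same grid.
#' @param entropy_bins Number of histogram bins (default 1024).
#' @param entropy_range Numeric length-2 ADC range in 1e-6 mm^2/s for the
#'   entropy histogram (default `c(0, 4000)`).
#' @return Named list: the eight statistics plus `n_voxels` (count of valid
#'   masked voxels entering the statistics).
#' @export
histogram_features <- function(adc, mask, entropy_bins = 1024,
                               entropy_range = c(0, 4000)) {
  stopifnot(inherits(adc, "adc_map"))
  m <- if (inherits(mask, "threshold_mask")) mask$mask else mask
  if (!identical(dim(m), dim(adc$volume$data)))
    stop("mask and ADC map are on different grids")
  x <- adc$volume$data[m & adc$validity]
  n <- length(x)
  if (n == 0L)
    stop("empty mask: no valid ADC voxels under the segmentation")

  mu <- mean(x)
  sdv <- if (n >= 2L) stats::sd(x) else NA_real_
  q <- unname(stats::quantile(x, c(0.05, 0.5, 0.95), type = 7))
  m2 <- mean((x - mu)^2)
  skew <- if (n >= 3L && m2 > 0) mean((x - mu)^3) / m2^1.5 else NA_real_
  kurt <- if (n >= 4L && m2 > 0) mean((x - mu)^4) / m2^2 - 3 else NA_real_

  # fixed-range histogram; out-of-range values clamped to the edge bins
  edges <- seq(entropy_range[1L], entropy_range[2L], length.out = entropy_bins + 1L)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L
  bin[bin > entropy_bins] <- entropy_bins
  p <- tabulate(bin, nbins = entropy_bins) / n
  p <- p[p > 0]
  entr <- -sum(p * log2(p))

  list(ADCmean = mu, ADCsd = sdv, ADCmd = q[2L], ADC5p = q[1L],
       ADC95p = q[3L], ADCsk = skew, ADCkurt = kurt, ADCentr = entr,
       n_voxels = n)
}

#' Percentage change between two feature values
#'
#' `100 * (f_later - f_earlier) / f_earlier`, the inter-timepoint change
#' used for all delta features: baseline-referenced changes use T0 as the
#' earlier value, the after-vs-during change uses T1. A zero denominator
#' yields `NA` with a warning; pipeline code carries these as flagged
#' missing delta records.
#'
#' @param f_later,f_earlier Feature values (vectorised).
#' @return Percentage change(s).
#' @export
pct_change <- function(f_later, f_earlier) {
  out <- 100 * (f_later - f_earlier) / f_earlier
  zero <- is.finite(f_earlier) & f_earlier == 0
  if (any(zero, na.rm = TRUE)) {
    warning("zero denominator in percentage change; returning NA")
    out[zero] <- NA_real_
  }
  out
}

#' Extract the full per-timepoint feature set for one patient series
#'
#' Computes the ADC map once, then for every segmentation threshold the
#' diffusion volume plus the eight ADC histogram statistics — 9 features x
#' 6 default thresholds = 54 records per patient-timepoint.
#'
#' @param series A [dwi_series] holding the b-value pair.
#' @param thresholds Segmentation thresholds in percent
#'   (default `c(5, 10, 20, 40, 60, 80)`).
#' @param b_low,b_high The b-value pair; segmentation runs on `b_high`.
#' @param reference Threshold reference rule, see [segment_threshold()].
#' @param clip_negative Passed to [compute_adc()].
#' @param entropy_bins,entropy_range Passed to [histogram_features()].
#' @param adc Optional precomputed `adc_map` to use instead of recomputing
#'   from the series.
#' @return A data.frame of feature records with columns `patient_id`,
#'   `timepoint`, `threshold_percent`, `feature_name`, `value`, `n_voxels`.
#'   Units: cm^3 for DV; 1e-6 mm^2/s for mean/sd/md/5p/95p; dimensionless
#'   for skewness/kurtosis/entropy.
#' @export
extract_patient_features <- function(series,
                                     thresholds = DEFAULT_THRESHOLDS,
                                     b_low = 50, b_high = 800,
                                     reference = "p99.9",
                                     clip_negative = FALSE,
                                     entropy_bins = 1024,
                                     entropy_range = c(0, 4000),
                                     adc = NULL) {
  stopifnot(inherits(series, "dwi_series"))
  if (is.null(adc))
    adc <- compute_adc(series, b_low = b_low, b_high = b_high,
                       clip_negative = clip_negative)
  bvol <- get_bvolume(series, b_high)
  rows <- lapply(thresholds, function(th) {
    msk <- segment_threshold(bvol, th, reference = reference)
    dv <- diffusion_volume(msk, bvol$spacing)
    hf <- tryCatch(
      histogram_features(adc, msk, entropy_bins = entropy_bins,
                         entropy_range = entropy_range),
      error = function(e) stop(sprintf(
        "patient %s T%d th=%g%%: %s", series$patient_id, series$timepoint,
        th, conditionMessage(e)), call. = FALSE))
    data.frame(
      patient_id = series$patient_id,
      timepoint = series$timepoint,
      threshold_percent = th,
      feature_name = FEATURE_NAMES,
      value = c(dv, hf$ADCmean, hf$ADCsd, hf$ADCmd, hf$ADC5p, hf$ADC95p,
                hf$ADCsk, hf$ADCkurt, hf$ADCentr),
      n_voxels = c(sum(msk$mask), rep(hf$n_voxels, 8L)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Inter-timepoint percentage-change table
#'
#' Builds delta records for the pairs baseline-to-interim (`"01"`),
#' baseline-to-EOT (`"02"`) and interim-to-EOT (`"12"`) from a long-format
#' feature table covering multiple timepoints. The earlier timepoint of
#' each pair is the denominator. Records whose denominator feature is zero
#' or whose endpoint is undefined are kept with `value = NA` and
#' `flagged = TRUE`.
#'
#' @param features Feature table from [extract_patient_features()] rows
#'   (multiple patients/timepoints stacked).
#' @param pairs Character subset of `c("01", "02", "12")`.
#' @return Data.frame with columns `patient_id`, `threshold_percent`,
#'   `feature_name`, `pair`, `value`, `flagged`.
#' @export
compute_deltas <- function(features, pairs = c("01", "02", "12")) {
  pairs <- match.arg(pairs, several.ok = TRUE)
  key <- function(tp) features[features$timepoint == tp,
                               c("patient_id", "threshold_percent",
                                 "feature_name", "value")]
  out <- lapply(pairs, function(pr) {
    t_from <- as.integer(substr(pr, 1L, 1L))
    t_to <- as.integer(substr(pr, 2L, 2L))
    a <- key(t_from); b <- key(t_to)
    mrg <- merge(a, b, by = c("patient_id", "threshold_percent", "feature_name"),
                 suffixes = c("_from", "_to"))
    zero_den <- is.finite(mrg$value_from) & mrg$value_from == 0
    val <- suppressWarnings(pct_change(mrg$value_to, mrg$value_from))
    data.frame(
      patient_id = mrg$patient_id,
      threshold_percent = mrg$threshold_percent,
      feature_name = mrg$feature_name,
      pair = pr,
      value = val,
      flagged = zero_den | !is.finite(val),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  res[order(res$patient_id, res$pair, res$threshold_percent,
            match(res$feature_name, FEATURE_NAMES)), , drop = FALSE]
}
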