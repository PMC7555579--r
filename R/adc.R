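#' Compute the apparent diffusion coefficient map
#'
#' Voxelwise mono-exponential ADC from a two-b-value series:
#' \deqn{ADC = \ln(S_{low}/S_{high}) / (b_{high} - b_{low})}
#' reported in units of 1e-6 mm^2/s, the convention used for all feature
#' tables in this package. The low b-value (default 50 s/mm^2) is used as
#' acquired rather than idealised to b = 0, matching the
#' perfusion-suppressed two-point convention.
#'
#' Voxels where either signal is non-positive have no defined log-ratio and
#' are marked invalid; downstream histogram statistics exclude them.
#' Negative ADC values (noise pushing S_high above S_low) are retained by
#' default and their count is recorded in the result, since the handling in
#' vendor tools is not standardised; set `clip_negative = TRUE` to clamp
#' them to zero.
#'
#' @param series A [dwi_series] containing both b-values.
#' @param b_low,b_high The b-value pair in s/mm^2; `b_high > b_low`.
#' @param clip_negative Clamp negative ADC values to 0 (default `FALSE`).
#' @return An `adc_map`: list with `volume` (an [image_volume] of ADC in
#'   1e-6 mm^2/s, `NA` where invalid), `validity` (logical array), `b_pair`,
#'   and `n_negative` (count of negative ADC voxels before any clipping).
#' @export
compute_adc <- function(series, b_low = 50, b_high = 800,
                        clip_negative = FALSE) {
  stopifnot(inherits(series, "dwi_series"))
  if (b_high <= b_low)
    stop("`b_high` must be strictly greater than `b_low`")
  vlow <- get_bvolume(series, b_low)
  vhigh <- get_bvolume(series, b_high)
  s_low <- vlow$data
  s_high <- vhigh$data

  valid <- s_low > 0 & s_high > 0
  adc <- array(NA_real_, dim = dim(s_low))
  # log-ratio over the b-value gap, rescaled from mm^2/s to 1e-6 mm^2/s
  adc[valid] <- log(s_low[valid] / s_high[valid]) / (b_high - b_low) * 1e6
  n_negative <- sum(adc < 0, na.rm = TRUE)
  if (clip_negative) adc[valid & adc < 0] <- 0

  structure(
    list(volume = image_volume(adc, vlow$spacing, vlow$orientation),
         validity = valid,
         b_pair = c(b_low, b_high),
         n_negative = n_negative,
         clipped = clip_negative),
    class = "adc_map"
  )
}

#' @export
print.adc_map <- function(x, ...) {
  vals <- x$volume$data[x$validity]
  cat(sprintf(
    "<adc_map> b = (%g, %g) s/mm^2, %d/%d valid voxels, median %.1f x1e-6 mm^2/s, %d negative%s\n",
    x$b_pair[1L], x$b_pair[2L], sum(x$validity), length(x$validity),
    stats::median(vals), x$n_negative, if (x$clipped) " (clipped)" else ""))
  invisible(x)
}

#' Wrap a precomputed ADC volume as an adc_map
#'
#' For cohorts where a scanner-computed ADC map is available, it can be
#' ingested directly instead of being recomputed from the b-value pair.
#' Non-finite voxels are marked invalid.
#'
#' @param vol An [image_volume] with values in 1e-6 mm^2/s.
#' @param b_pair The b-value pair the map was derived from (metadata only).
#' @return An `adc_map`.
#' @export
as_adc_map <- function(vol, b_pair = c(50, 800)) {
  stopifnot(inherits(vol, "image_volume"))
  valid <- is.finite(vol$data)
  structure(
    list(volume = vol, validity = valid, b_pair = as.numeric(b_pair),
         n_negative = sum(vol$data < 0, na.rm = TRUE), clipped = FALSE),
    class = "adc_map"
  )
}
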