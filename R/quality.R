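#' Scan quality thresholds
#'
#' @param snr_db Minimum signal-to-noise ratio in dB (retina-band signal
#'   power over background power).
#' @param centration_um Maximum allowed offset of the foveal pit from the
#'   scan centre.
#' @param uniformity Maximum allowed left/right brightness ratio
#'   (always >= 1).
#' @return A named list of thresholds.
#' @export
quality_thresholds <- function(snr_db = 25, centration_um = 500,
                               uniformity = 1.3) {
  list(snr_db = snr_db, centration_um = centration_um,
       uniformity = uniformity)
}

#' Scan quality gate
#'
#' Operationalises the acquisition quality criteria: signal strength,
#' centration and brightness uniformity.  SNR is computed as
#' `10 log10(P_retina / P_background)` where `P` is mean squared
#' intensity over the detected retina band versus the rows outside it;
#' centration is the distance of the detected foveal pit column from the
#' image centre; uniformity is the ratio of mean retina-band intensity
#' between the brighter and darker lateral half.
#'
#' @param scan A [bscan].
#' @param thresholds See [quality_thresholds()].
#' @return A tibble of class `quality_report` with `snr_db`,
#'   `centration_offset_um`, `brightness_uniformity` and `passed`.
#' @export
quality_check <- function(scan, thresholds = quality_thresholds()) {
  stopifnot(inherits(scan, "bscan"))
  img <- scan$pixels
  band <- .retina_band(img)
  inside <- max(1, band[1]):min(nrow(img), band[2])
  # background from the vitreous above the retina: the rows below the
  # band carry the blurred tail of the bright outer-retina complex and
  # would inflate the noise-floor estimate
  outside <- seq_len(max(0, band[1] - 4L))
  p_sig <- mean(img[inside, ]^2)
  p_bg <- if (length(outside)) mean(img[outside, ]^2) else 0
  snr <- if (p_bg > 0) 10 * log10(p_sig / p_bg) else Inf

  pit_col <- detect_fovea_column(scan)
  centration <- abs(pit_col - (ncol(img) + 1) / 2) * scan$lateral_um_per_px

  half <- ncol(img) %/% 2
  left <- mean(img[inside, 1:half])
  right <- mean(img[inside, (ncol(img) - half + 1):ncol(img)])
  unif <- max(left, right) / max(min(left, right), .Machine$double.eps)

  passed <- (snr > thresholds$snr_db) &&
    (centration <= thresholds$centration_um) &&
    (unif <= thresholds$uniformity)
  out <- tibble(snr_db = snr, centration_offset_um = centration,
                brightness_uniformity = unif, passed = passed)
  class(out) <- c("quality_report", class(out))
  out
}

#' Locate the foveal pit column
#'
#' The inner retinal surface (first bright crossing per column) is
#' deepest at the pit; the estimate is the smoothed arg-max of that
#' surface, restricted to the central half of the scan.
#'
#' @param scan A [bscan].
#' @return Fractional column index of the pit.
#' @export
detect_fovea_column <- function(scan) {
  img <- scan$pixels
  H <- nrow(img); W <- ncol(img)
  band <- .retina_band(img)
  bg <- stats::median(img[seq_len(max(1, band[1] - 2)), ])
  thr <- bg + 0.5 * (stats::quantile(img, 0.95, names = FALSE) - bg)
  top <- apply(img >= thr, 2, function(col) {
    i <- which(col)
    if (length(i)) i[1] else NA_real_
  })
  top <- stats::runmed(ifelse(is.na(top), stats::median(top, na.rm = TRUE), top), 11)
  central <- seq(max(1, round(W * 0.25)), min(W, round(W * 0.75)))
  central[which.max(top[central])]
}
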