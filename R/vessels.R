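# retina band estimate shared by the quality gate and vessel detector:
# rows whose smoothed mean intensity rises a fraction above background
.retina_band <- function(img, frac = 0.25) {
  p <- rowMeans(img)
  p <- stats::runmed(p, 5)
  bg <- stats::median(c(head(p, 5), tail(p, 5)))
  thr <- bg + frac * (max(p) - bg)
  idx <- which(p > thr)
  if (length(idx) < 2) return(c(1L, nrow(img)))
  c(min(idx), max(idx))
}

#' Detect vessel-shadow columns
#'
#' Blood in inner-retinal vessels absorbs the beam and casts a dark
#' vertical shadow.  A column is flagged when its mean intensity over the
#' retina band drops more than `k` robust standard deviations below a
#' rolling median of column means; flagged runs are dilated by two
#' columns to catch the shadow penumbra.  The rule compares a column
#' only to its neighbourhood, so it is invariant to global gain.
#'
#' @param scan A [bscan].
#' @param window Rolling-median window in columns (odd).
#' @param k Robust-SD multiplier for the drop threshold.
#' @param min_drop Minimum fractional drop below the rolling median; a
#'   column must also be at least this much darker than its
#'   neighbourhood, which keeps smooth anatomical shading from being
#'   flagged on nearly noise-free scans.
#' @param fovea_exclude_um Half-width of the zone around the detected
#'   foveal centre that is never flagged: the fovea is avascular, and
#'   the walls of the pit darken the column mean in exactly the way a
#'   shadow does.
#' @param dilate Columns added on each side of a flagged run.
#' @return Sorted integer vector of flagged column indices (possibly
#'   empty).
#' @export
detect_vessel_shadows <- function(scan, window = 61, k = 2.5,
                                  min_drop = 0.08,
                                  fovea_exclude_um = 400, dilate = 2) {
  stopifnot(inherits(scan, "bscan"))
  img <- scan$pixels
  band <- .retina_band(img)
  cm <- colMeans(img[band[1]:band[2], , drop = FALSE])
  window <- min(window, 2 * (length(cm) %/% 2) - 1)
  if (is_odd(window) == FALSE) window <- window - 1
  roll <- stats::runmed(cm, window, endrule = "median")
  resid <- cm - roll
  rsd <- stats::mad(resid)
  if (rsd <= 0) rsd <- stats::sd(resid)
  if (!isTRUE(rsd > 0)) return(integer(0))
  flagged <- which(resid < -k * rsd & cm < (1 - min_drop) * roll)
  if (fovea_exclude_um > 0 && length(flagged)) {
    fc <- detect_fovea_column(scan)
    flagged <- flagged[abs(flagged - fc) * scan$lateral_um_per_px >
                         fovea_exclude_um]
  }
  if (length(flagged) == 0) return(integer(0))
  out <- sort(unique(unlist(lapply(flagged, function(j) {
    (j - dilate):(j + dilate)
  }))))
  out[out >= 1 & out <= length(cm)]
}

#' Interpolate out vessel-shadow columns
#'
#' Replaces every flagged column, row by row, with linear interpolation
#' between its nearest unflagged neighbours; unflagged columns are
#' returned bit-identical.  Runs touching the image edge are filled by
#' nearest-neighbour extension (with a message).
#'
#' @param scan A [bscan].
#' @param columns Integer column indices to replace (e.g. from
#'   [detect_vessel_shadows()]).
#' @return A [bscan] with the columns replaced.
#' @export
remove_vessels <- function(scan, columns) {
  stopifnot(inherits(scan, "bscan"))
  if (length(columns) == 0) return(scan)
  W <- ncol(scan$pixels)
  columns <- sort(unique(as.integer(columns)))
  stopifnot(all(columns >= 1), all(columns <= W))
  keep <- setdiff(1:W, columns)
  if (length(keep) < 2) abort("too few unflagged columns to interpolate")
  runs <- split(columns, cumsum(c(1, diff(columns) != 1)))
  if (any(vapply(runs, function(r) 1 %in% r || W %in% r, logical(1)))) {
    inform("vessel run touches the image edge; filled by nearest-neighbour extension")
  }
  img <- scan$pixels
  filled <- t(apply(img, 1, function(row) {
    row[columns] <- stats::approx(keep, row[keep], xout = columns,
                                  rule = 2)$y
    row
  }))
  scan$pixels <- filled
  scan$vessel_columns <- columns
  scan
}
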