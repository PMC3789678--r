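#' Microcyst detector parameters
#'
#' Thresholds that operationalise "well-circumscribed areas of
#' hyporeflectivity" confined to the INL band.
#'
#' @param c Relative hyporeflectivity threshold: a pixel is a candidate
#'   when it falls below `(1 - c)` times the local INL median.
#' @param roll_window Columns of the rolling window used for the local
#'   INL median (odd).
#' @param min_area_px2 Minimum connected-component area in pixels.
#' @param elong_ratio Minimum axial/lateral extent ratio; cysts are
#'   elongated perpendicular to the layers, but slightly round ones are
#'   admitted.
#' @param rim_contrast Minimum rim-to-interior mean intensity ratio
#'   ("well-circumscribed").
#' @param margin_px Rows of clearance to the INL boundaries a component
#'   must keep to count as fully inside the band.
#' @param prefilter_size 2-D median window applied before thresholding
#'   (small, to suppress isolated speckle minima).
#' @return A named list of class `cyst_params`.
#' @export
cyst_params <- function(c = 0.35, roll_window = 201, min_area_px2 = 6,
                        elong_ratio = 0.8, rim_contrast = 1.3,
                        margin_px = 1, prefilter_size = 3) {
  stopifnot(c > 0, c < 1, is_odd(roll_window), rim_contrast >= 1)
  structure(list(c = c, roll_window = roll_window,
                 min_area_px2 = min_area_px2, elong_ratio = elong_ratio,
                 rim_contrast = rim_contrast, margin_px = margin_px,
                 prefilter_size = prefilter_size),
            class = "cyst_params")
}

#' Detect hyporeflective INL microcysts on one B-scan
#'
#' Searches the INL band (between the traced GCL-IPL/INL and INL/OPL
#' boundaries) for well-circumscribed hyporeflective regions: pixels
#' darker than `(1 - c)` times a rolling local median of the INL are
#' grouped into connected components and kept if they are large enough,
#' lie fully inside the band, are at least `elong_ratio` times as tall
#' (axially) as wide, and show sufficient rim contrast.  Columns whose
#' INL boundaries failed are excluded from the search (with a message),
#' never searched with made-up boundaries.
#'
#' @param scan A [bscan].
#' @param boundaries The scan's traced `layer_boundaries`.
#' @param params A [cyst_params()].
#' @param eye `"OD"` or `"OS"` (for radial-line labelling).
#' @return A tibble of class `microcyst_set`, one row per cyst:
#'   `slice, line, centroid_col, centroid_row, eccentricity_um,
#'   area_px2, area_um2, axial_um, lateral_um, contrast`, with
#'   attributes `n_cysts`, `has_microcysts` and `columns_excluded`.
#' @export
detect_microcysts <- function(scan, boundaries, params = cyst_params(),
                              eye = "OD") {
  stopifnot(inherits(scan, "bscan"), inherits(boundaries, "layer_boundaries"))
  wide <- .boundaries_wide(boundaries)
  H <- nrow(scan$pixels); W <- ncol(scan$pixels)
  ax <- scan$axial_um_per_px
  lat <- scan$lateral_um_per_px
  fovea <- attr(boundaries, "fovea_column")
  empty <- tibble(slice = integer(0), line = integer(0),
                  centroid_col = numeric(0), centroid_row = numeric(0),
                  eccentricity_um = numeric(0), area_px2 = numeric(0),
                  area_um2 = numeric(0), axial_um = numeric(0),
                  lateral_um = numeric(0), contrast = numeric(0))

  top <- wide[, "GCLIPL_INL"]
  bot <- wide[, "INL_OPL"]
  bad_cols <- which(!is.finite(top) | !is.finite(bot))
  if (length(bad_cols) > 0) {
    inform(sprintf("%d columns excluded from microcyst search (failed INL boundaries)",
                   length(bad_cols)))
  }

  finish <- function(tab) {
    class(tab) <- c("microcyst_set", class(tab))
    attr(tab, "n_cysts") <- nrow(tab)
    attr(tab, "has_microcysts") <- nrow(tab) > 0
    attr(tab, "columns_excluded") <- bad_cols
    attr(tab, "slice_index") <- scan$slice_index
    attr(tab, "eye") <- eye
    tab
  }
  if (length(bad_cols) == W) return(finish(empty))

  img <- scan$pixels
  if (params$prefilter_size == 3) {
    img <- .median3x3(clamp01(img))
  } else if (params$prefilter_size > 3) {
    img <- as.matrix(EBImage::medianFilter(clamp01(img),
                                           (params$prefilter_size - 1) / 2))
  }

  rows <- matrix(1:H, H, W)
  band <- sweep(rows, 2, top, ">") & sweep(rows, 2, bot, "<")
  band[, bad_cols] <- FALSE
  if (!any(band)) return(finish(empty))

  # local INL median: per-column medians smoothed by a rolling median
  col_med <- rep(NA_real_, W)
  for (j in setdiff(1:W, bad_cols)) {
    r <- band[, j]
    if (any(r)) col_med[j] <- stats::median(img[r, j])
  }
  filled <- col_med
  if (anyNA(filled)) {
    ok <- which(!is.na(filled))
    if (length(ok) < 2) return(finish(empty))
    filled <- stats::approx(ok, filled[ok], xout = 1:W, rule = 2)$y
  }
  win <- min(params$roll_window, 2 * (W %/% 2) - 1)
  local_med <- stats::runmed(filled, win, endrule = "median")

  thr <- (1 - params$c) * local_med
  candidates <- band & sweep(img, 2, thr, "<")
  if (!any(candidates)) return(finish(empty))

  lab <- EBImage::bwlabel(candidates)
  n_lab <- max(lab)
  keep <- list()
  brush <- EBImage::makeBrush(3, "box")
  for (k in seq_len(n_lab)) {
    px <- which(lab == k)
    if (length(px) < params$min_area_px2) next
    rr <- ((px - 1) %% H) + 1
    cc <- ((px - 1) %/% H) + 1
    ax_ext <- (max(rr) - min(rr) + 1) * ax
    lat_ext <- (max(cc) - min(cc) + 1) * lat
    if (ax_ext < params$elong_ratio * lat_ext) next
    # fully inside the band, with margin
    inside <- all(rr > top[cc] + params$margin_px) &&
      all(rr < bot[cc] - params$margin_px)
    if (!inside) next
    comp <- lab == k
    rim <- EBImage::dilate(comp, brush) & !comp & band
    if (!any(rim)) next
    contrast <- mean(img[rim]) / max(mean(img[comp]), .Machine$double.eps)
    if (contrast < params$rim_contrast) next
    c0 <- mean(cc)
    x_um <- (c0 - fovea) * lat
    side <- if (x_um >= 0) 1 else -1
    keep[[length(keep) + 1]] <- tibble(
      slice = scan$slice_index,
      line = .slice_to_line(scan$slice_index, side, eye),
      centroid_col = c0,
      centroid_row = mean(rr),
      eccentricity_um = abs(x_um) * side,
      area_px2 = length(px),
      area_um2 = length(px) * ax * lat,
      axial_um = ax_ext,
      lateral_um = lat_ext,
      contrast = contrast)
  }
  finish(if (length(keep)) dplyr::bind_rows(keep) else empty)
}

#' Cohort-level microcyst summary
#'
#' Prevalence (percent of analysed eyes with at least one cyst, rounded
#' to the nearest integer percent), per-quadrant cyst counts and mean
#' cyst extents.
#'
#' Quadrants are derived from the radial-line template (line `l` points
#' along `(l - 1) * 30` degrees from the temporal horizontal): lines
#' 1-3 supero-temporal, 4-6 supero-nasal, 7-9 infero-nasal, 10-12
#' infero-temporal.
#'
#' @param cysts A tibble of detected cysts across eyes, with `subject`,
#'   `eye` and `line` columns (rows from [detect_microcysts()] results
#'   bound together; may have zero rows).
#' @param eyes A tibble of all analysed eyes: columns `subject`, `eye`
#'   (one row per analysed eye, whether or not it has cysts).
#' @return A list of class `cyst_summary`: `n_eyes`, `n_affected`,
#'   `prevalence_pct` (integer), `quadrant_counts` (tibble),
#'   `mean_axial_um`, `mean_lateral_um`, `mean_area_um2`.
#' @export
cohort_cyst_summary <- function(cysts, eyes) {
  eyes <- dplyr::distinct(as_tibble(eyes), .data$subject, .data$eye)
  if (nrow(eyes) == 0) abort("no analysed eyes: prevalence undefined")
  cysts <- as_tibble(cysts)
  if (nrow(cysts) > 0) {
    stopifnot(all(c("subject", "eye", "line") %in% names(cysts)))
    affected <- dplyr::distinct(cysts, .data$subject, .data$eye)
    affected <- dplyr::semi_join(affected, eyes, by = c("subject", "eye"))
  } else {
    affected <- eyes[0, ]
  }
  quad_of <- function(line) {
    c("supero-temporal", "supero-nasal",
      "infero-nasal", "infero-temporal")[(line - 1) %/% 3 + 1]
  }
  quads <- tibble(quadrant = c("supero-temporal", "supero-nasal",
                               "infero-nasal", "infero-temporal"))
  counts <- if (nrow(cysts) > 0) {
    dplyr::count(dplyr::mutate(cysts, quadrant = quad_of(.data$line)),
                 .data$quadrant, name = "n_cysts")
  } else {
    tibble(quadrant = character(0), n_cysts = integer(0))
  }
  counts <- dplyr::left_join(quads, counts, by = "quadrant")
  counts$n_cysts[is.na(counts$n_cysts)] <- 0L

  structure(list(
    n_eyes = nrow(eyes),
    n_affected = nrow(affected),
    prevalence_pct = as.integer(round(100 * nrow(affected) / nrow(eyes))),
    quadrant_counts = counts,
    mean_axial_um = if (nrow(cysts)) mean(cysts$axial_um) else NA_real_,
    mean_lateral_um = if (nrow(cysts)) mean(cysts$lateral_um) else NA_real_,
    mean_area_um2 = if (nrow(cysts)) mean(cysts$area_um2) else NA_real_
  ), class = "cyst_summary")
}

#' @export
print.cyst_summary <- function(x, ...) {
  cat(sprintf("<cyst_summary> %d/%d eyes affected (%d%%)\n",
              x$n_affected, x$n_eyes, x$prevalence_pct))
  print(x$quadrant_counts)
  invisible(x)
}
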