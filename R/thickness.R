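#' Radial sampling protocol
#'
#' The macular star protocol: 6 slices through the fovea at 30-degree
#' steps give 12 radial half-lines; layer thickness is sampled at 3
#' eccentricities per half-line, 36 points in all.  Points closer to the
#' fovea than the first eccentricity are excluded (layer boundaries are
#' indistinct inside the pit).
#'
#' Line numbering: line `l` points along `(l - 1) * 30` degrees,
#' counterclockwise from the temporal horizontal of a right eye; left
#' eyes are mirrored onto this template, so lines 5-6 and 8-9 are always
#' the supero- and infero-nasal obliques.
#'
#' @param n_slices Number of acquired slices.
#' @param angular_step_deg Angle between consecutive slices.
#' @param slice_length_um Slice length.
#' @param eccentricities_um Sample eccentricities per half-line,
#'   strictly increasing, all positive.  The default spans 750-2150 um:
#'   the inner limit enforces the central exclusion zone (boundaries are
#'   unreliable inside the pit), while the outer limit leaves room for
#'   the 5-column averaging window inside the scanned half-line (a
#'   sample at exactly half the slice length would sit on the outermost
#'   A-scan and could not be averaged).
#' @return A list of class `radial_protocol`.
#' @export
radial_protocol <- function(n_slices = 6L, angular_step_deg = 30,
                            slice_length_um = 4500,
                            eccentricities_um = c(750, 1450, 2150)) {
  stopifnot(n_slices * angular_step_deg == 180,
            all(diff(eccentricities_um) > 0),
            all(eccentricities_um > 0),
            max(eccentricities_um) <= slice_length_um / 2)
  structure(list(
    n_slices = as.integer(n_slices),
    angular_step_deg = angular_step_deg,
    slice_length_um = slice_length_um,
    points_per_halfline = length(eccentricities_um),
    eccentricities_um = eccentricities_um,
    n_lines = as.integer(2 * n_slices),
    n_points = as.integer(2 * n_slices * length(eccentricities_um))
  ), class = "radial_protocol")
}

#' Sample the 36-point paramacular thickness grid
#'
#' Converts the traced boundaries of a full radial scan set into the
#' per-eye thickness grid: for each of the 12 half-lines and each
#' protocol eccentricity, thickness is `(lower - upper boundary row) *
#' axial um/px`, averaged over a 5-column window centred on the column
#' at `fovea +/- eccentricity`.  Entries over failed boundary columns,
#' or beyond the scan edge, are marked invalid, never extrapolated.
#'
#' @param boundary_sets List of `layer_boundaries` (one per slice, any
#'   order; slice index and calibration are read from their attributes).
#' @param protocol A [radial_protocol()].
#' @param eye `"OD"` or `"OS"`.
#' @param subject Subject identifier carried into the output.
#' @param window Columns averaged per sample point (odd).
#' @return A tibble of class `thickness_grid`:
#'   `(line, eccentricity_um, layer, thickness_um, valid)` with
#'   `subject` and `eye` attributes; exactly
#'   `12 * length(eccentricities) * 3` rows.
#' @export
sample_grid <- function(boundary_sets, protocol = radial_protocol(),
                        eye = "OD", subject = NA_character_, window = 5L) {
  stopifnot(length(boundary_sets) >= protocol$n_slices)
  by_slice <- list()
  for (bd in boundary_sets) {
    s <- attr(bd, "slice_index")
    by_slice[[as.character(s)]] <- list(
      wide = .boundaries_wide(bd),
      fovea = attr(bd, "fovea_column"),
      ax = attr(bd, "axial_um_per_px"),
      lat = attr(bd, "lateral_um_per_px"))
  }
  half <- (window - 1L) %/% 2L
  pairs <- list(RNFL = c("ILM", "RNFL_GCLIPL"),
                GCLIPL = c("RNFL_GCLIPL", "GCLIPL_INL"),
                INL = c("GCLIPL_INL", "INL_OPL"))

  grid <- tidyr::expand_grid(line = seq_len(protocol$n_lines),
                             eccentricity_um = protocol$eccentricities_um,
                             layer = .layer_names)
  res <- purrr::pmap(grid, function(line, eccentricity_um, layer) {
    ls <- .line_to_slice(line, eye)
    sl <- by_slice[[as.character(ls$slice)]]
    if (is.null(sl)) return(list(th = NA_real_, valid = FALSE))
    W <- nrow(sl$wide)
    c0 <- round(sl$fovea + ls$side * eccentricity_um / sl$lat)
    cols <- (c0 - half):(c0 + half)
    # a sample point at the scan edge keeps its in-range window columns
    # (>= 3 of them); a point truly beyond the edge is invalid, never
    # extrapolated
    cols <- cols[cols >= 1 & cols <= W]
    if (length(cols) < max(3L, half + 1L)) {
      return(list(th = NA_real_, valid = FALSE))
    }
    up <- sl$wide[cols, pairs[[layer]][1]]
    lo <- sl$wide[cols, pairs[[layer]][2]]
    if (any(!is.finite(up)) || any(!is.finite(lo))) {
      return(list(th = NA_real_, valid = FALSE))
    }
    list(th = mean(lo - up) * sl$ax, valid = TRUE)
  })
  out <- dplyr::mutate(grid,
                       thickness_um = purrr::map_dbl(res, "th"),
                       valid = purrr::map_lgl(res, "valid"),
                       subject = subject, eye = eye)
  class(out) <- c("thickness_grid", class(out))
  attr(out, "subject") <- subject
  attr(out, "eye") <- eye
  attr(out, "protocol") <- protocol
  out
}

#' Per-eye layer thickness summary
#'
#' Arithmetic mean thickness per layer over valid grid entries.  An eye
#' with fewer than `min_valid` valid grid points (of 36) is flagged
#' unanalyzable, mirroring the quality exclusion of the measurement
#' protocol.
#'
#' @param grid A [sample_grid()] result.
#' @param min_valid Minimum valid points per layer for the eye to count.
#' @return A tibble `(layer, mean_um, n_valid, n_invalid, analyzable)`
#'   with the grid's subject/eye attributes carried over as columns.
#' @export
eye_summary <- function(grid, min_valid = 30L) {
  stopifnot(inherits(grid, "thickness_grid"))
  out <- grid |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(
      mean_um = mean(.data$thickness_um[.data$valid]),
      n_valid = sum(.data$valid),
      n_invalid = sum(!.data$valid),
      .groups = "drop") |>
    dplyr::mutate(analyzable = .data$n_valid >= min_valid,
                  subject = attr(grid, "subject"),
                  eye = attr(grid, "eye"))
  if (any(!out$analyzable)) {
    inform(sprintf("eye %s/%s flagged unanalyzable (%d valid points)",
                   attr(grid, "subject"), attr(grid, "eye"),
                   min(out$n_valid)))
  }
  out
}
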