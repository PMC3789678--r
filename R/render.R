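#' Render one radial B-scan from a phantom
#'
#' Rasterises the phantom geometry into a depth-by-lateral intensity
#' image: each band is filled with its reflectivity (with partial-volume
#' weighting at boundaries), blurred axially by a Gaussian PSF,
#' multiplied by gamma speckle, attenuated inside vessel-shadow columns,
#' and, if the phantom carries microcysts on this slice, darkened inside
#' each cyst ellipse.  Ground-truth boundary rows (fractional pixels, row
#' centre convention, row 1 at the vitreous top), the cyst mask and the
#' shadowed column indices are attached to the result.
#'
#' Rendering is pure: the same (phantom, slice, acquisition, seed)
#' produces a bit-identical image.
#'
#' @param phantom A [make_layer_geometry()] phantom, optionally with
#'   microcysts added by [inject_microcysts()].
#' @param slice_index Slice number 0-5.
#' @param acq An [acquisition_model()].
#' @param seed Integer seed for the speckle draw.
#' @return An object of class `bscan`: a list with `pixels` (matrix,
#'   depth x lateral, intensities in `[0,1]`), calibration fields,
#'   `fovea_column`, `slice_index`, `truth` (tibble of ground-truth
#'   boundary rows per column), `cyst_mask`, `cyst_truth` and
#'   `shadow_columns`.
#' @export
render_bscan <- function(phantom, slice_index, acq = acquisition_model(),
                         seed = 1L) {
  stopifnot(inherits(phantom, "retina_phantom"), slice_index %in% 0:5)
  H <- acq$depth_px
  W <- acq$ascan_count
  ax <- acq$axial_um_per_px
  lat <- acq$lateral_um_per_px

  centre_col <- (W + 1) / 2
  fovea_col <- centre_col + phantom$fovea_center_um / lat
  x_um <- ((1:W) - fovea_col) * lat   # lateral position relative to fovea

  d <- layer_depths(phantom, slice_index, x_um)   # um, W x 7
  if (any(d[, "RPE_BASE"] / ax >= H) || any(d[, "ILM"] <= 0)) {
    abort("phantom does not fit inside the image depth range")
  }

  refl <- phantom$reflectivity
  band_refl <- c(refl$vitreous, refl$rnfl, refl$gclipl, refl$inl,
                 refl$opl, refl$onl, refl$pr_rpe, refl$below)
  # band edges in row-edge units (0 = top edge of row 1)
  edges <- cbind(0, d / ax, H)   # W x 9

  img <- matrix(0, H, W)
  rtop <- matrix(0:(H - 1), H, W)   # upper edge of each pixel
  for (b in seq_along(band_refl)) {
    top <- matrix(edges[, b], H, W, byrow = TRUE)
    bot <- matrix(edges[, b + 1], H, W, byrow = TRUE)
    ov <- pmin(bot, rtop + 1) - pmax(top, rtop)
    ov[ov < 0] <- 0
    img <- img + band_refl[b] * ov
  }

  # axial PSF: 1-D Gaussian convolution along depth
  sig_px <- acq$psf_axial_sigma_um / ax
  if (sig_px > 1e-3) {
    half <- max(1L, ceiling(3 * sig_px))
    k <- stats::dnorm(-half:half, sd = sig_px)
    k <- matrix(k / sum(k), ncol = 1)
    img <- EBImage::filter2(img, k, boundary = "replicate")
  }

  if (is.finite(acq$speckle_shape)) {
    noise <- withr::with_seed(child_seed(seed, "speckle", slice_index), {
      matrix(rgamma(H * W, shape = acq$speckle_shape,
                    rate = acq$speckle_shape), H, W)
    })
    img <- img * noise
  }

  shadow_cols <- integer(0)
  if (!is.null(acq$shadow_columns) && nrow(acq$shadow_columns) > 0) {
    for (i in seq_len(nrow(acq$shadow_columns))) {
      s <- acq$shadow_columns[i, ]
      cols <- which(abs(((1:W) - centre_col) * lat - s$pos_um) <= s$width_um / 2)
      if (length(cols)) {
        img[, cols] <- img[, cols] * s$atten
        shadow_cols <- union(shadow_cols, cols)
      }
    }
  }

  # carve microcysts for this slice into the pixels; record the mask
  mask <- NULL
  cy_truth <- NULL
  cysts <- phantom$cysts
  if (!is.null(cysts)) cysts <- cysts[cysts$slice == slice_index, , drop = FALSE]
  if (!is.null(cysts) && nrow(cysts) > 0) {
    mask <- matrix(FALSE, H, W)
    rows <- matrix(1:H, H, W)
    cols <- matrix(1:W, H, W, byrow = TRUE)
    keep <- logical(nrow(cysts))
    for (i in seq_len(nrow(cysts))) {
      cy <- cysts[i, ]
      xr <- cy$x_um
      dloc <- layer_depths(phantom, slice_index, xr)
      band_th <- dloc[, "INL_OPL"] - dloc[, "GCLIPL_INL"]
      if (band_th <= cy$axial_um + 2) {
        inform(sprintf(
          "microcyst %d on slice %d skipped: INL band (%.1f um) too thin for %.1f um cyst",
          i, slice_index, band_th, cy$axial_um))
        next
      }
      keep[i] <- TRUE
      r0 <- (dloc[, "GCLIPL_INL"] + dloc[, "INL_OPL"]) / 2 / ax + 0.5
      c0 <- fovea_col + xr / lat
      a <- cy$axial_um / 2 / ax
      bpx <- max(cy$lateral_um / 2 / lat, 0.71)  # never thinner than a pixel
      el <- ((rows - r0) / a)^2 + ((cols - c0) / bpx)^2 <= 1
      mask <- mask | el
    }
    cy_truth <- cysts[keep, c("slice", "line", "eccentricity_um", "x_um",
                              "axial_um", "lateral_um"), drop = FALSE]
    if (any(mask)) img[mask] <- img[mask] * (1 - phantom$cyst_intensity_drop)
    if (nrow(cy_truth) == 0) { mask <- NULL; cy_truth <- NULL }
  }

  img <- clamp01(img)

  truth <- tibble(
    column = rep(1:W, times = length(.measured_boundaries)),
    boundary = rep(.measured_boundaries, each = W),
    row_px = as.vector(d[, .measured_boundaries] / ax + 0.5)
  )

  structure(list(
    pixels = img,
    axial_um_per_px = ax,
    lateral_um_per_px = lat,
    fovea_column = fovea_col,
    slice_index = slice_index,
    truth = truth,
    cyst_mask = mask,
    cyst_truth = cy_truth,
    shadow_columns = shadow_cols
  ), class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan> slice %d: %d x %d px, %.2f x %.2f um/px, fovea col %.1f\n",
              x$slice_index, nrow(x$pixels), ncol(x$pixels),
              x$axial_um_per_px, x$lateral_um_per_px, x$fovea_column))
  invisible(x)
}

#' Construct a B-scan object from an existing image
#'
#' Wraps a plain intensity matrix (for example read from TIFF/PNG) with
#' the calibration metadata the segmentation functions need.
#'
#' @param pixels Depth-by-lateral matrix with finite intensities in
#'   `[0,1]`; row 1 is the vitreous side.
#' @param axial_um_per_px,lateral_um_per_px Calibration in um/pixel.
#' @param slice_index Slice number 0-5.
#' @param fovea_column Lateral pixel index of the foveal centre, or `NA`
#'   if it must be detected.
#' @return A `bscan` object.
#' @export
bscan <- function(pixels, axial_um_per_px = 3.9,
                  lateral_um_per_px = 4500 / ncol(pixels),
                  slice_index = 0L, fovea_column = NA_real_) {
  pixels <- as.matrix(pixels)
  if (length(pixels) == 0) abort("empty image")
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 1)) {
    abort("intensities must be finite and within [0, 1]")
  }
  stopifnot(axial_um_per_px > 0, lateral_um_per_px > 0)
  structure(list(
    pixels = pixels,
    axial_um_per_px = axial_um_per_px,
    lateral_um_per_px = lateral_um_per_px,
    fovea_column = fovea_column,
    slice_index = as.integer(slice_index),
    truth = NULL, cyst_mask = NULL, cyst_truth = NULL,
    shadow_columns = integer(0)
  ), class = "bscan")
}

#' Add INL microcysts to a phantom
#'
#' Draws a cyst population from a [cyst_spec()] and attaches it to the
#' phantom.  Each cyst is an ellipse with its major axis perpendicular to
#' the layers, placed on an allowed radial line within the eccentricity
#' range.  The INL is locally thickened (a smooth Gaussian bump of the
#' GCL-IPL/INL boundary) wherever needed so that every cyst fits strictly
#' inside the band -- microcystic change physically expands the INL, so
#' injected eyes also measure thicker.  Cysts become visible (darkened
#' pixels plus a ground-truth mask) when the phantom is rendered with
#' [render_bscan()]; a cyst that still cannot fit at render time is
#' skipped with a message, never mis-placed.
#'
#' @param phantom A [make_layer_geometry()] phantom.
#' @param spec A [cyst_spec()].
#' @param seed Integer seed for the placement draws.
#' @param n Optional explicit cyst count (otherwise drawn uniformly from
#'   `spec$count_range`).
#' @param eye `"OD"` or `"OS"`: the allowed radial lines are defined on
#'   the right-eye template, so left eyes are mirrored when mapping a
#'   line to a slice and side.
#' @return The phantom with a `cysts` table attached.
#' @export
inject_microcysts <- function(phantom, spec = cyst_spec(), seed = 1L,
                              n = NULL, eye = "OD") {
  stopifnot(inherits(phantom, "retina_phantom"), inherits(spec, "cyst_spec"))
  if (max(spec$eccentricity_range_um) > phantom$half_len_um) {
    abort("cyst eccentricity range extends beyond the scanned half-line")
  }
  placed <- withr::with_seed(child_seed(seed, "cysts"), {
    nn <- n %||% sample(spec$count_range[1]:spec$count_range[2], 1)
    if (nn == 0) NULL else tibble(
      line = sample(spec$allowed_radial_lines, nn, replace = TRUE),
      eccentricity_um = runif(nn, spec$eccentricity_range_um[1],
                              spec$eccentricity_range_um[2]),
      axial_um = runif(nn, spec$axial_extent_um[1], spec$axial_extent_um[2]),
      lateral_um = runif(nn, spec$lateral_extent_um[1],
                         spec$lateral_extent_um[2])
    )
  })
  if (is.null(placed)) {
    phantom$cysts <- NULL
    phantom$cyst_intensity_drop <- spec$intensity_drop
    return(phantom)
  }
  geom <- purrr::map(placed$line, .line_to_slice, eye = eye)
  placed$slice <- purrr::map_int(geom, ~ as.integer(.x$slice))
  placed$x_um <- purrr::map_dbl(geom, "side") * placed$eccentricity_um

  # local INL thickening so the cyst fits with a 6 um margin
  placed$bump_um <- 0
  placed$bump_sigma_um <- pmax(placed$lateral_um * 1.2, 30)
  for (i in seq_len(nrow(placed))) {
    base_th <- .layer_thickness_um(phantom, "INL", placed$slice[i],
                                   placed$x_um[i])
    placed$bump_um[i] <- max(6, placed$axial_um[i] + 12 - base_th)
  }
  phantom$cysts <- placed
  phantom$cyst_intensity_drop <- spec$intensity_drop
  phantom
}
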