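#' Build a layered retina phantom with a foveal pit
#'
#' Constructs the ground-truth geometry used by the synthetic B-scan
#' renderer: seven boundary surfaces (ILM, RNFL/GCL-IPL, GCL-IPL/INL,
#' INL/OPL, plus three outer-retina surfaces) over lateral position, for
#' each of the six radial slices of the macular star protocol.  The three
#' inner layers (RNFL, combined GCL/IPL, INL) thin smoothly to zero inside
#' the foveal pit; their base thicknesses are scaled so that the mean
#' thickness sampled at the 36 paramacular grid points of `protocol`
#' equals the requested target.
#'
#' Geometry is analytic: boundary depths are evaluated exactly at any
#' lateral position, so ground truth is available in fractional pixels at
#' whatever sampling the acquisition model uses.
#'
#' @param rnfl_um,gclipl_um,inl_um Target mean layer thickness over the
#'   36-point grid, in micrometres.
#' @param pit_radius_um Foveal pit radius; the pit is a Gaussian thinning
#'   profile with standard deviation `pit_radius_um / 2`.
#' @param fovea_center_um Lateral position of the foveal centre relative
#'   to the scan centre (0 = perfectly centred acquisition).
#' @param line_gain Optional per-radial-line thickness multipliers: a list
#'   with elements `rnfl`, `gclipl`, `inl`, each a numeric vector of
#'   length 12 (default all 1).  Used to impose azimuthal (for example
#'   nasal/temporal) thickness topography.
#' @param outer_um Named vector of fixed outer-retina thicknesses in
#'   micrometres (`opl`, `onl`, `pr`); these are not measured, they only
#'   give the renderer a realistic outer retina.
#' @param rpe_base_um Depth of the RPE base below the image top.
#' @param bow_um Amplitude of the parabolic bowing of the whole retina.
#' @param undulation_um Standard-deviation scale of the smooth per-slice
#'   depth undulation (cosine harmonics); affects absolute depths only,
#'   never thicknesses.
#' @param reflectivity Named list of band reflectivities in `[0,1]`.
#' @param protocol Radial sampling protocol, see [radial_protocol()].
#' @param seed Integer seed for the undulation harmonics.
#'
#' @return An object of class `retina_phantom`.
#' @seealso [render_bscan()], [inject_microcysts()], [layer_depths()]
#' @export
#' @examples
#' ph <- make_layer_geometry(32.2, 98.1, 39.6, seed = 1)
#' d <- layer_depths(ph, slice_index = 0, x_um = c(-1500, 0, 1500))
#' d[, "GCLIPL_INL"] - d[, "RNFL_GCLIPL"]  # GCL/IPL thickness, um
make_layer_geometry <- function(rnfl_um = 32.2, gclipl_um = 98.1,
                                inl_um = 39.6,
                                pit_radius_um = 350,
                                fovea_center_um = 0,
                                line_gain = NULL,
                                outer_um = c(opl = 25, onl = 70, pr = 70),
                                rpe_base_um = 480,
                                bow_um = 15,
                                undulation_um = 3,
                                reflectivity = default_reflectivity(),
                                protocol = radial_protocol(),
                                seed = 1L) {
  targets <- c(RNFL = rnfl_um, GCLIPL = gclipl_um, INL = inl_um)
  if (any(targets < 0)) abort("target layer thicknesses must be >= 0")
  if (is.null(line_gain)) {
    line_gain <- list(rnfl = rep(1, 12), gclipl = rep(1, 12), inl = rep(1, 12))
  }
  stopifnot(all(lengths(line_gain) == 12))

  sigma <- pit_radius_um / 2
  pit_factor <- function(x) 1 - exp(-x^2 / (2 * sigma^2))

  # scale base thickness so that the mean over the 36 grid points hits the
  # target exactly (pit factor and line gains both enter the grid mean)
  ecc <- protocol$eccentricities_um
  base <- vapply(seq_along(.layer_names), function(i) {
    gains <- line_gain[[c("rnfl", "gclipl", "inl")[i]]]
    w <- mean(outer(pit_factor(ecc), gains))  # 3 ecc x 12 lines
    if (targets[i] == 0) return(0)
    if (w <= 0) abort("pit profile removes the whole grid; infeasible geometry")
    targets[i] / w
  }, numeric(1))
  names(base) <- .layer_names

  # feasibility: accumulate upward from the RPE base and keep a margin of
  # vitreous above the ILM at the thickest admissible column
  margin_top <- 30
  used <- sum(outer_um)
  for (i in rev(seq_along(.layer_names))) {
    gmax <- max(line_gain[[c("rnfl", "gclipl", "inl")[i]]])
    used <- used + base[i] * gmax
    if (rpe_base_um - used < margin_top) {
      abort(sprintf(
        "infeasible geometry: adding layer %s exceeds the available depth",
        .layer_names[i]))
    }
  }

  # smooth per-slice depth undulation: 3 cosine harmonics, zero mean
  und <- withr::with_seed(child_seed(seed, "undulation"), {
    lapply(1:6, function(s) {
      list(amp = rnorm(3, 0, undulation_um / (1:3)),
           phase = runif(3, 0, 2 * pi))
    })
  })

  structure(list(
    base_um = base,
    targets_um = targets,
    pit_radius_um = pit_radius_um,
    pit_sigma_um = sigma,
    fovea_center_um = fovea_center_um,
    line_gain = line_gain,
    outer_um = outer_um,
    rpe_base_um = rpe_base_um,
    bow_um = bow_um,
    half_len_um = protocol$slice_length_um / 2,
    undulation = und,
    reflectivity = reflectivity,
    cysts = NULL,
    seed = seed
  ), class = "retina_phantom")
}

#' Default band reflectivities for the renderer
#'
#' Approximate relative backscatter of each band on spectral-domain OCT:
#' bright RNFL and photoreceptor/RPE complex, moderate plexiform layers,
#' dark nuclear layers, near-black vitreous.
#' @return Named list of intensities in `[0,1]`.
#' @export
default_reflectivity <- function() {
  list(vitreous = 0.015, rnfl = 0.85, gclipl = 0.45, inl = 0.20,
       opl = 0.55, onl = 0.32, pr_rpe = 0.82, below = 0.015)
}

#' @export
print.retina_phantom <- function(x, ...) {
  cat("<retina_phantom>\n")
  cat("  base thickness (um):",
      paste(sprintf("%s=%.1f", names(x$base_um), x$base_um), collapse = ", "), "\n")
  cat("  pit radius:", x$pit_radius_um, "um; fovea offset:",
      x$fovea_center_um, "um\n")
  if (!is.null(x$cysts)) cat("  microcysts:", nrow(x$cysts), "\n")
  invisible(x)
}

# per-line gain blended smoothly across the fovea: x > 0 is the line for
# this slice's positive half (line s+1), x < 0 the opposite half (s+7)
.slice_gain <- function(phantom, layer_key, slice_index, x_um) {
  g <- phantom$line_gain[[layer_key]]
  gp <- g[slice_index + 1]
  gn <- g[slice_index + 7]
  gn + (gp - gn) * stats::plogis(x_um / 150)
}

# inner-layer thickness profile in um at lateral position x (relative to
# the fovea) on one slice
.layer_thickness_um <- function(phantom, layer, slice_index, x_um) {
  key <- c(RNFL = "rnfl", GCLIPL = "gclipl", INL = "inl")[[layer]]
  f <- 1 - exp(-x_um^2 / (2 * phantom$pit_sigma_um^2))
  th <- phantom$base_um[[layer]] * f *
    .slice_gain(phantom, key, slice_index, x_um)
  if (layer == "INL" && !is.null(phantom$cysts)) {
    cy <- phantom$cysts[phantom$cysts$slice == slice_index, , drop = FALSE]
    if (nrow(cy) > 0) {
      for (i in seq_len(nrow(cy))) {
        th <- th + cy$bump_um[i] *
          exp(-(x_um - cy$x_um[i])^2 / (2 * cy$bump_sigma_um[i]^2))
      }
    }
  }
  th
}

.slice_undulation <- function(phantom, slice_index, x_um) {
  u <- phantom$undulation[[slice_index + 1]]
  L <- 2 * phantom$half_len_um
  out <- 0
  for (m in 1:3) {
    out <- out + u$amp[m] * cos(2 * pi * m * x_um / L + u$phase[m])
  }
  out
}

#' Evaluate ground-truth boundary depths
#'
#' Returns the depth (micrometres below the image top) of every boundary
#' surface of a phantom at the requested lateral positions on one slice.
#'
#' @param phantom A [make_layer_geometry()] phantom.
#' @param slice_index Slice number, 0 to 5 (slice k runs at k*30 degrees).
#' @param x_um Lateral positions in micrometres relative to the foveal
#'   centre (positive = the slice's positive half-line).
#' @return Numeric matrix, one row per position, columns named by boundary.
#' @export
layer_depths <- function(phantom, slice_index, x_um) {
  stopifnot(slice_index %in% 0:5)
  bow <- phantom$bow_um * (x_um / phantom$half_len_um)^2 +
    .slice_undulation(phantom, slice_index, x_um)
  rpe <- phantom$rpe_base_um + bow
  onl_pr <- rpe - phantom$outer_um[["pr"]]
  opl_onl <- onl_pr - phantom$outer_um[["onl"]]
  inl_opl <- opl_onl - phantom$outer_um[["opl"]]
  gclipl_inl <- inl_opl - .layer_thickness_um(phantom, "INL", slice_index, x_um)
  rnfl_gclipl <- gclipl_inl -
    .layer_thickness_um(phantom, "GCLIPL", slice_index, x_um)
  ilm <- rnfl_gclipl - .layer_thickness_um(phantom, "RNFL", slice_index, x_um)
  out <- cbind(ILM = ilm, RNFL_GCLIPL = rnfl_gclipl, GCLIPL_INL = gclipl_inl,
               INL_OPL = inl_opl, OPL_ONL = opl_onl, ONL_PR = onl_pr,
               RPE_BASE = rpe)
  out
}

#' Ground-truth thickness grid of a phantom
#'
#' Samples the analytic layer thicknesses of a phantom at the 36 grid
#' points of the radial protocol, i.e. the values a perfect segmentation
#' and sampler would report.
#'
#' @inheritParams layer_depths
#' @param protocol A [radial_protocol()].
#' @param eye `"OD"` or `"OS"`; left eyes are mirrored onto the right-eye
#'   line-numbering template.
#' @return A tibble `(line, eccentricity_um, layer, thickness_um)`.
#' @export
phantom_truth_grid <- function(phantom, protocol = radial_protocol(),
                               eye = "OD") {
  grid <- tidyr::expand_grid(line = 1:12,
                             eccentricity_um = protocol$eccentricities_um,
                             layer = .layer_names)
  th <- purrr::pmap_dbl(grid, function(line, eccentricity_um, layer) {
    ls <- .line_to_slice(line, eye)
    .layer_thickness_um(phantom, layer, ls$slice, ls$side * eccentricity_um)
  })
  dplyr::mutate(grid, thickness_um = th)
}

# line (1..12 on the right-eye template) -> (slice 0..5, lateral sign).
# Line l points along (l - 1) * 30 degrees, counterclockwise from the
# temporal horizontal of a right eye; slice k is acquired along k * 30
# degrees, its positive lateral half being the k * 30 direction.  Left
# eyes are mirrored about the vertical axis (theta -> 180 - theta) so
# nasal/temporal semantics are preserved.
.line_to_slice <- function(line, eye = "OD") {
  stopifnot(line %in% 1:12)
  theta <- (line - 1) * 30
  if (identical(eye, "OS")) theta <- (180 - theta) %% 360
  list(slice = (theta %% 180) %/% 30, side = if (theta < 180) 1 else -1)
}

# inverse map: (slice, side, eye) -> template line number
.slice_to_line <- function(slice, side, eye = "OD") {
  theta <- slice * 30 + if (side > 0) 0 else 180
  if (identical(eye, "OS")) theta <- (180 - theta) %% 360
  as.integer(theta / 30) + 1L
}
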