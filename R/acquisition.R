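#' Acquisition model for synthetic B-scans
#'
#' Describes how a phantom is turned into pixels: calibration, image
#' size, axial point-spread blur, multiplicative speckle, and vessel
#' shadows.
#'
#' Speckle is modelled as multiplicative gamma noise with unit mean and
#' shape `speckle_shape`; frame averaging of the acquisition protocol is
#' represented only through a high shape value (averaging N uncorrelated
#' speckle realisations multiplies the shape by about N).  Use
#' `speckle_shape = Inf` for noise-free rendering.
#'
#' @param axial_um_per_px Axial calibration, micrometres per pixel.
#' @param ascan_count Number of A-scans (image columns).
#' @param scan_length_um Lateral scan length; the lateral calibration is
#'   `scan_length_um / ascan_count` unless given explicitly.
#' @param lateral_um_per_px Optional explicit lateral calibration; must
#'   agree with `scan_length_um / ascan_count` within one pixel.
#' @param depth_px Image depth in pixels.
#' @param speckle_shape Gamma shape of the multiplicative speckle.
#' @param shadow_columns Vessel shadows: a data frame with columns
#'   `pos_um` (lateral position relative to the scan centre), `width_um`
#'   and `atten` (attenuation factor in (0, 1]); `NULL` for none.
#' @param psf_axial_sigma_um Axial Gaussian PSF sigma.
#' @param background_level Intensity floor outside the retina.
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(axial_um_per_px = 3.9,
                              ascan_count = 1536L,
                              scan_length_um = 4500,
                              lateral_um_per_px = NULL,
                              depth_px = 160L,
                              speckle_shape = 100,
                              shadow_columns = NULL,
                              psf_axial_sigma_um = 8,
                              background_level = 0.015) {
  lateral <- lateral_um_per_px %||% (scan_length_um / ascan_count)
  if (abs(ascan_count * lateral - scan_length_um) > lateral) {
    abort("ascan_count * lateral_um_per_px must match scan_length_um within one pixel")
  }
  if (!is.null(shadow_columns)) {
    shadow_columns <- as_tibble(shadow_columns)
    stopifnot(all(c("pos_um", "width_um", "atten") %in% names(shadow_columns)))
    if (any(shadow_columns$atten <= 0 | shadow_columns$atten > 1)) {
      abort("shadow attenuation factors must lie in (0, 1]")
    }
  }
  stopifnot(axial_um_per_px > 0, depth_px >= 8, speckle_shape > 0)
  structure(list(
    axial_um_per_px = axial_um_per_px,
    lateral_um_per_px = lateral,
    scan_length_um = scan_length_um,
    ascan_count = as.integer(ascan_count),
    depth_px = as.integer(depth_px),
    speckle_shape = speckle_shape,
    shadow_columns = shadow_columns,
    psf_axial_sigma_um = psf_axial_sigma_um,
    background_level = background_level
  ), class = "acquisition_model")
}

#' Microcyst population specification
#'
#' Parameters of the hyporeflective INL microcysts injected into an eye:
#' how many, where (eccentricity range and allowed radial lines), their
#' size (elongated perpendicular to the layers, so the axial extent
#' exceeds the lateral), and how dark they are relative to the local INL.
#'
#' Defaults place cysts 750-2000 um from the fovea on the supero- and
#' infero-nasal lines, matching the topography reported for microcystic
#' macular change after optic neuritis.
#'
#' @param count_range Integer interval: cysts per affected eye.
#' @param eccentricity_range_um Radial placement interval from the fovea.
#' @param allowed_radial_lines Template line numbers that may carry cysts
#'   (lines 5, 6, 8, 9 are the supero-/infero-nasal obliques).
#' @param axial_extent_um,lateral_extent_um Size intervals; axial must
#'   dominate lateral (elongation perpendicular to the layers).
#' @param intensity_drop Fraction of the local intensity removed inside a
#'   cyst, in (0, 1].
#' @return An object of class `cyst_spec`.
#' @export
cyst_spec <- function(count_range = c(3L, 10L),
                      eccentricity_range_um = c(750, 2000),
                      allowed_radial_lines = c(5L, 6L, 8L, 9L),
                      axial_extent_um = c(20, 35),
                      lateral_extent_um = c(12, 25),
                      intensity_drop = 0.7) {
  stopifnot(length(count_range) == 2, count_range[1] <= count_range[2],
            count_range[1] >= 0)
  stopifnot(eccentricity_range_um[1] > 0,
            eccentricity_range_um[1] <= eccentricity_range_um[2])
  stopifnot(all(allowed_radial_lines %in% 1:12))
  if (min(axial_extent_um) <= max(lateral_extent_um) &&
      mean(axial_extent_um) <= mean(lateral_extent_um)) {
    abort("cysts must be elongated perpendicular to the layers (axial > lateral)")
  }
  stopifnot(intensity_drop > 0, intensity_drop <= 1)
  structure(list(
    count_range = as.integer(count_range),
    eccentricity_range_um = eccentricity_range_um,
    allowed_radial_lines = as.integer(allowed_radial_lines),
    axial_extent_um = axial_extent_um,
    lateral_extent_um = lateral_extent_um,
    intensity_drop = intensity_drop
  ), class = "cyst_spec")
}

#' Cohort simulation specification
#'
#' Generative parameters for a paired-eye case/control cohort: per-group
#' multivariate-normal layer thickness targets (RNFL, GCL/IPL, INL, in
#' um), inter-layer correlation matrices, the within-subject coupling of
#' fellow-eye thickness, and the fraction of case eyes that receive INL
#' microcysts.  Thickness draws are truncated at 1 um.
#'
#' The defaults reproduce the published group statistics for optic
#' neuritis (ON) eyes versus healthy control eyes: control means
#' 32.2/98.1/39.6 um with SDs 2/5/3 and correlations (RNFL-GCLIPL 0.14,
#' RNFL-INL 0.03, GCLIPL-INL 0.65); ON means 27.8/69.3/42.9 um with SDs
#' 4/14/6 and correlations (0.80, -0.61, -0.44).
#'
#' @param n_per_group Subjects per group.
#' @param control_mean,control_sd,on_mean,on_sd Length-3 vectors in the
#'   order RNFL, GCL/IPL, INL.
#' @param control_corr,on_corr 3x3 correlation matrices (symmetric PSD,
#'   unit diagonal).
#' @param fellow_coupling Within-subject between-eye correlation of each
#'   layer's thickness, in `[-1, 1]`.
#' @param cyst_prevalence Fraction of ON eyes receiving microcysts;
#'   exactly `round(prevalence * n)` eyes are affected.
#' @param cyst_assignment `"random"` assigns affected eyes uniformly;
#'   `"extreme"` assigns them to the eyes with the largest INL draw,
#'   mimicking cysts marking the severe end of the spectrum.
#' @param cyst_inl_shift_um Additional INL thickness given to
#'   cyst-positive eyes (a thicker-INL stratum), default 0.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 36L,
                        control_mean = c(32.2, 98.1, 39.6),
                        control_sd = c(2, 5, 3),
                        control_corr = matrix(c(1, 0.14, 0.03,
                                                0.14, 1, 0.65,
                                                0.03, 0.65, 1), 3, 3),
                        on_mean = c(27.8, 69.3, 42.9),
                        on_sd = c(4, 14, 6),
                        on_corr = matrix(c(1, 0.80, -0.61,
                                           0.80, 1, -0.44,
                                           -0.61, -0.44, 1), 3, 3),
                        fellow_coupling = 0.8,
                        cyst_prevalence = 5 / 36,
                        cyst_assignment = c("random", "extreme"),
                        cyst_inl_shift_um = 0) {
  cyst_assignment <- match.arg(cyst_assignment)
  check_corr <- function(m, label) {
    if (!isTRUE(all.equal(m, t(m))) || any(abs(diag(m) - 1) > 1e-12)) {
      abort(sprintf("%s correlation matrix must be symmetric with unit diagonal", label))
    }
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      abort(sprintf("%s correlation matrix is not positive semi-definite", label))
    }
  }
  check_corr(control_corr, "control")
  check_corr(on_corr, "ON")
  stopifnot(all(control_sd > 0), all(on_sd > 0))
  stopifnot(cyst_prevalence >= 0, cyst_prevalence <= 1)
  stopifnot(abs(fellow_coupling) <= 1)
  structure(list(
    n_per_group = as.integer(n_per_group),
    control_mean = control_mean, control_sd = control_sd,
    control_corr = control_corr,
    on_mean = on_mean, on_sd = on_sd, on_corr = on_corr,
    fellow_coupling = fellow_coupling,
    cyst_prevalence = cyst_prevalence,
    cyst_assignment = cyst_assignment,
    cyst_inl_shift_um = cyst_inl_shift_um
  ), class = "cohort_spec")
}
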