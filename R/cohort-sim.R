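#' Simulate a paired-eye case/control cohort
#'
#' Draws per-eye ground-truth layer thickness targets from the group
#' multivariate normals of a [cohort_spec()].  Control subjects
#' contribute one eye (laterality chosen at random); ON subjects
#' contribute a designated ON eye and a fellow eye whose thicknesses are
#' coupled with within-subject correlation `fellow_coupling` (the joint
#' 6-variate covariance is `Sigma (x) [[1, rho], [rho, 1]]`, so coupling 1
#' makes the eyes identical).  Draws are truncated at 1 um.  Exactly
#' `round(prevalence * n)` ON eyes are flagged to receive microcysts.
#'
#' This returns the ground-truth table only; use [render_eye()] to turn
#' any row pair into an actual radial scan set.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; every draw derives from it.
#' @return A tibble of class `oct_cohort`, one row per eye:
#'   `subject, group, role (control/on/fellow), eye (OD/OS), rnfl_um,
#'   gclipl_um, inl_um, cyst, age, sex, duration_on_to_oct, duration_ms`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_per_group
  withr::with_seed(child_seed(seed, "cohort"), {
    # controls: one eye from the control MVN
    Sc <- diag(spec$control_sd) %*% spec$control_corr %*% diag(spec$control_sd)
    ctl <- MASS::mvrnorm(n, spec$control_mean, Sc)
    ctl <- pmax(ctl, 1)

    # ON subjects: joint (ON eye, fellow eye) 6-variate draw
    So <- diag(spec$on_sd) %*% spec$on_corr %*% diag(spec$on_sd)
    rho <- spec$fellow_coupling
    S6 <- rbind(cbind(So, rho * So), cbind(rho * So, So))
    # guard tiny asymmetries from the kron construction
    S6 <- (S6 + t(S6)) / 2
    onj <- MASS::mvrnorm(n, rep(spec$on_mean, 2), S6)
    onj <- pmax(onj, 1)

    n_cyst <- round(spec$cyst_prevalence * n)
    cyst_idx <- switch(spec$cyst_assignment,
      random = sample(n, n_cyst),
      extreme = order(onj[, 3], decreasing = TRUE)[seq_len(n_cyst)])
    cyst <- seq_len(n) %in% cyst_idx
    onj[cyst, 3] <- onj[cyst, 3] + spec$cyst_inl_shift_um

    ctl_eye <- sample(c("OD", "OS"), n, replace = TRUE)
    on_eye <- sample(c("OD", "OS"), n, replace = TRUE)
    age_c <- pmax(rnorm(n, 39.5, 10.7), 18)
    age_o <- pmax(rnorm(n, 39.5, 9.8), 18)
    sex_c <- sample(c("F", "M"), n, replace = TRUE, prob = c(27, 9) / 36)
    sex_o <- sample(c("F", "M"), n, replace = TRUE, prob = c(28, 8) / 36)
    dur_on <- pmin(pmax(stats::rlnorm(n, log(38), 0.9), 3), 203)
    dur_ms <- pmin(pmax(dur_on + stats::rlnorm(n, log(10), 1), 3), 250)

    out <- dplyr::bind_rows(
      tibble(subject = sprintf("C%03d", 1:n), group = "control",
             role = "control", eye = ctl_eye,
             rnfl_um = ctl[, 1], gclipl_um = ctl[, 2], inl_um = ctl[, 3],
             cyst = FALSE, age = age_c, sex = sex_c,
             duration_on_to_oct = NA_real_, duration_ms = NA_real_),
      tibble(subject = sprintf("P%03d", 1:n), group = "ON",
             role = "on", eye = on_eye,
             rnfl_um = onj[, 1], gclipl_um = onj[, 2], inl_um = onj[, 3],
             cyst = cyst, age = age_o, sex = sex_o,
             duration_on_to_oct = dur_on, duration_ms = dur_ms),
      tibble(subject = sprintf("P%03d", 1:n), group = "ON",
             role = "fellow", eye = ifelse(on_eye == "OD", "OS", "OD"),
             rnfl_um = onj[, 4], gclipl_um = onj[, 5], inl_um = onj[, 6],
             cyst = FALSE, age = age_o, sex = sex_o,
             duration_on_to_oct = dur_on, duration_ms = dur_ms)
    )
    class(out) <- c("oct_cohort", class(out))
    attr(out, "spec") <- spec
    attr(out, "seed") <- seed
    out
  })
}

#' Render the radial scan set of one simulated eye
#'
#' Builds a phantom whose grid-mean layer thicknesses equal the eye's
#' ground-truth draw, injects microcysts if the eye is flagged, and
#' renders all six radial slices.
#'
#' @param truth_row One row of a [simulate_cohort()] table.
#' @param acq An [acquisition_model()].
#' @param cysts A [cyst_spec()] used when `truth_row$cyst` is `TRUE`.
#' @param seed Integer seed; combined with subject and eye so that every
#'   eye gets an independent, reproducible speckle and cyst draw.
#' @return A list of class `eye_scan_set`: `scans` (list of 6 [bscan]
#'   objects), `phantom`, `truth_row`.
#' @export
render_eye <- function(truth_row, acq = acquisition_model(),
                       cysts = cyst_spec(), seed = 1L) {
  stopifnot(nrow(truth_row) == 1)
  eseed <- child_seed(seed, truth_row$subject, truth_row$eye)
  ph <- make_layer_geometry(
    rnfl_um = truth_row$rnfl_um,
    gclipl_um = truth_row$gclipl_um,
    inl_um = truth_row$inl_um,
    seed = eseed
  )
  if (isTRUE(truth_row$cyst)) {
    ph <- inject_microcysts(ph, cysts, seed = eseed, eye = truth_row$eye)
  }
  scans <- lapply(0:5, function(s) render_bscan(ph, s, acq, seed = eseed))
  structure(list(scans = scans, phantom = ph, truth_row = truth_row,
                 eye = truth_row$eye, subject = truth_row$subject),
            class = "eye_scan_set")
}
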