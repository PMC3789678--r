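#' Two-group comparison of per-eye layer means
#'
#' Unpaired two-sample Student t-test (pooled variance by default, the
#' classical "student t-test"; Welch available as an option) on per-eye
#' layer mean thicknesses.
#'
#' @param data A tibble of eye summaries with at least `group` and the
#'   value column named by `layer` (e.g. from [summarise_eyes()]), or
#'   any data frame with one row per eye.
#' @param layer Name of the value column to compare (e.g. `"inl_um"`).
#' @param group Name of the grouping column (two levels).
#' @param var_equal Pooled-variance Student test (`TRUE`, default) or
#'   Welch (`FALSE`).
#' @return A one-row tibble: group means and SDs (to 0.1 um when
#'   printed), `t`, `df`, `p`, and the group labels.
#' @export
group_compare <- function(data, layer, group = "group", var_equal = TRUE) {
  data <- as_tibble(data)
  stopifnot(layer %in% names(data), group %in% names(data))
  g <- factor(data[[group]])
  if (nlevels(g) != 2) abort("group_compare needs exactly two groups")
  x <- data[[layer]][g == levels(g)[1]]
  y <- data[[layer]][g == levels(g)[2]]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) abort("need >= 2 eyes per group")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      inform("zero variance in both groups with equal means; p = 1 by convention")
      tt <- list(statistic = c(t = 0), parameter = c(df = length(x) + length(y) - 2),
                 p.value = 1)
    } else {
      warn("zero variance in both groups with different means; p = 0 by convention")
      tt <- list(statistic = c(t = sign(mean(x) - mean(y)) * Inf),
                 parameter = c(df = length(x) + length(y) - 2), p.value = 0)
    }
  } else {
    tt <- stats::t.test(x, y, var.equal = var_equal)
  }
  tibble(layer = layer,
         group1 = levels(g)[1], group2 = levels(g)[2],
         n1 = length(x), n2 = length(y),
         mean1 = mean(x), sd1 = sd(x),
         mean2 = mean(y), sd2 = sd(y),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
}

#' Pearson correlation with two-sided p-value
#'
#' Standard product-moment correlation; the p-value comes from the t
#' transform with n - 2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (n >= 3, finite).
#' @return A one-row tibble `(r, n, t, df, p)`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3) {
    abort("pearson_r needs equal-length finite vectors with n >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: zero variance in x or y")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), n = length(x),
         t = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value)
}

#' Inter-eye asymmetry analysis
#'
#' For each eligible subject the fellow-eye layer mean is subtracted
#' from the ON-eye layer mean (a thinner ON-eye layer gives a negative
#' difference), removing inter-subject anatomical variability.  The
#' analysis then correlates the GCL/IPL asymmetry with the INL
#' asymmetry across subjects.  Subjects without an analyzable fellow
#' eye (including binocular ON, which has no unaffected fellow eye) are
#' excluded with a message.
#'
#' @param summaries Eye-level tibble with columns `subject`, `role`
#'   (`"on"` / `"fellow"`), layer means `rnfl_um`, `gclipl_um`,
#'   `inl_um`, and optionally `cyst` (logical, ON eye cyst status) and
#'   `exclude` (logical, e.g. binocular ON).
#' @return A list of class `asymmetry_result`: `records` (per-subject
#'   differences, with cyst flag), `correlation` (a [pearson_r()] row
#'   for dGCL/IPL vs dINL, or `NULL` if undefined), `n_excluded`.
#' @export
asymmetry_analysis <- function(summaries) {
  summaries <- as_tibble(summaries)
  need <- c("subject", "role", "rnfl_um", "gclipl_um", "inl_um")
  stopifnot(all(need %in% names(summaries)))
  if (!"exclude" %in% names(summaries)) summaries$exclude <- FALSE
  if (!"cyst" %in% names(summaries)) summaries$cyst <- FALSE

  on_eyes <- dplyr::filter(summaries, .data$role == "on", !.data$exclude)
  fellow <- dplyr::filter(summaries, .data$role == "fellow", !.data$exclude)
  rec <- dplyr::inner_join(on_eyes, fellow, by = "subject",
                           suffix = c("_on", "_fellow"))
  dropped <- setdiff(unique(summaries$subject[summaries$role == "on"]),
                     rec$subject)
  if (length(dropped) > 0) {
    inform(sprintf("%d subject(s) dropped from asymmetry analysis (no fellow eye or excluded)",
                   length(dropped)))
  }
  records <- tibble(
    subject = rec$subject,
    d_rnfl_um = rec$rnfl_um_on - rec$rnfl_um_fellow,
    d_gclipl_um = rec$gclipl_um_on - rec$gclipl_um_fellow,
    d_inl_um = rec$inl_um_on - rec$inl_um_fellow,
    cyst = rec$cyst_on)
  if (nrow(records) < 3) abort("asymmetry analysis needs >= 3 eligible subjects")
  corr <- tryCatch(pearson_r(records$d_gclipl_um, records$d_inl_um),
                   error = function(e) {
                     inform(paste("asymmetry correlation undefined:",
                                  conditionMessage(e)))
                     NULL
                   })
  structure(list(records = records, correlation = corr,
                 n_excluded = length(dropped)),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf("<asymmetry_result> %d subjects (%d excluded)\n",
              nrow(x$records), x$n_excluded))
  if (!is.null(x$correlation)) {
    cat(sprintf("  corr(dGCL/IPL, dINL): r = %.2f, p = %.3g\n",
                x$correlation$r, x$correlation$p))
  } else {
    cat("  correlation undefined\n")
  }
  invisible(x)
}

#' Point-wise topographic deviation between groups
#'
#' Computes, at each of the 36 grid points and for each layer, the
#' difference in mean thickness between the ON group and the control
#' group, and correlates the GCL/IPL deviation with the INL deviation
#' across the grid points.
#'
#' Sign conventions (also stated in the output): the `deviation_um`
#' column is control mean - ON mean for RNFL and GCL/IPL (thinning
#' positive) and ON mean - control mean for the INL (thickening
#' positive), mirroring how deviation maps are usually drawn.  The
#' cross-layer correlation uses the signed ON - control differences for
#' both layers, so co-localised GCL/IPL loss and INL gain give a
#' negative r.
#'
#' @param control_grids,on_grids Long tibbles of grid measurements with
#'   columns `subject, line, eccentricity_um, layer, thickness_um,
#'   valid` (rows from [sample_grid()] bound together).
#' @param min_eyes Minimum valid eyes per group at a point for it to
#'   enter the correlation.
#' @return A list of class `deviation_map`: `map` (per point and layer:
#'   group means, ns, `deviation_um`, `signed_diff_um` = ON - control),
#'   `cross_layer` ([pearson_r()] of the GCL/IPL vs INL signed
#'   differences), `dropped_points`, and nasal/temporal aggregates.
#' @export
pointwise_deviation <- function(control_grids, on_grids, min_eyes = 2L) {
  prep <- function(g, label) {
    g <- as_tibble(g)
    stopifnot(all(c("line", "eccentricity_um", "layer", "thickness_um") %in% names(g)))
    if (!"valid" %in% names(g)) g$valid <- TRUE
    dplyr::summarise(
      dplyr::group_by(dplyr::filter(g, .data$valid),
                      .data$line, .data$eccentricity_um, .data$layer),
      mean_um = mean(.data$thickness_um), n = dplyr::n(), .groups = "drop")
  }
  ctl <- prep(control_grids, "control")
  on <- prep(on_grids, "ON")
  map <- dplyr::inner_join(ctl, on, by = c("line", "eccentricity_um", "layer"),
                           suffix = c("_control", "_on"))
  map <- dplyr::mutate(map,
    signed_diff_um = .data$mean_um_on - .data$mean_um_control,
    deviation_um = ifelse(.data$layer == "INL",
                          .data$signed_diff_um, -.data$signed_diff_um),
    nasal = .data$line %in% 5:9,
    quadrant = c("supero-temporal", "supero-nasal", "infero-nasal",
                 "infero-temporal")[(.data$line - 1) %/% 3 + 1])

  usable <- dplyr::filter(map, .data$n_control >= min_eyes,
                          .data$n_on >= min_eyes)
  dropped <- dplyr::anti_join(
    dplyr::distinct(map, .data$line, .data$eccentricity_um),
    dplyr::distinct(usable, .data$line, .data$eccentricity_um),
    by = c("line", "eccentricity_um"))
  if (nrow(dropped) > 0) {
    inform(sprintf("%d grid point(s) dropped from the cross-layer correlation",
                   nrow(dropped)))
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(usable, "line", "eccentricity_um", "layer", "signed_diff_um"),
    names_from = "layer", values_from = "signed_diff_um")
  cross <- tryCatch(pearson_r(wide$GCLIPL, wide$INL),
                    error = function(e) NULL)
  aggregates <- dplyr::summarise(
    dplyr::group_by(usable, .data$layer, .data$nasal),
    mean_deviation_um = mean(.data$deviation_um), .groups = "drop")

  structure(list(map = map, cross_layer = cross,
                 dropped_points = dropped, aggregates = aggregates,
                 sign_note = paste(
                   "deviation_um: control - ON for RNFL/GCLIPL (thinning",
                   "positive), ON - control for INL (thickening positive)")),
            class = "deviation_map")
}

#' @export
print.deviation_map <- function(x, ...) {
  cat("<deviation_map>", nrow(x$map), "point-layer entries\n")
  if (!is.null(x$cross_layer)) {
    cat(sprintf("  cross-layer (GCL/IPL vs INL, signed): r = %.2f, p = %.3g\n",
                x$cross_layer$r, x$cross_layer$p))
  }
  cat(" ", x$sign_note, "\n")
  invisible(x)
}

#' Correlation of INL thickness with a clinical covariate
#'
#' @param summaries Eye-level tibble with an `inl_um` column.
#' @param covariate Name of the covariate column (e.g.
#'   `"duration_on_to_oct"`), or a numeric vector of the same length.
#' @return A [pearson_r()] row.
#' @export
covariate_correlation <- function(summaries, covariate) {
  summaries <- as_tibble(summaries)
  v <- if (is.character(covariate)) {
    stopifnot(covariate %in% names(summaries))
    summaries[[covariate]]
  } else {
    covariate
  }
  pearson_r(summaries$inl_um, v)
}

#' Compare cyst-positive and cyst-negative eyes
#'
#' Applies [group_compare()] per layer to the cyst-defined split of ON
#' eyes, and re-runs the GCL/IPL-INL correlation excluding cyst-positive
#' eyes.  Both analyses are computed from the single measurement table
#' passed in, so "with" and "without" results are directly comparable.
#'
#' @param summaries ON-eye tibble with `cyst` (logical), `rnfl_um`,
#'   `gclipl_um`, `inl_um`.
#' @param layers Value columns to compare.
#' @return A list of class `subgroup_result`: `comparison` (one
#'   [group_compare()] row per layer), `corr_all`, `corr_no_cysts`
#'   (GCL/IPL vs INL [pearson_r()] with and without cyst-positive
#'   eyes), `n_cyst`, `n_no_cyst`.
#' @export
subgroup_compare <- function(summaries,
                             layers = c("rnfl_um", "gclipl_um", "inl_um")) {
  summaries <- as_tibble(summaries)
  stopifnot("cyst" %in% names(summaries))
  n1 <- sum(summaries$cyst); n0 <- sum(!summaries$cyst)
  if (n1 == 0 || n0 == 0) abort("both subgroups must be non-empty")
  if (n1 < 2 || n0 < 2) {
    abort(sprintf("insufficient n for subgroup comparison (%d vs %d eyes)", n1, n0))
  }
  summaries$cyst_group <- ifelse(summaries$cyst, "cyst", "no_cyst")
  comparison <- dplyr::bind_rows(lapply(layers, function(l) {
    group_compare(summaries, l, group = "cyst_group")
  }))
  corr_all <- pearson_r(summaries$gclipl_um, summaries$inl_um)
  no <- summaries[!summaries$cyst, ]
  corr_no <- pearson_r(no$gclipl_um, no$inl_um)
  structure(list(comparison = comparison, corr_all = corr_all,
                 corr_no_cysts = corr_no, n_cyst = n1, n_no_cyst = n0),
            class = "subgroup_result")
}
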