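#' Widen grid measurements into per-eye layer summaries
#'
#' Collapses a long table of grid measurements (rows from
#' [sample_grid()] results bound together, one row per subject, eye,
#' grid point and layer) into one row per eye with `rnfl_um`,
#' `gclipl_um` and `inl_um` mean columns.
#'
#' @param grids Long measurement tibble with `subject`, `eye`, `layer`,
#'   `thickness_um`, `valid` columns.
#' @param min_valid Minimum valid points per layer for an eye to be
#'   analyzable.
#' @return A tibble, one row per eye: layer means, minimum valid count
#'   across layers, `analyzable`.
#' @export
summarise_eyes <- function(grids, min_valid = 30L) {
  grids <- as_tibble(grids)
  out <- grids |>
    dplyr::group_by(.data$subject, .data$eye, .data$layer) |>
    dplyr::summarise(mean_um = mean(.data$thickness_um[.data$valid]),
                     n_valid = sum(.data$valid), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "layer",
                       values_from = c("mean_um", "n_valid"))
  dplyr::transmute(out,
    subject = .data$subject, eye = .data$eye,
    rnfl_um = .data$mean_um_RNFL,
    gclipl_um = .data$mean_um_GCLIPL,
    inl_um = .data$mean_um_INL,
    n_valid = pmin(.data$n_valid_RNFL, .data$n_valid_GCLIPL,
                   .data$n_valid_INL),
    analyzable = .data$n_valid >= min_valid)
}

#' Full cohort analysis
#'
#' Reproduces the study's statistical chain on eye-level summaries and
#' grid measurements: per-layer group comparisons, within-group
#' inter-layer Pearson correlations, the inter-eye asymmetry analysis,
#' covariate correlations, the cyst subgroup comparison, and the
#' 36-point topographic deviation analysis.
#'
#' @param summaries Eye-level tibble with columns `subject`, `group`
#'   (`"control"` / `"ON"`), `role` (`"control"` / `"on"` /
#'   `"fellow"`), `rnfl_um`, `gclipl_um`, `inl_um`, and optionally
#'   `cyst`, `exclude`, `duration_on_to_oct`, `duration_ms`.  The
#'   analysis set is controls plus designated ON eyes; fellow eyes
#'   enter only the asymmetry analysis.
#' @param grids Optional long grid table (see [summarise_eyes()]) for
#'   the point-wise deviation analysis.
#' @return A list of class `cohort_analysis` with elements
#'   `group_table`, `correlations`, `asymmetry`, `covariates`,
#'   `subgroup`, `deviation`.
#' @export
analyze_cohort <- function(summaries, grids = NULL) {
  summaries <- as_tibble(summaries)
  if (!"cyst" %in% names(summaries)) summaries$cyst <- FALSE
  if (!"exclude" %in% names(summaries)) summaries$exclude <- FALSE
  main <- dplyr::filter(summaries, .data$role %in% c("control", "on"))

  layers <- c("rnfl_um", "gclipl_um", "inl_um")
  group_table <- dplyr::bind_rows(lapply(layers, function(l) {
    group_compare(main, l)
  }))

  pairs <- list(c("rnfl_um", "gclipl_um"), c("rnfl_um", "inl_um"),
                c("gclipl_um", "inl_um"))
  correlations <- dplyr::bind_rows(lapply(split(main, main$group), function(d) {
    dplyr::bind_rows(lapply(pairs, function(pair) {
      r <- tryCatch(pearson_r(d[[pair[1]]], d[[pair[2]]]),
                    error = function(e) NULL)
      if (is.null(r)) return(NULL)
      dplyr::mutate(r, group = d$group[1], x = pair[1], y = pair[2],
                    .before = 1)
    }))
  }))

  asym <- tryCatch(asymmetry_analysis(summaries), error = function(e) {
    inform(paste("asymmetry analysis skipped:", conditionMessage(e)))
    NULL
  })

  on_eyes <- dplyr::filter(main, .data$group == "ON")
  covs <- dplyr::bind_rows(lapply(
    intersect(c("duration_on_to_oct", "duration_ms"), names(on_eyes)),
    function(cv) {
      v <- on_eyes[[cv]]
      r <- tryCatch(pearson_r(on_eyes$inl_um, v), error = function(e) NULL)
      if (is.null(r)) return(NULL)
      dplyr::mutate(r, covariate = cv, .before = 1)
    }))

  subgroup <- tryCatch(subgroup_compare(on_eyes), error = function(e) {
    inform(paste("cyst subgroup comparison skipped:", conditionMessage(e)))
    NULL
  })

  deviation <- NULL
  if (!is.null(grids)) {
    grids <- as_tibble(grids)
    key <- dplyr::select(main, "subject", "eye", "group")
    g2 <- dplyr::inner_join(grids, key, by = c("subject", "eye"))
    deviation <- pointwise_deviation(
      dplyr::filter(g2, .data$group == "control"),
      dplyr::filter(g2, .data$group == "ON"))
  }

  structure(list(group_table = group_table, correlations = correlations,
                 asymmetry = asym, covariates = covs, subgroup = subgroup,
                 deviation = deviation),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis>\n\nGroup comparison (per-eye layer means):\n")
  gt <- dplyr::mutate(x$group_table, dplyr::across(
    c("mean1", "sd1", "mean2", "sd2"), ~ round(.x, 1)))
  print(as.data.frame(gt), row.names = FALSE)
  cat("\nInter-layer correlations by group:\n")
  print(as.data.frame(dplyr::mutate(x$correlations,
                                    r = round(.data$r, 2))), row.names = FALSE)
  if (!is.null(x$asymmetry)) { cat("\n"); print(x$asymmetry) }
  if (!is.null(x$deviation)) { cat("\n"); print(x$deviation) }
  invisible(x)
}

# ---- broom-style tidiers ----------------------------------------------

#' Tidy a cohort analysis
#'
#' Returns the correlation table (`type = "correlation"`), the group
#' comparison (`"group"`), covariate correlations (`"covariate"`) or
#' the deviation map (`"deviation"`).
#'
#' @param x A `cohort_analysis`.
#' @param type Which component to tidy.
#' @param ... Unused.
#' @export
tidy.cohort_analysis <- function(x, type = c("correlation", "group",
                                             "covariate", "deviation"), ...) {
  type <- match.arg(type)
  switch(type,
         correlation = x$correlations,
         group = x$group_table,
         covariate = x$covariates,
         deviation = if (is.null(x$deviation)) tibble() else x$deviation$map)
}

#' @export
glance.cohort_analysis <- function(x, ...) {
  asym_r <- if (!is.null(x$asymmetry) && !is.null(x$asymmetry$correlation)) {
    x$asymmetry$correlation$r
  } else NA_real_
  dev_r <- if (!is.null(x$deviation) && !is.null(x$deviation$cross_layer)) {
    x$deviation$cross_layer$r
  } else NA_real_
  tibble(n_eyes = sum(x$group_table$n1[1], x$group_table$n2[1]),
         asymmetry_r = asym_r, deviation_r = dev_r)
}

#' @export
tidy.asymmetry_result <- function(x, ...) x$records

#' @export
glance.asymmetry_result <- function(x, ...) {
  if (is.null(x$correlation)) {
    tibble(n = nrow(x$records), r = NA_real_, p = NA_real_,
           n_excluded = x$n_excluded)
  } else {
    tibble(n = nrow(x$records), r = x$correlation$r, p = x$correlation$p,
           n_excluded = x$n_excluded)
  }
}

#' @export
tidy.deviation_map <- function(x, ...) x$map

#' @export
glance.deviation_map <- function(x, ...) {
  if (is.null(x$cross_layer)) {
    tibble(r = NA_real_, p = NA_real_, n_points = nrow(x$map) / 3)
  } else {
    tibble(r = x$cross_layer$r, p = x$cross_layer$p,
           n_points = x$cross_layer$n)
  }
}

#' @export
tidy.cyst_summary <- function(x, ...) x$quadrant_counts

#' @export
glance.cyst_summary <- function(x, ...) {
  tibble(n_eyes = x$n_eyes, n_affected = x$n_affected,
         prevalence_pct = x$prevalence_pct,
         mean_axial_um = x$mean_axial_um,
         mean_lateral_um = x$mean_lateral_um)
}
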