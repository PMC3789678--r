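#' Pipeline configuration
#'
#' One flat, YAML-serialisable container for every tunable of the
#' simulate - quality-gate - segment - measure - detect - analyze
#' chain.  Every parameter has the package default; a config written
#' with [write_config()] and read back with [read_config()] is
#' identical.
#'
#' @param n_per_group Subjects per group for simulation runs.
#' @param seed Master RNG seed for the whole pipeline.
#' @param ascan_count,depth_px,speckle_shape,axial_um_per_px Acquisition
#'   settings (see [acquisition_model()]).
#' @param eccentricities_um Protocol sample eccentricities.
#' @param cyst_prevalence,fellow_coupling Cohort generative settings
#'   (see [cohort_spec()]).
#' @param segmentation A [seg_params()].
#' @param cyst_detection A [cyst_params()].
#' @param cyst_injection A [cyst_spec()].
#' @param var_equal Student (pooled) vs Welch group tests.
#' @param write_images Write per-slice TIFFs during simulation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_per_group = 8L,
                            seed = 1L,
                            ascan_count = 768L,
                            depth_px = 160L,
                            speckle_shape = 100,
                            axial_um_per_px = 3.9,
                            eccentricities_um = c(750, 1450, 2150),
                            cyst_prevalence = 5 / 36,
                            fellow_coupling = 0.8,
                            segmentation = seg_params(),
                            cyst_detection = cyst_params(),
                            cyst_injection = cyst_spec(),
                            var_equal = TRUE,
                            write_images = FALSE) {
  structure(list(
    n_per_group = as.integer(n_per_group),
    seed = as.integer(seed),
    ascan_count = as.integer(ascan_count),
    depth_px = as.integer(depth_px),
    speckle_shape = speckle_shape,
    axial_um_per_px = axial_um_per_px,
    eccentricities_um = eccentricities_um,
    cyst_prevalence = cyst_prevalence,
    fellow_coupling = fellow_coupling,
    segmentation = unclass(segmentation),
    cyst_detection = unclass(cyst_detection),
    cyst_injection = unclass(cyst_injection),
    var_equal = var_equal,
    write_images = write_images
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  # named atomic vectors become YAML maps so their names survive
  listify <- function(x) {
    if (is.list(x)) lapply(x, listify)
    else if (!is.null(names(x)) && length(x) > 1) as.list(x)
    else x
  }
  yaml::write_yaml(listify(unclass(config)), path, precision = 15L)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, c(
    raw[setdiff(names(raw), c("segmentation", "cyst_detection",
                              "cyst_injection"))],
    list(segmentation = do.call(seg_params, .unlist_keep(raw$segmentation)),
         cyst_detection = do.call(cyst_params, .unlist_keep(raw$cyst_detection)),
         cyst_injection = do.call(cyst_spec, .unlist_keep(raw$cyst_injection)))))
  cfg
}

# yaml turns named numeric vectors into lists; restore them
.unlist_keep <- function(x) {
  lapply(x, function(v) if (is.list(v)) unlist(v) else v)
}

#' Run the full pipeline
#'
#' Simulates a cohort (or loads scans from `input_dir`), applies the
#' quality gate, segments every slice of every analysed eye, samples
#' the 36-point grids, detects INL microcysts, runs the cohort
#' analysis, and writes all artifacts (CSV tables, an analysis JSON and
#' a log) into `out_dir`.  Every artifact carries the config hash and
#' seed in a comment header.  The run is deterministic given the
#' config, including its seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param input_dir Optional directory with existing scans
#'   (`<subject>_<eye>_slice<k>.tif` plus `metadata.csv` with columns
#'   `subject, group, role, eye, cyst`); when `NULL`, a cohort is
#'   simulated.
#' @return Invisibly, a list with `truth`, `summaries`, `grids`,
#'   `cysts`, `quality`, `analysis`, `cyst_summary` and the output paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         input_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(unclass(config))
  meta <- list(config_hash = cfg_hash, seed = config$seed)
  logf <- file.path(out_dir, "pipeline.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)

  acq <- acquisition_model(
    axial_um_per_px = config$axial_um_per_px,
    ascan_count = config$ascan_count,
    depth_px = config$depth_px,
    speckle_shape = config$speckle_shape)
  protocol <- radial_protocol(eccentricities_um = config$eccentricities_um)
  segp <- do.call(seg_params, config$segmentation)
  cystp <- do.call(cyst_params, config$cyst_detection)
  cysts_spec <- do.call(cyst_spec, config$cyst_injection)

  if (is.null(input_dir)) {
    spec <- cohort_spec(n_per_group = config$n_per_group,
                        cyst_prevalence = config$cyst_prevalence,
                        fellow_coupling = config$fellow_coupling)
    truth <- simulate_cohort(spec, seed = config$seed)
    logline("simulated cohort: %d eyes", nrow(truth))
    eye_source <- function(row) {
      render_eye(row, acq, cysts_spec, seed = config$seed)$scans
    }
  } else {
    md_path <- file.path(input_dir, "metadata.csv")
    truth <- read_table_csv(md_path,
                            required = c("subject", "group", "role", "eye"))
    if (!"cyst" %in% names(truth)) truth$cyst <- NA
    logline("loaded metadata for %d eyes from %s", nrow(truth), input_dir)
    eye_source <- function(row) {
      lapply(0:5, function(s) {
        f <- file.path(input_dir,
                       sprintf("%s_%s_slice%d.tif", row$subject, row$eye, s))
        if (!file.exists(f)) abort(sprintf("stage segment: missing scan %s", f))
        tryCatch(
          read_bscan(f, axial_um_per_px = config$axial_um_per_px,
                     slice_index = s),
          error = function(e) {
            abort(sprintf("stage load: corrupt or unreadable scan %s (%s)",
                          f, conditionMessage(e)))
          })
      })
    }
  }

  all_grids <- vector("list", nrow(truth))
  all_cysts <- vector("list", nrow(truth))
  quality <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    scans <- tryCatch(eye_source(row), error = function(e) {
      abort(sprintf("stage render/load failed for %s/%s: %s",
                    row$subject, row$eye, conditionMessage(e)))
    })
    q <- dplyr::bind_rows(lapply(scans, quality_check))
    quality[[i]] <- dplyr::mutate(q, subject = row$subject, eye = row$eye,
                                  slice = 0:5)
    bds <- lapply(scans, segment_bscan, params = segp)
    grid <- sample_grid(bds, protocol, eye = row$eye, subject = row$subject)
    all_grids[[i]] <- grid
    cy <- dplyr::bind_rows(lapply(seq_along(scans), function(s) {
      detect_microcysts(scans[[s]], bds[[s]], cystp, eye = row$eye)
    }))
    if (nrow(cy) > 0) {
      cy$subject <- row$subject; cy$eye <- row$eye
      all_cysts[[i]] <- as_tibble(cy)
    }
    if (isTRUE(config$write_images)) {
      for (s in seq_along(scans)) {
        write_bscan(scans[[s]], file.path(out_dir,
          sprintf("%s_%s_slice%d.tif", row$subject, row$eye, s - 1)))
      }
    }
    logline("eye %s/%s: quality %s, %d cysts", row$subject, row$eye,
            ifelse(all(quality[[i]]$passed), "pass", "FLAGGED"),
            if (is.null(all_cysts[[i]])) 0 else nrow(all_cysts[[i]]))
  }

  grids <- dplyr::bind_rows(all_grids)
  cysts <- dplyr::bind_rows(all_cysts[!vapply(all_cysts, is.null, logical(1))])
  if (nrow(cysts) == 0) {
    cysts <- tibble(subject = character(0), eye = character(0),
                    line = integer(0))
  }
  quality <- dplyr::bind_rows(quality)

  summaries <- summarise_eyes(grids)
  summaries <- dplyr::left_join(
    summaries,
    dplyr::select(truth, dplyr::any_of(c("subject", "eye", "group", "role",
                                         "duration_on_to_oct", "duration_ms"))),
    by = c("subject", "eye"))
  cyst_eyes <- dplyr::distinct(cysts, .data$subject, .data$eye)
  summaries$cyst <- paste(summaries$subject, summaries$eye) %in%
    paste(cyst_eyes$subject, cyst_eyes$eye)

  analyzed <- dplyr::filter(summaries, .data$role %in% c("control", "on"))
  cyst_sum <- cohort_cyst_summary(
    dplyr::semi_join(cysts, analyzed, by = c("subject", "eye")),
    dplyr::select(analyzed, "subject", "eye"))
  analysis <- analyze_cohort(summaries, grids)

  write_table_csv(truth, file.path(out_dir, "cohort_truth.csv"), meta)
  write_table_csv(grids, file.path(out_dir, "grids.csv"), meta)
  write_table_csv(summaries, file.path(out_dir, "summaries.csv"), meta)
  write_table_csv(cysts, file.path(out_dir, "cysts.csv"), meta)
  write_table_csv(quality, file.path(out_dir, "quality.csv"), meta)
  if (!is.null(analysis$deviation)) {
    write_table_csv(analysis$deviation$map,
                    file.path(out_dir, "deviation_map.csv"),
                    c(meta, sign = analysis$deviation$sign_note))
  }
  report <- list(
    config_hash = cfg_hash, seed = config$seed,
    group_table = analysis$group_table,
    correlations = analysis$correlations,
    asymmetry = if (!is.null(analysis$asymmetry)) {
      glance(analysis$asymmetry)
    },
    covariates = analysis$covariates,
    cyst_prevalence_pct = cyst_sum$prevalence_pct,
    cyst_quadrants = cyst_sum$quadrant_counts)
  jsonlite::write_json(report, file.path(out_dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  write_config(config, file.path(out_dir, "config.yaml"))
  logline("analysis written; cyst prevalence %d%%", cyst_sum$prevalence_pct)

  invisible(list(truth = truth, grids = grids, summaries = summaries,
                 cysts = cysts, quality = quality, analysis = analysis,
                 cyst_summary = cyst_sum, out_dir = out_dir))
}
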