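test_that("cyst-free noise-free scans give an empty set", {
  sc <- test_scan(Inf)
  d <- detect_microcysts(sc, test_segmentation(Inf))
  expect_identical(nrow(d), 0L)
  expect_false(attr(d, "has_microcysts"))
})

test_that("no false detections on cyst-free eyes at default speckle", {
  for (seed in 1:3) {
    ph <- make_layer_geometry(seed = seed)
    sc <- render_bscan(ph, 1, test_acq(100), seed = seed)
    d <- detect_microcysts(sc, segment_bscan(sc))
    expect_identical(nrow(d), 0L)
  }
})

test_that("injected cysts are found and localised on the truth masks", {
  tr <- tibble::tibble(subject = "M", eye = "OD", cyst = TRUE,
                       rnfl_um = 27.8, gclipl_um = 69.3, inl_um = 42.9)
  es <- render_eye(tr, test_acq(100),
                   cyst_spec(count_range = c(6L, 6L)), seed = 5)
  n_inj <- nrow(es$phantom$cysts)
  found <- 0; outside <- 0
  for (s in 1:6) {
    sc <- es$scans[[s]]
    d <- detect_microcysts(sc, segment_bscan(sc))
    if (nrow(d) == 0) next
    mask <- sc$cyst_mask
    for (i in seq_len(nrow(d))) {
      r <- round(d$centroid_row[i]); c <- round(d$centroid_col[i])
      hit <- !is.null(mask) &&
        any(mask[max(1, r - 2):min(nrow(mask), r + 2),
                 max(1, c - 2):min(ncol(mask), c + 2)])
      if (hit) found <- found + 1 else outside <- outside + 1
    }
  }
  expect_gte(found, n_inj - 1)
  expect_identical(outside, 0)
})

test_that("detected cysts respect the generated topography", {
  tr <- tibble::tibble(subject = "M2", eye = "OS", cyst = TRUE,
                       rnfl_um = 25, gclipl_um = 60, inl_um = 48)
  es <- render_eye(tr, test_acq(100), cyst_spec(count_range = c(8L, 8L)),
                   seed = 8)
  d <- dplyr::bind_rows(lapply(1:6, function(s) {
    detect_microcysts(es$scans[[s]], segment_bscan(es$scans[[s]]),
                      eye = "OS")
  }))
  expect_gt(nrow(d), 0)
  expect_true(all(d$line %in% c(5L, 6L, 8L, 9L)))
  # centroid localisation tolerance: half a cyst width
  expect_true(all(abs(d$eccentricity_um) > 700))
  expect_true(all(abs(d$eccentricity_um) < 2060))
})

test_that("all reported cyst pixels lie inside the traced INL band", {
  tr <- tibble::tibble(subject = "M3", eye = "OD", cyst = TRUE,
                       rnfl_um = 27.8, gclipl_um = 69.3, inl_um = 45)
  es <- render_eye(tr, test_acq(100), cyst_spec(), seed = 13)
  for (s in 1:6) {
    bd <- segment_bscan(es$scans[[s]])
    d <- detect_microcysts(es$scans[[s]], bd)
    if (nrow(d) == 0) next
    w <- boundaries_wide(bd)
    for (i in seq_len(nrow(d))) {
      cc <- round(d$centroid_col[i])
      expect_gt(d$centroid_row[i], w[cc, "GCLIPL_INL"])
      expect_lt(d$centroid_row[i], w[cc, "INL_OPL"])
    }
  }
})

test_that("eyes with injected cysts measure a strictly thicker INL", {
  acq <- test_acq(100)
  for (seed in c(2, 9)) {
    tr <- tibble::tibble(subject = paste0("C", seed), eye = "OD",
                         cyst = TRUE, rnfl_um = 27.8, gclipl_um = 69.3,
                         inl_um = 42.9)
    with_cy <- measure_eye(tr, acq, seed = seed)
    tr0 <- tr; tr0$cyst <- FALSE
    without <- measure_eye(tr0, acq, seed = seed)
    m1 <- mean(with_cy$grid$thickness_um[with_cy$grid$layer == "INL"],
               na.rm = TRUE)
    m0 <- mean(without$grid$thickness_um[without$grid$layer == "INL"],
               na.rm = TRUE)
    expect_gt(m1, m0)
  }
})

test_that("prevalence arithmetic and quadrant mapping are exact", {
  eyes <- tidyr::expand_grid(subject = sprintf("P%02d", 1:36), eye = "OD")
  cysts <- tibble::tibble(subject = sprintf("P%02d", 1:5), eye = "OD",
                          line = c(5L, 6L, 8L, 9L, 5L),
                          axial_um = 25, lateral_um = 15, area_um2 = 300)
  s <- cohort_cyst_summary(cysts, eyes)
  expect_identical(s$prevalence_pct, 14L)
  expect_identical(s$n_affected, 5L)
  qc <- s$quadrant_counts
  expect_identical(qc$n_cysts[qc$quadrant == "supero-temporal"], 0L)
  expect_identical(qc$n_cysts[qc$quadrant == "infero-temporal"], 0L)
  expect_identical(sum(qc$n_cysts), 5L)

  s0 <- cohort_cyst_summary(cysts[0, ], eyes)
  expect_identical(s0$prevalence_pct, 0L)
  expect_error(cohort_cyst_summary(cysts, eyes[0, ]), "undefined|no analysed")
})
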