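test_that("the default protocol defines 12 lines at 30 degrees and 36 points", {
  p <- radial_protocol()
  expect_identical(p$n_lines, 12L)
  expect_identical(p$angular_step_deg, 30)
  expect_identical(p$n_points, 36L)
  expect_true(all(p$eccentricities_um >= 750))
})

test_that("protocol validation rejects inconsistent geometry", {
  expect_error(radial_protocol(n_slices = 5L))
  expect_error(radial_protocol(eccentricities_um = c(750, 700)))
  expect_error(radial_protocol(eccentricities_um = c(750, 3000)))
})

test_that("a laterally flat phantom samples to its constant thickness", {
  # negligible pit so thickness is constant over the sampled region
  ph <- make_layer_geometry(30, 80, 40, pit_radius_um = 1, seed = 1)
  sc <- lapply(0:5, function(s) render_bscan(ph, s, test_acq(Inf), seed = 1))
  bds <- lapply(sc, truth_boundaries)
  grid <- sample_grid(bds, radial_protocol(), subject = "F")
  expect_identical(nrow(grid), 108L)  # 36 points x 3 layers
  expect_true(all(grid$valid))
  for (tg in list(c("RNFL", 30), c("GCLIPL", 80), c("INL", 40))) {
    v <- grid$thickness_um[grid$layer == tg[1]]
    expect_true(all(abs(v - as.numeric(tg[2])) < 1))
  }
})

test_that("grids from segmented scans match phantom truth within 2 um RMS", {
  tr <- tibble::tibble(subject = "S", eye = "OD", cyst = FALSE,
                       rnfl_um = 32.2, gclipl_um = 98.1, inl_um = 39.6)
  m <- measure_eye(tr, test_acq(Inf), seed = 3)
  tg <- phantom_truth_grid(m$eye$phantom, radial_protocol())
  cmp <- dplyr::inner_join(m$grid, tg,
                           by = c("line", "eccentricity_um", "layer"),
                           suffix = c("", ".t"))
  err <- cmp$thickness_um - cmp$thickness_um.t
  expect_lt(sqrt(mean(err^2)), 2)
})

test_that("every line/eccentricity pair appears exactly once per layer", {
  sc <- lapply(0:5, function(s) render_bscan(
    make_layer_geometry(seed = 2), s, test_acq(Inf), seed = 2))
  grid <- sample_grid(lapply(sc, truth_boundaries), radial_protocol())
  counts <- table(grid$line, grid$eccentricity_um, grid$layer)
  expect_true(all(counts == 1))
})

test_that("rotating the thickness field by 30 degrees permutes the lines", {
  gains <- 1 + 0.2 * sin(2 * pi * (1:12) / 12)
  mk <- function(g) {
    lg <- list(rnfl = rep(1, 12), gclipl = g, inl = rep(1, 12))
    ph <- make_layer_geometry(line_gain = lg, undulation_um = 0, seed = 1)
    sc <- lapply(0:5, function(s) render_bscan(ph, s, test_acq(Inf), seed = 1))
    sample_grid(lapply(sc, truth_boundaries), radial_protocol())
  }
  g1 <- mk(gains)
  g2 <- mk(gains[c(2:12, 1)])   # field rotated by one 30-degree step
  a <- subset(as.data.frame(g1), layer == "GCLIPL")
  b <- subset(as.data.frame(g2), layer == "GCLIPL")
  b$line_unrot <- (b$line %% 12) + 1
  m <- merge(a, b, by.x = c("line", "eccentricity_um"),
             by.y = c("line_unrot", "eccentricity_um"))
  expect_true(all(abs(m$thickness_um.x - m$thickness_um.y) < 1))
})

test_that("eye summaries average valid entries and flag sparse eyes", {
  grid <- tidyr::expand_grid(line = 1:12, eccentricity_um = c(750, 1450, 2150),
                             layer = c("RNFL", "GCLIPL", "INL"))
  grid$thickness_um <- 40
  grid$valid <- TRUE
  grid$subject <- "T"; grid$eye <- "OD"
  class(grid) <- c("thickness_grid", class(grid))
  attr(grid, "subject") <- "T"; attr(grid, "eye") <- "OD"
  s <- eye_summary(grid)
  expect_equal(s$mean_um, rep(40, 3))
  expect_equal(s$n_valid, rep(36L, 3))

  grid2 <- grid
  grid2$thickness_um[1] <- 400
  grid2$valid[1] <- FALSE
  s2 <- eye_summary(grid2)
  g2 <- s2[s2$layer == grid2$layer[1], ]
  expect_equal(g2$mean_um, 40)       # invalid entry masked out
  expect_equal(g2$n_invalid, 1L)

  grid3 <- grid
  grid3$valid[grid3$layer == "INL"][1:10] <- FALSE
  expect_message(s3 <- eye_summary(grid3), "unanalyzable")
  expect_false(all(s3$analyzable))
})

test_that("cohort-level INL mean is recovered end to end", {
  # measurement machinery applied to rendered + segmented eyes; modest n
  # per eye but the mean over eyes must sit close to the generative mean
  spec <- cohort_spec(n_per_group = 12L)
  tr <- simulate_cohort(spec, seed = 19)
  ctl <- tr[tr$role == "control", ]
  acq <- test_acq(100)
  means <- sapply(seq_len(nrow(ctl)), function(i) {
    m <- measure_eye(ctl[i, ], acq, seed = 19)
    s <- eye_summary(m$grid)
    c(s$mean_um[s$layer == "INL"], ctl$inl_um[i])
  })
  bias <- mean(means[1, ] - means[2, ])
  expect_lt(abs(bias), 1)
})
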