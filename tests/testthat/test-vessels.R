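# shadow positions stay outside the foveal avascular zone, as real
# vessels do
shadow_acq <- function(speckle = 100, n = 3) {
  pos <- c(-1500, -700, 900, 1600, 550)[seq_len(n)]
  test_acq(speckle, shadow_columns = data.frame(
    pos_um = pos, width_um = 70, atten = 0.5))
}

test_that("shadow-free scans yield an empty flag set", {
  expect_length(detect_vessel_shadows(test_scan(Inf)), 0)
  expect_length(detect_vessel_shadows(test_scan(100)), 0)
})

test_that("injected shadows are flagged with few false positives", {
  ph <- make_layer_geometry(seed = 2)
  sc <- render_bscan(ph, 0, shadow_acq(100, 3), seed = 2)
  flagged <- detect_vessel_shadows(sc)
  truth <- sc$shadow_columns
  sens <- mean(truth %in% flagged)
  # flagged runs are dilated by two columns by design; false positives
  # are columns further than that margin from any true shadow column
  near_truth <- unique(as.vector(outer(truth, -2:2, "+")))
  fp <- length(setdiff(flagged, near_truth)) /
    (ncol(sc$pixels) - length(near_truth))
  expect_gte(sens, 0.9)
  expect_lte(fp, 0.01)
})

test_that("shadow detection is invariant to global gain", {
  ph <- make_layer_geometry(seed = 2)
  sc <- render_bscan(ph, 0, shadow_acq(100, 3), seed = 2)
  dim70 <- sc
  dim70$pixels <- sc$pixels * 0.7
  expect_identical(detect_vessel_shadows(sc), detect_vessel_shadows(dim70))
})

test_that("remove_vessels is the identity for an empty column set", {
  sc <- test_scan(100)
  expect_identical(remove_vessels(sc, integer(0))$pixels, sc$pixels)
})

test_that("interpolation restores a laterally linear image exactly", {
  ramp <- matrix(rep(seq(0, 1, length.out = 100), each = 50), 50, 100)
  sc <- bscan(ramp)
  out <- remove_vessels(sc, 40L)
  expect_equal(out$pixels[, 40], ramp[, 40], tolerance = 1e-12)
  expect_identical(out$pixels[, -40], ramp[, -40])
})

test_that("edge-touching runs are filled by extension with a message", {
  ramp <- matrix(rep(seq(0.1, 0.9, length.out = 50), each = 30), 30, 50)
  expect_message(out <- remove_vessels(bscan(ramp), 1:3), "edge")
  expect_equal(out$pixels[, 1], ramp[, 4], tolerance = 1e-12)
})

test_that("thickness at the grid survives five vessel shadows within 2 um RMS", {
  tr <- tibble::tibble(subject = "V", eye = "OD", cyst = FALSE,
                       rnfl_um = 32.2, gclipl_um = 98.1, inl_um = 39.6)
  base <- measure_eye(tr, test_acq(100), seed = 31)
  ph <- base$eye$phantom
  acq_sh <- shadow_acq(100, 5)
  eseed <- octinl:::child_seed(31, "V", "OD")  # same speckle as the base run
  bds <- lapply(0:5, function(s) {
    segment_bscan(render_bscan(ph, s, acq_sh, seed = eseed))
  })
  grid_sh <- sample_grid(bds, radial_protocol(), eye = "OD", subject = "V")
  d <- grid_sh$thickness_um - base$grid$thickness_um
  expect_lt(sqrt(mean(d^2)), 2)
})
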