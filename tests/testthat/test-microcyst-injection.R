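test_that("a zero cyst count leaves the scan unchanged with no mask", {
  ph <- make_layer_geometry(seed = 1)
  ph0 <- inject_microcysts(ph, cyst_spec(count_range = c(0L, 0L)), seed = 1)
  a <- render_bscan(ph, 2, test_acq(80), seed = 2)
  b <- render_bscan(ph0, 2, test_acq(80), seed = 2)
  expect_identical(a$pixels, b$pixels)
  expect_null(b$cyst_mask)
})

test_that("default cysts sit on allowed nasal lines within 750-2000 um", {
  for (seed in 1:5) {
    for (eye in c("OD", "OS")) {
      ph <- inject_microcysts(make_layer_geometry(42.9, 69.3, 42.9, seed = seed),
                              cyst_spec(), seed = seed, eye = eye)
      cy <- ph$cysts
      expect_gt(nrow(cy), 0)
      expect_true(all(cy$line %in% c(5L, 6L, 8L, 9L)))
      expect_true(all(cy$eccentricity_um >= 750 & cy$eccentricity_um <= 2000))
      # slice/side consistent with the eye's template mapping
      for (i in seq_len(nrow(cy))) {
        ls <- octinl:::.line_to_slice(cy$line[i], eye)
        expect_equal(cy$slice[i], ls$slice)
        expect_equal(sign(cy$x_um[i]), ls$side)
      }
    }
  }
})

test_that("rendered cyst masks are elongated perpendicular to the layers", {
  ph <- inject_microcysts(make_layer_geometry(27.8, 69.3, 42.9, seed = 3),
                          cyst_spec(), seed = 3)
  acq <- test_acq(Inf)
  for (s in sort(unique(ph$cysts$slice))) {
    sc <- render_bscan(ph, s, acq, seed = 3)
    expect_false(is.null(sc$cyst_mask))
    lab <- EBImage::bwlabel(sc$cyst_mask)
    for (k in seq_len(max(lab))) {
      px <- which(lab == k)
      rr <- range(((px - 1) %% nrow(lab)) + 1)
      cc <- range(((px - 1) %/% nrow(lab)) + 1)
      ax_um <- diff(rr) * sc$axial_um_per_px
      lat_um <- diff(cc) * sc$lateral_um_per_px
      expect_gt(ax_um, lat_um)
    }
  }
})

test_that("cyst pixels are darkened and confined to the INL band", {
  ph <- inject_microcysts(make_layer_geometry(seed = 7), cyst_spec(),
                          seed = 7)
  acq <- test_acq(Inf)
  s <- ph$cysts$slice[1]
  with_cysts <- render_bscan(ph, s, acq, seed = 7)
  ph_clean <- ph; ph_clean$cysts <- NULL
  clean <- render_bscan(ph_clean, s, acq, seed = 7)
  m <- with_cysts$cyst_mask
  expect_true(all(with_cysts$pixels[m] < clean$pixels[m] + 1e-12))
  tw <- truth_wide(with_cysts)
  px <- which(m)
  rr <- ((px - 1) %% nrow(m)) + 1
  cc <- ((px - 1) %/% nrow(m)) + 1
  expect_true(all(rr > tw[cc, "GCLIPL_INL"]))
  expect_true(all(rr < tw[cc, "INL_OPL"]))
})

test_that("a cyst that cannot fit in a thin INL is skipped with a message", {
  ph <- make_layer_geometry(inl_um = 12, seed = 2)
  # force no thickening bump so the fit must fail
  ph <- inject_microcysts(ph, cyst_spec(axial_extent_um = c(30, 34),
                                        count_range = c(2L, 2L)), seed = 2)
  ph$cysts$bump_um <- 0
  expect_message(render_bscan(ph, ph$cysts$slice[1], test_acq(Inf), seed = 2),
                 "skipped")
})

test_that("cyst spec validation catches degenerate shapes", {
  expect_error(cyst_spec(axial_extent_um = c(5, 8),
                         lateral_extent_um = c(10, 20)), "elongated")
  expect_error(cyst_spec(eccentricity_range_um = c(-10, 100)))
})
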