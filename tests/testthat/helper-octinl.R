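# shared fixtures: all synthetic, generated in code, cached per session

.fix <- new.env(parent = emptyenv())

test_acq <- function(speckle = 100, width = 768L, ...) {
  acquisition_model(ascan_count = width, depth_px = 160L,
                    speckle_shape = speckle, ...)
}

# one rendered control-anatomy scan + its segmentation, cached
test_scan <- function(speckle = Inf, seed = 1L, slice = 0L) {
  key <- paste0("scan_", speckle, "_", seed, "_", slice)
  if (is.null(.fix[[key]])) {
    ph <- make_layer_geometry(32.2, 98.1, 39.6, seed = seed)
    .fix[[key]] <- render_bscan(ph, slice, test_acq(speckle), seed = seed)
  }
  .fix[[key]]
}

test_segmentation <- function(speckle = Inf, seed = 1L, slice = 0L) {
  key <- paste0("seg_", speckle, "_", seed, "_", slice)
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- segment_bscan(test_scan(speckle, seed, slice))
  }
  .fix[[key]]
}

# wide matrix of truth rows for a rendered scan
truth_wide <- function(scan) {
  m <- matrix(scan$truth$row_px, ncol = 4)
  colnames(m) <- unique(scan$truth$boundary)
  m
}

boundaries_wide <- function(bd) {
  w <- max(bd$column)
  m <- sapply(unique(bd$boundary), function(bn) bd$row_px[bd$boundary == bn])
  matrix(m, nrow = w, dimnames = list(NULL, unique(bd$boundary)))
}

# columns in the measurement region (outside the foveal collapse zone,
# where the protocol samples); boundary accuracy is assessed there
analysis_cols <- function(scan, min_ecc_um = 500) {
  x <- (seq_len(ncol(scan$pixels)) - scan$fovea_column) * scan$lateral_um_per_px
  which(abs(x) > min_ecc_um)
}

# synthesize perfect layer_boundaries from a scan's ground truth, for
# tests of the sampling machinery that should not depend on segmentation
truth_boundaries <- function(scan) {
  out <- scan$truth
  out$provenance <- "traced"
  class(out) <- c("layer_boundaries", class(out))
  attr(out, "fovea_column") <- scan$fovea_column
  attr(out, "failed_boundaries") <- character(0)
  attr(out, "axial_um_per_px") <- scan$axial_um_per_px
  attr(out, "lateral_um_per_px") <- scan$lateral_um_per_px
  attr(out, "slice_index") <- scan$slice_index
  out
}

# render + segment a full eye and sample its grid (used by several suites)
measure_eye <- function(truth_row, acq, seed, cysts = cyst_spec(),
                        use_truth_boundaries = FALSE) {
  es <- render_eye(truth_row, acq, cysts, seed = seed)
  bds <- if (use_truth_boundaries) {
    lapply(es$scans, truth_boundaries)
  } else {
    lapply(es$scans, segment_bscan)
  }
  grid <- sample_grid(bds, radial_protocol(), eye = truth_row$eye,
                      subject = truth_row$subject)
  list(eye = es, boundaries = bds, grid = grid)
}

# textbook formulas used as independent oracles
oracle_t_pooled <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = tt, p = 2 * pt(-abs(tt), n - 2))
}

# exact Fisher 95% interval around a generative rho at sample size n
fisher_ci <- function(rho, n) {
  z <- atanh(rho)
  tanh(z + c(-1, 1) * qnorm(0.975) / sqrt(n - 3))
}
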