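#' Sequential multi-scale median filtering
#'
#' Applies 2-D median filters of increasing window size in sequence
#' (defaults 3, 7, 15 pixels).  Small windows remove speckle outliers,
#' larger ones flatten residual texture while median filtering preserves
#' the step edges between retinal bands.
#'
#' Windows up to `axial_cap` pixels are square 2-D medians; larger
#' windows are applied laterally only (a running median along each row).
#' A square window taller than the thinnest retinal band (the RNFL is
#' often under 10 pixels) mixes intensities across two boundaries and
#' biases edge positions axially, whereas boundaries vary slowly along
#' the lateral direction, so wide lateral windows are safe.
#'
#' @param x A [bscan] or a numeric matrix in `[0,1]`.
#' @param sizes Odd window sizes, each >= 3, applied in order.
#' @param axial_cap Largest window run as a full 2-D median.
#' @return A filtered matrix of the same shape.
#' @export
multiscale_median_filter <- function(x, sizes = c(3, 7, 15),
                                     axial_cap = 3) {
  img <- if (inherits(x, "bscan")) x$pixels else as.matrix(x)
  if (any(!is_odd(sizes)) || any(sizes < 3)) {
    abort("median window sizes must be odd and >= 3")
  }
  img <- clamp01(img)
  for (s in sizes) {
    if (s == 3) {
      img <- .median3x3(img)
    } else if (s <= axial_cap) {
      img <- as.matrix(EBImage::medianFilter(img, (s - 1) / 2))
    } else {
      img <- t(apply(img, 1, stats::runmed, k = s, endrule = "median"))
    }
  }
  img
}

# vectorised 3x3 median via the classic selection decomposition: sort
# each row triple of the window, then the median of the nine is
# median(max of the row-minima, median of the row-medians, min of the
# row-maxima).  Image edges replicate.
.median3x3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  sh <- function(dr, dc) {
    m[pmin(pmax(1:H + dr, 1), H), pmin(pmax(1:W + dc, 1), W), drop = FALSE]
  }
  med3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))
  rmin <- list(); rmed <- list(); rmax <- list()
  for (i in 1:3) {
    dr <- i - 2L
    a <- sh(dr, -1); b <- sh(dr, 0); c <- sh(dr, 1)
    rmin[[i]] <- pmin(a, b, c)
    rmed[[i]] <- med3(a, b, c)
    rmax[[i]] <- pmax(a, b, c)
  }
  med3(pmax(rmin[[1]], rmin[[2]], rmin[[3]]),
       med3(rmed[[1]], rmed[[2]], rmed[[3]]),
       pmin(rmax[[1]], rmax[[2]], rmax[[3]]))
}

#' Canny edge detection with scale-free hysteresis thresholds
#'
#' Standard Canny: Gaussian-smoothed central-difference gradient,
#' non-maximum suppression along the quantised gradient direction, then
#' hysteresis.  The high threshold is `high_frac` times the robust
#' maximum gradient magnitude (its 99.9th percentile) and the low
#' threshold is `low_frac` times the high one.  Anchoring the thresholds
#' to the strongest edge rather than to a bulk quantile keeps the edge
#' map invariant to global intensity rescaling while retaining the
#' weaker inter-layer interfaces, whose gradient is only about a third
#' of the vitreoretinal one.
#'
#' @param img Numeric matrix (typically the median-filtered scan).
#' @param low_frac Low threshold as a fraction of the high threshold.
#' @param high_frac High threshold as a fraction of the robust maximum
#'   gradient magnitude.
#' @param sigma Gaussian smoothing sigma in pixels.
#' @return A logical edge matrix with attributes `gx`, `gy` (smoothed
#'   gradients; `gy` is the derivative along depth, positive when
#'   intensity increases downward), `mag`, `weak` (the thinned candidate
#'   mask above the low threshold), `high_threshold` and
#'   `low_threshold`.
#' @export
canny_boundaries <- function(img, low_frac = 0.5, high_frac = 0.2,
                             sigma = 2) {
  img <- as.matrix(img)
  if (any(!is.finite(img))) abort("image must be finite")
  H <- nrow(img); W <- ncol(img)
  sm <- if (sigma > 0) as.matrix(EBImage::gblur(img, sigma = sigma)) else img

  # central differences; replicate edges
  gy <- (sm[c(2:H, H), ] - sm[c(1, 1:(H - 1)), ]) / 2   # along depth
  gx <- (sm[, c(2:W, W)] - sm[, c(1, 1:(W - 1))]) / 2   # along lateral
  mag <- sqrt(gx^2 + gy^2)
  # unsmoothed axial gradient: used downstream for sub-pixel boundary
  # refinement, where the Gaussian tails of neighbouring interfaces
  # would otherwise bias the peak position
  gy_raw <- (img[c(2:H, H), ] - img[c(1, 1:(H - 1)), ]) / 2

  if (max(mag) <= 0) {
    edges <- matrix(FALSE, H, W)
    attributes(edges) <- c(attributes(edges),
                           list(gx = gx, gy = gy, mag = mag,
                                high_threshold = 0))
    return(edges)
  }

  # non-maximum suppression: quantise direction into 4 sectors and
  # compare with the two neighbours along the gradient
  ang <- atan2(gy, gx)            # [-pi, pi]
  sector <- floor((ang + pi) / (pi / 4) + 0.5) %% 8 %% 4  # centred 45-degree bins
  shift <- function(m, dr, dc) {
    r <- pmin(pmax(1:H + dr, 1), H)
    c <- pmin(pmax(1:W + dc, 1), W)
    m[r, c, drop = FALSE]
  }
  nms <- matrix(FALSE, H, W)
  nbr <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))  # sector 0..3 directions
  for (s in 0:3) {
    d <- nbr[[s + 1]]
    ok <- sector == s & mag >= shift(mag, d[1], d[2]) &
      mag >= shift(mag, -d[1], -d[2])
    nms <- nms | ok
  }
  # with quantised directions a gently sloping ridge can fail its
  # diagonal-sector test and break the line; admit axial maxima of
  # predominantly vertical gradients as well, which keeps the long
  # near-horizontal layer interfaces continuous
  nms <- nms | (abs(gy) >= abs(gx) & mag >= shift(mag, 1, 0) &
                  mag >= shift(mag, -1, 0))
  # suppress border artefacts of the smoothing kernel
  bpx <- max(2L, ceiling(sigma))
  nms[c(seq_len(bpx), (H - bpx + 1):H), ] <- FALSE
  nms[, c(seq_len(bpx), (W - bpx + 1):W)] <- FALSE

  hi <- high_frac * stats::quantile(mag, 0.999, names = FALSE)
  lo <- low_frac * hi
  strong <- nms & mag >= hi
  weak <- nms & mag >= lo

  # hysteresis: keep weak components that touch a strong pixel.  The
  # weaker inter-layer interfaces survive because every boundary line
  # converges onto the strong merged edge at the foveal pit.
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  edges <- matrix(as.vector(lab) %in% keep, H, W)

  attributes(edges) <- c(attributes(edges),
                         list(gx = gx, gy = gy, gy_raw = gy_raw,
                              mag = mag, weak = weak,
                              high_threshold = hi, low_threshold = lo))
  edges
}
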