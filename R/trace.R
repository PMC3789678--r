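#' Segmentation parameters
#'
#' All tunables of the layer segmentation chain, with their defaults:
#' median window sizes, Canny quantile thresholds and smoothing, vessel
#' detection rule, and the dynamic-programming surface tracer (smoothness
#' penalty, maximum per-column jump, and per-layer maximum thickness band
#' caps that keep a boundary from locking onto the next interface of the
#' same contrast polarity).
#'
#' `lambda` is expressed in units of the Canny high threshold (one
#' gradient unit) per pixel of vertical jump between neighbouring
#' columns.
#'
#' @param median_sizes Odd median window sizes applied in sequence.
#' @param canny_low_frac,canny_high_frac,canny_sigma See
#'   [canny_boundaries()].
#' @param vessel_window,vessel_k See [detect_vessel_shadows()].
#' @param lambda Smoothness penalty per pixel of jump, in units of the
#'   Canny high threshold.
#' @param max_jump Maximum vertical step (pixels) between adjacent
#'   columns of a traced boundary.
#' @param max_thickness_um Named vector of band caps for RNFL, GCLIPL,
#'   INL.
#' @param glue Attraction (in Canny high-threshold units) toward the row
#'   of the previously traced boundary.  Inside the foveal pit the inner
#'   layers collapse and a boundary's own edge disappears; the glue term
#'   lets the collapsed boundary ride on the surface above it instead of
#'   bridging the pit, while being too weak to compete with a real edge
#'   on the flanks.
#' @param refine_subpixel Parabolic sub-pixel refinement of each traced
#'   row on the polarity-matched gradient.
#' @return A named list of class `seg_params`.
#' @export
seg_params <- function(median_sizes = c(3, 7, 15),
                       canny_low_frac = 0.5,
                       canny_high_frac = 0.2,
                       canny_sigma = 2,
                       vessel_window = 61,
                       vessel_k = 2.5,
                       lambda = 1,
                       max_jump = 2L,
                       max_thickness_um = c(RNFL = 90, GCLIPL = 160, INL = 90),
                       glue = 1.2,
                       refine_subpixel = TRUE) {
  structure(list(median_sizes = median_sizes,
                 canny_low_frac = canny_low_frac,
                 canny_high_frac = canny_high_frac,
                 canny_sigma = canny_sigma,
                 vessel_window = vessel_window,
                 vessel_k = vessel_k,
                 lambda = lambda,
                 max_jump = as.integer(max_jump),
                 max_thickness_um = max_thickness_um,
                 glue = glue,
                 refine_subpixel = refine_subpixel),
            class = "seg_params")
}

# contrast polarity of each measured interface (sign of d(intensity)/d(depth))
.boundary_polarity <- c(ILM = 1, RNFL_GCLIPL = -1, GCLIPL_INL = -1,
                        INL_OPL = 1)

# minimum-cost vertical path through a cost matrix, one row per column,
# with |row(j) - row(j-1)| <= max_jump and penalty lambda per pixel of
# jump; rmin/rmax give the admissible row band per column.
# Returns integer rows, or NULL if no admissible path exists.
.dp_trace <- function(cost, rmin, rmax, lambda, max_jump) {
  H <- nrow(cost); W <- ncol(cost)
  BIG <- 1e18
  adm <- matrix(FALSE, H, W)
  for (j in 1:W) {
    lo <- max(1L, rmin[j]); hi <- min(H, rmax[j])
    if (lo <= hi) adm[lo:hi, j] <- TRUE
  }
  if (!any(adm[, 1])) return(NULL)
  D <- cost[, 1]
  D[!adm[, 1]] <- BIG
  ptr <- matrix(0L, H, W)
  shifts <- -max_jump:max_jump
  for (j in 2:W) {
    best <- rep(BIG, H)
    bests <- rep(0L, H)
    for (s in shifts) {
      # candidate predecessor row r - s feeding row r
      val <- rep(BIG, H)
      if (s >= 0) {
        src <- 1:(H - s)
        val[src + s] <- D[src] + lambda * abs(s)
      } else {
        src <- (1 - s):H
        val[src + s] <- D[src] + lambda * abs(s)
      }
      upd <- val < best
      best[upd] <- val[upd]
      bests[upd] <- s
    }
    D <- cost[, j] + best
    D[!adm[, j]] <- BIG
    ptr[, j] <- bests
    if (all(D >= BIG)) return(NULL)
  }
  path <- integer(W)
  path[W] <- which.min(D)
  if (D[path[W]] >= BIG) return(NULL)
  for (j in W:2) path[j - 1] <- path[j] - ptr[path[j], j]
  path
}

# sub-pixel refinement of an integer path on the signed raw gradient
# g = polarity * gy_raw: vertex of a weighted least-squares parabola
# over 7 rows (weights tapering at the ends so that the Gaussian tail
# of a neighbouring interface two bands away contributes little).  The
# fit is recentred on the best of the three rows around the DP row
# first; corrections are clamped (vertex to +-1 px of the recentred
# row, total to +-1.5 px of the DP row).
.refine_subpixel <- function(path, g) {
  H <- nrow(g)
  out <- as.numeric(path)
  K <- 3L
  t <- -K:K
  w <- c(0.25, 0.75, 1, 1, 1, 0.75, 0.25)
  W1 <- sum(w); Swt2 <- sum(w * t^2); Swt4 <- sum(w * t^4)
  for (j in seq_along(path)) {
    r <- path[j]
    if (r <= K + 1 || r >= H - K) next
    r <- r - 2L + which.max(c(g[r - 1, j], g[r, j], g[r + 1, j]))
    y <- g[(r - K):(r + K), j]
    b <- sum(w * t * y) / Swt2
    cc <- (sum(w * t^2 * y) - Swt2 / W1 * sum(w * y)) /
      (Swt4 - Swt2^2 / W1)
    if (abs(cc) > 1e-12) {
      d <- -b / (2 * cc)
      rr <- r + max(min(d, 1), -1)
      out[j] <- max(min(rr, path[j] + 1.5), path[j] - 1.5)
    }
  }
  out
}

#' Trace ordered layer boundaries through the edge/gradient field
#'
#' Converts the Canny edge map and smoothed gradient into the four
#' measured boundaries (ILM, RNFL/GCL-IPL, GCL-IPL/INL, INL/OPL),
#' extracted top-down in anatomical order.  Each boundary is the
#' minimum-cost lateral path through a cost field
#' `-polarity * d(intensity)/d(depth) - bonus * edge`, restricted to a
#' band below the previously traced boundary (ordering and non-crossing
#' hold by construction) and no deeper than the layer's maximum
#' plausible thickness.  A smoothness penalty `lambda` (in Canny
#' high-threshold units) is paid per pixel of vertical jump per column.
#'
#' If no admissible path exists for a boundary, that boundary and all
#' deeper ones are flagged failed and returned as `NA`, never fabricated.
#'
#' @param edges Edge map from [canny_boundaries()] (with gradient
#'   attributes).
#' @param scan The [bscan] the edges came from (for calibration and
#'   vessel provenance).
#' @param params A [seg_params()].
#' @param vessel_columns Columns whose traced values derive from
#'   interpolated image data; marked in the provenance field.
#' @return A tibble of class `layer_boundaries`:
#'   `(column, boundary, row_px, provenance)` where provenance is
#'   `"traced"`, `"interpolated"` (under a removed vessel) or `"failed"`.
#'   Attributes: `fovea_column`, `failed_boundaries`.
#' @export
trace_layer_boundaries <- function(edges, scan, params = seg_params(),
                                   vessel_columns = integer(0)) {
  stopifnot(inherits(scan, "bscan"))
  gy <- attr(edges, "gy")
  hi <- attr(edges, "high_threshold")
  if (is.null(gy)) abort("edge map must carry gradient attributes from canny_boundaries()")
  H <- nrow(edges); W <- ncol(edges)
  ax <- scan$axial_um_per_px
  hi <- max(hi, 1e-9)
  lo <- attr(edges, "low_threshold") %||% (0.5 * hi)
  lambda <- params$lambda * hi
  max_jump <- params$max_jump

  caps_px <- c(NA, params$max_thickness_um[c("RNFL", "GCLIPL", "INL")] / ax)
  prev <- rep(0, W)        # virtual boundary above the image
  rows <- list()
  failed <- character(0)
  for (b in seq_along(.measured_boundaries)) {
    bn <- .measured_boundaries[b]
    pol <- .boundary_polarity[[bn]]
    g <- pol * gy
    # attraction concentrated on polarity-matched axial ridge maxima
    # above the Canny low threshold: thin 1-px lines, so the blurred
    # tail of an adjacent interface exerts almost no pull; a weak
    # ungated term bridges ridge gaps
    up <- rbind(g[1, ], g[-H, ])
    dn <- rbind(g[-1, ], g[H, ])
    gate <- (g >= up) & (g >= dn) & (g >= lo)
    cost <- -g * (0.1 + 0.9 * gate)
    rmin <- pmax(1L, as.integer(ceiling(prev)))
    rmax <- if (is.na(caps_px[b])) rep(H, W) else
      pmin(H, as.integer(floor(prev + caps_px[b])))
    if (b > 1) {
      # the previous boundary's own ridge has the same polarity for the
      # RNFL/GCL-IPL and GCL-IPL/INL pair: suppress all attraction
      # within 1 px of it and offer only the glue term there, so a
      # boundary rides on its predecessor exactly where its own edge
      # has vanished (the pit) and nowhere else
      pr <- round(prev)
      for (dd in -1:1) {
        rr <- pmin(pmax(pr + dd, 1L), H)
        cost[cbind(rr, 1:W)] <- 0
      }
      gr <- pmin(pmax(pr, rmin), H)   # first admissible row at/below prev
      cost[cbind(gr, 1:W)] <- -params$glue * hi
    }
    path <- .dp_trace(cost, rmin, rmax, lambda, max_jump)
    if (is.null(path)) {
      failed <- .measured_boundaries[b:length(.measured_boundaries)]
      for (bn2 in failed) rows[[bn2]] <- rep(NA_real_, W)
      break
    }
    rp <- if (params$refine_subpixel) {
      .refine_subpixel(path, pol * (attr(edges, "gy_raw") %||% gy))
    } else {
      as.numeric(path)
    }
    rp <- pmax(rp, prev)          # non-crossing after refinement
    rows[[bn]] <- rp
    prev <- rp
  }

  # foveal pit = deepest point of the traced inner surface; fall back to
  # the image-based detector when the ILM failed
  fovea <- if (!is.null(rows[["ILM"]]) && !anyNA(rows[["ILM"]])) {
    ilm_s <- stats::runmed(rows[["ILM"]], min(31, 2 * (W %/% 2) - 1))
    central <- seq(max(1, round(W * 0.25)), min(W, round(W * 0.75)))
    central[which.max(ilm_s[central])]
  } else {
    detect_fovea_column(scan)
  }

  prov <- rep("traced", W)
  prov[vessel_columns] <- "interpolated"
  out <- dplyr::bind_rows(lapply(.measured_boundaries, function(bn) {
    tibble(column = 1:W, boundary = bn, row_px = rows[[bn]],
           provenance = ifelse(is.na(rows[[bn]]), "failed", prov))
  }))
  class(out) <- c("layer_boundaries", class(out))
  attr(out, "fovea_column") <- fovea
  attr(out, "failed_boundaries") <- failed
  attr(out, "axial_um_per_px") <- ax
  attr(out, "lateral_um_per_px") <- scan$lateral_um_per_px
  attr(out, "slice_index") <- scan$slice_index
  out
}

#' Segment one B-scan end-to-end
#'
#' The full per-scan chain: vessel-shadow detection and removal,
#' multi-scale median filtering, Canny edge detection, and ordered
#' boundary tracing.
#'
#' @param scan A [bscan].
#' @param params A [seg_params()].
#' @return A `layer_boundaries` tibble (see [trace_layer_boundaries()]),
#'   with the detected vessel columns in attribute `vessel_columns`.
#' @export
segment_bscan <- function(scan, params = seg_params()) {
  vcols <- detect_vessel_shadows(scan, window = params$vessel_window,
                                 k = params$vessel_k)
  clean <- remove_vessels(scan, vcols)
  filt <- multiscale_median_filter(clean, params$median_sizes)
  edges <- canny_boundaries(filt, low_frac = params$canny_low_frac,
                            high_frac = params$canny_high_frac,
                            sigma = params$canny_sigma)
  out <- trace_layer_boundaries(edges, clean, params,
                                vessel_columns = vcols)
  attr(out, "vessel_columns") <- vcols
  out
}

# wide matrix (W x 4) of boundary rows from a layer_boundaries tibble
.boundaries_wide <- function(bd) {
  W <- max(bd$column)
  out <- sapply(.measured_boundaries, function(bn) {
    bd$row_px[bd$boundary == bn]
  })
  matrix(out, nrow = W, dimnames = list(NULL, .measured_boundaries))
}
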