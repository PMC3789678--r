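#' Write a B-scan as 16-bit grayscale TIFF
#'
#' @param scan A [bscan].
#' @param path Output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_bscan <- function(scan, path) {
  stopifnot(inherits(scan, "bscan"))
  tiff::writeTIFF(clamp01(scan$pixels), path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a grayscale B-scan image
#'
#' Reads a TIFF or PNG written by [write_bscan()] (or any grayscale
#' image with intensities in `[0,1]`) and wraps it as a [bscan].
#'
#' @param path Image path (`.tif`/`.tiff`/`.png`).
#' @inheritParams bscan
#' @return A [bscan].
#' @export
read_bscan <- function(path, axial_um_per_px = 3.9,
                       lateral_um_per_px = NULL, slice_index = 0L) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = {
      if (!requireNamespace("png", quietly = TRUE)) {
        abort("the png package is needed to read PNG scans")
      }
      png::readPNG(path)
    },
    abort(sprintf("unsupported image format: '%s'", ext)))
  if (length(dim(px)) == 3) px <- px[, , 1]
  if (anyNA(px) || any(!is.finite(px))) {
    abort(sprintf("corrupt image: %s", path))
  }
  bscan(px, axial_um_per_px = axial_um_per_px,
        lateral_um_per_px = lateral_um_per_px %||% (4500 / ncol(px)),
        slice_index = slice_index)
}

#' Write traced boundaries to CSV
#'
#' Long format `(slice, column_px, boundary, row_px, provenance)`.
#'
#' @param boundary_sets A `layer_boundaries` object or list of them.
#' @param path Output CSV path.
#' @param meta Optional named list written as `# key: value` header
#'   comment lines (e.g. config hash and seed).
#' @return `path`, invisibly.
#' @export
write_boundaries_csv <- function(boundary_sets, path, meta = NULL) {
  if (inherits(boundary_sets, "layer_boundaries")) {
    boundary_sets <- list(boundary_sets)
  }
  tab <- dplyr::bind_rows(lapply(boundary_sets, function(bd) {
    tibble(slice = attr(bd, "slice_index"), column_px = bd$column,
           boundary = bd$boundary, row_px = bd$row_px,
           provenance = bd$provenance)
  }))
  .write_csv_with_header(tab, path, meta)
}

#' Write a long measurement table to CSV
#'
#' @param tab A tibble (grids, summaries, cysts ...).
#' @param path Output CSV path.
#' @param meta Optional named list for `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(tab, path, meta = NULL) {
  .write_csv_with_header(as_tibble(tab), path, meta)
}

.write_csv_with_header <- function(tab, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(meta)) {
    for (k in names(meta)) {
      writeLines(sprintf("# %s: %s", k, format(meta[[k]])), con)
    }
  }
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Read a measurement CSV written by this package
#'
#' Skips `#` header comment lines and validates that the requested
#' columns are present.
#'
#' @param path CSV path.
#' @param required Character vector of required column names.
#' @return A tibble; header metadata in attribute `meta`.
#' @export
read_table_csv <- function(path, required = character(0)) {
  lines <- readLines(path, n = 50)
  n_meta <- sum(cumprod(startsWith(lines, "#")))
  meta <- list()
  if (n_meta > 0) {
    kv <- sub("^# *", "", lines[seq_len(n_meta)])
    keys <- sub(":.*$", "", kv)
    vals <- trimws(sub("^[^:]*:", "", kv))
    meta <- as.list(setNames(vals, keys))
  }
  tab <- as_tibble(utils::read.csv(path, skip = n_meta,
                                   stringsAsFactors = FALSE))
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(sprintf("%s lacks required column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  attr(tab, "meta") <- meta
  tab
}
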