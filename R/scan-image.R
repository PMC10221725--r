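# ScanImage: a 2D detected-intensity grid over (y, z) focal positions.
# data is an n_y x n_z matrix, rows indexed by axis_y, columns by axis_z.

#' Construct a scan image
#'
#' Container for a 2D confocal scan: a non-negative intensity matrix with
#' micrometre axis vectors and a metadata list sufficient to reproduce the
#' scan (optics, phantom, photon count, seed, mode).
#'
#' @param data Numeric matrix, `length(axis_y)` rows by `length(axis_z)`
#'   columns, finite and non-negative.
#' @param axis_y,axis_z Strictly monotone coordinate vectors in um.
#' @param meta Named list of provenance metadata.
#' @return An object of class `scan_image`.
#' @export
scan_image <- function(data, axis_y, axis_z, meta = list()) {
  data <- as.matrix(data)
  if (nrow(data) != length(axis_y) || ncol(data) != length(axis_z))
    stop("data must be length(axis_y) x length(axis_z)")
  if (!all(is.finite(data)) || any(data < 0))
    stop("scan image data must be finite and non-negative")
  mono <- function(a) length(a) == 1L || all(diff(a) > 0) || all(diff(a) < 0)
  if (!mono(axis_y) || !mono(axis_z))
    stop("axes must be strictly monotone")
  structure(list(data = data, axis_y = as.numeric(axis_y),
                 axis_z = as.numeric(axis_z), meta = meta),
            class = "scan_image")
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("Confocal scan image: %d x %d pixels\n",
              nrow(x$data), ncol(x$data)))
  cat(sprintf("  y in [%.6g, %.6g] um, z in [%.6g, %.6g] um\n",
              min(x$axis_y), max(x$axis_y), min(x$axis_z), max(x$axis_z)))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.scan_image <- function(x, ...) x$data

#' @export
plot.scan_image <- function(x, log = FALSE, floor = 1e-4, ...) {
  d <- x$data
  if (log) d <- log10(pmax(d / max(d), floor))
  graphics::image(x$axis_y, x$axis_z, d, xlab = "y (um)", ylab = "z (um)",
                  useRaster = TRUE, ...)
  invisible(x)
}

replace_data <- function(image, data, extra_meta = NULL) {
  m <- image$meta
  if (!is.null(extra_meta)) m[names(extra_meta)] <- extra_meta
  scan_image(data, image$axis_y, image$axis_z, m)
}
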