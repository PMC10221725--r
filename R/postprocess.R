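# Post-processing of scan images, mirroring the evaluation pipeline used for
# both measured and simulated scans: per-line background subtraction, moving
# average, normalisation, cubic upscaling and logarithmic display.  The
# quantitative pipeline order is subtract -> smooth -> normalise -> view.

#' Normalise a scan image
#'
#' `reference = "max"` scales so the global maximum equals 1.
#' `reference = "region"` scales by the maximum inside the rectangle
#' `region = c(y_min, y_max, z_min, z_max)` (used to normalise to the signal
#' of a particular surface when brighter artefacts are present elsewhere).
#'
#' @param image A [scan_image()].
#' @param reference `"max"` or `"region"`.
#' @param region Length-4 numeric rectangle for `"region"` mode.
#' @return The normalised `scan_image`.
#' @export
normalise <- function(image, reference = c("max", "region"), region = NULL) {
  stopifnot(inherits(image, "scan_image"))
  reference <- match.arg(reference)
  ref <- if (reference == "max") {
    max(image$data)
  } else {
    if (is.null(region) || length(region) != 4)
      stop("region mode needs region = c(y_min, y_max, z_min, z_max)")
    iy <- image$axis_y >= region[1] & image$axis_y <= region[2]
    iz <- image$axis_z >= region[3] & image$axis_z <= region[4]
    if (!any(iy) || !any(iz)) stop("region contains no pixels")
    max(image$data[iy, iz])
  }
  if (ref <= 0) stop("cannot normalise: reference maximum is zero")
  replace_data(image, image$data / ref)
}

#' Moving-average filter along scan lines
#'
#' 1D box filter of odd `width` applied along the chosen axis for every
#' line; edges are handled by shrinking the window.  (Exact mean
#' preservation holds for signals vanishing near the edges; boundary pixels
#' are re-weighted by the shrunken windows.)
#'
#' @param image A [scan_image()].
#' @param width Odd window width in pixels (5 in the reference evaluation).
#' @param axis `"y"` (filter along y for each z line, default) or `"z"`.
#' @return Filtered `scan_image`.
#' @export
moving_average <- function(image, width = 5, axis = c("y", "z")) {
  stopifnot(inherits(image, "scan_image"))
  axis <- match.arg(axis)
  if (width %% 2 == 0) stop("width must be odd")
  if (width == 1) return(image)
  d <- image$data
  if (axis == "y") {
    for (j in seq_len(ncol(d))) d[, j] <- box_filter_vec(image$data[, j], width)
  } else {
    for (i in seq_len(nrow(d))) d[i, ] <- box_filter_vec(image$data[i, ], width)
  }
  replace_data(image, d)
}

#' Cubic upscaling of a scan image
#'
#' Refines both axes by an integer `factor` (output dimension
#' `(n - 1) * factor + 1` per axis) and interpolates the data with separable
#' natural cubic splines; interpolated values are clipped at zero.
#'
#' @param image A [scan_image()].
#' @param factor Integer upscaling factor (>= 1; 2 in the reference
#'   evaluation).
#' @return Upscaled `scan_image`.
#' @export
upscale_cubic <- function(image, factor = 2) {
  stopifnot(inherits(image, "scan_image"))
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be a positive integer")
  if (factor == 1) return(image)
  refine <- function(a) {
    n <- (length(a) - 1L) * factor + 1L
    seq(a[1], a[length(a)], length.out = n)
  }
  ay <- refine(image$axis_y); az <- refine(image$axis_z)
  d1 <- matrix(0, length(ay), ncol(image$data))
  for (j in seq_len(ncol(image$data)))
    d1[, j] <- stats::spline(image$axis_y, image$data[, j], xout = ay,
                             method = "natural")$y
  d2 <- matrix(0, length(ay), length(az))
  for (i in seq_len(nrow(d1)))
    d2[i, ] <- stats::spline(image$axis_z, d1[i, ], xout = az,
                             method = "natural")$y
  d2[d2 < 0] <- 0
  scan_image(d2, ay, az, c(image$meta, list(upscaled = factor)))
}

#' Subtract a per-line background estimate
#'
#' Removes a background level estimated independently on every scan line
#' (along the chosen axis) and clips at zero.  The default estimator is the
#' line's 5th percentile, which is robust against sparse bright reflexes; a
#' `"min"` estimator is also available.
#'
#' @param image A [scan_image()].
#' @param estimator `"percentile"` (default) or `"min"`.
#' @param p Percentile level for the `"percentile"` estimator.
#' @param axis Lines run along this axis (default `"y"`: one background value
#'   per z level).
#' @return Background-subtracted `scan_image`.
#' @export
subtract_background_lines <- function(image,
                                      estimator = c("percentile", "min"),
                                      p = 0.05, axis = c("y", "z")) {
  stopifnot(inherits(image, "scan_image"))
  estimator <- match.arg(estimator)
  axis <- match.arg(axis)
  est <- function(v) if (estimator == "min") min(v) else
    stats::quantile(v, p, names = FALSE, type = 7)
  d <- image$data
  if (axis == "y") {
    for (j in seq_len(ncol(d))) d[, j] <- pmax(d[, j] - est(d[, j]), 0)
  } else {
    for (i in seq_len(nrow(d))) d[i, ] <- pmax(d[i, ] - est(d[i, ]), 0)
  }
  replace_data(image, d)
}

#' Logarithmic display transform
#'
#' Returns `log10(pmax(gain * data, floor))` as a plain matrix with axis
#' attributes.  `gain` reproduces the empirically determined constant
#' factors used to compensate unmodelled experimental losses in display
#' comparisons; it is a display option only.
#'
#' @param image A [scan_image()] (normally already normalised).
#' @param floor Relative intensity floor (> 0).
#' @param gain Per-pixel gain applied before flooring (default 1).
#' @return Matrix of log10 values with attributes `axis_y`, `axis_z`.
#' @export
log_view <- function(image, floor = 1e-4, gain = 1) {
  stopifnot(inherits(image, "scan_image"))
  if (floor <= 0) stop("floor must be positive")
  out <- log10(pmax(gain * image$data, floor))
  attr(out, "axis_y") <- image$axis_y
  attr(out, "axis_z") <- image$axis_z
  out
}
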