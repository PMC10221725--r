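# Multi-cylinder phantom geometries: random generation, tilt transform and
# JSON serialisation.  All cylinders are parallel to the x axis; the slab
# cross-section in the y-z plane is centred at the origin.

PHANTOM_SCHEMA_VERSION <- 1L

#' Single cylinder description
#'
#' @param center_y,center_z Axis position in um (slab-centred coordinates).
#' @param radius Radius in um (> 0).
#' @param n_cyl Refractive index (> 0).
#' @return A named list of class `cylinder`.
#' @export
cylinder <- function(center_y, center_z, radius, n_cyl) {
  if (!is.numeric(radius) || radius <= 0) stop("cylinder radius must be > 0")
  if (!is.numeric(n_cyl) || n_cyl <= 0) stop("cylinder index must be > 0")
  structure(list(center_y = center_y, center_z = center_z,
                 radius = radius, n_cyl = n_cyl), class = "cylinder")
}

cylinder_table <- function(phantom) {
  if (length(phantom$cylinders) == 0)
    return(matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("cy", "cz", "r", "n"))))
  do.call(rbind, lapply(phantom$cylinders, function(cc)
    c(cy = cc$center_y, cz = cc$center_z, r = cc$radius, n = cc$n_cyl)))
}

check_overlaps <- function(tab, margin = 0) {
  n <- nrow(tab)
  if (n < 2) return(invisible(NULL))
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d <- sqrt((tab[j, "cy"] - tab[i, "cy"])^2 + (tab[j, "cz"] - tab[i, "cz"])^2)
    bad <- which(d < tab[i, "r"] + tab[j, "r"] + margin - 1e-9)
    if (length(bad))
      stop(sprintf("cylinders %d and %d overlap (centre distance %.4g < %.4g)",
                   i, j[bad[1]], d[bad[1]], tab[i, "r"] + tab[j[bad[1]], "r"]))
  }
  invisible(NULL)
}

#' Multi-cylinder phantom
#'
#' Validating constructor for a parallel-cylinder scene: cylinders must not
#' overlap and must lie fully inside the slab cross-section.
#'
#' @param cylinders List of [cylinder()] objects.
#' @param slab_y,slab_z Slab cross-section extents in um (default 200 x 200).
#' @param length_x Printed cylinder length in um (informational).
#' @param n_surround Refractive index of the surrounding medium.
#' @param seed Integer seed recorded for provenance (NA if hand-built).
#' @param fill Achieved fill fraction (computed if missing).
#' @return An object of class `phantom`.
#' @export
phantom <- function(cylinders, slab_y = 200, slab_z = 200, length_x = 200,
                    n_surround = 1.0, seed = NA_integer_, fill = NULL) {
  if (!is.numeric(n_surround) || n_surround <= 0)
    stop("n_surround must be positive")
  p <- structure(list(cylinders = cylinders, slab_y = slab_y, slab_z = slab_z,
                      length_x = length_x, n_surround = n_surround,
                      seed = seed), class = "phantom")
  tab <- cylinder_table(p)
  if (nrow(tab)) {
    inside <- abs(tab[, "cy"]) + tab[, "r"] <= slab_y / 2 + 1e-9 &
      abs(tab[, "cz"]) + tab[, "r"] <= slab_z / 2 + 1e-9
    if (!all(inside))
      stop(sprintf("cylinder %d does not fit inside the slab cross-section",
                   which(!inside)[1]))
    check_overlaps(tab)
  }
  p$fill <- if (is.null(fill)) {
    if (nrow(tab)) sum(pi * tab[, "r"]^2) / (slab_y * slab_z) else 0
  } else fill
  p
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Cylinder phantom: %d cylinders in a %g x %g um slab\n",
              length(x$cylinders), x$slab_y, x$slab_z))
  cat(sprintf("  fill fraction %.3f, n_surround %.4g, seed %s\n",
              x$fill, x$n_surround, format(x$seed)))
  invisible(x)
}

#' @export
plot.phantom <- function(x, ...) {
  graphics::plot(NA, xlim = c(-x$slab_y, x$slab_y) / 2,
                 ylim = c(-x$slab_z, x$slab_z) / 2,
                 asp = 1, xlab = "y (um)", ylab = "z (um)", ...)
  graphics::rect(-x$slab_y / 2, -x$slab_z / 2, x$slab_y / 2, x$slab_z / 2,
                 border = "grey")
  th <- seq(0, 2 * pi, length.out = 90)
  for (cc in x$cylinders)
    graphics::polygon(cc$center_y + cc$radius * cos(th),
                      cc$center_z + cc$radius * sin(th), border = "steelblue")
  invisible(x)
}

#' Generate a random non-overlapping cylinder phantom
#'
#' Rejection-samples cylinder centres uniformly over the admissible region of
#' the slab cross-section (the slab shrunk by one radius) until adding one
#' more cylinder would exceed `target_fill` of the cross-section area, or
#' until `max_rejects` consecutive rejections occur.  In the latter case the
#' partially filled phantom is returned with a warning.  Alternatively an
#' exact cylinder count can be requested with `n_cylinders`.
#'
#' @param radius Common cylinder radius in um (must fit in the slab).
#' @param target_fill Target area fill fraction in `[0, 0.5)` (about 0.10 for
#'   the reference phantoms).  Ignored when `n_cylinders` is given.
#' @param slab_y,slab_z Slab extents in um.
#' @param n_cyl Refractive index assigned to every cylinder.
#' @param n_surround Surrounding refractive index.
#' @param min_margin Minimum surface-to-surface separation in um (default 0).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param n_cylinders Optional exact number of cylinders to place.
#' @param max_rejects Consecutive-rejection cap (default 1e4).
#' @return A [phantom()] whose `fill` field records the achieved fraction.
#' @examples
#' p <- generate_phantom(10, 0.10, seed = 1, n_cyl = 1.6285)
#' p$fill
#' @export
generate_phantom <- function(radius, target_fill = 0.10,
                             slab_y = 200, slab_z = 200,
                             n_cyl = 1.6285, n_surround = 1.0,
                             min_margin = 0, seed = 1L,
                             n_cylinders = NULL, max_rejects = 1e4) {
  if (radius >= min(slab_y, slab_z) / 2)
    stop("radius must be smaller than half the slab extent")
  if (is.null(n_cylinders) && (target_fill < 0 || target_fill >= 0.5))
    stop("target_fill must be in [0, 0.5)")
  area <- slab_y * slab_z
  cyl_area <- pi * radius^2
  n_target <- if (!is.null(n_cylinders)) as.integer(n_cylinders) else
    floor(target_fill * area / cyl_area)   # adding one more would exceed target

  rng <- splitmix_stream(seed)
  centres <- matrix(numeric(0), 0, 2)
  rejects <- 0L
  capped <- FALSE
  while (nrow(centres) < n_target) {
    u <- rng(2)
    cy <- (u[1] - 0.5) * (slab_y - 2 * radius)
    cz <- (u[2] - 0.5) * (slab_z - 2 * radius)
    ok <- TRUE
    if (nrow(centres)) {
      d2 <- (centres[, 1] - cy)^2 + (centres[, 2] - cz)^2
      ok <- all(d2 >= (2 * radius + min_margin)^2)
    }
    if (ok) {
      centres <- rbind(centres, c(cy, cz))
      rejects <- 0L
    } else {
      rejects <- rejects + 1L
      if (rejects >= max_rejects) { capped <- TRUE; break }
    }
  }
  if (capped)
    warning(sprintf(
      "placement retry cap hit after %d cylinders (target %d); returning partial fill",
      nrow(centres), n_target))
  cyls <- lapply(seq_len(nrow(centres)), function(i)
    cylinder(centres[i, 1], centres[i, 2], radius, n_cyl))
  phantom(cyls, slab_y = slab_y, slab_z = slab_z,
          n_surround = n_surround, seed = as.integer(seed))
}

# Deterministic uniform stream independent of R's global RNG, shared with the
# C++ engine's generator family (counter-based splitmix64).
splitmix_stream <- function(seed) {
  offset <- 0
  function(n) {
    out <- cpp_uniforms(as.numeric(seed), offset, as.integer(n))
    offset <<- offset + n
    out
  }
}

#' Tilt a phantom in the y-z plane
#'
#' Rotates all cylinder centres by `angle` about the slab centre; radii are
#' unchanged.  Used to emulate a tilted sample mount.
#'
#' @param phantom A [phantom()].
#' @param angle Rotation angle in radians, `|angle| < pi/4`.
#' @return A new `phantom` (slab-inclusion constraints are re-checked only
#'   loosely: rotated cylinders may protrude; they are clipped by the scene
#'   bounds during simulation).
#' @export
tilt_phantom <- function(phantom, angle) {
  stopifnot(inherits(phantom, "phantom"))
  if (abs(angle) >= pi / 4) stop("|angle| must be < pi/4")
  ca <- cos(angle); sa <- sin(angle)
  cyls <- lapply(phantom$cylinders, function(cc) {
    cylinder(ca * cc$center_y - sa * cc$center_z,
             sa * cc$center_y + ca * cc$center_z,
             cc$radius, cc$n_cyl)
  })
  out <- phantom
  out$cylinders <- cyls
  out
}

#' Write a phantom to JSON / read it back
#'
#' The schema is `{version, seed, slab:{y,z,x}, n_surround, fill,
#' cylinders:[{cy,cz,r,n}]}` with all lengths in um.  The round trip is
#' lossless (full double precision).  On read, the phantom is re-validated:
#' overlapping cylinders or missing fields raise an error naming the problem.
#'
#' @param phantom A [phantom()].
#' @param path File path.
#' @return `write_phantom` returns `path` invisibly; `read_phantom` returns a
#'   `phantom`.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom"))
  tab <- cylinder_table(phantom)
  obj <- list(
    version = PHANTOM_SCHEMA_VERSION,
    seed = phantom$seed,
    slab = list(y = phantom$slab_y, z = phantom$slab_z, x = phantom$length_x),
    n_surround = phantom$n_surround,
    fill = phantom$fill,
    cylinders = lapply(seq_len(nrow(tab)), function(i)
      list(cy = tab[i, "cy"], cz = tab[i, "cz"],
           r = tab[i, "r"], n = tab[i, "n"]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed phantom JSON: ",
                                           conditionMessage(e)))
  required <- c("version", "slab", "n_surround", "cylinders")
  missing <- setdiff(required, names(obj))
  if (length(missing))
    stop("phantom JSON is missing required field(s): ",
         paste(missing, collapse = ", "))
  cyls <- lapply(obj$cylinders, function(cc) {
    fields <- setdiff(c("cy", "cz", "r", "n"), names(cc))
    if (length(fields))
      stop("cylinder entry missing field(s): ", paste(fields, collapse = ", "))
    cylinder(cc$cy, cc$cz, cc$r, cc$n)
  })
  phantom(cyls,
          slab_y = obj$slab$y, slab_z = obj$slab$z, length_x = obj$slab$x,
          n_surround = obj$n_surround,
          seed = if (is.null(obj$seed)) NA_integer_ else obj$seed,
          fill = obj$fill)
}
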