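# Two-dimensional confocal imaging integral driven by the cylinder
# scattering solution.  The detected amplitude at focus (y, z) is a double
# Riemann sum over incident and collected transverse wavenumbers ky, ky'
# inside the NA-limited band, with the scattering amplitude evaluated at the
# angle between the incident direction (ky, -kz) and the collected direction
# (ky', +kz').

#' Confocal image amplitude of a single cylinder (Maxwell model)
#'
#' Evaluates the two-dimensional confocal imaging integral
#' \deqn{U(y,z) = \sum_{k_y}\sum_{k_y'} S(k_y, k_y')
#'   \exp\{i[\,y(k_y'-k_y) + z\,\phi_z(k_z,k_z')\,]\}\,\Delta k^2}
#' by a midpoint Riemann sum over \eqn{k_y, k_y' \in [-k_{y,max}, k_{y,max}]}
#' with \eqn{k_{y,max} = k\,\mathrm{NA}} and constant pupil functions inside
#' the band, for both polarisations.  `S` is the cylinder amplitude at the
#' scattering angle between the incident direction \eqn{(k_y, -k_z)} and the
#' collected direction \eqn{(k_y', +k_z')},
#' \eqn{\cos\theta = (k_y k_y' - k_z k_z')/k^2}, so that
#' \eqn{k_y = k_y' = 0} is exact backscatter.
#'
#' The axial phase \eqn{\phi_z} carries a sign convention (see
#' `axial_convention`): the default `"roundtrip"` uses
#' \eqn{\phi_z = k_z' + k_z} (illumination and collection phases add, as for a
#' reflectance round trip) with the sign fixed so that the bright reflex of a
#' cylinder of radius R, centred at the origin and illuminated from
#' \eqn{z = +\infty}, appears at focus \eqn{z = +R}.  `"literal"` uses
#' \eqn{\phi_z = k_z' - k_z} with both roots positive, which cancels on the
#' diagonal and produces no axial sectioning; it is retained for comparison
#' only.
#'
#' @param solution A [solve_cylinder()] result for the cylinder to image.
#' @param na Numerical aperture (must not exceed `solution$n_surround`).
#' @param grid_y,grid_z Focus coordinate vectors in um, relative to the
#'   cylinder axis.
#' @param n_k Number of quadrature nodes per wavenumber axis (>= 16).
#' @param axial_convention `"roundtrip"` (default) or `"literal"`.
#' @return An object of class `confocal_field`: list with `grid_y`, `grid_z`,
#'   complex matrices `U_parallel` and `U_perp` (rows = y, cols = z),
#'   `intensity`, `wavenumber` (rad/um), `ky_max`, `n_k`.
#' @export
confocal_amplitude <- function(solution, na, grid_y, grid_z, n_k = 256,
                               axial_convention = c("roundtrip", "literal")) {
  stopifnot(inherits(solution, "cylinder_scattering"))
  axial_convention <- match.arg(axial_convention)
  ns <- solution$n_surround
  if (!is.numeric(na) || na <= 0 || na > ns)
    stop("need 0 < na <= n_surround")
  if (n_k < 16) stop("n_k must be at least 16")
  if (!all(is.finite(grid_y)) || !all(is.finite(grid_z)))
    stop("grid must be finite")
  lam_um <- solution$wavelength / 1000
  k <- 2 * pi * ns / lam_um
  ky_max <- k * na
  dk <- 2 * ky_max / n_k
  ky <- -ky_max + (seq_len(n_k) - 0.5) * dk      # midpoint nodes
  kz <- sqrt(pmax(k^2 - ky^2, 0))

  cth <- (outer(ky, ky) - outer(kz, kz)) / k^2    # [incident, collected]
  cth[cth > 1] <- 1; cth[cth < -1] <- -1
  theta <- acos(cth)

  Sp <- matrix(scattering_amplitude(solution, as.vector(theta), "parallel"),
               n_k, n_k)
  Ss <- matrix(scattering_amplitude(solution, as.vector(theta), "perp"),
               n_k, n_k)

  # Pixel phase factors.  U(p) = sum_j sum_j' S[j, j'] E_out[j', p] E_in[j, p]
  pts <- expand.grid(y = grid_y, z = grid_z)
  phase_out <- outer(ky, pts$y) + outer(kz, pts$z)
  E_out <- exp(1i * phase_out)
  if (axial_convention == "roundtrip") {
    E_in <- exp(1i * (-outer(ky, pts$y) + outer(kz, pts$z)))
  } else {
    E_in <- exp(1i * (-outer(ky, pts$y) - outer(kz, pts$z)))
  }
  Up <- colSums(E_in * (t(Sp) %*% E_out)) * dk^2
  Us <- colSums(E_in * (t(Ss) %*% E_out)) * dk^2
  Up <- matrix(Up, length(grid_y), length(grid_z))
  Us <- matrix(Us, length(grid_y), length(grid_z))

  structure(list(
    grid_y = grid_y, grid_z = grid_z,
    U_parallel = Up, U_perp = Us,
    intensity = unpolarised_intensity(Up, Us),
    wavenumber = k, ky_max = ky_max, n_k = n_k,
    axial_convention = axial_convention
  ), class = "confocal_field")
}

#' @export
print.confocal_field <- function(x, ...) {
  cat(sprintf("Confocal field: %d x %d pixels, k = %.4g rad/um, ky_max = %.4g\n",
              length(x$grid_y), length(x$grid_z), x$wavenumber, x$ky_max))
  invisible(x)
}

#' Unpolarised intensity from the two polarisation amplitudes
#'
#' Pixelwise \eqn{I = (|U_p|^2 + |U_s|^2)/2} for amplitude fields on
#' identical grids.
#'
#' @param U_parallel,U_perp Complex matrices of identical dimension.
#' @return Real non-negative matrix.
#' @export
unpolarised_intensity <- function(U_parallel, U_perp) {
  if (!identical(dim(U_parallel), dim(U_perp)))
    stop("amplitude grids must have identical dimensions")
  (Mod(U_parallel)^2 + Mod(U_perp)^2) / 2
}

#' Radius-averaged Maxwell confocal image
#'
#' The confocal image of a large cylinder carries interference fringes that
#' are very sensitive to the exact radius.  To emulate an ensemble of
#' nominally identical prints, images are computed for `n_samples` radii
#' evenly spaced over `base_radius +/- half_range` and their intensities
#' (not amplitudes) are averaged.
#'
#' @param base_radius Nominal radius in um.
#' @param half_range Half-width of the radius interval in um (0.25 for the
#'   reference 10 um cylinder).
#' @param n_samples Odd number of radius samples (>= 1), 11 by default.
#' @param wavelength Vacuum wavelength in nm.
#' @param n_cyl,n_surround Refractive indices.
#' @param na Numerical aperture.
#' @param grid_y,grid_z Focus coordinates in um relative to the cylinder axis.
#' @param n_k Quadrature nodes per axis.
#' @param axial_convention Passed to [confocal_amplitude()].
#' @return A [scan_image()] whose data is the mean unpolarised intensity.
#' @export
radius_averaged_image <- function(base_radius, half_range = 0.25,
                                  n_samples = 11, wavelength = 552,
                                  n_cyl = 1.6285, n_surround = 1.0,
                                  na = 0.6, grid_y, grid_z, n_k = 256,
                                  axial_convention = "roundtrip") {
  if (n_samples < 1 || n_samples %% 2 == 0)
    stop("n_samples must be an odd integer >= 1")
  radii <- if (n_samples == 1) base_radius else
    seq(base_radius - half_range, base_radius + half_range,
        length.out = n_samples)
  acc <- NULL
  for (r in radii) {
    sol <- solve_cylinder(r, wavelength, n_cyl, n_surround)
    fld <- confocal_amplitude(sol, na, grid_y, grid_z, n_k = n_k,
                              axial_convention = axial_convention)
    acc <- if (is.null(acc)) fld$intensity else acc + fld$intensity
  }
  scan_image(acc / length(radii), grid_y, grid_z,
             meta = list(engine = "maxwell", base_radius = base_radius,
                         half_range = half_range, n_samples = n_samples,
                         wavelength = wavelength, n_cyl = n_cyl,
                         n_surround = n_surround, na = na, n_k = n_k))
}
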