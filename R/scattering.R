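# Maxwell series solution for plane-wave scattering by an infinite dielectric
# cylinder at normal incidence.  Conventions: Hankel functions of the first
# kind with the exp(-i omega t) time dependence; the amplitude function
# T(theta) = c0 + 2 sum_n c_n cos(n theta) has theta = 0 in the forward
# direction, verified by the optical theorem (positive extinction).

cyl_bessel_table <- function(x, n_max) {
  # J_n, Y_n and derivatives for n = 0..n_max at a single positive x.
  n <- 0:(n_max + 1)
  J <- vapply(n, function(k) besselJ(x, k), numeric(1))
  Y <- vapply(n, function(k) besselY(x, k), numeric(1))
  dJ <- c(-J[2], (J[seq_len(n_max)] - J[3:(n_max + 2)]) / 2)
  dY <- c(-Y[2], (Y[seq_len(n_max)] - Y[3:(n_max + 2)]) / 2)
  idx <- seq_len(n_max + 1)
  list(J = J[idx], Y = Y[idx], dJ = dJ, dY = dY)
}

#' Solve plane-wave scattering by an infinite dielectric cylinder
#'
#' Computes the series coefficients of the two-dimensional Maxwell solution
#' for a plane wave normally incident on an infinite, non-absorbing circular
#' cylinder.  Both polarisations are returned: `coeff_parallel` (electric
#' field parallel to the cylinder axis, coefficients \eqn{b_n}) and
#' `coeff_perp` (electric field perpendicular to the axis, \eqn{a_n}).
#'
#' The size parameter is formed with the wavelength in the surrounding
#' medium, \eqn{x = 2\pi n_s r / \lambda_0}, and the relative index is
#' \eqn{m = n_\mathrm{cyl}/n_s} (real; `m < 1` is fully supported).  The
#' series is truncated at `ceiling(x + 4 x^{1/3} + 2)` orders unless
#' `max_order` is given.
#'
#' @param radius Cylinder radius in um.
#' @param wavelength Vacuum wavelength in nm.
#' @param n_cyl Refractive index of the cylinder (real, positive).
#' @param n_surround Refractive index of the surrounding medium.
#' @param max_order Optional override of the truncation order.
#' @return An object of class `cylinder_scattering` with fields `size_param`,
#'   `rel_index`, `max_order`, `coeff_parallel`, `coeff_perp` (complex vectors
#'   indexed n = 0..max_order) and the input parameters.
#' @examples
#' sol <- solve_cylinder(10, 552, 1.6285, 1.0)
#' sol$size_param                       # about 113.8
#' @export
solve_cylinder <- function(radius, wavelength, n_cyl, n_surround = 1.0,
                           max_order = NULL) {
  for (v in c(radius = radius, wavelength = wavelength,
              n_cyl = n_cyl, n_surround = n_surround)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("radius, wavelength, n_cyl and n_surround must be positive finite scalars")
  }
  if (is.complex(n_cyl) || is.complex(n_surround))
    stop("complex (absorbing) refractive indices are not supported")
  lam_um <- wavelength / 1000
  x <- 2 * pi * n_surround * radius / lam_um
  m <- n_cyl / n_surround
  N <- if (is.null(max_order)) ceiling(x + 4 * x^(1/3) + 2) else as.integer(max_order)
  tx <- cyl_bessel_table(x, N)
  tm <- cyl_bessel_table(m * x, N)
  H  <- complex(real = tx$J,  imaginary = tx$Y)
  dH <- complex(real = tx$dJ, imaginary = tx$dY)
  # E parallel to axis: E_z and its radial derivative continuous.
  b <- (m * tm$dJ * tx$J - tm$J * tx$dJ) / (m * tm$dJ * H - tm$J * dH)
  # E perpendicular: H_z continuous, (1/n^2) dH_z/dr continuous.
  a <- (tm$dJ * tx$J - m * tm$J * tx$dJ) / (tm$dJ * H - m * tm$J * dH)
  structure(list(
    size_param = x, rel_index = m, max_order = N,
    coeff_parallel = b, coeff_perp = a,
    radius = radius, wavelength = wavelength,
    n_cyl = n_cyl, n_surround = n_surround
  ), class = "cylinder_scattering")
}

#' @export
print.cylinder_scattering <- function(x, ...) {
  cat("Infinite-cylinder scattering solution (normal incidence)\n")
  cat(sprintf("  size parameter x = %.4g, relative index m = %.6g\n",
              x$size_param, x$rel_index))
  cat(sprintf("  %d series orders; Q_sca (unpolarised) = %.4g\n",
              x$max_order + 1L, scattering_efficiency(x, "unpolarised")))
  invisible(x)
}

solution_coeffs <- function(solution, polarisation) {
  switch(match.arg(polarisation, c("parallel", "perp")),
         parallel = solution$coeff_parallel,
         perp = solution$coeff_perp)
}

#' Angular scattering amplitude of a cylinder solution
#'
#' Evaluates the far-field amplitude function
#' \deqn{T(\theta) = c_0 + 2\sum_{n\ge 1} c_n \cos(n\theta)}
#' for one polarisation, where `theta` is the scattering angle measured from
#' the forward direction (`theta = pi` is exact backscatter).  The function is
#' even in `theta` by construction.
#'
#' @param solution A `cylinder_scattering` object.
#' @param theta Scattering angle(s) in radians (vectorised).
#' @param polarisation `"parallel"` or `"perp"`.
#' @return Complex amplitude(s), same length as `theta`.
#' @export
scattering_amplitude <- function(solution, theta,
                                 polarisation = c("parallel", "perp")) {
  stopifnot(inherits(solution, "cylinder_scattering"))
  cf <- solution_coeffs(solution, polarisation)
  n <- seq_len(length(cf) - 1L)
  out <- complex(length(theta))
  # chunked so that the cos(outer()) matrix stays modest for big theta sets
  step <- max(1L, floor(4e6 / length(n)))
  for (i0 in seq(1L, length(theta), by = step)) {
    ii <- i0:min(i0 + step - 1L, length(theta))
    C <- cos(outer(theta[ii], n))
    out[ii] <- cf[1] + 2 * drop(C %*% cf[-1])
  }
  out
}

#' Unpolarised scattered intensity
#'
#' Squared-amplitude angular intensity
#' \eqn{(|T_\mathrm{par}|^2 + |T_\mathrm{perp}|^2)/2} (or a single
#' polarisation's squared amplitude).
#'
#' @inheritParams scattering_amplitude
#' @param polarisation `"unpolarised"` (default), `"parallel"` or `"perp"`.
#' @return Non-negative intensity, same length as `theta`.
#' @export
scattering_intensity <- function(solution, theta,
                                 polarisation = c("unpolarised", "parallel", "perp")) {
  polarisation <- match.arg(polarisation)
  if (polarisation == "unpolarised") {
    (Mod(scattering_amplitude(solution, theta, "parallel"))^2 +
       Mod(scattering_amplitude(solution, theta, "perp"))^2) / 2
  } else {
    Mod(scattering_amplitude(solution, theta, polarisation))^2
  }
}

#' Scattering efficiency of a cylinder
#'
#' Scattered power per unit length normalised by the geometric cross-section,
#' \deqn{Q_\mathrm{sca} = \frac{2}{x}\Big(|c_0|^2 + 2\sum_{n\ge1}|c_n|^2\Big),}
#' per polarisation; the unpolarised value is the mean of the two.
#'
#' @inheritParams scattering_amplitude
#' @param polarisation `"unpolarised"`, `"parallel"` or `"perp"`.
#' @return Dimensionless efficiency.
#' @export
scattering_efficiency <- function(solution,
                                  polarisation = c("unpolarised", "parallel", "perp")) {
  polarisation <- match.arg(polarisation)
  q1 <- function(cf) (2 / solution$size_param) *
    (Mod(cf[1])^2 + 2 * sum(Mod(cf[-1])^2))
  switch(polarisation,
         parallel = q1(solution$coeff_parallel),
         perp = q1(solution$coeff_perp),
         unpolarised = (q1(solution$coeff_parallel) +
                          q1(solution$coeff_perp)) / 2)
}

#' Extinction efficiency (optical theorem)
#'
#' \eqn{Q_\mathrm{ext} = (2/x)\,\mathrm{Re}\,T(0)}.  For the non-absorbing
#' media supported here this equals [scattering_efficiency()] exactly, which
#' pins down the Hankel-function sign convention.
#'
#' @inheritParams scattering_efficiency
#' @return Dimensionless efficiency.
#' @export
extinction_efficiency <- function(solution,
                                  polarisation = c("unpolarised", "parallel", "perp")) {
  polarisation <- match.arg(polarisation)
  q1 <- function(cf) (2 / solution$size_param) * Re(cf[1] + 2 * sum(cf[-1]))
  switch(polarisation,
         parallel = q1(solution$coeff_parallel),
         perp = q1(solution$coeff_perp),
         unpolarised = (q1(solution$coeff_parallel) +
                          q1(solution$coeff_perp)) / 2)
}

#' Forward-to-backward scattering ratio in orders of magnitude
#'
#' Solves the cylinder scattering problem and returns
#' \eqn{\log_{10}\big(I_\mathrm{unpol}(0)/I_\mathrm{unpol}(\pi)\big)}, the
#' number of orders of magnitude between forward and exact backward
#' unpolarised scattered intensity.  The larger this number, the more light
#' penetrates past a cylinder instead of being reflected, which is the
#' mechanism behind the growth of confocal penetration depth at small index
#' contrast.
#'
#' @inheritParams solve_cylinder
#' @return log10 intensity ratio (dimensionless).
#' @examples
#' forward_backward_orders(10, 552, 1.6285, 1.0)     # about 2-3 orders
#' forward_backward_orders(10, 552, 1.5133, 1.518)   # about 7 orders
#' @export
forward_backward_orders <- function(radius, wavelength, n_cyl, n_surround = 1.0) {
  if (isTRUE(all.equal(n_cyl, n_surround, tolerance = 0)) || n_cyl == n_surround)
    stop("forward/backward ratio is undefined for n_cyl == n_surround (no scattered field)")
  sol <- solve_cylinder(radius, wavelength, n_cyl, n_surround)
  i0 <- scattering_intensity(sol, 0, "unpolarised")
  ipi <- scattering_intensity(sol, pi, "unpolarised")
  log10(i0 / ipi)
}
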