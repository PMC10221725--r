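#' Diameter of the thin lens matching a numerical aperture
#'
#' The confocal model places a thin lens at axial distance `2f` above the
#' focus.  Its diameter is chosen so that the lens rim subtends the half-angle
#' `asin(na/ns)` from the focal point,
#' \deqn{d_\mathrm{lens} = \frac{4 f \, (\mathrm{NA}/n_s)}
#'                              {\sqrt{1 - (\mathrm{NA}/n_s)^2}}.}
#'
#' @param na Numerical aperture (dimensionless, `0 < na < ns`).
#' @param focal_length Focal length `f` of the lens, in mm.
#' @param n_surround Refractive index `ns` of the medium between lens and
#'   sample (1 for air, 1.518 for typical immersion oil).
#' @return Lens diameter in the same units as `focal_length`.
#' @examples
#' lens_diameter(0.6, 2, 1.0)          # 6 mm
#' lens_diameter(1.4, 0.3, 1.518)      # about 2.86 mm
#' @export
lens_diameter <- function(na, focal_length, n_surround = 1.0) {
  stopifnot(is.numeric(na), is.numeric(focal_length), is.numeric(n_surround))
  if (na <= 0 || focal_length <= 0 || n_surround <= 0)
    stop("na, focal_length and n_surround must be positive")
  if (na >= n_surround)
    stop("numerical aperture must be smaller than the surrounding index")
  s <- na / n_surround
  4 * focal_length * s / sqrt(1 - s^2)
}

#' Confocal optical system description
#'
#' Bundles the parameters of the simulated confocal microscope: numerical
#' aperture, focal length of the (thin) lens, pinhole radius, surrounding
#' refractive index and laser wavelength.  The lens diameter is derived from
#' the NA via [lens_diameter()].
#'
#' @param na Numerical aperture.
#' @param focal_length Focal length in mm (2 mm for the air objective,
#'   0.3 mm for the oil objective used as defaults elsewhere).
#' @param pinhole_radius Pinhole radius in the object-side plane, in um.
#' @param n_surround Refractive index of the surrounding medium.
#' @param wavelength Vacuum wavelength in nm (informational for the ray
#'   tracer; used by the wave calculations).
#' @return An object of class `optical_system`: a list with the arguments plus
#'   `lens_diameter` (mm) and `lens_radius` (mm).
#' @examples
#' optical_system(na = 0.6, focal_length = 2, pinhole_radius = 1.68)
#' @export
optical_system <- function(na, focal_length, pinhole_radius,
                           n_surround = 1.0, wavelength = 552) {
  if (!is.numeric(pinhole_radius) || pinhole_radius <= 0)
    stop("pinhole_radius must be positive")
  if (!is.numeric(wavelength) || wavelength <= 0)
    stop("wavelength must be positive")
  d <- lens_diameter(na, focal_length, n_surround)
  structure(list(
    na = na,
    focal_length = focal_length,
    pinhole_radius = pinhole_radius,
    n_surround = n_surround,
    wavelength = wavelength,
    lens_diameter = d,
    lens_radius = d / 2
  ), class = "optical_system")
}

#' @export
print.optical_system <- function(x, ...) {
  cat("Confocal optical system\n")
  cat(sprintf("  NA %.3g in medium n = %.4g (half-angle %.1f deg)\n",
              x$na, x$n_surround, asin(x$na / x$n_surround) * 180 / pi))
  cat(sprintf("  focal length %g mm, lens diameter %.4g mm\n",
              x$focal_length, x$lens_diameter))
  cat(sprintf("  pinhole radius %g um, wavelength %g nm\n",
              x$pinhole_radius, x$wavelength))
  invisible(x)
}

#' Airy-unit pinhole radius
#'
#' Object-side radius of a one-Airy-unit pinhole,
#' `1.22 * lambda / (2 NA)`, in um.
#'
#' @param na Numerical aperture.
#' @param wavelength Vacuum wavelength in nm.
#' @return Radius in um.
#' @export
airy_radius <- function(na, wavelength = 552) {
  1.22 * (wavelength / 1000) / (2 * na)
}

#' Reference material and setup constants
#'
#' Refractive indices of the two photoresists the phantoms are printed from
#' (at 552 nm), of air and of standard immersion oil, together with the
#' default laser wavelength.  Convenience values for setting up the worked
#' configurations: e.g. the index contrast of the IP-S resin in immersion oil
#' is `1.5133 - 1.518 = -0.0048`.
#'
#' @return A named list with elements `n_ips`, `n_ipn162`, `n_air`, `n_oil`
#'   and `wavelength_nm`.
#' @examples
#' with(clsm_materials(), n_ips - n_oil)   # -0.0048
#' @export
clsm_materials <- function() {
  list(n_ips = 1.5133, n_ipn162 = 1.6285,
       n_air = 1.0, n_oil = 1.518,
       wavelength_nm = 552)
}
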