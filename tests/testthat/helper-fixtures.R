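# Shared fixtures: reference optical systems and single-cylinder scenes.

air_optics <- function(pinhole = 1.68)
  optical_system(na = 0.6, focal_length = 2, pinhole_radius = pinhole,
                 n_surround = 1.0, wavelength = 552)

oil_optics <- function(na = 1.4)
  optical_system(na = na, focal_length = 0.3, pinhole_radius = 0.72,
                 n_surround = 1.518, wavelength = 552)

single_cylinder_phantom <- function(radius = 10, n_cyl = 1.6285,
                                    n_surround = 1.0)
  phantom(list(cylinder(0, 0, radius, n_cyl)), n_surround = n_surround)

empty_phantom <- function(n_surround = 1.0)
  phantom(list(), n_surround = n_surround)

fixture_path <- function(name)
  system.file("extdata", name, package = "confocyl", mustWork = TRUE)
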