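# R surface of the Monte Carlo transport engine.  The hot loops live in
# src/mc_core.cpp; these wrappers handle unit conversion (focal lengths in mm
# -> um), argument validation and the per-pixel seed derivation.

mm_to_um <- function(x) x * 1000

#' Launch photons from the lens towards a focal point
#'
#' Samples photon start positions on the lens disc (area-uniform by default:
#' \eqn{r_0 = r_\mathrm{lens}\sqrt{\xi_1}}, \eqn{\phi_0 = 2\pi\xi_2}) and
#' directs each photon at the geometric focus.  A `literal` mode with
#' \eqn{r_0 = r_\mathrm{lens}\,\xi_1} (radius-uniform, density weighted
#' towards the lens centre) is selectable for replication studies.
#'
#' @param optics An [optical_system()].
#' @param focal_point Numeric `(x, y, z)` focus position in um.
#' @param n Number of photons to launch.
#' @param seed Integer seed of the deterministic stream.
#' @param literal Use the radius-uniform launch density.
#' @return A list with `position` (n x 3 matrix, um) and `direction`
#'   (n x 3 unit vectors); the lens plane is at `z = focal_point[3] + 2f`.
#' @export
launch_photon <- function(optics, focal_point = c(0, 0, 0), n = 1,
                          seed = 1, literal = FALSE) {
  stopifnot(inherits(optics, "optical_system"))
  r_lens <- mm_to_um(optics$lens_radius)
  f <- mm_to_um(optics$focal_length)
  pos <- cpp_launch_positions(as.integer(n), r_lens, as.numeric(seed),
                              isTRUE(literal))
  pos[, 1] <- pos[, 1] + focal_point[1]
  pos[, 2] <- pos[, 2] + focal_point[2]
  pos[, 3] <- focal_point[3] + 2 * f
  dir <- cbind(focal_point[1] - pos[, 1],
               focal_point[2] - pos[, 2],
               focal_point[3] - pos[, 3])
  dir <- dir / sqrt(rowSums(dir^2))
  list(position = pos, direction = dir)
}

#' Ray / infinite-cylinder intersection
#'
#' Nearest positive intersection of a ray with an infinite cylinder aligned
#' with the x axis.  Hits closer than 1e-6 um are ignored (self-intersection
#' guard) and near-tangent rays (discriminant below 1e-12) count as misses.
#'
#' @param origin,direction Numeric length-3 ray origin (um) and direction
#'   (need not be normalised in y/z magnitude, but should be a unit vector
#'   for the returned distance to be metric).
#' @param cylinder A [cylinder()] or a list with `center_y`, `center_z`,
#'   `radius`.
#' @return A list: `hit` (logical); if `TRUE` also `distance` (um), `point`
#'   (length-3) and the outward unit `normal` at the hit.
#' @export
intersect_ray_cylinder <- function(origin, direction, cylinder) {
  cpp_intersect_ray_cylinder(as.numeric(origin), as.numeric(direction),
                             cylinder$center_y, cylinder$center_z,
                             cylinder$radius)
}

#' Unpolarised Fresnel reflectance of a planar dielectric interface
#'
#' \eqn{R = (R_s + R_p)/2} for incidence from index `n1` into `n2` with
#' incidence cosine `cos_i`; returns 1 beyond the critical angle.
#'
#' @param cos_i Cosine of the incidence angle, in `[0, 1]`.
#' @param n1,n2 Refractive indices on the incident / transmitted side.
#' @return Reflectance in `[0, 1]`.
#' @export
fresnel_reflectance <- function(cos_i, n1, n2) {
  vapply(cos_i, cpp_fresnel_reflectance, numeric(1), n1 = n1, n2 = n2)
}

#' Apply one Fresnel interface event to a photon direction
#'
#' With probability `R` (unpolarised Fresnel reflectance) the photon is
#' specularly reflected, otherwise refracted by Snell's law; the branch is
#' decided by the uniform variate `u` (`u < R` reflects), which makes the
#' event reproducible in tests.
#'
#' @param direction Unit direction of the incident photon.
#' @param normal Unit interface normal oriented against the incident ray.
#' @param n1,n2 Indices on the incident / far side.
#' @param u Uniform variate in `[0, 1)` deciding the branch.
#' @return List with the new unit `direction`, logical `transmitted` and the
#'   `reflectance` used for the branch.
#' @export
fresnel_interact <- function(direction, normal, n1, n2, u) {
  cpp_fresnel_interact(as.numeric(direction), as.numeric(normal), n1, n2, u)
}

phantom_cyl_matrix <- function(phantom) {
  tab <- cylinder_table(phantom)
  matrix(as.numeric(tab), nrow(tab), 4)
}

#' Trace a single photon through a phantom
#'
#' Propagates one photon (straight free flight, stochastic Fresnel events,
#' at most `max_events` interface interactions) until it either crosses the
#' lens plane travelling upward — where the aperture test and the ABCD
#' pinhole mapping are applied — or is lost.  Any ray emanating exactly from
#' the focal point maps to the pinhole centre.
#'
#' @param start,direction Photon start position (um) and direction.
#' @param phantom A [phantom()].
#' @param optics An [optical_system()].
#' @param focal_point `(x, y, z)` scan focus in um.
#' @param max_events Interface interaction cap (default 50).
#' @param seed Seed for the Fresnel branch stream.
#' @param mode `"3d"` or `"2d"` (detection on the y coordinate only).
#' @param keep_path Record the vertex list of the trajectory.
#' @return List with `detected`, `reached_lens`, `lens_hit` (x1, y1),
#'   `pinhole_pos` (x2, y2 relative to the optical axis) and optionally
#'   `path` (matrix of vertices).
#' @export
trace_photon <- function(start, direction, phantom, optics,
                         focal_point = c(0, 0, 0), max_events = 50,
                         seed = 1, mode = c("3d", "2d"), keep_path = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(optics, "optical_system"), inherits(phantom, "phantom"))
  cpp_trace_photon(as.numeric(start), as.numeric(direction),
                   phantom_cyl_matrix(phantom), phantom$n_surround,
                   mm_to_um(optics$lens_radius), mm_to_um(optics$focal_length),
                   optics$pinhole_radius, as.numeric(focal_point),
                   as.integer(max_events), mode == "2d",
                   as.numeric(seed), isTRUE(keep_path))
}

#' Detected photon fraction for one scan pixel
#'
#' Runs `n_photons` independent photons for the focus `focal_point` and
#' returns the detected fraction.  In `"2d"` mode launch positions and
#' directions are confined to the y-z plane and the pinhole test uses the y
#' coordinate only, matching the two-dimensional Maxwell comparison.
#'
#' @inheritParams trace_photon
#' @param n_photons Photons per pixel (>= 1).
#' @param literal Radius-uniform launch density (see [launch_photon()]).
#' @param collect_paths If > 0, also return up to this many detected-photon
#'   vertex paths.
#' @return A list with `fraction`, `detected`, `n_photons` and `paths`.
#' @export
simulate_pixel <- function(optics, phantom, focal_point, n_photons = 1e4,
                           seed = 1, mode = c("3d", "2d"),
                           max_events = 50, literal = FALSE,
                           collect_paths = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(optics, "optical_system"), inherits(phantom, "phantom"),
            n_photons >= 1)
  cpp_simulate_pixel(phantom_cyl_matrix(phantom), phantom$n_surround,
                     mm_to_um(optics$lens_radius),
                     mm_to_um(optics$focal_length),
                     optics$pinhole_radius, as.numeric(focal_point),
                     as.integer(n_photons), as.numeric(seed),
                     mode == "2d", isTRUE(literal), as.integer(max_events),
                     as.integer(collect_paths))
}

#' Derive the per-pixel seed used by [simulate_scan()]
#'
#' Deterministic hash of the base seed and pixel indices, so that pixels are
#' reproducible independently of evaluation order.
#'
#' @param base_seed Scan-level seed.
#' @param iy,iz Pixel indices (1-based).
#' @return A numeric seed.
#' @export
pixel_seed <- function(base_seed, iy, iz) {
  cpp_pixel_seed(as.numeric(base_seed), as.integer(iy), as.integer(iz))
}
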