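# Monte Carlo engine: lens sizing, launch sampling, intersections, Fresnel
# events, ABCD detection, pixel simulation.

test_that("lens diameter matches the NA for the reference objectives", {
  expect_equal(lens_diameter(0.6, 2, 1.0), 6.0, tolerance = 1e-12)
  expect_equal(lens_diameter(1.4, 0.3, 1.518), 2.8631, tolerance = 1e-4)
  # small-angle limit d -> 4 f na / ns
  expect_equal(lens_diameter(1e-4, 2, 1.0), 4 * 2 * 1e-4, tolerance = 1e-6)
  expect_error(lens_diameter(1.1, 2, 1.0), "smaller")
  # stored value consistent with recomputation
  opt <- oil_optics()
  expect_equal(opt$lens_diameter,
               lens_diameter(opt$na, opt$focal_length, opt$n_surround),
               tolerance = 1e-12)
})

test_that("launch sampling is area-uniform on the lens disc", {
  opt <- air_optics()
  lp <- launch_photon(opt, c(0, 0, 0), n = 1e6, seed = 7)
  r_lens <- 3000  # um
  r0 <- sqrt(lp$position[, 1]^2 + lp$position[, 2]^2)
  expect_lt(abs(mean(r0) / (2 / 3 * r_lens) - 1), 0.002)
  expect_true(all(r0 <= r_lens + 1e-9))
  # unit directions towards -z
  expect_equal(rowSums(lp$direction^2), rep(1, nrow(lp$direction)),
               tolerance = 1e-12)
  expect_true(all(lp$direction[, 3] < 0))
  # literal (radius-uniform) mode weights the centre: mean radius r_lens/2
  ll <- launch_photon(opt, c(0, 0, 0), n = 1e6, seed = 7, literal = TRUE)
  rl <- sqrt(ll$position[, 1]^2 + ll$position[, 2]^2)
  expect_lt(abs(mean(rl) / (r_lens / 2) - 1), 0.002)
})

test_that("ray-cylinder intersection agrees with a marching oracle", {
  cyl <- cylinder(1.5, -2.0, 7.0, 1.6)
  # axis-aligned sanity case
  hit <- intersect_ray_cylinder(c(0, 0, 30), c(0, 0, -1),
                                cylinder(0, 0, 10, 1.5))
  expect_true(hit$hit)
  expect_equal(hit$distance, 20, tolerance = 1e-9)
  expect_equal(hit$normal, c(0, 0, 1), tolerance = 1e-12)
  # exactly tangent ray counts as a miss
  expect_false(intersect_ray_cylinder(c(0, 10, 30), c(0, 0, -1),
                                      cylinder(0, 0, 10, 1.5))$hit)

  # marching oracle: step along the ray and find the first entry into the
  # cylinder by sign change of the radial distance
  march <- function(o, d, cc, tmax = 80, step = 1e-3) {
    t <- seq(step, tmax, by = step)
    y <- o[2] + t * d[2]; z <- o[3] + t * d[3]
    inside <- (y - cc$center_y)^2 + (z - cc$center_z)^2 < cc$radius^2
    i <- which(inside)[1]
    if (is.na(i)) return(NA_real_)
    t[i]
  }
  us <- matrix(confocyl:::cpp_uniforms(99, 0, 4L * 400L), ncol = 4)
  agree <- 0L
  for (i in seq_len(400)) {
    o <- c(0, (us[i, 1] - 0.5) * 40, 30)
    ang <- pi + (us[i, 2] - 0.5) * 1.5   # downward-ish directions
    d <- c(0, sin(ang - pi), -cos(ang - pi))
    d <- d / sqrt(sum(d^2))
    t_ref <- march(o, d, cyl)
    hit <- intersect_ray_cylinder(o, d, cyl)
    if (is.na(t_ref)) {
      # oracle may miss grazing hits shorter than its step resolution
      expect_true(!hit$hit || hit$distance > 0)
    } else {
      expect_true(hit$hit)
      expect_lt(abs(hit$distance - t_ref), 2e-3)
      agree <- agree + 1L
    }
  }
  expect_gt(agree, 100)   # the oracle exercised real hits
})

test_that("Fresnel reflectance and branching behave", {
  # normal incidence, air to resin
  expect_equal(fresnel_reflectance(1, 1.0, 1.6285),
               (0.6285 / 2.6285)^2, tolerance = 1e-12)
  # index-matched: no reflection, direction unchanged on transmission
  ev <- fresnel_interact(c(0, 0.6, -0.8), c(0, 0, 1), 1.5, 1.5, u = 0.999)
  expect_equal(ev$reflectance, 0)
  expect_equal(ev$direction, c(0, 0.6, -0.8), tolerance = 1e-12)
  # beyond the critical angle: reflectance 1
  cos_crit <- sqrt(1 - (1.518 / 1.6285)^2)
  expect_equal(fresnel_reflectance(cos_crit * 0.5, 1.6285, 1.518), 1)
  # R + T = 1 by construction; empirical branch frequency matches R
  R <- fresnel_reflectance(cos(0.5), 1.0, 1.6285)
  u <- confocyl:::cpp_uniforms(17, 0, 200000L)
  phat <- mean(u < R)
  expect_lt(abs(phat - R), 3 * sqrt(R * (1 - R) / 2e5))
  # energy split via Snell: transmitted direction obeys Snell's law
  ev2 <- fresnel_interact(c(0, sin(0.5), -cos(0.5)), c(0, 0, 1),
                          1.0, 1.6285, u = 0.999)
  expect_true(ev2$transmitted)
  expect_equal(ev2$direction[2], sin(0.5) / 1.6285, tolerance = 1e-12)
  expect_equal(sum(ev2$direction^2), 1, tolerance = 1e-12)
  # reflection branch: specular about the normal
  ev3 <- fresnel_interact(c(0, sin(0.5), -cos(0.5)), c(0, 0, 1),
                          1.0, 1.6285, u = 0)
  expect_false(ev3$transmitted)
  expect_equal(ev3$direction, c(0, sin(0.5), cos(0.5)), tolerance = 1e-12)
})

test_that("rays from the focal point map exactly to the pinhole centre", {
  opt <- air_optics()
  ph <- empty_phantom()
  for (d in list(c(0, 0, 1), c(0.2, -0.1, 1), c(-0.4, 0.3, 1))) {
    tr <- trace_photon(c(0, 0, 0), d, ph, opt, focal_point = c(0, 0, 0))
    expect_true(tr$detected)
    expect_lt(max(abs(tr$pinhole_pos)), 1e-9)
  }
  # off-axis focus: the mapping is focus-relative
  tr <- trace_photon(c(5, -3, 2), c(0.1, 0.2, 1), ph, opt,
                     focal_point = c(5, -3, 2))
  expect_lt(max(abs(tr$pinhole_pos)), 1e-9)
})

test_that("lateral displacement maps with magnification -1", {
  opt <- air_optics()
  ph <- empty_phantom()
  tr <- trace_photon(c(0.5, 0.3, 0), c(0.05, -0.02, 1), ph, opt,
                     focal_point = c(0, 0, 0))
  expect_equal(tr$pinhole_pos, c(-0.5, -0.3), tolerance = 1e-9)
})

test_that("apex retro-reflection is detected and reproduces the surface reflex", {
  opt <- air_optics()
  cyl <- cylinder(0, 0, 10, 1.6285)
  ph <- phantom(list(cyl), n_surround = 1.0)
  # compose: ray towards the apex, forced reflection (u = 0), upward retrace
  start <- c(0, 0, 20)
  hit <- intersect_ray_cylinder(start, c(0, 0, -1), cyl)
  ev <- fresnel_interact(c(0, 0, -1), hit$normal, 1.0, 1.6285, u = 0)
  expect_equal(ev$direction, c(0, 0, 1), tolerance = 1e-12)
  tr <- trace_photon(hit$point + 1e-5 * ev$direction, ev$direction,
                     empty_phantom(), opt, focal_point = c(0, 0, 10))
  expect_true(tr$detected)

  # detected fraction at the apex focus vs a deterministic ray-fan oracle:
  # every launch ray retro-reflects with probability R(angle of incidence),
  # so the detected fraction is the launch-weighted mean reflectance
  px <- simulate_pixel(opt, ph, c(0, 0, 10), n_photons = 2e5, seed = 21)
  angles <- asin(seq(1e-3, opt$na, length.out = 1e4))  # fan over the aperture
  # area-uniform launch weights: w ~ r0 dr0 with r0 = 2f tan(angle)
  r0 <- 2 * 2000 * tan(angles)
  w <- r0 * c(diff(r0)[1], diff(r0))
  R_mean <- sum(fresnel_reflectance(cos(angles), 1.0, 1.6285) * w) / sum(w)
  expect_gt(px$fraction, 0)
  expect_lt(abs(px$fraction - R_mean) / R_mean, 0.1)
})

test_that("empty phantom detects nothing and seeds reproduce exactly", {
  opt <- air_optics()
  expect_equal(simulate_pixel(opt, empty_phantom(), c(0, 0, 0),
                              n_photons = 1e4, seed = 5)$fraction, 0)
  ph <- single_cylinder_phantom()
  a <- simulate_pixel(opt, ph, c(0, 0, 8), n_photons = 5e4, seed = 33)
  b <- simulate_pixel(opt, ph, c(0, 0, 8), n_photons = 5e4, seed = 33)
  expect_identical(a$detected, b$detected)
  c2 <- simulate_pixel(opt, ph, c(0, 0, 8), n_photons = 5e4, seed = 34)
  expect_false(identical(a$detected, c2$detected))
})

test_that("enlarging the pinhole never loses a detected photon", {
  ph <- single_cylinder_phantom()
  base <- NULL
  counts <- vapply(c(0.4, 0.8, 1.68, 3.0), function(rp) {
    opt <- air_optics(pinhole = rp)
    simulate_pixel(opt, ph, c(0, 0, 4), n_photons = 5e4, seed = 9)$detected
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("detected-photon paths can be collected for path analysis", {
  opt <- oil_optics()
  ph <- single_cylinder_phantom(n_surround = 1.518)
  px <- simulate_pixel(opt, ph, c(0, 0, -12), n_photons = 2e4, seed = 41,
                       collect_paths = 5)
  expect_gt(length(px$paths), 0)
  p1 <- px$paths[[1]]
  expect_true(is.matrix(p1) && ncol(p1) == 3)
  # path starts on the lens plane (z = zf + 2f = -12 + 600)
  expect_equal(p1[1, 3], -12 + 600, tolerance = 1e-9)
})
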