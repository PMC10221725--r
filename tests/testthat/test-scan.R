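# Scan orchestration, post-processing operators and image I/O.

test_that("a 1x1 scan equals the single-pixel simulation", {
  opt <- air_optics()
  ph <- single_cylinder_phantom()
  img <- simulate_scan(opt, ph, grid_y = 0, grid_z = 8, n_photons = 2e4,
                       seed = 4)
  px <- simulate_pixel(opt, ph, c(0, 0, 8), n_photons = 2e4,
                       seed = pixel_seed(4, 1L, 1L))
  expect_equal(img$data[1, 1], px$fraction)
})

test_that("empty phantom scans to an all-zero image, reproducibly", {
  opt <- air_optics()
  img <- simulate_scan(opt, empty_phantom(), seq(-5, 5, 5), seq(-5, 5, 5),
                       n_photons = 1e3, seed = 1)
  expect_true(all(img$data == 0))
  ph <- single_cylinder_phantom()
  a <- simulate_scan(opt, ph, c(-1, 1), c(7, 9), n_photons = 1e4, seed = 8)
  b <- simulate_scan(opt, ph, c(-1, 1), c(7, 9), n_photons = 1e4, seed = 8)
  expect_identical(a$data, b$data)
})

test_that("mirror symmetry: reflected phantom gives the mirrored mean image", {
  opt <- air_optics()
  ph <- phantom(list(cylinder(6, 0, 8, 1.6285)), n_surround = 1.0)
  ph_m <- phantom(list(cylinder(-6, 0, 8, 1.6285)), n_surround = 1.0)
  y <- seq(-12, 12, 3)
  img <- simulate_scan(opt, ph, y, c(6, 10), n_photons = 3e4, seed = 2)
  img_m <- simulate_scan(opt, ph_m, y, c(6, 10), n_photons = 3e4, seed = 2)
  mirrored <- img_m$data[rev(seq_along(y)), ]
  # agreement within 3 sigma binomial MC error, pixel by pixel
  sd_pix <- sqrt(pmax(img$data, 1 / 3e4) / 3e4) +
    sqrt(pmax(mirrored, 1 / 3e4) / 3e4)
  expect_true(all(abs(img$data - mirrored) <= 3 * sd_pix))
})

test_that("halving the photon count inflates MC error by about sqrt(2)", {
  opt <- air_optics()
  ph <- single_cylinder_phantom()
  f <- c(0, 0, 10)
  est <- function(np) vapply(1:40, function(s)
    simulate_pixel(opt, ph, f, n_photons = np, seed = 1000 + s)$fraction, 1)
  s_full <- sd(est(8e3)); s_half <- sd(est(4e3))
  ratio <- s_half / s_full
  # 40 replicates: sd of the sd ratio is roughly 1/sqrt(2*39) ~ 0.11; 3 sigma
  expect_gt(ratio, sqrt(2) - 3 * 0.16)
  expect_lt(ratio, sqrt(2) + 3 * 0.16)
})

test_that("normalise scales the chosen reference to one and is idempotent", {
  img <- scan_image(matrix(c(1, 2, 4, 8), 2, 2), c(0, 1), c(0, 1))
  n1 <- normalise(img)
  expect_equal(max(n1$data), 1)
  expect_equal(normalise(n1)$data, n1$data)
  nr <- normalise(img, "region", region = c(0, 1, 0, 0))  # first column
  expect_equal(max(nr$data[, 1]), 1)
  expect_gt(max(nr$data), 1)
  zero <- scan_image(matrix(0, 2, 2), c(0, 1), c(0, 1))
  expect_error(normalise(zero), "zero")
})

test_that("moving average filters as a shrinking-window box", {
  m <- matrix(0, 9, 1); m[5, 1] <- 1
  img <- scan_image(m, 1:9, 1)
  sm <- moving_average(img, 5)
  expect_equal(sm$data[3:7, 1], rep(1 / 5, 5))
  expect_equal(sum(sm$data), 1)            # interior impulse preserves mass
  expect_equal(moving_average(img, 1)$data, img$data)
  const <- scan_image(matrix(3, 4, 4), 1:4, 1:4)
  expect_equal(moving_average(const, 5)$data, const$data)
  expect_error(moving_average(img, 4), "odd")
})

test_that("cubic upscaling is exact on linear fields and sizes correctly", {
  y <- seq(0, 4, 1); z <- seq(0, 6, 2)
  lin <- outer(y, z, function(a, b) 2 * a + 0.5 * b + 1)
  img <- scan_image(lin, y, z)
  up <- upscale_cubic(img, 2)
  expect_equal(dim(up$data), c((5 - 1) * 2 + 1, (4 - 1) * 2 + 1))
  ref <- outer(up$axis_y, up$axis_z, function(a, b) 2 * a + 0.5 * b + 1)
  expect_equal(up$data, ref, tolerance = 1e-9)
  expect_true(all(up$data >= 0))
  expect_equal(upscale_cubic(img, 1)$data, img$data)
})

test_that("line background subtraction removes constant row offsets", {
  z <- 1:3; y <- 1:6
  base <- matrix(rep(c(0.2, 0.5, 0.1), each = 6), 6, 3)   # per-z-line offset
  sig <- matrix(0, 6, 3); sig[3, 2] <- 1
  img <- scan_image(base + sig, y, z)
  out <- subtract_background_lines(img, estimator = "min")
  expect_equal(out$data, sig)
  zero <- scan_image(matrix(0, 3, 3), 1:3, 1:3)
  expect_equal(subtract_background_lines(zero)$data, zero$data)
  # percentile estimator leaves sparse bright features intact
  out2 <- subtract_background_lines(img, estimator = "percentile", p = 0.05)
  expect_gt(out2$data[3, 2], 0.9)
})

test_that("log view floors, gains and keeps axes", {
  img <- scan_image(matrix(c(1, 0.1, 0.01, 0), 2, 2), c(0, 1), c(0, 1))
  lv <- log_view(img, floor = 1)
  expect_true(all(lv == 0))
  lv2 <- log_view(img, floor = 1e-4)
  expect_equal(lv2[1, 1], 0)
  expect_equal(lv2[2, 2], -4)
  lv5 <- log_view(img, floor = 1e-6, gain = 5)
  expect_equal(lv5[1, 1] , log10(5), tolerance = 1e-12)
  expect_equal(attr(lv2, "axis_y"), c(0, 1))
})

test_that("pipeline order matters and is applied as documented", {
  img <- scan_image(matrix(c(0.2, 1, 0.4, 0.3), 2, 2), c(0, 1), c(0, 1))
  a <- normalise(moving_average(img, 3))
  b <- moving_average(normalise(img), 3)
  expect_false(isTRUE(all.equal(a$data, b$data)))
})

test_that("TIFF + sidecar round trip preserves the image", {
  img <- scan_image(matrix(runif(12), 3, 4) * 0.9, c(-1, 0, 1),
                    c(0, 2, 4, 6), meta = list(n_photons = 10, seed = 3))
  f <- tempfile(fileext = ".tif")
  write_image(img, f)
  back <- read_image(f)
  expect_equal(back$data, img$data, tolerance = 1e-7)  # float32 payload
  expect_equal(back$axis_y, img$axis_y)
  expect_equal(back$axis_z, img$axis_z)
  expect_equal(back$meta$seed, 3)
  # identical writes are byte-identical (reproducibility of artefacts)
  f2 <- tempfile(fileext = ".tif")
  write_image(img, f2)
  expect_identical(readBin(f, "raw", 1e6), readBin(f2, "raw", 1e6))
  # missing sidecar is an error
  file.remove(sidecar <- paste0(f, ".json"))
  expect_error(read_image(f), "sidecar")
  # CSV export matches the grid
  fc <- tempfile(fileext = ".csv")
  write_image_csv(img, fc)
  df <- read.csv(fc)
  expect_equal(nrow(df), 12)
  expect_equal(matrix(df$intensity, 3, 4), img$data, tolerance = 1e-12)
})

test_that("axial profile peak finder reports strict maxima only", {
  z <- seq(-15, -2, 0.25)
  intens <- exp(-(z + 12)^2 / 0.18) + 0.4 * exp(-(z + 8)^2 / 0.5) + 1e-4
  prof <- confocyl:::profile_peaks(z, intens, smooth = 3)
  expect_true(all(diff(prof$peaks$z) > 0))
  expect_equal(sort(round(prof$peaks$z)), c(-12, -8))
  # peaks are strict local maxima of the smoothed profile
  for (zp in prof$peaks$z) {
    i <- which(z == zp)
    expect_gte(prof$smoothed[i], prof$smoothed[i - 1])
    expect_gte(prof$smoothed[i], prof$smoothed[i + 1])
  }
  # empty scene: no peaks
  opt <- air_optics()
  ap <- axial_reflex_positions(opt, empty_phantom(), c(-5, 5),
                               n_positions = 11, n_photons = 500, seed = 1)
  expect_equal(nrow(ap$peaks), 0)
})
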