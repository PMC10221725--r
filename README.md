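# confocyl

Simulation of reflectance confocal laser scanning microscope (CLSM) images
of micro-printed phantoms built from parallel dielectric cylinders.

Confocal reflectance microscopy forms its image from light that is focused
into a sample and scattered back through a pinhole conjugate to the focus.
Phantoms of 3D-printed parallel cylinders (radii 5–10 μm, photoresist
indices 1.5133 / 1.6285, imaged in air or immersion oil) have exactly known
geometry, so every feature of their CLSM image can be attributed to a
specific optical mechanism — provided one has faithful forward models.
`confocyl` is aimed at researchers in biomedical optics and microscopy who
want to do exactly that. It implements:

* **Cylinder scattering series** — the Maxwell solution for a plane wave
  normally incident on an infinite dielectric cylinder, both polarisations:
  coefficients, angular amplitude T(θ) = c₀ + 2Σₙ cₙ cos nθ, scattering
  efficiencies Q = (2/x)(|c₀|² + 2Σ|cₙ|²) with x = 2π nₛ r/λ₀, and
  forward/backward intensity ratios (`solve_cylinder()`,
  `scattering_amplitude()`, `scattering_efficiency()`,
  `forward_backward_orders()`).
* **Confocal imaging integral** — the 2D wave-optical image of a single
  cylinder, U(y,z) = ΣΣ S(k_y, k_y′) exp{i[y(k_y′−k_y) + z(k_z′+k_z)]} Δk²
  over the NA-limited band, with unpolarised intensity
  I = (|U_p|² + |U_s|²)/2 and 11-radius incoherent averaging
  (`confocal_amplitude()`, `radius_averaged_image()`).
* **Phantom generator** — random non-overlapping cylinder layouts in a
  200×200 μm slab at ~10 % area fill, with tilt transform and a versioned
  JSON schema (`generate_phantom()`, `tilt_phantom()`, `read_phantom()`).
* **Monte Carlo transport** (Rcpp) — rays launched area-uniformly from a
  lens sized by d = 4f(NA/nₛ)/√(1−(NA/nₛ)²), specular Fresnel interfaces
  with stochastic branching, analytic ray–cylinder intersection, and
  thin-lens ABCD detection (tan α₂ = −p₁/f + tan α₁, p₂ = p₁ + 2f tan α₂)
  onto a pinhole; counter-based per-pixel seeding for bit-reproducible
  scans (`simulate_pixel()`, `simulate_scan()`,
  `axial_reflex_positions()`).
* **Post-processing** — per-line background subtraction, moving average,
  normalisation, cubic upscaling, log display; float32 TIFF + JSON sidecar
  I/O (`normalise()`, `moving_average()`, `upscale_cubic()`,
  `subtract_background_lines()`, `log_view()`, `write_image()`).

A thin command-line front end ships at `inst/cli/confocyl`
(`scatter`, `make-phantom`, `maxwell-image`, `simulate-scan`,
`axial-profile`, `postprocess`).

## Worked example

```r
library(confocyl)

# Orders of magnitude between forward and backward scattering (r = 10 um)
forward_backward_orders(10, 552, 1.6285, 1.000)
#> [1] 2.634578
forward_backward_orders(10, 552, 1.5133, 1.518)
#> [1] 7.20709

# Scattering-efficiency ratio, largest vs smallest index contrast
scattering_efficiency(solve_cylinder(10, 552, 1.6285, 1.000)) /
  scattering_efficiency(solve_cylinder(10, 552, 1.5133, 1.518))
#> [1] 3.126808

# Axial reflexes beneath a single 10 um cylinder in oil (NA 1.4)
oil <- optical_system(na = 1.4, focal_length = 0.3, pinhole_radius = 0.72,
                      n_surround = 1.518, wavelength = 552)
ph  <- phantom(list(cylinder(0, 0, 10, 1.6285)), n_surround = 1.518)
axial_reflex_positions(oil, ph, z_range = c(-15, -2), n_positions = 66,
                       n_photons = 1e6, seed = 1, min_prominence = 8e-6)
#> Axial profile: 66 positions, z in [-15, -2] um
#>   peaks (z um, prominence):
#>      -12.000   0.000778
#>       -8.400   1.83e-05
#>       -4.400   2.7e-05
```

The first two numbers say that dropping the refractive-index contrast from
0.6285 (resin in air) to −0.0047 (resin in oil) moves the forward/backward
scattering ratio from ~10² to ~10⁷ while the total scattering efficiency
falls only ~3×: near index matching, light keeps going forward, which is
why deeper cylinders become visible. The axial profile locates the three
discrete subsurface reflexes of a single cylinder: rays reflected at the
lower surface after refraction (2 μm below it, the dominant one at
nominal focus −12 μm), and two families of lateral paths (≈8 μm and
≈4.5 μm below the centre).

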