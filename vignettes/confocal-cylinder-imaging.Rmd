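---
title: "Simulating confocal reflectance images of cylinder phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating confocal reflectance images of cylinder phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confocyl)
```

## The problem

A reflectance confocal laser scanning microscope (CLSM) focuses a laser spot
into a sample, collects the back-reflected light through the same objective,
and rejects out-of-focus light with a pinhole conjugate to the focus.
Micro-printed phantoms made of parallel dielectric cylinders (radii 5–10 um,
photoresist indices 1.5133 or 1.6285, imaged in air or immersion oil) have
exactly known geometry, which makes them a rare test bed for image-formation
models: every bright feature in the scan can be traced to a specific optical
path.  `confocyl` provides the two complementary models needed for that
exercise and the plumbing around them:

* an exact wave-optical reference for a **single** cylinder (Maxwell series
  plus a two-dimensional confocal imaging integral), and
* a geometric-optics **Monte Carlo** photon-transport engine that scales to
  multi-cylinder phantoms and reproduces each image feature mechanistically.

## Cylinder scattering series

For a plane wave normally incident on an infinite non-absorbing cylinder the
scattered field separates into two uncoupled polarisations (electric field
parallel or perpendicular to the axis).  `solve_cylinder()` computes the
series coefficients for both from the boundary conditions, using Bessel
functions of the first and second kind (Hankel functions of the first kind
with the $e^{-i\omega t}$ convention; `extinction_efficiency()` equals
`scattering_efficiency()` for these lossless media, which pins the sign
convention down).  The governing quantities are the size parameter
$x = 2\pi n_s r/\lambda_0$ — formed with the wavelength *in the surrounding
medium* — and the relative index $m = n_\mathrm{cyl}/n_s$, which may be
below 1 (resin in immersion oil).  The series is truncated at
$\lceil x + 4x^{1/3} + 2\rceil$ orders; doubling that changes the
efficiencies by less than $10^{-8}$ relative for every configuration used
here.

The angular amplitude $T(\theta) = c_0 + 2\sum_n c_n\cos n\theta$ (with
$\theta = 0$ forward) yields the two numbers that explain the penetration
behaviour of the phantoms:

```{r scattering}
# orders of magnitude between forward and backward scattering
forward_backward_orders(10, 552, 1.6285, 1.000)   # resin in air
forward_backward_orders(10, 552, 1.6285, 1.518)   # resin in oil
forward_backward_orders(10, 552, 1.5133, 1.518)   # near index match
```

As the index contrast shrinks, backward scattering collapses much faster
than the total scattering efficiency (which only drops about threefold for
the 10 um cylinder), so progressively more light reaches — and returns from —
deeper cylinders.

## Confocal imaging integral

`confocal_amplitude()` evaluates the detected amplitude of a single cylinder
over focus positions $(y, z)$ as a double midpoint Riemann sum over incident
and collected transverse wavenumbers inside the NA-limited band
$|k_y| \le k\,\mathrm{NA}$, with constant pupils, equal excitation and
collection paths, and the scattering amplitude taken at the angle between
the incident direction $(k_y, -k_z)$ and the collected direction
$(k_y', +k_z')$.  Two numerical choices deserve a note:

* **Midpoint nodes.** The integrand's $k_z = \sqrt{k^2 - k_y^2}$ varies
  steeply near $|k_y| = k\,\mathrm{NA}$ for high apertures; midpoint nodes
  avoid evaluating at the band edge.  With the default `n_k = 256` nodes per
  axis, doubling to 512 changes the normalised image by under 1 % RMS.
* **Axial phase sign.** Taking both axial roots positive makes the printed
  phase $z(k_z'-k_z)$ vanish for $k_y'=k_y$ and kills axial sectioning.
  Projecting the scattered field on the *conjugate* collection mode gives
  $z(k_z'+k_z)$ — the reflectance round trip ($e^{2ik_zz}$ for a planar
  mirror).  This is the default (`axial_convention = "roundtrip"`) and is
  validated by a structural test: the bright reflex of a cylinder of radius
  $R$ illuminated from $z=+\infty$ must sit at focus $z=+R$.  The literal
  reading stays available as `axial_convention = "literal"` for comparison.

Because the image of a large cylinder carries radius-sensitive interference
fringes, `radius_averaged_image()` averages the *intensities* (not
amplitudes — nominally identical prints are mutually incoherent) of 11
images spanning $\pm 0.25$ um around the nominal radius, emulating an
ensemble of prints.

A point worth stating explicitly, because it constrains what "the brightest
pixel" means: geometric optics predicts the **centre** of the cylinder to
outshine the **surface apex**.  At the apex every ray retro-reflects with
probability $R$ (the Fresnel reflectance), while at the centre every ray
meets the surface along its own normal and returns either directly ($R$) or
off the far wall ($T^2R$), totalling $\approx 2R$.  Both engines reproduce
this ratio (about 0.47 vs 1 in the radius-averaged wave image at NA 0.6);
scan displays are therefore normalised to the *surface* maximum when the
surface feature is the reference of interest (`normalise(..., "region")`).

## Phantom model

`generate_phantom()` rejection-samples non-overlapping cylinder centres
uniformly over the admissible region of a 200 × 200 um slab cross-section
until adding one more cylinder would exceed the target fill fraction
(default 10 %), or until 10^4 consecutive rejections — far below the jamming
regime, so the cap only matters for deliberately infeasible requests, which
return a partial phantom with a warning.  With this stopping rule a 10 %
target yields 12 cylinders of radius 10 um (fill 9.4 %) and 50 of radius
5 um; an exact count can be requested instead (`n_cylinders = 51` gives the
10.0 % fill used by the reference five-micron phantom).  Two frozen layouts
ship under `inst/extdata/` (files suffixed `-synthetic`); they are
regenerable from their recorded seeds and are *not* claimed to equal any
physically printed layout.  Sample tilt is modelled by `tilt_phantom()` as a
rigid rotation of the centres.  Support frames, substrate and surface
roughness of real prints are not modelled.

## Monte Carlo transport

Each pixel of a scan is an independent experiment: `n_photons` rays start on
the lens disc (placed $2f$ above the focus, diameter from `lens_diameter()`
to match the NA), converge on the geometric focus, and then alternate
straight free flight with specular interface events.  Volume scattering and
absorption are fixed to zero — the phantoms' contrast lives entirely at the
cylinder surfaces — and the engine validates nothing else is requested.
Choices that were genuinely open:

* **Launch density.** Start radii are sampled area-uniformly
  ($r_0 = r_\mathrm{lens}\sqrt{\xi}$), the distribution that makes the rays
  "evenly sampled in the lens plane"; a radius-uniform mode
  (`literal = TRUE`, density $\propto 1/r$) is kept selectable because the
  plain $r_0 = r_\mathrm{lens}\xi$ rule also appears in the literature.
* **Unpolarised stochastic branching.** At an interface the photon reflects
  with probability $R = (R_s+R_p)/2$ and refracts otherwise, with weight 1.
  This is unbiased, keeps the tally a plain count, and avoids path-splitting
  bookkeeping; polarisation is tracked only in the wave model.  A cap of 50
  interface events terminates pathological total-internal-reflection loops.
* **Detection.** A photon crossing the lens plane upward inside the aperture
  is mapped to the detection plane by the thin-lens ABCD step
  $\tan\alpha_2 = -p_1/f + \tan\alpha_1$, $p_2 = p_1 + 2f\tan\alpha_2$ per
  transverse axis (coordinates relative to the optical axis through the
  focus), and counted if it lands inside the pinhole radius.  A ray
  emanating exactly from the focal point maps to the pinhole centre
  identically — the property test asserts this to $10^{-9}$ um.
* **Reproducibility.** Randomness comes from a counter-based splitmix64
  stream seeded per pixel by `pixel_seed(base_seed, iy, iz)`, so pixels are
  independent of evaluation order and bit-reproducible; the same stream
  drives the phantom sampler.
* **2D mode.** For comparison with the two-dimensional wave model,
  `mode = "2d"` confines launch positions and directions to the y–z plane
  and tests only the y coordinate at the pinhole.

`intersect_ray_cylinder()` solves the ray–cylinder quadratic analytically;
hits closer than $10^{-6}$ um are ignored (self-intersection guard) and
near-tangent rays (discriminant $< 10^{-12}$) count as misses.  A
surface-marching oracle cross-checks hit/miss classification and distances
in the tests.

## What the axial reflexes mean

For a single 10 um cylinder of index 1.6285 in oil (NA 1.4, pinhole radius
0.72 um), an axial line scan beneath the cylinder shows discrete detected
maxima whose mechanisms the path dump (`collect_paths`) makes explicit:

* near $z \approx -12$ um (2 um below the lower surface): near-axial rays
  refract at the top surface, which images the nominal focus onto the lower
  surface, reflect there perpendicularly and retrace — by far the strongest
  subsurface feature in this model (detected fraction $\approx 10^{-3}$);
* near $z \approx -8$ um: rays entering and leaving through the *sides*
  reflect off the underside (detected fraction $\approx 5\times10^{-5}$);
* near $z \approx -4.5$ um: a similar lateral family at steeper internal
  angles;
* near $z \approx -19.5$ um: multiple internal reflections produce a weak
  focus-like spot, resolvable at a reduced aperture (NA 0.9) or elevated
  photon counts.

`axial_reflex_positions()` locates these as strict local maxima of the
3-sample-smoothed profile, ranked by *topographic* prominence (height above
the key saddle towards higher terrain).  Nearest-valley prominence would
fragment a noise-roughened bump into micro-peaks and is deliberately not
used.  The default prominence floor is five times a noise level estimated
from the lower quartile of the profile; for the weak lateral reflexes the
analyses here pass an explicit floor of $8\times10^{-6}$, about four times
the binomial standard error of the smoothed profile at the reflex level for
$3\times10^6$ photons per position.

## Post-processing

The evaluation pipeline applied to scans (simulated or measured) is
config-fixed in the order subtract → smooth → normalise → view:
`subtract_background_lines()` (per-line 5th percentile by default — robust
against sparse bright reflexes; `"min"` available), `moving_average()`
(odd window, shrinking at the edges; the mean is preserved exactly for
signals vanishing near the borders), `normalise()` (global or
region-referenced maximum), `upscale_cubic()` (separable natural splines,
exact on linear fields, clipped at zero), and `log_view()` with an optional
display gain reproducing the empirically determined compensation factors
used when comparing against attenuated measurements — a display device only,
never part of a quantitative result.

## Problem sizes and what the tests show

The shipped tests and the acceptance script run at desk scale: axial lines
of 41–66 positions at $10^6$–$3\times10^6$ photons per position and scan
rasters up to 121 line positions at $2\times10^5$ photons, a few minutes in
total on one core.  Full-field 201 × 201 rasters at $10^7$–$10^8$ photons
per pixel are reachable through the same API (`simulate_scan()` with a
larger grid and budget) but are multi-hour jobs.  The synthetic phantoms
emulate ideal geometry: perfectly smooth, perfectly parallel, fully dense
cylinders with no support structures or substrate.  Passing tests therefore
validate the *image-formation model* — launch, refraction, reflection,
detection, and the wave reference — not the unmodelled experimental effects
(surface roughness, frame shadowing, substrate reflections, aberrations)
that a real measurement adds on top.

## Known limitations

* Geometric optics in the MC: no diffraction or interference, so
  wavelength-scale structure (PSF widths, fringes) exists only in the wave
  model.
* The wave model is strictly two-dimensional and single-cylinder.
* Normal incidence only; cylinders are ideal, infinite along x and clipped
  by the scene bounds.
* Absorbing or coated cylinders, Gaussian-beam launch models and aberrated
  pupils are out of scope.
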