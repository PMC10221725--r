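Package: confocyl
Title: Ray and Wave Simulation of Confocal Reflectance Imaging of Cylinder Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates reflectance confocal laser scanning microscope (CLSM)
    images of microscopic phantoms built from parallel dielectric cylinders.
    Provides the Maxwell series solution for plane-wave scattering by an
    infinite cylinder at normal incidence (coefficients, angular amplitude
    functions, scattering efficiencies, forward/backward ratios), a
    two-dimensional confocal imaging integral driven by that solution, a
    generator for random non-overlapping multi-cylinder phantoms, a seeded
    ray-based Monte Carlo photon transport engine with Fresnel interfaces and
    an ABCD thin-lens pinhole detection model, and the post-processing steps
    used to evaluate simulated scans (normalisation, line background
    subtraction, moving average, cubic upscaling, logarithmic display).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
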