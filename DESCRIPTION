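Package: xscatter
Title: Quasi-Monte Carlo X-Ray Scatter Simulation for CT Geometries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates per-scatter-order X-ray scatter intensity images at a
    CT detector from a voxelized phantom using forced fixed detection
    variance reduction driven by scrambled Sobol' (quasi-Monte Carlo) or
    pseudorandom points.  Includes exact voxel ray tracing, Walker alias
    and rational inverse transform (RITA) samplers, Klein-Nishina and
    form-factor scatter physics on bundled attenuation tables, reference
    phantom builders, a deterministic Beer-Lambert primary projector, an
    analog Monte Carlo validation oracle, and evaluation metrics (relative
    difference, figure of merit, efficiency improvement factor).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
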