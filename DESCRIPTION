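Package: fppl
Title: Flexible-Pattern Particle Labeling for Bright Particles in Noisy Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects small bright particulate objects (such as calcified
    microspheres in backscattered-electron SEM images of cardiovascular
    tissue) in 8-bit grayscale micrographs. Implements a pattern-matching
    discriminant built around a 3x3 bright core, an ignored gap ring and
    eight peripheral blocks, scanned pixel by pixel over an image pyramid so
    that particles of widely varying size, shape and brightness are labeled
    by a single pattern. Also provides classic baseline detectors
    (threshold-based particle labeling with optional rolling-ball background
    subtraction or Sobel edge enhancement, and multi-template matching with
    a normalized L1 similarity), point-set evaluation of detections against
    manually marked references (detection, false-negative and
    false-positive rates), and deterministic synthetic micrograph
    generators with exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    png,
    tiff,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
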