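Package: facersa
Title: Face-Space Encoding Models and Representational Similarity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and model-comparison pipeline for norm-based
    face-space representations. Builds polar-grid stimulus sets on random
    2D slices through a high-dimensional reference face space; predicts
    representational distance matrices and regional-mean activation
    profiles from sigmoidal-ramp, Gaussian- and inverted-Gaussian-exemplar,
    and Gabor-filter encoding models with a measurement-level
    population-averaging mechanism; estimates cross-validated
    (crossnobis) discriminant distances from noisy run-wise pattern
    estimates with shrinkage noise-covariance; and adjudicates between
    models with multiple-regression RSA, noise ceilings, and grid-search
    fitting under leave-one-participant-out cross-validation. Includes
    generators for counterbalanced (De Bruijn) trial sequences,
    pair-of-pairs similarity judgments, and synthetic participants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
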