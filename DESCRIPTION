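Package: dryvision
Title: Machine-Vision Monitoring and Moisture-Ratio Modeling of Microwave Drying
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Online machine-vision analysis of food drying image sequences.
    Segments bright samples on a dark background by metric histogram
    thresholding, labels and hole-fills particles, filters dust, and
    quantifies area shrinkage as an area-ratio time series. Tracks dry-basis
    moisture content and moisture ratio from a parallel weight series, and
    models the relation between area ratio and moisture ratio with an
    extreme learning machine (random hidden layer, pseudoinverse output
    weights) or a small feedforward neural network trained by
    Levenberg-Marquardt with weight decay and early stopping. Includes a
    synthetic drying-run generator (shrinking disks with bubbles and dust,
    Page-law moisture kinetics) for validation and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, png, jsonlite, yaml, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
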