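Package: alpinepheno
Title: Phenology and Root Growth Analysis for Alpine Grassland Season-Manipulation Experiments
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing above- and belowground phenology of alpine
    grassland under experimentally advanced growing seasons. Computes canopy
    greenness (green chromatic coordinate) from RGB photographs, processes
    mini-rhizotron scan stacks (destriping, normalization, phase-correlation
    alignment, tiling, classical root segmentation, root area and diameter
    quantification), extracts phenological timepoints from penalized-spline
    smoothers (onset, peak, 50 percent decline, growth quantiles, maximum
    rate, area under the curve), derives growing-season windows and
    growing-degree-hours from soil-temperature logs, computes a
    photosynthetic vigour index, and provides the group-contrast statistics
    used in such studies. A synthetic-data generator with known ground truth
    emulates the study design so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mgcv,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    jpeg,
    yaml,
    optparse
Config/testthat/edition: 3
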