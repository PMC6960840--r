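Package: ddsr
Title: Hyperspectral Image Classification by Diverse Density and Sparse
    Representation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised classification of hyperspectral reflectance cubes
    under small training-sample conditions. A representative spectrum
    (dictionary atom) is learned per ground-cover class by maximizing a
    multiple-instance diverse-density objective with a noisy-OR bag model;
    each pixel is then decomposed over the learned dictionary with a
    sign- and simplex-constrained matching pursuit, and classified by a
    hybrid coefficient-threshold / minimum-residual decision rule.
    Includes ENVI-format cube input/output, a synthetic scene simulator
    with known ground truth, accuracy/kappa evaluation, and a
    PCA-plus-minimum-distance baseline classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse
Config/testthat/edition: 3
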