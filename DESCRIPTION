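Package: campwave
Title: Quantification of Intracellular cAMP and Calcium Wave Propagation in Giant Amoeboid Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for fluorescence biosensor time-lapse recordings
    of enlarged (multinucleated) Dictyostelium discoideum cells: inverted and
    min-max intensity normalization, ratiometric shading correction, region and
    kymograph extraction, logistic (sigmoid) fitting of activation and decay
    kinetics, grid-based half-time mapping, finite-difference gradient direction
    analysis, and one-dimensional wave-propagation velocity estimation. Includes
    a discrete-time stochastic cell growth and division (sizer) model and a
    synthetic movie generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    yaml,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
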