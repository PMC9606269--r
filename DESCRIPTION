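Package: photobleachr
Title: Single-Molecule Photobleaching Step Analysis and Subunit Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for determining membrane-receptor oligomer
    stoichiometry from single-molecule TIRF photobleaching experiments.
    Simulates movies of immobile fluorescently labeled receptor particles
    with known stoichiometry, detects diffraction-limited spots with an
    a trous B3-spline wavelet filter refined by 2D Gaussian fits, links
    detections into tracks and extracts background-subtracted intensity
    traces, counts photobleaching steps by penalized change-point fitting,
    and inverts the observed step histogram through a binomial
    incomplete-labeling model (non-negative least squares) to recover the
    true monomer-through-pentamer particle distribution, subunit-level
    fractions, and receptor-density summaries with bootstrap uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
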