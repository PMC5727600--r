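Package: disectr
Title: Design-Based Stereology with the Physical Disector and Fractionator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for design-based stereological estimation of total particle
    number and regional volume from serially sectioned tissue, built around the
    physical disector applied in a fractionator design. Implements the unbiased
    counting-frame rule with extended exclusion lines, bidirectional disector
    counting on aligned section pairs, systematic uniform random sampling (SURS)
    of sections and X-Y frame grids, fractionator number estimation, Cavalieri
    point-counting volume estimation, and the coefficient-of-error machinery for
    systematic sampling (noise, A/B/C product sums, Var_SURS, CE, group-level
    variance decomposition). Includes rigid self-similarity alignment of section
    image pairs with a manual-override path, and a synthetic 3D particle phantom
    simulator with known ground truth for Monte Carlo validation of every
    estimator.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
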