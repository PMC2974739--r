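Package: biionic
Title: Biionic GHK Permeability and Voltage-Dependent Block Analysis for
    Two-Electrode Voltage-Clamp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates and analyses two-electrode voltage-clamp (TEVC)
    recordings from Xenopus laevis oocytes expressing glutamate-gated ion
    channels. Implements the biionic Goldman-Hodgkin-Katz (GHK) equation for
    the permeability of Ca2+ relative to lumped intracellular monovalent
    cations, its algebraic inverse for calibrating the intracellular
    monovalent concentration from a reference channel, reversal-potential
    estimation from background-subtracted current-voltage ramps with junction
    potential correction, Woodhull-style voltage-dependent open-channel block,
    percent-block quantification of timed agonist/Mg2+ applications, the
    leak-current decomposition of apparent block exceeding 100 percent, and a
    synthetic TEVC sweep generator that provides ground truth for
    parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
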