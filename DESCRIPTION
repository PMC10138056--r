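Package: cherrymeta
Title: Cherry-Picking Vulnerability Diagnostics for Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Inverse-variance fixed-effect and random-effects meta-analysis
    (DerSimonian-Laird between-study variance), together with diagnostics
    that quantify how vulnerable a pooled one-sided conclusion is to
    cherry-picking of studies: greedy and exhaustive top-S subset selection
    that forces (non)significance, closed-form bounds on the number of
    selected studies for which such manipulation succeeds with stated
    probability, Monte Carlo estimation of false-conclusion proportions over
    scenario grids, conversion of 2x2 contingency tables to log odds-ratio
    studies, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
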