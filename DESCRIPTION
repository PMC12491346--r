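Package: fetcea
Title: Cost-Effectiveness Analysis of Amino-Acid PET Decision Trees for
    Treatment-Related Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic modelling of the cost-effectiveness of adding
    O-(2-[18F]fluoroethyl)-L-tyrosine (FET) PET to MRI in the follow-up of
    treated pediatric CNS tumors. Implements two diagnostic decision trees
    that score each imaging strategy by its probability of correctly
    identifying treatment-related changes, builds per-scan and per-lesion
    imaging costs from itemized fee-schedule entries, and computes
    incremental and plain cost-effectiveness ratios (ICER, CER). Robustness
    is assessed by one-way deterministic sensitivity analysis with
    tornado-ordered output and by Monte Carlo probabilistic sensitivity
    analysis with positive-truncated normal chance-node draws and
    gamma-distributed costs. A synthetic lesion-cohort generator and exact
    study fixtures make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
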