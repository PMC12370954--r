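Package: selfthin
Title: Climate-Sensitive Self-Thinning Analysis for Even-Aged Forest Stands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate static and dynamic (growth-mortality
    allocation) self-thinning models from permanent-plot forest inventories,
    derive carrying-capacity climate sensitivities with uncertainty
    propagation, analyse the relative size of dying trees (k factor), and
    project warming impacts on stand density and carbon stock. Includes a
    synthetic even-aged stand-dynamics generator with known truth parameters
    for end-to-end testing, negative-binomial mortality GLMMs with growth and
    count offsets, and leave-one-plot-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    glmmTMB,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
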