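Package: stat1ple
Title: Identifiability and Sensitivity Analysis of IFN-gamma Induced STAT1
    Signalling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delay differential equation model of interferon-gamma induced
    STAT1 signalling in pancreatic stellate and cancer cells, with chi-squared
    parameter estimation by hybrid simulated-annealing/quasi-Newton multistart,
    profile-likelihood identifiability analysis with pointwise and simultaneous
    confidence intervals, randomized-data overfitting analysis with effective
    degrees of freedom, profile-based trajectory uncertainty bands, and
    time-dependent metabolic control coefficient sensitivity analysis. Includes
    a synthetic time-series generator emulating sparse immunoblot and
    immunofluorescence designs for the two cell-type regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
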