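Package: chronotox
Title: Coupled Core-Clock and Irinotecan PK-PD Modelling for Treatment Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and fitting a coupled model of the mammalian
    core circadian clock and cellular irinotecan pharmacokinetics and
    -dynamics in colorectal cancer cell lines. Provides a transcription-
    translation ODE network for core-clock and drug-metabolism genes with
    light/Zeitgeber forcing, CMA-ES parameter estimation with LASSO-
    regularized knock-out fitting, circadian cytotoxicity profile prediction
    from dead-cell dynamics, phase-response analysis for Zeitgeber pulses,
    and a synthetic circadian expression generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
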