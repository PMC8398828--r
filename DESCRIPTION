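Package: ussingr
Title: Simulation and Analysis of Ussing-Chamber Permeation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ex vivo Ussing-chamber experiments that follow
    the absorption and intestinal biotransformation of natural products by
    LC-MS metabolite profiling. Provides a compartmental kinetic simulator of
    the donor/membrane/acceptor system (passive permeation, tissue deposition,
    O-glycoside hydrolysis, hydroxylation, aliquot sampling with buffer or
    stock replacement, lognormal measurement noise with limit-of-detection
    censoring, and TEER viability traces), readers and writers for aligned
    LC-MS feature tables, targeted feature matching by m/z and retention time,
    semi-quantitative compartment ratios, external-calibration quantification
    with ICH Q2(R1) detection limits, apparent-permeability and transport-index
    metrics with sampling-volume correction, and rule-based classification of
    each compound's fate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
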