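Package: blindex
Title: Blinding Assessment for Sham-Controlled Randomised Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing blinding success in two-arm randomised
    controlled trials with a five-level intervention-perception instrument.
    Computes arm-specific Bang blinding indices with Wald confidence
    intervals, the summed study-level Bang index, and a weighted James
    blinding index with percentile-bootstrap intervals, together with
    adequacy classifications. Includes a brute-force reconstruction oracle
    that recovers collapsed response counts from published point estimates
    and confidence intervals, precision-based design calculations
    (confidence-interval half-width versus sample size), descriptive
    statistics and Welch unequal-variance mean-difference intervals for
    secondary outcomes, and a synthetic trial generator with stratified
    permuted-block randomisation, parameterised guess behaviour and normal
    range-of-motion outcomes. An end-to-end pipeline ingests respondent-level
    CSV data and renders a trial-report table as JSON, text or markdown.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
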