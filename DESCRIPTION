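Package: rpgrowth
Title: Dental Biorhythm (Retzius Periodicity) and Adolescent Growth Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links a long-period dental biorhythm, the Retzius periodicity (RP)
    estimated from primary-molar enamel histology, to longitudinal adolescent
    anthropometry. Provides RP estimation by cross-striation counting and by the
    daily-secretion-rate ratio method with the two-matching-estimates inclusion
    rule; robust fixed-bandwidth kernel-weighted local cubic growth-curve
    smoothing with velocity curves and four-level maturity staging; LMS
    BMI-for-age z-scores and percentiles; interval gains and seasonal/lockdown
    period labelling; a statistics suite (quadratic regression of log gains on
    log RP, Kruskal-Wallis with Dunn post-hoc comparisons, partial correlation,
    2x2 contingency relative risk, standardised betas, Bonferroni adjustment);
    a synthetic cohort generator with Preece-Baines growth curves and matching
    simulated histology; and a pipeline that assembles a full analysis report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
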