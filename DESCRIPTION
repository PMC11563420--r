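Package: crcscreen
Title: Microsimulation Cost-Utility Analysis of Targeted Bowel Cancer
    Screening Recruitment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov microsimulation of colorectal cancer natural history
    (adenoma-carcinoma pathway) and participation in Australia's National
    Bowel Cancer Screening Program, built to evaluate tailored recruitment
    interventions for Arabic- and Mandarin-speaking communities. Simulates
    biennial immunochemical faecal occult blood test screening, colonoscopy
    follow-up and surveillance, stage-specific survival, and background
    mortality in annual cycles; attaches 2019 Australian-dollar costs and
    utility weights to simulated histories; and reports incremental
    cost-effectiveness ratios (cost per quality-adjusted life year) with
    probabilistic sensitivity analysis, discount-rate sensitivity analysis,
    and registry-style validation. Includes an interrupted-time-series
    effectiveness stage that turns screening-register style monthly kit
    counts into participation uplift scenarios, and synthetic-data
    generators for census populations, survival tables, life tables, and
    monthly kit-return series.
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
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
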