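Package: mycotrace
Title: Dual Carbon-13/Nitrogen-15 Label Tracing in Mycorrhizal Plant-Soil Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of dual 13C-CO2 / 15N pulse-chase labeling
    experiments in ectomycorrhizal plant-soil systems. Provides isotope
    notation conversions and atom-percent-excess arithmetic, whole-system
    label budgets across plant, soil and litter pools, phospholipid fatty
    acid (PLFA) stable-isotope-probing mass balance with biomarker group
    assignment, chloroform-fumigation-extraction microbial biomass
    calculations, NanoSIMS multilayer ion-count stack processing with
    region-of-interest Poisson counting statistics, nonparametric community
    statistics (rank tests, Dunn post-hoc, correspondence analysis, ANOSIM),
    and a seeded synthetic-data generator that emulates the full experiment
    for testing and power analysis.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
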