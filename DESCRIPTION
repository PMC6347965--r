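Package: lfqfit
Title: Length-Frequency Stock Assessment for Trapped Crustacean Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Length-based population-dynamics analysis for commercially trapped
    crustaceans, built around cephalothorax-length frequency data. Implements
    ELEFAN (electronic length frequency analysis) with moving-average
    restructuring and growth-curve scoring, von Bertalanffy growth parameter
    search by simulated annealing and by a genetic algorithm, Powell-Wetherall
    estimation of Z/K and asymptotic length from pooled lengths, the standard
    decomposition of total mortality into natural and fishing components with
    the exploitation rate, reproductive and effort indices (GSI, HSI, CPUE,
    fecundity, sex-ratio tests), and an individual-based population simulator
    with pulsed recruitment and trap size-selectivity so that every estimator
    can be validated against known truth. Length-frequency matrices are stored
    as SummarizedExperiment objects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'growth.R'
    'elefan.R'
    'lfqfit-package.R'
    'mortality.R'
    'repro.R'
    'records.R'
    'pipeline.R'
    'plot.R'
    'simulate.R'
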