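Package: lynxrescue
Title: Genetic Monitoring and Individual-Based Modelling of Genetic Rescue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genetic monitoring of small, reintroduced carnivore
    populations and for planning genetic rescue by translocation.  Provides
    microsatellite genotype input/output (long-table CSV and GenePop),
    diversity statistics (observed and Nei's unbiased expected
    heterozygosity, allelic diversity, Fis), effective inbreeding relative
    to a source population with a travelling-window temporal series,
    dosage-based PCA, and a bias-corrected linkage-disequilibrium estimator
    of effective population size with jackknife confidence intervals.  A
    forward-time, overlapping-generation individual-based simulator couples
    Mendelian inheritance and pedigree identity-by-descent with an
    inbreeding-load survival model (lethal equivalents), carrying capacity
    and translocation events; founder calibration, translocation-scenario
    optimisation and a random-forest sensitivity metamodel are built on top
    of it.  Developed around the Dinaric Eurasian lynx reinforcement as the
    motivating case.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    lhs
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
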