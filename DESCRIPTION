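Package: palaeometab
Title: Metabolic Physiology of Fossil Mammaliaforms from Cementochronology,
    Allometry and Phylogenetic Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring basal and maximum metabolic physiology of
    fossil mammaliaforms from tooth-cementum increment counts. Aggregates
    multi-observer increment-count tables into maximum-lifespan estimates with
    observer-agreement statistics, estimates body mass from dentary and skull
    allometry, fits phylogenetic generalized least squares (PGLS) regressions
    with Pagel's lambda and nested phylogenetic ANCOVA model ladders to extant
    trait data, projects fossil lifespans onto those regressions to estimate
    mass-specific standard metabolic rate and postnatal growth constants, and
    computes the femoral nutrient-foramen blood-flow index. A synthetic-data
    module generates phylogenies, phylogenetically correlated trait tables,
    observer-noisy increment tables and foramen sets with known ground truth
    for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
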