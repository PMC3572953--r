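Package: ahrgwas
Title: Cross-Species Association Mapping of Airway Hyperresponsiveness
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating a mouse inbred-strain survey of baseline
    airway hyperresponsiveness (AHR) with human asthma genome-wide association
    studies. Computes dose-response slope phenotypes, runs kinship-corrected
    mixed-model association across strains (restricted maximum likelihood over
    the residual/genetic variance ratio), maps nominally associated mouse
    genes onto human orthologs through a homology map, screens multi-ancestry
    human GWAS summary statistics over ortholog gene windows, and combines
    evidence across replication studies with direction-aware one-sided
    p-values, Fisher's combined probability method, and sample-size-weighted
    z-score meta-analysis. Includes a seeded synthetic-data generator with
    recorded ground truth so the full pipeline is testable without access to
    the original cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
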