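Package: toxra
Title: Guided Read-Across, Study Reliability and TTC Workflows for
    Chemical Safety Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analogue-based chemical safety assessment:
    compound registries with structure handling, molecular descriptor
    computation and standardisation, structure- and property-based
    similarity measures combined into an Analogue Quality score,
    structural-alert (chemotype) profiling with endpoint enrichment
    z-scores, study reliability scoring from minimum-inclusion-criteria
    rule outcomes and expert Opinion Scores, weight-of-evidence
    read-across reliability via joint probability and Dempster-Shafer
    combination, NOAEL bound estimation from structural nearest
    neighbours, and a non-cancer Threshold of Toxicological Concern
    (TTC) decision tree with cohort-of-concern and organophosphate
    branches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
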