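Package: procpharm
Title: Process-Pharmacology Drug Repurposing via Gene Ontology Process Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes a trait-associated gene set by Gene Ontology
    over-representation analysis and functional abstraction, projects drugs and
    a virtual trait drug into a shared space of biological processes via
    drug-target and gene-process incidence matrices, prunes candidates by
    nested computed ABC analysis of reciprocal Euclidean distances, and
    extracts the U-matrix watershed cluster of an emergent self-organizing map
    (toroid grid) that contains the virtual drug as the repurposing candidate
    list. Includes a synthetic-data generator with a planted process signature
    and drug cluster for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
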