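Package: mfclone
Title: Clonal Relatedness Analysis of Multifocal Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decide whether the tumor nodules of a multifocal
    cancer patient arose from a single disseminating clone (intrahepatic
    metastasis, IM) or from independent tumorigenesis (multicentric
    occurrence, MO). Implements a frequency-weighted clonality score on
    shared somatic variants with a cohort-frequency permutation null,
    patient-level IM/MO/mixed classification, construction of tumor units
    (clonally related sets versus solitary tumors) with union/max-deviation
    aggregation of mutations and copy number, a pair-class similarity
    framework (clonal versus non-clonal versus inter-patient biopsy pairs),
    group-comparison statistics, and a synthetic multifocal-cohort
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
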