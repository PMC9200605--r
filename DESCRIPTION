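Package: subgofa
Title: Sub-Ontology Functional Analysis of Clonal Mosaicism Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Segments the Gene Ontology into rooted sub-ontologies, measures
    information-content (Lin) semantic similarity between patients' mosaic
    chromosomal-alteration derived GO annotation sets within each
    sub-ontology, clusters patients by Ward's method, and flags sub-ontology
    roots whose two-group partition separates cases from controls (Fisher's
    exact test with Benjamini-Hochberg FDR). Includes the conventional
    per-gene and per-term Fisher baselines, a disease-gene detection-ratio
    evaluation, and seeded generators for synthetic ontologies, gene tracks,
    annotation maps and case/control mosaicism cohorts with a planted
    functional signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
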