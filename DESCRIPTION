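Package: toxaudit
Title: Toxin Annotation and Proteome-Referenced Auditing for Venom-Gland
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Homology-based toxin annotation of venom-gland transcriptomes
    and a proteome-referenced audit of its accuracy. Implements exact
    Smith-Waterman protein search with Karlin-Altschul E-values against
    toxin databases of three relatedness tiers, signal-peptide and
    deduplication post-processing of translated open reading frames,
    FPKM-based comparative expression filtering between venom gland and a
    control tissue, neighbor-joining family trees with clade-level evidence
    propagation, and set-based evaluation (Venn regions, false-positive
    rates vs. the venom proteome, family-diversity profiles,
    precision/recall against ground truth, intraspecific cluster overlap).
    A synthetic-data generator simulates toxin gene families on birth-death
    trees with venom-gland-biased expression and expression-dependent
    proteomic detection, so the whole pipeline is testable end to end with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
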