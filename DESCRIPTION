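Package: crisprtriage
Title: Discriminating CRISPR/Cas9 Off-Target Mutations from Inherent and
    Somaclonal Variation in Edited Plant Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A genome-wide pipeline for separating bona fide CRISPR/Cas9
    off-target mutations from pre-existing (maternal) variation and
    somaclonal (tissue-culture) variation in whole-genome-sequenced cohorts
    of edited plants. Enumerates candidate off-target sites for each guide
    (up to five protospacer mismatches; NGG/NAG/NGA PAM classes), scores
    them with a position-weighted specificity model, hard-filters variant
    calls, performs the wild-type/negative/edited cohort set arithmetic
    that isolates private variants, attributes private variants to sites
    through flanking windows, re-assesses every site on a variant-applied
    ("personalized") genome to detect PAM creation and destruction,
    estimates per-site mutation rates, and classifies the inheritance of
    edits across generations. A seeded synthetic-cohort simulator with a
    machine-readable truth table makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    knitr,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
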