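Package: aexapr
Title: Quadrant Classification of Aggregation-Prone Regions in Therapeutic Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physicochemical classification of short peptide stretches that
    nucleate aggregation of therapeutic proteins (aggregation-prone regions,
    APRs). Ships a curated reference set of 84 APR peptides, 22 tregitopes and
    42 tregitope-derived control 5-mers with eight sequence-level descriptors;
    implements the AEx scoring expression
    Ln(AM - IP + AC x ROT) - (QPCaco - NON), the four-class quadrant rule on
    the (QPlogS, AEx) plane, and Cooper validation statistics
    (sensitivity, specificity, accuracy, predictivity). Recovers per-residue
    descriptor tables from the sequence-level reference values by
    minimum-norm least squares, which turns the classifier into a
    sliding-window scanner for arbitrary protein sequences in FASTA.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    vctrs,
    withr,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
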