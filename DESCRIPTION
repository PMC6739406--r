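Package: xcimir
Title: Discovery and Prioritization of X-Linked microRNAs Escaping X Inactivation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A database-style desk pipeline for identifying X-chromosome
    microRNAs that putatively escape X-chromosome inactivation (XCI) and
    prioritizing them by target and pathway evidence. Classifies X-linked
    genes as XCI escapers under two evidence dialects (hybrid-line expression
    counts and Xi/Xa allelic expression ratios), normalizes gene symbols
    against an HGNC-style map, reconciles escaper sets, maps miRNA loci into
    escaper gene bodies by interval containment, applies a tissue-specific
    escape filter, tests validated target sets for pathway over-representation
    with a hypergeometric test and Benjamini-Hochberg adjustment, and ranks
    candidate miRNAs. Also implements the validation-arm arithmetic:
    2^-ddCt relative quantification with dual reference normalization and
    median-fluorescence-intensity ratios. A seeded synthetic-data module
    generates every input table, including a deterministic reference fixture,
    so the whole pipeline runs and is verified offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    fgsea,
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
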