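Package: varthresh
Title: Evidence-Based Tailoring of Variant-Effect-Predictor Thresholds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating variant-effect-predictor score thresholds
    against clinical phenotype labels of Mendelian-disease missense variants.
    Implements a clinical classification key for disease-associated (DAV),
    partial-phenotype and no-phenotype-associated (NPAV) variants, curation
    exclusion filters, orientation-aware general and gene-specific dual
    thresholds (median +/- 2 SD), multi-predictor consensus calls, weighted
    mean rescaling, Grantham Variation (GV) conservation scoring of protein
    multiple sequence alignments, between-group sequence divergence with
    bootstrap standard errors, genetic-code enumeration of theoretical
    single-nucleotide-accessible substitutions, and a percentile-based scan
    for variants under negative selection.  Seeded synthetic-data generators
    allow every stage to be exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
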