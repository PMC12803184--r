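Package: acetylatlas
Title: Multi-Tissue Acetylome Site Quantification, Enrichment and Structural Context
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-search analysis of immunoenriched acetyl-lysine proteomics
    site reports from multi-tissue DIA experiments. Applies localization and
    q-value identification filters, collapses peptide evidence to unique sites,
    builds log2 abundance matrices with tissue-level median normalization and
    left-shifted Gaussian (missing-not-at-random) imputation, summarizes and
    standardizes tissue-by-sex profiles, clusters sites with per-group Fisher
    over-representation, selects variably enriched ontology terms with overlap
    and parent-child pruning, extracts flanking-sequence motif logos against an
    all-lysine proteome background, computes per-residue model confidence
    (pLDDT) and Shrake-Rupley solvent-accessible surface area from predicted
    structures, and maps sites to human clinical variants with abundance-rank
    fold enrichment. Includes a seeded synthetic-data generator that emulates
    the full study design with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
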