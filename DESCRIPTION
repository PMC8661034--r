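Package: derivtree
Title: Transcriptomic Derivedness Indices for Cross-Species Embryonic Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how far embryonic transcriptomes have diverged from a
    common ancestor. Builds ortholog-group expression tables from per-species
    gene-level TPM tables (aggregating paralogs, zero-filling lost genes),
    scans combinations of normalization, distance and distance-tree inference
    methods against three explicit selection criteria (species monophyly,
    consistency with a reference species phylogeny, and gray-level
    co-occurrence smoothness of within-species distance images), extracts
    per-embryo derivedness indices as branch lengths from the inferred
    ancestral node, summarises them over replicate-resampled (BRI) trees with
    consensus supports, and identifies derivedness-correlative ortholog-groups
    with category, temporal-pleiotropy and enrichment summaries. Includes a
    seeded synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
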