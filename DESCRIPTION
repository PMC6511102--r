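Package: parazburden
Title: Paralog Conservation Z-Scores and Regional Missense Burden for
    Protein-Coding Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variant-level computations for protein genotype-phenotype
    studies of the syntaxin-1B type: parsing and classification of
    protein variants in HGVS p. notation, sliding-window mutational
    density of population variant positions over a coding sequence with
    projection to amino-acid coordinates, per-residue paralog
    conservation z-scores (para_zscore) from a paralog-family multiple
    sequence alignment, and regional enrichment testing of patient
    versus population missense positions (Fisher's exact test,
    permutation test, and rank-sum comparison of conservation scores).
    Includes a seeded synthetic-data generator for paralog families and
    variant cohorts with planted ground truth, so every pipeline stage
    is verifiable without external variant databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
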