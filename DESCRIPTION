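Package: sigoverlap
Title: Rank-Based Overlap Testing of Differential Expression Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds differentially expressed gene signatures from two-group
    log2 expression matrices using the signed fold-change convention
    (ratio r for r >= 1, -1/r otherwise), maps signatures across species
    through orthologue tables, and tests the overlap of two ranked
    signatures with a running Fisher procedure: repeated one-sided
    hypergeometric tails over matched ranked prefixes, summarised as a
    single corrected p-value, with a four-way directional decomposition
    (up/up, down/down, up/down, down/up). Concordant gene sets can then be
    partitioned across three cell-type developmental signatures into Venn
    regions with contribution percentages and direction-concordance
    counts. A seeded synthetic-data generator with planted shared
    programs makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
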