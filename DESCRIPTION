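Package: mirslice
Title: miRNA Curation, Cleavage-Target Prediction and Conservation in Cnidarians
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates candidate microRNA precursors against structural and
    read-support criteria (2-nt 3' overhang, 5'-end read homogeneity,
    mature/star complementarity, read depth, shuffle-based fold significance),
    predicts highly complementary mRNA target sites of the plant-like,
    slicing kind found in cnidarians, verifies sites with degradome (PARE)
    cleavage evidence under the exact 10-bp offset geometry of
    Argonaute-mediated slicing, and quantifies cross-species conservation and
    turnover of both miRNAs and their target sites (reciprocal-best-hit
    orthology, category I/II/III target classification, substitution
    profiles, Dollo parsimony gain/loss reconstruction, turnover rates).
    Ships a synthetic-data generator with ground truth known by construction
    for every pipeline input.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
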