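Package: wcsea
Title: Weighted Concept Signature Enrichment Analysis for Pathway Discovery
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deep pathway-enrichment analysis for weighted (WCSEA) and
    unweighted (CSEA) gene lists, designed to tolerate the high noise and
    dropout rates of single-cell transcriptomics. Every gene in the genome
    is scored for functional relatedness to the input list via a penalized
    cumulative molecular-concept signature (the uniConSig score), and
    pathway enrichment is then tested on the concept-signature-sorted
    genome with a weighted Kolmogorov-Smirnov statistic and permutation
    normalized enrichment scores. Includes crosstalk disambiguation of
    overlapping pathways, CSEA-based pathway-pathway association matrices
    with network export, a synthetic fixture generator with planted
    signal, and a dropout-simulation benchmark of rank stability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
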