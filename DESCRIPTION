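Package: polyfam
Title: Gene-Family Characterization in an Allohexaploid Genome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a genome-wide gene-family
    characterization workflow for allohexaploid wheat: homology-hit and
    domain-evidence membership filtering with chromosomal-order naming and
    protein statistics (molecular weight, isoelectric point); 1:1:1 homoeolog
    triad detection and per-tissue expression-bias classification by Euclidean
    distance to seven archetypes with ternary coordinates; expressed-gene
    calls, k-means tissue-preference clustering and stress log-ratios; tandem
    duplication clustering, chromosomal-segment enrichment tests and
    Nei-Gojobori (1986) Ka/Ks; miRNA target scoring with degradome cleavage
    grading; replicate-reproducible ChIP-seq peak derivation and gene-body
    mark assignment. A synthetic-data module generates every input with
    planted ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer,
    withr
Config/testthat/edition: 3
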