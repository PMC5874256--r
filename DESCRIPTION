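Package: evnet
Title: Enhancer-Variant Integration and Regulatory Genomics Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates GWAS variant panels with lineage-specific enhancer
    landscapes defined from transcription-factor and histone-mark ChIP-seq
    peaks. Provides an interval engine with nearest-TSS gene annotation,
    position-weight-matrix motif scanning with variant-centered positional
    density profiles, hypergeometric and permutation-based gene-set
    enrichment (GSEA), peak-centered tag-density matrices with centered
    K-means clustering, ROSE-style superenhancer stitching and rank-cutoff
    calling, cross-species expression-kinetics filtering, and a synthetic
    data generator that emulates the statistical structure of all inputs
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    igraph,
    withr
Config/testthat/edition: 3
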