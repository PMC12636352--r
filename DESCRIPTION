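Package: kmerbash
Title: K-Mer Based In Silico Promoter Bashing for Pan-Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links intraspecies promoter sequence variation to gene expression
    variation across a pan-genome. Promoter alleles of each pangene are
    decomposed into k-mers, near-identical k-mers are grouped into
    one-mismatch clusters, and cluster occurrence counts are jointly
    regressed on expression with a spike-and-slab Bayesian variable
    selection model fitted by Gibbs sampling. Posterior inclusion
    probabilities with a local false discovery rate rule prioritise
    candidate cis-regulatory k-mer clusters, which are then refined to
    putative functional sites by per-pangene regression. Companion tools
    compute alignment-free promoter similarity, expression variability with
    running-median normalisation, cross-validated selection of the k-mer
    size, position-weight-matrix enrichment with an exact-p scanner,
    peak-overlap enrichment, and a synthetic pan-genome generator with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    utils,
    methods,
    Matrix,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
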