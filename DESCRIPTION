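Package: isoquantr
Title: Isoform Expression Estimation from RNA-Seq Segment Counts with
    Positional Bias Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood estimation of alternative-splicing isoform
    expression from RNA-seq alignments. Genes are partitioned into disjoint
    exonic segments, per-segment read counts are modelled as independent
    Poisson variables, and non-uniform positional read distributions are
    corrected with nonparametric bias curves (a global curve pooled over
    single-isoform genes and a local per-gene curve) that reweight the
    gene-structure indicator matrix. The concave log-likelihood is maximized
    by coordinate-wise binary search on the gradient. Includes a seeded
    single-end read simulator with configurable positional bias that writes
    SAM/GTF/ground-truth fixtures, and a major-isoform recovery rate (MIRR)
    evaluation of estimates against simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
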