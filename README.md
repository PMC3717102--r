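# isoquantr

Isoform-level expression estimation from RNA-seq alignments, for
transcriptomics analysts who have genome-mapped reads (SAM) and a gene
annotation (GTF or refFlat) and want per-isoform expression with
correction for non-uniform positional read distributions.

## The model

Each gene is partitioned into disjoint exonic **segments** — maximal
intervals with constant isoform membership — described by lengths
`l_j` and a 0/1 inclusion matrix `a_ij` over the gene's `m` isoforms.
The read count of segment `j` is Poisson with rate

```
lambda_j = l_j * w * sum_i b_ij * theta_i
```

where `theta_i` is the expression of isoform `i`, `w` the library read
total, and `b_ij` a *weighted* structure matrix: the indicator `a_ij`
reweighted by two nonparametric positional bias curves — a **global
bias curve** estimated from single-isoform genes, shared by the whole
library, and a per-gene **local bias curve** estimated from
constitutive segments — mixed as
`b_ij = alpha * GBM_ij + (1 - alpha) * LBM_ij`. The concave
log-likelihood is maximized by **coordinate binary search**: bisection
on each monotone partial gradient, at most `ceil(log2((hi-lo)/eps))`
iterations per 1-D search, with a pattern-move acceleration along each
sweep's displacement. Estimates are reported as `theta` and
`RPKM = theta * 1e9`. Accuracy against simulated ground truth is scored
by the **major isoform recovery rate (MIRR)**: the fraction of genes
whose most-expressed isoform is correctly identified.

A seeded simulator generates matching fixtures (GTF annotation,
single-end biased or uniform reads as valid SAM, and a ground-truth
expression table), so the whole method is testable end to end without
external data.

## Worked example

```r
library(isoquantr)

# 20 genes on a synthetic chromosome: 5 single-isoform (bias
# calibration), 15 with a cassette exon; 200k uniform 75 bp reads
ann <- simulate_annotation(n_genes = 20,
                           isoforms_per_gene = c(rep(1, 5), rep(2, 15)),
                           seed = 101, gtf = "example.gtf")
sim <- simulate_reads(ann$models, n_reads = 2e5, sam = "example.sam",
                      seed = 102, truth = "truth.tsv")

est <- run_pipeline("example.sam", "example.gtf", out = "estimates.tsv")
head(est[est$gene_id %in% c("g006", "g007"), ], 4)
#>   gene_id isoform_id    theta  rpkm gene_read_count loglik converged ambiguous
#> 6    g006    g006.t1 1.96e-05 19605           14615  -26.9      TRUE     FALSE
#> 7    g006    g006.t2 1.47e-05 14652           14615  -26.9      TRUE     FALSE
#> 8    g007    g007.t1 7.81e-06  7808            6339  -24.9      TRUE     FALSE
#> 9    g007    g007.t2 9.95e-06  9946            6339  -24.9      TRUE     FALSE

mirr(sim$truth, est)
#> MIRR: 15/15 genes correct = 1.0000 (0 excluded, 0 estimate ties)
```

For gene `g006` the first isoform is called major (`theta` 1.96e-05 vs
1.47e-05, i.e. ~19.6k vs ~14.7k RPKM); for `g007` the second. All 15
two-isoform genes match the simulated truth, and true vs estimated
`theta` correlate at 1.00 at this depth.

A thin command-line wrapper ships in `inst/scripts/isoquant`:

```sh
Rscript inst/scripts/isoquant simulate --out-dir sim --genes 50 --reads 100000 --seed 1
Rscript inst/scripts/isoquant run --sam sim/reads.sam --gtf sim/annotation.gtf --out est.tsv
Rscript inst/scripts/isoquant mirr --truth sim/truth.tsv --est est.tsv
```

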