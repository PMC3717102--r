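#' Generate a synthetic multi-isoform annotation
#'
#' Builds non-overlapping genes on one synthetic chromosome and (optionally)
#' writes them as GTF. A gene with one isoform gets `single_exons` exons,
#' all included. A gene with `m >= 2` isoforms gets `m + 3` exons: isoform 1
#' contains all of them and isoform `k` (k >= 2) skips exon `k + 1`, so
#' every pair of isoforms differs by a cassette exon while the first two
#' and the last exon stay constitutive. Because exons of one gene are
#' either shared exactly or skipped whole, the exons are themselves the
#' constant-membership segments.
#'
#' @param n_genes number of genes.
#' @param isoforms_per_gene integer scalar or vector (recycled) of isoform
#'   counts per gene.
#' @param exon_length integer range `c(min, max)` of exon lengths.
#' @param intron_length integer range of intron lengths.
#' @param single_exons exons per single-isoform gene; their longer bodies
#'   stabilize relative-position binning for global-bias calibration.
#' @param gap intergenic gap in bases.
#' @param chrom synthetic chromosome name.
#' @param seed optional RNG seed for reproducible structures.
#' @param gtf optional path; when given, a valid GTF is written there.
#' @return list with `models` (named list of [gene_model()]) and `gtf`
#'   (path or `NULL`).
#' @export
simulate_annotation <- function(n_genes = 50L, isoforms_per_gene = 2L,
                                exon_length = c(300L, 600L),
                                intron_length = c(200L, 800L),
                                single_exons = 8L, gap = 2000L,
                                chrom = "chrS", seed = NULL, gtf = NULL) {
  stopifnot(n_genes >= 1L, all(isoforms_per_gene >= 1L))
  if (!is.null(seed)) set.seed(seed)
  m_per <- rep_len(as.integer(isoforms_per_gene), n_genes)
  pos <- 1000L
  models <- list()
  gtf_lines <- character(0)
  for (g in seq_len(n_genes)) {
    m <- m_per[g]
    n_ex <- if (m == 1L) as.integer(single_exons) else m + 3L
    # sample() on a scalar range would draw from 1:x; use explicit bounds
    rint <- function(k, lohi)
      lohi[1L] + sample.int(lohi[2L] - lohi[1L] + 1L, k, replace = TRUE) - 1L
    el <- rint(n_ex, exon_length)
    il <- if (n_ex > 1L) rint(n_ex - 1L, intron_length) else integer(0)
    starts <- pos + cumsum(c(0L, el[-n_ex] + il))
    ends <- starts + el
    gid <- sprintf("g%03d", g)
    iso_exons <- lapply(seq_len(m), function(i) {
      keep <- if (i == 1L) seq_len(n_ex) else setdiff(seq_len(n_ex), i + 1L)
      data.frame(start = starts[keep], end = ends[keep])
    })
    names(iso_exons) <- sprintf("%s.t%d", gid, seq_len(m))
    seg <- segment_gene(iso_exons)
    models[[gid]] <- gene_model(gid, chrom, "+", names(iso_exons),
                                seg$segments, seg$inclusion)
    if (!is.null(gtf)) {
      for (i in seq_len(m)) {
        e <- iso_exons[[i]]
        gtf_lines <- c(gtf_lines, sprintf(
          "%s\tsim\texon\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; transcript_id \"%s\";",
          chrom, e$start + 1L, e$end, gid, names(iso_exons)[i]))
      }
    }
    pos <- ends[n_ex] + gap
  }
  if (!is.null(gtf)) writeLines(gtf_lines, gtf)
  list(models = models, gtf = gtf)
}

.isoform_table <- function(models) {
  rows <- list()
  for (g in models) {
    a <- g$inclusion
    for (i in seq_len(nrow(a))) {
      inc <- which(a[i, ] == 1L)
      rows[[length(rows) + 1L]] <- list(
        gene_id = g$gene_id, isoform_id = g$isoform_ids[i],
        chrom = g$chrom,
        seg_start = g$segments$start[inc],
        seg_len = g$segments$length[inc],
        length = sum(g$segments$length[inc]))
    }
  }
  rows
}

#' Simulate biased single-end reads as SAM
#'
#' Draws `n_reads` single-end reads from the gene models: each read picks
#' an isoform with probability proportional to `weight_i * length_i`, then
#' a 5' start position from the positional bias density (flat when `bias`
#' is `NULL`), resampling starts that fall within `read_length` of the 3'
#' end; the transcript position is projected across junctions to a genomic
#' coordinate and emitted as a minimal valid SAM record (FLAG 0, CIGAR
#' `<read_length>M`, placeholder SEQ/QUAL). The truth table reports the
#' sampling weights, the implied model-scale expression `theta_true =
#' weight_i / sum_k(weight_k * length_k)` (so that the expected total rate
#' equals the read count), and realized per-isoform read counts. Output is
#' byte-identical for identical inputs and seed.
#'
#' @param models named list of [gene_model()] objects (plus strand only).
#' @param n_reads total number of reads to draw.
#' @param sam path of the SAM file to write.
#' @param weights optional per-isoform expression weights in the row order
#'   of the truth table; default log-normal (meanlog 0, sdlog 1) draws.
#' @param read_length read length in bases.
#' @param bias a [bias_curve()] giving the start-position density over
#'   relative transcript position, or `NULL` for uniform sampling.
#' @param seed optional RNG seed.
#' @param truth optional path to also write the truth table as TSV.
#' @return invisibly, a list with `sam`, `truth` (data.frame `gene_id`,
#'   `isoform_id`, `weight`, `theta_true`, `reads_sampled`) and `n_reads`.
#' @export
simulate_reads <- function(models, n_reads, sam, weights = NULL,
                           read_length = 75L, bias = NULL, seed = NULL,
                           truth = NULL) {
  stopifnot(n_reads >= 0L, read_length >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (any(vapply(models, `[[`, "", "strand") == "-"))
    stop("the simulator emits plus-strand genes only")
  iso <- .isoform_table(models)
  K <- length(iso)
  lens <- vapply(iso, `[[`, numeric(1), "length")
  if (is.null(weights)) weights <- stats::rlnorm(K, 0, 1)
  stopifnot(length(weights) == K, all(weights >= 0), any(weights > 0))
  ok <- lens >= read_length
  if (!all(ok))
    warning(sum(!ok), " isoform(s) shorter than the read length excluded from sampling",
            call. = FALSE)
  p <- weights * lens * ok
  if (n_reads > 0L && sum(p) <= 0)
    stop("no sampleable isoform: all weights are zero or all isoforms are shorter than the read length")
  theta_true <- weights * ok / sum(weights[ok] * lens[ok])
  chroms <- unique(vapply(models, `[[`, "", "chrom"))
  seqlen <- vapply(chroms, function(ch) {
    max(vapply(models, function(g)
      if (g$chrom == ch) max(g$segments$end) else 0L, numeric(1))) + 1000
  }, numeric(1))
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(seqlen)))
  reads_sampled <- integer(K)
  if (n_reads > 0L) {
    idx <- sample.int(K, n_reads, replace = TRUE, prob = p)
    reads_sampled <- tabulate(idx, K)
    gpos <- integer(n_reads)
    rname <- character(n_reads)
    for (k in which(reads_sampled > 0L)) {
      sel <- which(idx == k)
      nk <- length(sel)
      L <- lens[k]
      maxs <- L - read_length
      if (is.null(bias)) {
        off <- sample.int(maxs + 1L, nk, replace = TRUE) - 1L
      } else {
        wts <- bias$weights
        B <- length(wts)
        off <- integer(nk)
        todo <- seq_len(nk)
        while (length(todo) > 0L) {
          kb <- sample.int(B, length(todo), replace = TRUE, prob = wts)
          tt <- (kb - 1L + stats::runif(length(todo))) / B
          cand <- floor(tt * L)
          good <- cand <= maxs
          off[todo[good]] <- cand[good]
          todo <- todo[!good]
        }
      }
      cum <- cumsum(c(0L, iso[[k]]$seg_len))
      si <- findInterval(off, cum[-length(cum)])
      gpos[sel] <- iso[[k]]$seg_start[si] + off - cum[si]
      rname[sel] <- iso[[k]]$chrom
    }
    body <- data.table::data.table(
      qname = sprintf("r%07d", seq_len(n_reads)),
      flag = 0L, rname = rname, pos = gpos + 1L, mapq = 255L,
      cigar = sprintf("%dM", read_length), rnext = "*", pnext = 0L,
      tlen = 0L, seq = "*", qual = "*")
    writeLines(header, sam)
    data.table::fwrite(body, sam, sep = "\t", col.names = FALSE,
                       append = TRUE, quote = FALSE)
  } else {
    writeLines(header, sam)
  }
  truth_df <- data.frame(
    gene_id = vapply(iso, `[[`, "", "gene_id"),
    isoform_id = vapply(iso, `[[`, "", "isoform_id"),
    weight = weights, theta_true = theta_true,
    reads_sampled = reads_sampled, stringsAsFactors = FALSE)
  if (!is.null(truth))
    data.table::fwrite(truth_df, truth, sep = "\t")
  invisible(list(sam = sam, truth = truth_df, n_reads = n_reads))
}
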