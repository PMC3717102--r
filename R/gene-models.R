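#' Gene models as disjoint exonic segments
#'
#' A `gene_model` describes one gene as a set of `n` disjoint exonic
#' segments together with an `m x n` 0/1 inclusion matrix saying which of
#' the `m` isoforms contains each segment. Segments are maximal genomic
#' intervals over which isoform membership is constant, so the per-segment
#' Poisson counting model is well defined even when isoform exons overlap.
#' All coordinates are 0-based half-open.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`; relative positions for bias curves are
#'   measured 5' to 3' on this strand.
#' @param isoform_ids character vector of `m` isoform identifiers.
#' @param segments data.frame with integer columns `start`, `end`,
#'   `length`, one row per segment, sorted by `start`, pairwise disjoint.
#' @param inclusion integer `m x n` matrix of 0/1 (rows = isoforms).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, isoform_ids, segments,
                       inclusion) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  strand <- match.arg(strand, c("+", "-"))
  m <- length(isoform_ids)
  n <- nrow(segments)
  if (m < 1L || n < 1L)
    stop("gene '", gene_id, "': needs >= 1 isoform and >= 1 segment")
  if (!all(c("start", "end", "length") %in% names(segments)))
    stop("segments must have columns start, end, length")
  if (any(segments$start >= segments$end))
    stop("gene '", gene_id, "': segment with start >= end")
  if (any(segments$length != segments$end - segments$start))
    stop("gene '", gene_id, "': segment length != end - start")
  if (n > 1L && any(segments$end[-n] > segments$start[-1L]))
    stop("gene '", gene_id, "': segments overlap or are unsorted")
  inclusion <- matrix(as.integer(inclusion), nrow = m, ncol = n,
                      dimnames = list(isoform_ids, NULL))
  if (!all(inclusion %in% c(0L, 1L)))
    stop("inclusion matrix must be 0/1")
  if (any(rowSums(inclusion) == 0L))
    stop("gene '", gene_id, "': isoform including no segment")
  if (any(colSums(inclusion) == 0L))
    stop("gene '", gene_id, "': segment included by no isoform")
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         isoform_ids = as.character(isoform_ids),
         segments = segments, inclusion = inclusion),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s%s): %d isoform(s), %d segment(s), %d bp exonic\n",
              x$gene_id, x$chrom, x$strand, length(x$isoform_ids),
              nrow(x$segments), sum(x$segments$length)))
  invisible(x)
}

#' Total exonic (segment-union) length of a gene
#' @param gene a [gene_model()].
#' @return integer number of bases.
#' @export
exonic_length <- function(gene) sum(gene$segments$length)

#' Length of one isoform (sum of its included segments)
#' @param gene a [gene_model()].
#' @param i isoform index.
#' @return integer number of bases.
#' @export
isoform_length <- function(gene, i) {
  sum(gene$segments$length[gene$inclusion[i, ] == 1L])
}

.norm_intervals <- function(x, what = "isoform") {
  x <- as.data.frame(x)
  if (ncol(x) < 2L) stop(what, " intervals need start and end columns")
  names(x)[1:2] <- c("start", "end")
  if (nrow(x) == 0L) stop(what, " with no intervals")
  if (any(x$start >= x$end)) stop(what, " interval with start >= end")
  x <- x[order(x$start), , drop = FALSE]
  if (nrow(x) > 1L && any(x$end[-nrow(x)] > x$start[-1L]))
    stop(what, " intervals overlap")
  x
}

#' Partition isoform exons into constant-membership segments
#'
#' Splits the exonic union of a gene into maximal runs of bases whose set of
#' covering isoforms is constant, and records membership in an inclusion
#' matrix. This is the counting unit of the Poisson model: each segment has
#' a single well-defined 0/1 inclusion status per isoform.
#'
#' @param isoform_exons list (one element per isoform) of data.frames or
#'   two-column matrices of 0-based half-open `start`/`end` intervals;
#'   intervals within one isoform must be disjoint.
#' @return list with `segments` (data.frame `start`, `end`, `length`) and
#'   `inclusion` (`m x n` 0/1 integer matrix, rows in input isoform order).
#' @examples
#' seg <- segment_gene(list(
#'   A = data.frame(start = c(0, 200), end = c(100, 300)),
#'   B = data.frame(start = c(0, 150), end = c(100, 300))))
#' seg$segments
#' seg$inclusion
#' @export
segment_gene <- function(isoform_exons) {
  m <- length(isoform_exons)
  if (m == 0L) stop("empty isoform list")
  ex <- lapply(isoform_exons, .norm_intervals)
  bp <- sort(unique(unlist(lapply(ex, function(e) c(e$start, e$end)))))
  cs <- bp[-length(bp)]
  ce <- bp[-1L]
  # membership of each candidate piece: isoform i covers [cs,ce) iff one of
  # its exons contains it (pieces never straddle an exon boundary)
  memb <- matrix(FALSE, nrow = m, ncol = length(cs))
  for (i in seq_len(m)) {
    idx <- findInterval(cs, ex[[i]]$start)
    ok <- idx >= 1L
    ok[ok] <- ce[ok] <= ex[[i]]$end[idx[ok]]
    memb[i, ] <- ok
  }
  keep <- colSums(memb) > 0L
  cs <- cs[keep]; ce <- ce[keep]
  memb <- memb[, keep, drop = FALSE]
  # merge adjacent pieces with identical membership into maximal runs
  key <- apply(memb, 2L, paste, collapse = "")
  n <- length(cs)
  grp <- integer(n)
  g <- 1L
  grp[1L] <- 1L
  if (n > 1L) {
    for (k in 2:n) {
      if (!(cs[k] == ce[k - 1L] && key[k] == key[k - 1L])) g <- g + 1L
      grp[k] <- g
    }
  }
  start <- as.integer(tapply(cs, grp, min))
  end <- as.integer(tapply(ce, grp, max))
  first <- match(unique(grp), grp)
  inclusion <- matrix(as.integer(memb[, first, drop = FALSE]), nrow = m)
  rownames(inclusion) <- names(isoform_exons)
  list(segments = data.frame(start = start, end = end,
                             length = end - start),
       inclusion = inclusion)
}

.build_models <- function(tx_tab, source_label) {
  # tx_tab: data.frame gene, tx, chrom, strand, start, end (0-based half-open)
  out <- list()
  for (g in unique(tx_tab$gene)) {
    gt <- tx_tab[tx_tab$gene == g, , drop = FALSE]
    bad_tx <- vapply(split(gt$chrom, gt$tx),
                     function(ch) length(unique(ch)) > 1L, logical(1))
    if (any(bad_tx)) {
      warning("gene '", g, "': transcript spanning two chromosomes; gene skipped",
              call. = FALSE)
      next
    }
    if (length(unique(gt$chrom)) > 1L) {
      warning("gene '", g, "': transcripts on different chromosomes; gene skipped",
              call. = FALSE)
      next
    }
    txs <- unique(gt$tx)
    exons <- lapply(txs, function(t) {
      e <- gt[gt$tx == t, c("start", "end"), drop = FALSE]
      dup <- duplicated(e)
      if (any(dup)) {
        warning("gene '", g, "' transcript '", t,
                "': duplicate exon record(s) collapsed", call. = FALSE)
        e <- e[!dup, , drop = FALSE]
      }
      e
    })
    names(exons) <- txs
    seg <- segment_gene(exons)
    strand <- gt$strand[1L]
    if (!strand %in% c("+", "-")) strand <- "+"
    out[[g]] <- gene_model(g, gt$chrom[1L], strand, txs,
                           seg$segments, seg$inclusion)
  }
  out
}

#' Read gene models from a GTF annotation
#'
#' Parses `exon` features (attributes `gene_id`, `transcript_id`) into one
#' [gene_model()] per gene. GTF 1-based closed coordinates are converted to
#' the internal 0-based half-open convention.
#'
#' @param path path to a GTF file.
#' @return named list of [gene_model()] objects, keyed and ordered by first
#'   appearance of `gene_id`.
#' @export
read_gtf_models <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(body) == 0L) return(list())
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    b <- which(nf < 9L)[1L]
    stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields, found %d",
                 body[b], nf[b]))
  }
  starts <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  if (anyNA(starts) || anyNA(ends)) {
    b <- which(is.na(starts) | is.na(ends))[1L]
    stop(sprintf("malformed GTF line %d: non-numeric start/end coordinate",
                 body[b]))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  if (!all(c("type", "gene_id", "transcript_id") %in% names(S4Vectors::mcols(gr))))
    stop("GTF lacks gene_id/transcript_id attributes")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) return(list())
  df <- as.data.frame(gr)
  tx_tab <- data.frame(
    gene = as.character(df$gene_id),
    tx = as.character(df$transcript_id),
    chrom = as.character(df$seqnames),
    strand = as.character(df$strand),
    start = df$start - 1L,   # to 0-based half-open
    end = df$end,
    stringsAsFactors = FALSE)
  .build_models(tx_tab, "GTF")
}

#' Read gene models from a refFlat annotation
#'
#' Parses the 11-column UCSC refFlat dialect (geneName, name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds).
#' refFlat exon coordinates are already 0-based half-open. Rows whose
#' `exonCount` disagrees with the comma lists are rejected with a warning;
#' duplicate transcript names within a gene keep the last row.
#'
#' @param path path to a refFlat file.
#' @return named list of [gene_model()] objects.
#' @export
read_refflat_models <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  if (length(raw) == 0L) return(list())
  fields <- strsplit(raw, "\t", fixed = TRUE)
  rows <- list()
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < 11L) {
      warning(sprintf("refFlat row %d: expected 11 fields, found %d; row rejected",
                      k, length(f)), call. = FALSE)
      next
    }
    nex <- suppressWarnings(as.integer(f[9L]))
    es <- suppressWarnings(as.integer(strsplit(f[10L], ",", fixed = TRUE)[[1L]]))
    ee <- suppressWarnings(as.integer(strsplit(f[11L], ",", fixed = TRUE)[[1L]]))
    if (is.na(nex) || anyNA(es) || anyNA(ee) ||
        length(es) != nex || length(ee) != nex) {
      warning(sprintf("refFlat row %d: exonCount disagrees with exon lists; row rejected",
                      k), call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = f[1L], tx = f[2L], chrom = f[3L], strand = f[4L],
      start = es, end = ee, row = k, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(list())
  tab <- do.call(rbind, rows)
  # duplicate transcript name within a gene: last row wins
  key <- paste(tab$gene, tab$tx, sep = "\r")
  last_row <- tapply(tab$row, key, max)
  keep <- last_row[key] == tab$row
  if (!all(tapply(tab$row, key, function(r) length(unique(r))) == 1L))
    warning("duplicate transcript name(s) within a gene; last record wins",
            call. = FALSE)
  .build_models(tab[keep, c("gene", "tx", "chrom", "strand", "start", "end")],
                "refFlat")
}

#' Read gene models from GTF or refFlat
#' @param path annotation file path.
#' @param format `"auto"` (by extension; `.refflat`/`.refFlat`/`.txt` treated
#'   as refFlat, otherwise GTF), `"gtf"` or `"refflat"`.
#' @return named list of [gene_model()] objects.
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "refflat")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(refflat|txt)$", path, ignore.case = TRUE))
      "refflat" else "gtf"
  }
  switch(format, gtf = read_gtf_models(path), refflat = read_refflat_models(path))
}
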