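#' Stream retained alignments from a SAM file
#'
#' Reads a SAM file (header optional) and returns one record per retained
#' alignment. Unmapped (FLAG 0x4), secondary (0x100) and supplementary
#' (0x800) alignments are dropped; both mates of a pair are kept as
#' independent single-end records. Only the mandatory FLAG, RNAME and POS
#' fields are used; POS is converted to 0-based. Records whose FLAG or POS
#' cannot be parsed are skipped with a warning and tallied.
#'
#' @param path path to a SAM file.
#' @return data.frame with columns `chrom` and `pos` (0-based leftmost
#'   aligned base), with attributes `n_records` (parseable body records) and
#'   `n_skipped` (unparseable records).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  # header lines ('@'-prefixed) appear only at the top; count them
  n_head <- 0L
  con <- file(path, "r")
  on.exit(close(con), add = TRUE)
  repeat {
    chunk <- readLines(con, n = 1024L)
    if (length(chunk) == 0L) break
    at <- startsWith(chunk, "@")
    if (all(at)) {
      n_head <- n_head + length(chunk)
    } else {
      n_head <- n_head + match(FALSE, at) - 1L
      break
    }
  }
  empty <- data.frame(chrom = character(), pos = integer())
  dt <- tryCatch(
    suppressWarnings(data.table::fread(
      path, skip = n_head, header = FALSE, sep = "\t", fill = TRUE,
      select = 2:4, col.names = c("flag", "chrom", "pos"),
      colClasses = list(character = 1:11), quote = "",
      showProgress = FALSE, blank.lines.skip = TRUE)),
    error = function(e) NULL)
  if (is.null(dt) || nrow(dt) == 0L) {
    attr(empty, "n_records") <- 0L
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  flag <- suppressWarnings(as.integer(dt$flag))
  pos <- suppressWarnings(as.integer(dt$pos))
  bad <- is.na(flag) | is.na(pos)
  if (any(bad))
    warning(sum(bad), " SAM record(s) with unparseable FLAG/POS skipped",
            call. = FALSE)
  flag <- flag[!bad]; pos <- pos[!bad]; chrom <- dt$chrom[!bad]
  drop <- bitwAnd(flag, 0x4L) != 0L |
    bitwAnd(flag, 0x100L) != 0L |
    bitwAnd(flag, 0x800L) != 0L |
    pos < 1L | chrom == "*"
  out <- data.frame(chrom = chrom[!drop], pos = pos[!drop] - 1L,
                    stringsAsFactors = FALSE)
  attr(out, "n_records") <- length(flag)
  attr(out, "n_skipped") <- sum(bad)
  out
}

.segment_table <- function(genes) {
  lst <- lapply(seq_along(genes), function(gi) {
    g <- genes[[gi]]
    l <- g$segments$length
    data.table::data.table(
      chrom = g$chrom, start = g$segments$start, end = g$segments$end,
      gi = gi, si = seq_along(l),
      uoff = cumsum(c(0L, l))[seq_along(l)])
  })
  data.table::rbindlist(lst)
}

#' Count reads per exonic segment
#'
#' Assigns each retained alignment by its leftmost aligned base: a read
#' whose 5'-most genomic base falls inside segment `j` of gene `g`
#' increments `x_j` of that gene. A base inside segments of several
#' overlapping genes increments each such gene. The library total `w`
#' scales the Poisson rates `lambda_j = l_j w sum_i b_ij theta_i`.
#'
#' @param alignments data.frame from [read_alignments()] (columns `chrom`,
#'   `pos`, 0-based).
#' @param genes list of [gene_model()] objects.
#' @param w_mode `"all"`: `w` is every retained alignment in the file;
#'   `"assigned"`: only alignments falling inside annotated segments.
#' @return list of class `segment_counts` with elements `counts` (named
#'   list, one integer vector `x_j` per gene), `offsets` (named list of
#'   0-based offsets of each assigned read within the gene's exonic union,
#'   in genomic orientation), `w`, `n_alignments`, `n_assigned`,
#'   `n_intergenic` (alignments outside every annotated segment).
#' @export
count_reads <- function(alignments, genes, w_mode = c("all", "assigned")) {
  w_mode <- match.arg(w_mode)
  stopifnot(length(genes) >= 1L)
  ids <- vapply(genes, `[[`, "", "gene_id")
  counts <- lapply(genes, function(g) integer(nrow(g$segments)))
  offsets <- lapply(genes, function(g) integer(0))
  names(counts) <- ids
  names(offsets) <- ids
  n_aln <- nrow(alignments)
  n_assigned <- 0L
  if (n_aln > 0L) {
    seg <- .segment_table(genes)
    lev <- unique(c(unique(alignments$chrom), unique(seg$chrom)))
    rd <- GenomicRanges::GRanges(
      factor(alignments$chrom, levels = lev),
      IRanges::IRanges(start = alignments$pos + 1L, width = 1L))
    sg <- GenomicRanges::GRanges(
      factor(seg$chrom, levels = lev),
      IRanges::IRanges(start = seg$start + 1L, end = seg$end))
    ov <- GenomicRanges::findOverlaps(rd, sg)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    n_assigned <- length(unique(qh))
    if (length(qh) > 0L) {
      hit <- data.table::data.table(
        gi = seg$gi[sh], si = seg$si[sh],
        off = seg$uoff[sh] + alignments$pos[qh] - seg$start[sh])
      tal <- hit[, list(x = .N), by = c("gi", "si")]
      for (k in seq_len(nrow(tal)))
        counts[[tal$gi[k]]][tal$si[k]] <- tal$x[k]
      offs <- split(hit$off, hit$gi)
      for (nm in names(offs))
        offsets[[as.integer(nm)]] <- offs[[nm]]
    }
  }
  w <- if (w_mode == "all") n_aln else n_assigned
  structure(
    list(counts = counts, offsets = offsets, w = w,
         n_alignments = n_aln, n_assigned = n_assigned,
         n_intergenic = n_aln - n_assigned),
    class = "segment_counts")
}
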