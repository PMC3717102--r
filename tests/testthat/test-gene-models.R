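test_that("segment_gene handles identical, overlapping and disjoint isoforms", {
  # identical isoforms collapse to one shared segment
  s <- segment_gene(list(A = data.frame(start = 0, end = 100),
                         B = data.frame(start = 0, end = 100)))
  expect_equal(nrow(s$segments), 1L)
  expect_equal(unname(s$inclusion), matrix(1L, 2, 1))

  # partially overlapping exon sets split at membership changes
  s <- segment_gene(list(
    A = data.frame(start = c(0, 200), end = c(100, 300)),
    B = data.frame(start = c(0, 150), end = c(100, 300))))
  expect_equal(s$segments$start, c(0L, 150L, 200L))
  expect_equal(s$segments$end, c(100L, 200L, 300L))
  expect_equal(unname(s$inclusion), rbind(c(1L, 0L, 1L), c(1L, 1L, 1L)))

  # disjoint isoforms give one exclusive segment each
  s <- segment_gene(list(A = data.frame(start = 0, end = 100),
                         B = data.frame(start = 200, end = 300)))
  expect_equal(nrow(s$segments), 2L)
  expect_equal(unname(s$inclusion), rbind(c(1L, 0L), c(0L, 1L)))

  # adjacent exons of one isoform merge into a single segment
  s <- segment_gene(list(A = data.frame(start = c(0, 100),
                                        end = c(100, 200))))
  expect_equal(nrow(s$segments), 1L)
  expect_equal(s$segments$length, 200L)

  expect_error(segment_gene(list()), "empty")
})

test_that("segmentation matches the base-level membership oracle and is a partition", {
  set.seed(421)
  for (rep in 1:30) {
    ex <- random_isoform_exons()
    got <- segment_gene(ex)
    want <- oracle_segments(ex)
    expect_equal(got$segments$start, want$segments$start)
    expect_equal(got$segments$end, want$segments$end)
    expect_equal(unname(got$inclusion), unname(want$inclusion))
    # partition: total segment length equals the exonic-union size
    union_bases <- unique(unlist(lapply(ex, function(e)
      unlist(mapply(seq, e$start, e$end - 1L, SIMPLIFY = FALSE)))))
    expect_equal(sum(got$segments$length), length(union_bases))
    # round trip: included segments reconstruct each isoform's base set
    for (i in seq_along(ex)) {
      inc <- got$inclusion[i, ] == 1L
      rec <- unlist(mapply(seq, got$segments$start[inc],
                           got$segments$end[inc] - 1L, SIMPLIFY = FALSE))
      orig <- unlist(mapply(seq, ex[[i]]$start, ex[[i]]$end - 1L,
                            SIMPLIFY = FALSE))
      expect_setequal(rec, orig)
    }
  }
})

test_that("GTF parsing converts coordinates and segments genes", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1\tsrc\texon\t1\t100\t.\t+\t.",
                   'gene_id "g1"; transcript_id "t1";', sep = "\t"), gtf)
  gm <- read_gtf_models(gtf)
  expect_length(gm, 1L)
  expect_equal(gm$g1$segments$start, 0L)       # 1-based closed -> 0-based
  expect_equal(gm$g1$segments$end, 100L)
  expect_equal(unname(gm$g1$inclusion), matrix(1L, 1, 1))

  empty <- tempfile(fileext = ".gtf")
  writeLines(character(0), empty)
  expect_length(read_gtf_models(empty), 0L)

  fix <- tempfile(fileext = ".gtf")
  writeLines(c(
    sprintf("chr1\tsrc\texon\t%d\t%d\t.\t+\t.\tgene_id \"G\"; transcript_id \"A\";",
            c(1L, 201L), c(100L, 300L)),
    sprintf("chr1\tsrc\texon\t%d\t%d\t.\t+\t.\tgene_id \"G\"; transcript_id \"B\";",
            c(1L, 151L), c(100L, 300L))), fix)
  gm <- read_gtf_models(fix)
  expect_equal(gm$G$segments$start, c(0L, 150L, 200L))
  expect_equal(gm$G$segments$end, c(100L, 200L, 300L))
  expect_equal(unname(gm$G$inclusion), rbind(c(1L, 0L, 1L), c(1L, 1L, 1L)))

  bad <- tempfile(fileext = ".gtf")
  writeLines(c("chr1\tsrc\texon\t1\t100\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";",
               "chr1 broken line"), bad)
  expect_error(read_gtf_models(bad), "line 2")
})

test_that("transcripts spanning two chromosomes skip the gene with a warning", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chr1\ts\texon\t1\t100\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";",
    "chr2\ts\texon\t1\t100\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";",
    "chr1\ts\texon\t1\t100\t.\t+\t.\tgene_id \"g2\"; transcript_id \"t2\";"), gtf)
  expect_warning(gm <- read_gtf_models(gtf), "two chromosomes")
  expect_equal(names(gm), "g2")
})

test_that("refFlat parsing matches GTF on the same gene structure", {
  rf <- tempfile(fileext = ".refflat")
  writeLines(c(
    "G\tA\tchr1\t+\t0\t300\t0\t300\t2\t0,200,\t100,300,",
    "G\tB\tchr1\t+\t0\t300\t0\t300\t2\t0,150,\t100,300,"), rf)
  gm_rf <- read_refflat_models(rf)

  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    sprintf("chr1\tsrc\texon\t%d\t%d\t.\t+\t.\tgene_id \"G\"; transcript_id \"A\";",
            c(1L, 201L), c(100L, 300L)),
    sprintf("chr1\tsrc\texon\t%d\t%d\t.\t+\t.\tgene_id \"G\"; transcript_id \"B\";",
            c(1L, 151L), c(100L, 300L))), gtf)
  gm_gtf <- read_gtf_models(gtf)
  expect_equal(gm_rf$G$segments, gm_gtf$G$segments)
  expect_equal(gm_rf$G$inclusion, gm_gtf$G$inclusion)

  # single row with 2 exons; grouping of rows by gene name
  one <- tempfile()
  writeLines("g\tt\tchr1\t+\t0\t300\t0\t300\t2\t0,200,\t100,300,", one)
  gm <- read_refflat_models(one)
  expect_length(gm, 1L)
  expect_length(gm$g$isoform_ids, 1L)
  expect_equal(nrow(gm$g$segments), 2L)
  expect_length(gm_rf$G$isoform_ids, 2L)

  # exonCount disagreeing with the lists rejects the row
  bad <- tempfile()
  writeLines(c("g\tt\tchr1\t+\t0\t300\t0\t300\t3\t0,200,\t100,300,",
               "h\tu\tchr1\t+\t0\t100\t0\t100\t1\t0,\t100,"), bad)
  expect_warning(gm <- read_refflat_models(bad), "exonCount")
  expect_equal(names(gm), "h")
})

test_that("gene_model enforces its invariants", {
  segs <- data.frame(start = c(0L, 200L), end = c(100L, 300L),
                     length = c(100L, 100L))
  expect_error(gene_model("g", "chr1", "+", c("A"), segs,
                          matrix(c(1L, 0L), 1, 2)), "included by no isoform")
  expect_error(gene_model("g", "chr1", "+", c("A", "B"), segs,
                          matrix(c(1L, 0L, 1L, 0L), 2, 2)),
               "including no segment")
  bad <- data.frame(start = c(0L, 50L), end = c(100L, 300L),
                    length = c(100L, 250L))
  expect_error(gene_model("g", "chr1", "+", "A", bad,
                          matrix(1L, 1, 2)), "overlap")
})
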