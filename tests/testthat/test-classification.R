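# shared two-exon transcript: exons [10,20) and [30,40) on chr1
two_exon_tt <- function(strand = "+") {
  transcript_table("t1", "chr1", strand,
                   list(c(10L, 30L)), list(c(20L, 40L)), gene = "g1")
}

mk_calls <- function(chrom, start, end, strand, id = NULL) {
  if (is.null(id)) id <- sprintf("c%d", seq_along(start))
  calls <- data.frame(id = id, chrom = chrom, start = as.integer(start),
                      end = as.integer(end), strand = strand,
                      stringsAsFactors = FALSE)
  class(calls) <- c("circ_calls", "data.frame")
  calls
}

test_that("containment flags follow the boundary-exon inequalities", {
  t <- two_exon_tt()[1, ]
  expect_equal(compute_flags(list(start = 10L, end = 40L), t),
               list(start_flag = 1L, end_flag = 1L))
  expect_equal(compute_flags(list(start = 15L, end = 35L), t),
               list(start_flag = 1L, end_flag = 1L))
  # call starting before the first exon of a wider transcript
  wide <- transcript_table("t2", "chr1", "+",
                           list(c(5L, 30L)), list(c(8L, 40L)))
  expect_equal(compute_flags(list(start = 9L, end = 40L), wide[1, ]),
               list(start_flag = 0L, end_flag = 1L))
  # flags are undefined without a boundary exon
  expect_error(compute_flags(list(start = 22L, end = 28L), t), "overlapping")
})

test_that("a boundary-matching call on matching strands is exonic with exon blocks", {
  cls <- classify_calls(mk_calls("chr1", 10L, 40L, "+"), two_exon_tt())
  expect_equal(cls$circ_class, "exonic")
  expect_equal(cls$block_count, 2L)
  expect_equal(cls$block_sizes[[1L]], c(10L, 10L))
  expect_equal(cls$block_offsets[[1L]], c(0L, 20L))
  expect_equal(cls$length, 20L) # spliced, not genomic, length
  expect_equal(cls$best_transcript, "t1")
  expect_equal(cls$host_gene, "g1")
})

test_that("endpoints inside exons clip the first and last block", {
  cls <- classify_calls(mk_calls("chr1", 15L, 35L, "+"), two_exon_tt())
  expect_equal(cls$circ_class, "exonic")
  expect_equal(cls$block_sizes[[1L]], c(5L, 5L))
  expect_equal(cls$block_offsets[[1L]], c(0L, 15L))
  # agrees with the position-scan oracle
  want <- oracle_blocks(list(start = 15L, end = 35L), two_exon_tt()[1, ])
  expect_equal(cls$block_sizes[[1L]], want$sizes)
  expect_equal(cls$block_offsets[[1L]], want$offsets)
})

test_that("a call inside a single intron is intronic with one block", {
  cls <- classify_calls(mk_calls("chr1", 22L, 28L, "+"), two_exon_tt())
  expect_equal(cls$circ_class, "intronic")
  expect_equal(cls$block_count, 1L)
  expect_equal(cls$block_sizes[[1L]], 6L)
  expect_equal(cls$block_offsets[[1L]], 0L)
})

test_that("no containing transcript means class other over the whole span", {
  cls <- classify_calls(mk_calls("chr7", 100L, 160L, "+"), two_exon_tt())
  expect_equal(cls$circ_class, "other")
  expect_equal(cls$best_transcript, "NA")
  expect_equal(cls$transcript_strand, "NA")
  expect_true(is.na(cls$transcript_start))
  expect_equal(cls$block_sizes[[1L]], 60L)
})

test_that("an antisense boundary match is demoted to other, not exonic", {
  cls <- classify_calls(mk_calls("chr1", 10L, 40L, "-"), two_exon_tt("+"))
  expect_equal(cls$circ_class, "other")
  expect_equal(cls$best_transcript, "t1") # still selected, strand fails
  expect_equal(cls$block_sizes[[1L]], 30L) # single genomic-span block
})

test_that("unknown call strand waives the strand test and echoes '.'", {
  cls <- classify_calls(mk_calls("chr1", 10L, 40L, "."), two_exon_tt("-"))
  expect_equal(cls$circ_class, "exonic")
  expect_equal(cls$strand, ".")
  expect_equal(cls$transcript_strand, "-")
})

test_that("a call spanning exons with an endpoint in an intron is other", {
  # start inside intron [20,30): exons overlap but start_flag = 0
  cls <- classify_calls(mk_calls("chr1", 25L, 40L, "+"), two_exon_tt())
  expect_equal(cls$circ_class, "other")
})

test_that("classification partitions calls and keeps blocks consistent", {
  fx <- generate_fixture(fixture_spec(seed = 5, n_calls = 120,
                                      chrom_length = 60000L, gene_count = 12),
                         dir = tempfile())
  cls <- classify_calls(fx$calls, fx$transcripts)
  expect_equal(nrow(cls), nrow(fx$calls))
  expect_true(all(cls$circ_class %in% c("exonic", "intronic", "other")))
  smry <- classification_summary(cls)
  expect_equal(sum(smry$count[smry$class != "total"]),
               smry$count[smry$class == "total"])
  for (i in seq_len(nrow(cls))) {
    sz <- cls$block_sizes[[i]]
    off <- cls$block_offsets[[i]]
    expect_equal(sum(sz), cls$length[i])
    expect_true(all(sz > 0L))
    expect_true(all(off >= 0L))
    expect_true(all(off + sz <= cls$end[i] - cls$start[i]))
    if (length(off) > 1L) expect_true(all(diff(off) > 0L))
    if (cls$circ_class[i] != "exonic") {
      expect_equal(cls$block_count[i], 1L)
      expect_equal(sz, cls$end[i] - cls$start[i])
    }
    if (cls$circ_class[i] == "exonic") {
      expect_equal(off[1L], 0L)
      expect_equal(off[length(off)] + sz[length(sz)], cls$end[i] - cls$start[i])
      expect_true(cls$strand[i] == "." ||
                    cls$strand[i] == cls$transcript_strand[i])
    }
  }
})

test_that("the classification table round-trips with exactly 15 columns", {
  tt <- two_exon_tt()
  calls <- mk_calls("chr1", c(10L, 22L, 70L), c(40L, 28L, 90L), c("+", "+", "-"))
  cls <- classify_calls(calls, tt)
  path <- tempfile()
  write_classification(cls, path, header = TRUE)
  lines <- readLines(path)
  expect_true(all(lengths(strsplit(lines, "\t", fixed = TRUE)) == 15L))
  back <- read_classification(path)
  expect_equal(back$circ_id, cls$circ_id)
  expect_equal(back$block_sizes, cls$block_sizes)
  expect_equal(back$transcript_start, cls$transcript_start)
  expect_equal(back$circ_class, cls$circ_class)
})

test_that("BED12 export mirrors the exonic block structure", {
  cls <- classify_calls(mk_calls("chr1", c(10L, 22L), c(40L, 28L), "+"),
                        two_exon_tt())
  path <- tempfile()
  write_bed12(cls, path)
  lines <- readLines(path)
  expect_length(lines, 1L) # only the exonic record
  f <- strsplit(lines, "\t")[[1L]]
  expect_equal(f[1:4], c("chr1", "10", "40", "c1"))
  expect_equal(f[10:12], c("2", "10,10,", "0,20,"))
})
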