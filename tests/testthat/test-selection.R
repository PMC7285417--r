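test_that("containment includes boundary-touching spans and excludes partial overlap", {
  tt <- transcript_table(c("a", "b", "c"), "chr1", "+",
                         list(100L, 100L, 150L),
                         list(500L, 400L, 500L))
  call <- list(id = "x", chrom = "chr1", start = 150L, end = 400L)
  expect_equal(candidate_transcripts(call, tt)$transcript_id, c("a", "b", "c"))
  call2 <- list(id = "y", chrom = "chr1", start = 50L, end = 400L)
  expect_equal(nrow(candidate_transcripts(call2, tt)), 0L)
  # equality of call and span is containment (exact-boundary case reachable)
  call3 <- list(id = "z", chrom = "chr1", start = 100L, end = 500L)
  expect_true("a" %in% candidate_transcripts(call3, tt)$transcript_id)
})

test_that("splice length sums exon lengths and is bounded by the span", {
  t1 <- transcript_table("t", "chr1", "+", list(c(10L, 30L)), list(c(20L, 40L)))
  expect_equal(splice_length(t1[1, ]), 20L)
  t2 <- transcript_table("u", "chr1", "+", list(0L), list(7L))
  expect_equal(splice_length(t2[1, ]), 7L)
  set.seed(3)
  for (i in 1:50) {
    inst <- rand_instance()
    for (j in seq_len(nrow(inst$candidates))) {
      tr <- inst$candidates[j, , drop = FALSE]
      sl <- splice_length(tr)
      span <- tr$end - tr$start
      expect_lte(sl, span)
      if (tr$exon_count == 1L) expect_equal(sl, span)
    }
  }
})

test_that("exons_in_boundary uses half-open overlap, partial overlaps count", {
  t <- transcript_table("t", "chr1", "+", list(c(10L, 30L)), list(c(20L, 40L)))[1, ]
  expect_equal(nrow(exons_in_boundary(t, list(start = 10L, end = 40L))), 2L)
  expect_equal(nrow(exons_in_boundary(t, list(start = 22L, end = 28L))), 0L)
  be <- exons_in_boundary(t, list(start = 15L, end = 35L))
  expect_equal(be$start, c(10L, 30L))
  # touching is not overlapping: exon [10,20) vs call starting at 20
  expect_equal(nrow(exons_in_boundary(t, list(start = 20L, end = 28L))), 0L)
})

test_that("exact-boundary matchers win by splice length, then span, then order", {
  call <- list(id = "c", chrom = "chr1", start = 100L, end = 500L)
  cands <- transcript_table(
    c("short_splice", "long_splice", "case2_bait"),
    "chr1", "+",
    list(c(100L, 400L), c(100L, 250L, 400L), c(90L, 200L, 300L, 400L, 480L)),
    list(c(200L, 500L), c(220L, 380L, 500L), c(150L, 260L, 360L, 460L, 520L))
  )
  sel <- select_best_transcript(call, cands)
  expect_equal(sel$case_used, "exact_boundary_match")
  expect_equal(sel$best$transcript_id, "long_splice") # splice 350 vs 200
  expect_equal(sel$candidate_count, 3L)
})

test_that("without an exact matcher the max-exons-in-boundary rule decides", {
  call <- list(id = "c", chrom = "chr1", start = 110L, end = 490L)
  cands <- transcript_table(
    c("three_exons", "two_exons"), "chr1", "+",
    list(c(100L, 200L, 400L), c(100L, 400L)),
    list(c(150L, 300L, 500L), c(300L, 500L))
  )
  sel <- select_best_transcript(call, cands)
  expect_equal(sel$case_used, "max_exons_in_boundary")
  expect_equal(sel$best$transcript_id, "three_exons")
})

test_that("full ties fall back to annotation-file order", {
  call <- list(id = "c", chrom = "chr1", start = 100L, end = 500L)
  cands <- transcript_table(c("first", "second"), "chr1", "+",
                            list(c(100L, 300L), c(100L, 300L)),
                            list(c(200L, 500L), c(200L, 500L)))
  expect_equal(select_best_transcript(call, cands)$best$transcript_id, "first")
})

test_that("no candidates yields the no_candidate case", {
  call <- list(id = "c", chrom = "chr9", start = 10L, end = 40L)
  sel <- select_best_transcript(call, toy_model()[0, ])
  expect_null(sel$best)
  expect_equal(sel$case_used, "no_candidate")
  expect_equal(sel$candidate_count, 0L)
})

test_that("selection agrees with the literal brute-force cascade on random instances", {
  set.seed(1234)
  n_case1 <- 0L
  n_case2 <- 0L
  for (i in 1:1000) {
    inst <- rand_instance()
    got <- select_best_transcript(inst$call, inst$candidates)
    want <- oracle_select(inst$call, inst$candidates)
    expect_identical(got$case_used, want$case_used)
    if (!is.na(want$best_id)) {
      expect_identical(got$best$transcript_id, want$best_id)
    } else {
      expect_null(got$best)
    }
    if (want$case_used == "exact_boundary_match") n_case1 <- n_case1 + 1L
    if (want$case_used == "max_exons_in_boundary") n_case2 <- n_case2 + 1L
  }
  # both branches of the cascade must actually have been exercised
  expect_gt(n_case1, 50L)
  expect_gt(n_case2, 50L)
})

test_that("selection is deterministic and an exact matcher always dominates", {
  set.seed(99)
  for (i in 1:200) {
    inst <- rand_instance()
    a <- select_best_transcript(inst$call, inst$candidates)
    b <- select_best_transcript(inst$call, inst$candidates)
    expect_identical(a, b)
    if (nrow(inst$candidates)) {
      exact <- inst$candidates$start == inst$call$start &
        inst$candidates$end == inst$call$end
      if (any(exact)) {
        expect_equal(a$case_used, "exact_boundary_match")
        expect_true(a$best$transcript_id %in% inst$candidates$transcript_id[exact])
      }
    }
  }
})

test_that("adding a non-winning candidate does not change the selection", {
  set.seed(17)
  for (i in 1:100) {
    inst <- rand_instance(max_cand = 6L)
    if (nrow(inst$candidates) < 1L) next
    base <- select_best_transcript(inst$call, inst$candidates)
    extra <- rand_candidate_exons(inst$call)
    add <- transcript_table("zzz_added", "chr1", sample(c("+", "-"), 1L),
                            list(extra$starts), list(extra$ends))
    grown <- rbind(inst$candidates, add)
    new <- select_best_transcript(inst$call, grown)
    if (new$best$transcript_id != "zzz_added") {
      expect_identical(new$best$transcript_id, base$best$transcript_id)
      expect_identical(new$case_used, base$case_used)
    } else {
      # the newcomer may only displace the winner by winning the cascade
      want <- oracle_select(inst$call, grown)
      expect_identical(new$best$transcript_id, want$best_id)
    }
  }
})
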