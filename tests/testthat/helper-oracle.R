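# Independent brute-force oracles. These deliberately re-derive the
# selection cascade and the block structure by literal rule application /
# position scanning, so they share no code with the implementation under
# test.

# literal two-case cascade over explicit loops
oracle_select <- function(call, candidates) {
  n <- nrow(candidates)
  if (n == 0L) return(list(best_id = NA_character_, case_used = "no_candidate"))
  exact <- integer(0)
  for (i in seq_len(n)) {
    s <- candidates$exon_starts[[i]]
    e <- candidates$exon_ends[[i]]
    if (s[1L] == call$start && e[length(e)] == call$end) exact <- c(exact, i)
  }
  overlap_count <- function(i) {
    s <- candidates$exon_starts[[i]]
    e <- candidates$exon_ends[[i]]
    cnt <- 0L
    for (k in seq_along(s)) {
      hit <- FALSE
      for (p in call$start:(call$end - 1L)) {
        if (p >= s[k] && p < e[k]) { hit <- TRUE; break }
      }
      if (hit) cnt <- cnt + 1L
    }
    cnt
  }
  if (length(exact)) {
    pool <- exact
    sl <- vapply(pool, function(i)
      sum(candidates$exon_ends[[i]] - candidates$exon_starts[[i]]), numeric(1))
    pool <- pool[sl == max(sl)]
    tl <- candidates$end[pool] - candidates$start[pool]
    pool <- pool[tl == max(tl)]
    return(list(best_id = candidates$transcript_id[pool[1L]],
                case_used = "exact_boundary_match"))
  }
  cnt <- vapply(seq_len(n), overlap_count, integer(1))
  pool <- which(cnt == max(cnt))
  tl <- candidates$end[pool] - candidates$start[pool]
  pool <- pool[tl == max(tl)]
  list(best_id = candidates$transcript_id[pool[1L]],
       case_used = "max_exons_in_boundary")
}

# position-scan oracle for exonic block structure (sizes/offsets)
oracle_blocks <- function(call, best) {
  s <- best$exon_starts[[1L]]
  e <- best$exon_ends[[1L]]
  pos <- call$start:(call$end - 1L)
  inexon <- vapply(pos, function(p) any(p >= s & p < e), logical(1))
  r <- rle(inexon)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  list(sizes = as.integer(r$lengths[keep]),
       offsets = as.integer(starts[keep] - 1L))
}

# one random transcript whose span contains [call$start, call$end)
# (first/last exon define the span, per the table invariants)
rand_candidate_exons <- function(call, max_exons = 6L) {
  cs <- call$start
  ce <- call$end
  ts <- if (stats::runif(1) < 0.3) cs else cs - sample(0:30, 1L)
  te <- if (stats::runif(1) < 0.3) ce else ce + sample(0:30, 1L)
  width <- te - ts
  nex <- sample(1:min(max_exons, max(1L, width %/% 4L)), 1L)
  if (nex == 1L) return(list(starts = ts, ends = te))
  cuts <- sort(sample((ts + 1L):(te - 1L), 2L * (nex - 1L)))
  list(starts = c(ts, cuts[seq(2L, length(cuts), by = 2L)]),
       ends = c(cuts[seq(1L, length(cuts), by = 2L)], te))
}

# a random selection instance: one call plus <= max_cand containing
# transcripts with <= max_exons exons each
rand_instance <- function(max_cand = 8L, max_exons = 6L) {
  cs <- sample(50:150, 1L)
  ce <- cs + sample(12:100, 1L)
  call <- list(id = "c", chrom = "chr1", start = cs, end = ce)
  ncand <- sample(0:max_cand, 1L)
  if (ncand == 0L) {
    return(list(call = call,
                candidates = transcript_table("t0", "chr1", "+",
                                              list(0L), list(1L))[0, ]))
  }
  cands <- lapply(seq_len(ncand), function(i) rand_candidate_exons(call, max_exons))
  list(call = call,
       candidates = transcript_table(paste0("t", seq_len(ncand)), "chr1",
                                     sample(c("+", "-"), ncand, replace = TRUE),
                                     lapply(cands, `[[`, "starts"),
                                     lapply(cands, `[[`, "ends")))
}

# independent reverse complement via chartr + reversed substring order
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s), "")[[1L]]),
        collapse = "")
}

# small deterministic gene model shared by the annotation tests:
# two genes, one with two transcripts, mixed strands
toy_model <- function() {
  transcript_table(
    id = c("t1", "t2", "t3"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "+", "-"),
    exon_starts = list(c(10L, 30L), c(10L, 50L), c(100L, 200L, 300L)),
    exon_ends = list(c(20L, 40L), c(25L, 70L), c(150L, 260L, 350L)),
    gene = c("g1", "g1", "g2")
  )
}

# render toy_model as GTF and GFF3 text files
write_toy_gtf <- function(path) {
  tt <- toy_model()
  lines <- unlist(lapply(seq_len(nrow(tt)), function(i) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     tt$gene[i], tt$transcript_id[i], tt$gene[i])
    sprintf("%s\tsrc\texon\t%d\t%d\t.\t%s\t.\t%s",
            tt$chrom[i], tt$exon_starts[[i]] + 1L, tt$exon_ends[[i]],
            tt$strand[i], attrs)
  }))
  writeLines(lines, path)
  path
}

write_toy_gff3 <- function(path) {
  tt <- toy_model()
  genes <- unique(tt$gene)
  lines <- c("##gff-version 3")
  for (g in genes) {
    rows <- which(tt$gene == g)
    lines <- c(lines, sprintf("%s\tsrc\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                              tt$chrom[rows[1L]],
                              min(tt$start[rows]) + 1L, max(tt$end[rows]),
                              tt$strand[rows[1L]], g, g))
    for (i in rows) {
      lines <- c(lines,
                 sprintf("%s\tsrc\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         tt$chrom[i], tt$start[i] + 1L, tt$end[i],
                         tt$strand[i], tt$transcript_id[i], g),
                 sprintf("%s\tsrc\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         tt$chrom[i], tt$exon_starts[[i]] + 1L, tt$exon_ends[[i]],
                         tt$strand[i], tt$transcript_id[i],
                         seq_along(tt$exon_starts[[i]]), tt$transcript_id[i]))
    }
  }
  writeLines(lines, path)
  path
}

# drop the S3 class and list-column attributes for field-by-field comparison
tt_fields <- function(tt) {
  data.frame(id = tt$transcript_id, chrom = tt$chrom, strand = tt$strand,
             start = tt$start, end = tt$end, n = tt$exon_count,
             es = vapply(tt$exon_starts, paste, character(1), collapse = ","),
             ee = vapply(tt$exon_ends, paste, character(1), collapse = ","),
             gene = tt$gene, stringsAsFactors = FALSE)
}
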