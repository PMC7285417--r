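#' Specification for a synthetic test fixture
#'
#' Describes a deterministic synthetic dataset: a random genome, a gene
#' annotation placed on it, and a set of circRNA calls planted with known
#' class, best transcript, block structure and sequence. The same seed and
#' spec always produce byte-identical files.
#'
#' @param seed Integer seed driving the single pseudo-random stream.
#' @param chrom_count Number of chromosomes.
#' @param chrom_length Length of each chromosome (bases).
#' @param gene_count Number of genes (placed without overlap; every third
#'   gene is forced to be single-transcript and multi-exon so intronic and
#'   clipped-exonic calls can always be planted).
#' @param transcripts_per_gene Integer range `c(min, max)`.
#' @param exons_per_transcript Integer range `c(min, max)`.
#' @param exon_length,intron_length Integer ranges `c(min, max)` in bases.
#' @param n_calls Number of circRNA calls to plant.
#' @param class_mix Named numeric vector of target proportions for
#'   `exonic`, `intronic`, `other`; must sum to 1. Realized counts are one
#'   multinomial draw, recorded in the truth table.
#' @param boundary_noise Probability of jittering a planted call's
#'   endpoints off their construction positions (truth fields become NA
#'   for jittered calls, since their class is no longer forced by
#'   construction).
#' @param exonic_clip_prob Fraction of exonic calls planted with endpoints
#'   inside (rather than exactly at) their terminal exons, to exercise
#'   block clipping.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, chrom_count = 3L, chrom_length = 100000L,
                         gene_count = 30L, transcripts_per_gene = c(1L, 3L),
                         exons_per_transcript = c(1L, 6L),
                         exon_length = c(50L, 300L), intron_length = c(50L, 500L),
                         n_calls = 500L,
                         class_mix = c(exonic = 0.6, intronic = 0.2, other = 0.2),
                         boundary_noise = 0, exonic_clip_prob = 0.3) {
  stopifnot(
    chrom_count >= 1L, chrom_length >= 5000L, gene_count >= 1L,
    transcripts_per_gene[1L] >= 1L, transcripts_per_gene[2L] >= transcripts_per_gene[1L],
    exons_per_transcript[1L] >= 1L, exons_per_transcript[2L] >= exons_per_transcript[1L],
    exon_length[1L] >= 10L, intron_length[1L] >= 10L, n_calls >= 1L,
    all(c("exonic", "intronic", "other") %in% names(class_mix)),
    abs(sum(class_mix) - 1) < 1e-9,
    boundary_noise >= 0, boundary_noise <= 1,
    exonic_clip_prob >= 0, exonic_clip_prob <= 1
  )
  spec <- list(seed = as.integer(seed), chrom_count = as.integer(chrom_count),
               chrom_length = as.integer(chrom_length),
               gene_count = as.integer(gene_count),
               transcripts_per_gene = as.integer(transcripts_per_gene),
               exons_per_transcript = as.integer(exons_per_transcript),
               exon_length = as.integer(exon_length),
               intron_length = as.integer(intron_length),
               n_calls = as.integer(n_calls),
               class_mix = class_mix[c("exonic", "intronic", "other")],
               boundary_noise = boundary_noise,
               exonic_clip_prob = exonic_clip_prob)
  class(spec) <- "fixture_spec"
  spec
}

.rint <- function(range) if (range[1L] == range[2L]) range[1L] else
  sample(range[1L]:range[2L], 1L)

# one transcript structure relative to offset 0: list(starts, ends)
.gen_tx_struct <- function(spec, min_exons = spec$exons_per_transcript[1L]) {
  n_ex <- .rint(c(max(min_exons, spec$exons_per_transcript[1L]),
                  spec$exons_per_transcript[2L]))
  elens <- vapply(seq_len(n_ex), function(i) .rint(spec$exon_length), integer(1))
  ilens <- if (n_ex > 1L) vapply(seq_len(n_ex - 1L), function(i)
    .rint(spec$intron_length), integer(1)) else integer(0)
  starts <- integer(n_ex)
  ends <- integer(n_ex)
  pos <- 0L
  for (k in seq_len(n_ex)) {
    starts[k] <- pos
    ends[k] <- pos + elens[k]
    pos <- ends[k] + if (k < n_ex) ilens[k] else 0L
  }
  list(starts = starts, ends = ends)
}

#' Generate a synthetic fixture with planted ground truth
#'
#' Writes, under `dir`: `genome.fa`, the same annotation rendered as
#' `annotation.gtf` and `annotation.gff3`, the same calls rendered in both
#' coordinate dialects (`calls_bed_like.tsv`, `calls_one_based.tsv`), and
#' `truth.tsv` (planted class, best transcript, blocks and sequence per
#' call). Truth is forced by the planting geometry, not by running any
#' pipeline code:
#'
#' * exonic calls have endpoints at (or, for clipped calls, inside) exon
#'   boundaries of a designated transcript; full-span calls rely on
#'   transcripts within a gene having pairwise distinct spans (so the
#'   designated transcript is the unique exact-boundary matcher), all
#'   other exonic and all intronic calls are planted in single-transcript
#'   genes (so the designated transcript is the only candidate);
#' * intronic calls sit strictly inside one intron;
#' * "other" calls rotate through intergenic placement, antisense
#'   exact-span matches (pinning the strand rule), and calls straddling a
#'   gene's 3' edge into intergenic space.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return A list with `spec`, `paths` (named file paths), `transcripts`
#'   (the planted [transcript_table()]), `calls` (canonical 0-based
#'   half-open), `truth` (data.frame), `genome` (named character vector).
#' @export
generate_fixture <- function(spec, dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)

  chroms <- paste0("chr", seq_len(spec$chrom_count))
  genome <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), spec$chrom_length, replace = TRUE),
          collapse = "")
  }, character(1))

  ## ---- gene and transcript placement -----------------------------------
  margin <- 500L
  cursors <- stats::setNames(rep(margin, length(chroms)), chroms)
  slots <- stats::setNames(vector("list", length(chroms)), chroms)
  genes <- vector("list", spec$gene_count)
  tx_counter <- 0L
  for (gi in seq_len(spec$gene_count)) {
    force_single <- (gi %% 3L) == 1L
    ntx <- if (force_single) 1L else .rint(spec$transcripts_per_gene)
    structs <- vector("list", ntx)
    offs <- integer(ntx)
    spans <- matrix(0L, nrow = 0L, ncol = 2L)
    for (j in seq_len(ntx)) {
      ok <- FALSE
      for (try in 1:25) {
        st <- .gen_tx_struct(spec, min_exons = if (force_single) 2L else
          spec$exons_per_transcript[1L])
        off <- if (j == 1L) 0L else sample(0:100, 1L)
        span <- c(off + st$starts[1L], off + st$ends[length(st$ends)])
        if (!any(spans[, 1L] == span[1L] & spans[, 2L] == span[2L])) {
          ok <- TRUE
          break
        }
      }
      if (!ok) .stopf("could not generate distinct transcript spans for gene %d", gi)
      structs[[j]] <- st
      offs[j] <- off
      spans <- rbind(spans, span)
    }
    slot_len <- max(spans[, 2L])
    strand <- sample(c("+", "-"), 1L)

    # place the slot on the first chromosome (round-robin start) with room
    placed <- FALSE
    order_ch <- chroms[((gi - 1L + seq_along(chroms) - 1L) %% length(chroms)) + 1L]
    for (ch in order_ch) {
      gap <- sample(300:800, 1L)
      at <- cursors[[ch]] + gap
      if (at + slot_len + margin <= spec$chrom_length) {
        slot <- c(at, at + slot_len)
        slots[[ch]] <- rbind(slots[[ch]], slot)
        cursors[[ch]] <- at + slot_len
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      .stopf("gene %d does not fit on any chromosome; increase chrom_length", gi)
    }
    gid <- sprintf("g%03d", gi)
    txs <- lapply(seq_len(ntx), function(j) {
      tx_counter <<- tx_counter + j - j + 1L
      list(id = sprintf("t%04d", tx_counter), gene = gid, chrom = ch,
           strand = strand,
           starts = slot[1L] + offs[j] + structs[[j]]$starts,
           ends = slot[1L] + offs[j] + structs[[j]]$ends)
    })
    genes[[gi]] <- list(id = gid, chrom = ch, strand = strand,
                        slot = slot, ntx = ntx, txs = txs,
                        single = ntx == 1L,
                        multi_exon = length(structs[[1L]]$starts) >= 2L)
  }

  all_tx <- do.call(c, lapply(genes, `[[`, "txs"))
  tt <- transcript_table(
    id = vapply(all_tx, `[[`, character(1), "id"),
    chrom = vapply(all_tx, `[[`, character(1), "chrom"),
    strand = vapply(all_tx, `[[`, character(1), "strand"),
    exon_starts = lapply(all_tx, `[[`, "starts"),
    exon_ends = lapply(all_tx, `[[`, "ends"),
    gene = vapply(all_tx, `[[`, character(1), "gene")
  )

  ## ---- plant calls ------------------------------------------------------
  counts <- stats::rmultinom(1L, spec$n_calls, spec$class_mix)[, 1L]
  used <- new.env(parent = emptyenv())
  is_used <- function(ch, s, e, st) {
    k <- paste(ch, s, e, st)
    if (!is.null(used[[k]])) return(TRUE)
    used[[k]] <- TRUE
    FALSE
  }
  gsub_seq <- function(ch, s, e) substr(genome[[ch]], s + 1L, e)

  single_genes <- Filter(function(g) g$single, genes)
  single_multi <- Filter(function(g) g$single && g$multi_exon, genes)
  if (counts[["intronic"]] > 0L && !length(single_multi)) {
    .stopf("no single-transcript multi-exon gene available for intronic calls")
  }

  plant_exonic <- function() {
    for (try in 1:50) {
      u <- stats::runif(1)
      if (u < spec$exonic_clip_prob && length(single_genes)) {
        g <- single_genes[[sample.int(length(single_genes), 1L)]]
        t <- g$txs[[1L]]
        ne <- length(t$starts)
        i <- sample.int(ne, 1L)
        j <- if (i < ne) sample(i:ne, 1L) else ne
        ei_len <- t$ends[i] - t$starts[i]
        s <- t$starts[i] + sample(0:(min(10L, ei_len - 2L)), 1L)
        ej_len <- t$ends[j] - t$starts[j]
        e <- t$ends[j] - sample(0:(min(10L, ej_len - 2L)), 1L)
        if (i == j && s >= e - 1L) next
      } else if (u < spec$exonic_clip_prob + 0.3 || !length(single_genes)) {
        # full transcript span: unique exact-boundary matcher by construction
        t <- all_tx[[sample.int(length(all_tx), 1L)]]
        i <- 1L
        j <- length(t$starts)
        s <- t$starts[1L]
        e <- t$ends[j]
      } else {
        # exact exon-pair boundaries inside a single-transcript gene
        g <- single_genes[[sample.int(length(single_genes), 1L)]]
        t <- g$txs[[1L]]
        ne <- length(t$starts)
        i <- sample.int(ne, 1L)
        j <- if (i < ne) sample(i:ne, 1L) else ne
        s <- t$starts[i]
        e <- t$ends[j]
      }
      if (is_used(t$chrom, s, e, t$strand)) next
      bs <- pmax(t$starts[i:j], s)
      bend <- pmin(t$ends[i:j], e)
      seq <- paste(vapply(seq_along(bs), function(k)
        gsub_seq(t$chrom, bs[k], bend[k]), character(1)), collapse = "")
      if (t$strand == "-") seq <- reverse_complement(seq)
      return(list(chrom = t$chrom, start = s, end = e, strand = t$strand,
                  class = "exonic", best = t$id,
                  sizes = as.integer(bend - bs), offsets = as.integer(bs - s),
                  seq = seq))
    }
    .stopf("failed to plant an exonic call after bounded retries")
  }

  plant_intronic <- function() {
    for (try in 1:50) {
      g <- single_multi[[sample.int(length(single_multi), 1L)]]
      t <- g$txs[[1L]]
      k <- sample.int(length(t$starts) - 1L, 1L)
      is0 <- t$ends[k]
      ie0 <- t$starts[k + 1L]
      ilen <- ie0 - is0
      s <- is0 + sample(0:min(10L, ilen - 2L), 1L)
      e <- ie0 - sample(0:min(10L, max(0L, ie0 - s - 2L)), 1L)
      if (s >= e) next
      if (is_used(t$chrom, s, e, t$strand)) next
      seq <- gsub_seq(t$chrom, s, e)
      if (t$strand == "-") seq <- reverse_complement(seq)
      return(list(chrom = t$chrom, start = s, end = e, strand = t$strand,
                  class = "intronic", best = t$id,
                  sizes = e - s, offsets = 0L, seq = seq))
    }
    .stopf("failed to plant an intronic call after bounded retries")
  }

  other_kind <- 0L
  plant_other <- function() {
    for (try in 1:60) {
      other_kind <<- other_kind + 1L
      kind <- other_kind %% 3L
      if (kind == 0L) {
        # intergenic
        ch <- chroms[[sample.int(length(chroms), 1L)]]
        sl <- slots[[ch]]
        bounds <- c(margin, if (!is.null(sl)) as.vector(t(sl)), spec$chrom_length - margin)
        gaps <- matrix(bounds, ncol = 2L, byrow = TRUE)
        if (!is.null(sl)) {
          edges <- sort(c(margin, as.vector(t(sl)), spec$chrom_length - margin))
          gaps <- cbind(edges[seq(1, length(edges), by = 2)],
                        edges[seq(2, length(edges), by = 2)])
        }
        gaps <- gaps[gaps[, 2L] - gaps[, 1L] >= 300L, , drop = FALSE]
        if (!nrow(gaps)) next
        gp <- gaps[sample.int(nrow(gaps), 1L), ]
        len <- sample(100:min(1000L, gp[2L] - gp[1L] - 100L), 1L)
        s <- gp[1L] + 50L + sample(0:(gp[2L] - gp[1L] - 100L - len), 1L)
        e <- s + len
        st <- sample(c("+", "-"), 1L)
        best <- "NA"
      } else if (kind == 1L) {
        # antisense exact span of a transcript
        t <- all_tx[[sample.int(length(all_tx), 1L)]]
        ch <- t$chrom
        s <- t$starts[1L]
        e <- t$ends[length(t$ends)]
        st <- if (t$strand == "+") "-" else "+"
        best <- t$id
      } else {
        # straddle a gene's edge into intergenic space
        g <- genes[[sample.int(length(genes), 1L)]]
        t <- g$txs[[sample.int(g$ntx, 1L)]]
        ch <- g$chrom
        span <- t$ends[length(t$ends)] - t$starts[1L]
        s <- t$starts[1L] + sample.int(span - 1L, 1L)
        e <- g$slot[2L] + sample(20:100, 1L)
        st <- t$strand
        best <- "NA"
      }
      if (is_used(ch, s, e, st)) next
      seq <- gsub_seq(ch, s, e)
      if (st == "-") seq <- reverse_complement(seq)
      return(list(chrom = ch, start = s, end = e, strand = st,
                  class = "other", best = best,
                  sizes = e - s, offsets = 0L, seq = seq))
    }
    .stopf("failed to plant an 'other' call after bounded retries")
  }

  planted <- c(
    lapply(seq_len(counts[["exonic"]]), function(i) plant_exonic()),
    lapply(seq_len(counts[["intronic"]]), function(i) plant_intronic()),
    lapply(seq_len(counts[["other"]]), function(i) plant_other())
  )
  planted <- planted[sample.int(length(planted))]

  # boundary jitter: truth no longer forced by construction -> NA truth
  if (spec$boundary_noise > 0) {
    for (i in seq_along(planted)) {
      if (stats::runif(1) < spec$boundary_noise) {
        p <- planted[[i]]
        p$start <- max(0L, p$start + sample(c(-3:-1, 1:3), 1L))
        p$end <- min(spec$chrom_length, p$end + sample(c(-3:-1, 1:3), 1L))
        if (p$start >= p$end) p$end <- p$start + 1L
        p$class <- NA_character_
        p$best <- NA_character_
        p$sizes <- NA_integer_
        p$offsets <- NA_integer_
        p$seq <- NA_character_
        planted[[i]] <- p
      }
    }
  }

  ids <- sprintf("circ_%04d", seq_along(planted))
  calls <- data.frame(
    id = ids,
    chrom = vapply(planted, `[[`, character(1), "chrom"),
    start = vapply(planted, function(p) as.integer(p$start), integer(1)),
    end = vapply(planted, function(p) as.integer(p$end), integer(1)),
    strand = vapply(planted, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE
  )
  class(calls) <- c("circ_calls", "data.frame")
  truth <- data.frame(
    id = ids,
    class = vapply(planted, `[[`, character(1), "class"),
    best_transcript = vapply(planted, `[[`, character(1), "best"),
    block_sizes = vapply(planted, function(p)
      paste(p$sizes, collapse = ","), character(1)),
    block_offsets = vapply(planted, function(p)
      paste(p$offsets, collapse = ","), character(1)),
    sequence = vapply(planted, `[[`, character(1), "seq"),
    stringsAsFactors = FALSE
  )

  ## ---- render files -----------------------------------------------------
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    gff3 = file.path(dir, "annotation.gff3"),
    calls_bed_like = file.path(dir, "calls_bed_like.tsv"),
    calls_one_based = file.path(dir, "calls_one_based.tsv"),
    truth = file.path(dir, "truth.tsv")
  )

  .write_lines <- function(lines, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
  }

  fa <- unlist(lapply(chroms, function(ch) {
    s <- genome[[ch]]
    c(paste0(">", ch),
      substring(s, seq(1, nchar(s), by = 70), pmin(seq(70, nchar(s) + 69, by = 70), nchar(s))))
  }))
  .write_lines(fa, paths$genome)

  gtf <- unlist(lapply(genes, function(g) {
    unlist(lapply(g$txs, function(t) {
      attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                       g$id, t$id, g$id)
      c(sprintf("%s\tfixture\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                g$chrom, t$starts[1L] + 1L, t$ends[length(t$ends)], g$strand, attrs),
        sprintf("%s\tfixture\texon\t%d\t%d\t.\t%s\t.\t%s",
                g$chrom, t$starts + 1L, t$ends, g$strand, attrs))
    }))
  }))
  .write_lines(gtf, paths$gtf)

  gff3 <- c("##gff-version 3", unlist(lapply(genes, function(g) {
    gene_line <- sprintf("%s\tfixture\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                         g$chrom,
                         min(vapply(g$txs, function(t) t$starts[1L], integer(1))) + 1L,
                         max(vapply(g$txs, function(t) t$ends[length(t$ends)], integer(1))),
                         g$strand, g$id, g$id)
    c(gene_line, unlist(lapply(g$txs, function(t) {
      c(sprintf("%s\tfixture\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                g$chrom, t$starts[1L] + 1L, t$ends[length(t$ends)], g$strand,
                t$id, g$id),
        sprintf("%s\tfixture\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                g$chrom, t$starts + 1L, t$ends, g$strand,
                t$id, seq_along(t$starts), t$id))
    })))
  })))
  .write_lines(gff3, paths$gff3)

  .write_lines(paste(calls$chrom, calls$start, calls$end, calls$strand,
                     calls$id, sep = "\t"), paths$calls_bed_like)
  .write_lines(paste(calls$chrom, calls$start + 1L, calls$end, calls$strand,
                     calls$id, sep = "\t"), paths$calls_one_based)

  .write_lines(c(paste(c("id", "class", "best_transcript", "block_sizes",
                         "block_offsets", "sequence"), collapse = "\t"),
                 paste(truth$id, truth$class, truth$best_transcript,
                       truth$block_sizes, truth$block_offsets, truth$sequence,
                       sep = "\t")),
               paths$truth)

  list(spec = spec, dir = dir, paths = paths, transcripts = tt,
       calls = calls, truth = truth, genome = genome)
}
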