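#' Start/End containment flags for a circRNA against its best transcript
#'
#' Given the best transcript's exons that overlap the circRNA boundary,
#' `start_flag = 1` when the circRNA start lies at or after the start of
#' the first overlapping exon (i.e. inside it, since overlap already forces
#' `call.start < exon.end`), and `end_flag = 1` when the circRNA end lies
#' at or before the end of the last overlapping exon.
#'
#' @param call A single call with `start`, `end`.
#' @param best One transcript row (a candidate containing the call, with at
#'   least one exon overlapping the boundary).
#' @return A list with integer `start_flag`, `end_flag` in \{0, 1\}.
#' @export
compute_flags <- function(call, best) {
  be <- exons_in_boundary(best, call)
  if (nrow(be) == 0L) {
    .stopf("compute_flags requires at least one exon overlapping the boundary")
  }
  list(
    start_flag = as.integer(call$start >= be$start[1L]),
    end_flag = as.integer(call$end <= be$end[nrow(be)])
  )
}

# NA-safe field extraction for records without a best transcript
.na_chr <- "NA"

.classify_one <- function(call, sel) {
  span <- call$end - call$start
  base <- list(
    circ_id = call$id, chrom = call$chrom, start = call$start, end = call$end,
    strand = call$strand,
    length = span, circ_class = "other", block_count = 1L,
    block_sizes = list(span), block_offsets = list(0L),
    best_transcript = .na_chr, transcript_strand = .na_chr,
    transcript_start = NA_integer_, transcript_end = NA_integer_,
    host_gene = .na_chr
  )
  best <- sel$best
  if (is.null(best)) return(base)

  base$best_transcript <- best$transcript_id
  base$transcript_strand <- best$strand
  base$transcript_start <- best$start
  base$transcript_end <- best$end
  base$host_gene <- best$gene

  be <- exons_in_boundary(best, call)
  if (nrow(be) > 0L) {
    fl <- compute_flags(call, best)
    strands_ok <- call$strand == "." || call$strand == best$strand
    if (fl$start_flag == 1L && fl$end_flag == 1L && strands_ok) {
      bs <- pmax(be$start, call$start)
      bend <- pmin(be$end, call$end)
      base$circ_class <- "exonic"
      base$block_count <- nrow(be)
      base$block_sizes <- list(as.integer(bend - bs))
      base$block_offsets <- list(as.integer(bs - call$start))
      base$length <- sum(bend - bs)
    }
    return(base)
  }

  # no exon overlaps the boundary: intronic iff the call sits inside one intron
  s <- best$exon_starts[[1L]]
  e <- best$exon_ends[[1L]]
  if (length(s) >= 2L) {
    in_intron <- any(e[-length(e)] <= call$start & call$end <= s[-1L])
    if (in_intron) base$circ_class <- "intronic"
  }
  base
}

#' Classify circRNAs as exonic, intronic, or other
#'
#' Applies the location-oriented three-way classification to every call
#' using its best transcript:
#'
#' * no best transcript -> `other`;
#' * exons overlap the boundary, both containment flags are 1, and the
#'   circRNA strand equals the transcript strand (or is unknown) ->
#'   `exonic`, with one block per boundary exon clipped to the call
#'   interval (only the first and last block can be clipped);
#' * no exon overlaps the boundary and the call lies within a single
#'   intron -> `intronic`, one block spanning the call;
#' * anything else -> `other`, one block spanning the call.
#'
#' The `length` column is the sum of block sizes: the spliced length for
#' exonic records, the genomic span otherwise.
#'
#' @param calls A `circ_calls` data.frame.
#' @param tt A [transcript_table()].
#' @param selections Optional precomputed [select_best()] result.
#' @return A `circ_classification` data.frame with the 15 columns
#'   `circ_id`, `chrom`, `start`, `end`, `strand`, `length`, `circ_class`,
#'   `block_count`, `block_sizes`, `block_offsets`, `best_transcript`,
#'   `transcript_strand`, `transcript_start`, `transcript_end`,
#'   `host_gene` (block columns are list columns of integer vectors).
#' @export
classify_calls <- function(calls, tt, selections = NULL) {
  if (is.null(selections)) selections <- select_best(calls, tt)
  recs <- lapply(seq_len(nrow(calls)), function(i) {
    .classify_one(calls[i, , drop = FALSE], selections[[i]])
  })
  out <- data.frame(
    circ_id = vapply(recs, `[[`, character(1), "circ_id"),
    chrom = vapply(recs, `[[`, character(1), "chrom"),
    start = vapply(recs, `[[`, integer(1), "start"),
    end = vapply(recs, `[[`, integer(1), "end"),
    strand = vapply(recs, `[[`, character(1), "strand"),
    length = vapply(recs, `[[`, integer(1), "length"),
    circ_class = vapply(recs, `[[`, character(1), "circ_class"),
    block_count = vapply(recs, `[[`, integer(1), "block_count"),
    stringsAsFactors = FALSE
  )
  out$block_sizes <- lapply(recs, function(r) r$block_sizes[[1L]])
  out$block_offsets <- lapply(recs, function(r) r$block_offsets[[1L]])
  out$best_transcript <- vapply(recs, `[[`, character(1), "best_transcript")
  out$transcript_strand <- vapply(recs, `[[`, character(1), "transcript_strand")
  out$transcript_start <- vapply(recs, `[[`, integer(1), "transcript_start")
  out$transcript_end <- vapply(recs, `[[`, integer(1), "transcript_end")
  out$host_gene <- vapply(recs, `[[`, character(1), "host_gene")
  class(out) <- c("circ_classification", "data.frame")
  out
}

.CLS_COLS <- c("circ_id", "chrom", "start", "end", "strand", "length",
               "circ_class", "block_count", "block_sizes", "block_offsets",
               "best_transcript", "transcript_strand", "transcript_start",
               "transcript_end", "host_gene")

#' Write the 15-column classification table
#'
#' Tab-separated, one row per circRNA, in the fixed 15-column order (id,
#' chromosome, start, end, strand, length, class, block count, comma-joined
#' block sizes, comma-joined block offsets, best transcript, transcript
#' strand, transcript start, transcript end, host gene). Missing transcript
#' fields are the literal `NA`.
#'
#' @param cls A `circ_classification` data.frame.
#' @param path Output path.
#' @param header Write a header line? (default `FALSE`).
#' @export
write_classification <- function(cls, path, header = FALSE) {
  ts <- ifelse(is.na(cls$transcript_start), "NA", as.character(cls$transcript_start))
  te <- ifelse(is.na(cls$transcript_end), "NA", as.character(cls$transcript_end))
  lines <- paste(cls$circ_id, cls$chrom, cls$start, cls$end, cls$strand,
                 cls$length, cls$circ_class, cls$block_count,
                 .join_ints(cls$block_sizes), .join_ints(cls$block_offsets),
                 cls$best_transcript, cls$transcript_strand, ts, te,
                 cls$host_gene, sep = "\t")
  if (header) lines <- c(paste(.CLS_COLS, collapse = "\t"), lines)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a 15-column classification table
#'
#' Inverse of [write_classification()]; detects and skips a header line.
#'
#' @param path Path to a classification TSV.
#' @return A `circ_classification` data.frame.
#' @export
read_classification <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && is.na(suppressWarnings(as.integer(fields[[1L]][3L])))) {
    fields <- fields[-1L]
  }
  nc <- lengths(fields)
  if (any(nc != 15L)) {
    .stopf("line %d of '%s' has %d columns, expected 15",
           which(nc != 15L)[1L], path, nc[nc != 15L][1L])
  }
  m <- do.call(rbind, fields)
  out <- data.frame(
    circ_id = m[, 1L], chrom = m[, 2L],
    start = as.integer(m[, 3L]), end = as.integer(m[, 4L]),
    strand = m[, 5L], length = as.integer(m[, 6L]),
    circ_class = m[, 7L], block_count = as.integer(m[, 8L]),
    stringsAsFactors = FALSE
  )
  out$block_sizes <- .split_ints(m[, 9L])
  out$block_offsets <- .split_ints(m[, 10L])
  out$best_transcript <- m[, 11L]
  out$transcript_strand <- m[, 12L]
  out$transcript_start <- suppressWarnings(as.integer(m[, 13L]))
  out$transcript_end <- suppressWarnings(as.integer(m[, 14L]))
  out$host_gene <- m[, 15L]
  class(out) <- c("circ_classification", "data.frame")
  out
}

#' Export exonic circRNAs as BED12
#'
#' Writes the exonic records of a classification as BED12, with the same
#' block structure as the classification table. thickStart/thickEnd equal
#' the interval; itemRgb is 0.
#'
#' @param cls A `circ_classification` data.frame.
#' @param path Output path.
#' @export
write_bed12 <- function(cls, path) {
  ex <- cls[cls$circ_class == "exonic", , drop = FALSE]
  lines <- paste(ex$chrom, ex$start, ex$end, ex$circ_id, 0L, ex$strand,
                 ex$start, ex$end, 0L, ex$block_count,
                 vapply(ex$block_sizes, function(x) paste0(paste(x, collapse = ","), ","), character(1)),
                 vapply(ex$block_offsets, function(x) paste0(paste(x, collapse = ","), ","), character(1)),
                 sep = "\t")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
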