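#' Build a transcript table from exon structures
#'
#' The transcript table is the package's central annotation model: one row
#' per transcript with its ordered exon structure, in 0-based half-open
#' genomic coordinates (so exon length = end - start, and splicing is plain
#' substring concatenation). It corresponds 1:1 to the 9-column text file
#' written by [write_transcript_table()].
#'
#' @param id Character vector of transcript identifiers (unique).
#' @param chrom Character vector of chromosome names.
#' @param strand Character vector, each `"+"` or `"-"`.
#' @param exon_starts,exon_ends Lists of integer vectors, one per
#'   transcript, 0-based half-open, ascending and non-overlapping.
#' @param gene Character vector of host gene names (default `"NA"`).
#' @return A `transcript_table`: a data.frame with columns `transcript_id`,
#'   `chrom`, `strand`, `start`, `end`, `exon_count`, and list columns
#'   `exon_starts`, `exon_ends`, plus `gene`.
#' @examples
#' transcript_table("t1", "chr1", "+", list(c(10L, 30L)), list(c(20L, 40L)), "g1")
#' @export
transcript_table <- function(id, chrom, strand, exon_starts, exon_ends,
                             gene = rep("NA", length(id))) {
  n <- length(id)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(strand) == 1L) strand <- rep(strand, n)
  if (length(gene) == 1L && n > 1L) gene <- rep(gene, n)
  stopifnot(n == length(chrom), n == length(strand),
            n == length(exon_starts), n == length(exon_ends))
  exon_starts <- lapply(exon_starts, as.integer)
  exon_ends <- lapply(exon_ends, as.integer)
  tt <- data.frame(
    transcript_id = as.character(id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    start = vapply(exon_starts, function(x) x[1L], integer(1)),
    end = vapply(exon_ends, function(x) x[length(x)], integer(1)),
    exon_count = lengths(exon_starts),
    stringsAsFactors = FALSE
  )
  tt$exon_starts <- exon_starts
  tt$exon_ends <- exon_ends
  tt$gene <- as.character(gene)
  class(tt) <- c("transcript_table", "data.frame")
  validate_transcript_table(tt)
  tt
}

#' Validate transcript-table invariants
#'
#' Checks, for every row: at least one exon; exons ascending and
#' non-overlapping; positive exon lengths; transcript start/end equal to the
#' first exon start / last exon end; strand one of `+`/`-`; unique ids.
#'
#' @param tt A `transcript_table`.
#' @return `tt`, invisibly; errors on the first violated invariant.
#' @export
validate_transcript_table <- function(tt) {
  need <- c("transcript_id", "chrom", "strand", "start", "end",
            "exon_count", "exon_starts", "exon_ends", "gene")
  if (!all(need %in% names(tt))) {
    .stopf("transcript table is missing columns: %s",
           paste(setdiff(need, names(tt)), collapse = ", "))
  }
  if (anyDuplicated(tt$transcript_id)) {
    .stopf("duplicate transcript id: %s",
           tt$transcript_id[duplicated(tt$transcript_id)][1L])
  }
  if (!all(tt$strand %in% c("+", "-"))) {
    .stopf("transcript strand must be '+' or '-' (offending id: %s)",
           tt$transcript_id[!tt$strand %in% c("+", "-")][1L])
  }
  for (i in seq_len(nrow(tt))) {
    s <- tt$exon_starts[[i]]
    e <- tt$exon_ends[[i]]
    if (length(s) < 1L || length(s) != length(e)) {
      .stopf("transcript %s: malformed exon lists", tt$transcript_id[i])
    }
    if (any(e <= s)) {
      .stopf("transcript %s: exon with non-positive length", tt$transcript_id[i])
    }
    if (length(s) > 1L && any(s[-1L] < e[-length(e)])) {
      .stopf("transcript %s: exons overlap or are unsorted", tt$transcript_id[i])
    }
    if (tt$start[i] != s[1L] || tt$end[i] != e[length(e)]) {
      .stopf("transcript %s: span does not match exon extremes", tt$transcript_id[i])
    }
    if (tt$exon_count[i] != length(s)) {
      .stopf("transcript %s: exon_count mismatch", tt$transcript_id[i])
    }
  }
  invisible(tt)
}

.detect_annotation_format <- function(path) {
  base <- sub("\\.(gz|bgz)$", "", basename(path))
  ext <- tolower(tools::file_ext(base))
  if (ext == "gtf") return("gtf")
  if (ext %in% c("gff", "gff3")) return("gff3")
  con <- gzfile(path, "rt")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) .stopf("cannot detect annotation format of '%s'", path)
    if (!startsWith(ln, "#") && nzchar(trimws(ln))) break
  }
  attr_col <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
  if (length(attr_col) < 9L) {
    .stopf("annotation line has %d tab-separated columns, expected >= 9: %s",
           length(attr_col), substr(ln, 1, 80))
  }
  if (grepl("\"", attr_col[9L], fixed = TRUE)) "gtf" else "gff3"
}

# first non-NA element, else fallback
.first_ok <- function(..., fallback = "NA") {
  for (v in list(...)) {
    if (length(v) >= 1L && !is.na(v[1L]) && nzchar(v[1L])) return(as.character(v[1L]))
  }
  fallback
}

#' Parse a GTF/GFF3 gene annotation into a transcript table
#'
#' Transcripts are assembled from `exon` feature lines only (parent
#' `transcript`/`mRNA` lines are optional, since many GTFs lack them and the
#' transcript span is defined by its exon extremes). Exon coordinates are
#' converted from the annotation's 1-based inclusive convention to 0-based
#' half-open by subtracting 1 from every start; ends are kept as printed.
#'
#' Host-gene resolution: GTF prefers `gene_name`, then `gene_id`; GFF3
#' prefers a `gene_name`/`gene` attribute, then the `Parent`-resolved gene
#' record's `Name`, then the gene record id; otherwise the literal `"NA"`.
#'
#' Transcripts whose exon lines carry a strand other than `+`/`-` are
#' excluded with a warning (strand is load-bearing for exonic
#' classification). A transcript id that recurs on different chromosomes or
#' strands is suffix-disambiguated (`id_2`, `id_3`, ...) with a warning.
#'
#' @param path Path to a GTF or GFF3 file (optionally gzip-compressed).
#' @param format `"gtf"`, `"gff3"`, or `"auto"` (detect from extension, then
#'   from the attribute dialect of the first data line).
#' @param chr_style Chromosome-name reconciliation, see [normalize_chrom()].
#' @return A [transcript_table()] whose row order is the first-appearance
#'   order of each transcript in the file (this order is the final
#'   tie-breaker of best-transcript selection).
#' @seealso [write_transcript_table()], [read_transcript_table()]
#' @export
parse_annotation <- function(path, format = c("auto", "gtf", "gff3"),
                             chr_style = "keep") {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("annotation file not found: %s", path)
  if (format == "auto") format <- .detect_annotation_format(path)

  gr <- rtracklayer::import(path, format = if (format == "gtf") "gtf" else "gff3")
  mc <- S4Vectors::mcols(gr)
  is_exon <- !is.na(mc$type) & as.character(mc$type) == "exon"
  ex <- gr[is_exon]
  if (length(ex) == 0L) .stopf("no exon features found in '%s'", path)
  exm <- S4Vectors::mcols(ex)

  getcol <- function(m, col) if (col %in% names(m)) m[[col]] else NULL

  if (format == "gtf") {
    tid <- as.character(getcol(exm, "transcript_id"))
    if (is.null(tid) || anyNA(tid)) {
      .stopf("GTF exon feature lacking a transcript_id attribute in '%s'", path)
    }
    gname <- getcol(exm, "gene_name")
    gid <- getcol(exm, "gene_id")
    gene <- vapply(seq_along(ex), function(i) {
      .first_ok(if (!is.null(gname)) gname[i], if (!is.null(gid)) gid[i])
    }, character(1))
    chrom <- as.character(GenomicRanges::seqnames(ex))
    strand <- as.character(GenomicRanges::strand(ex))
    start0 <- GenomicRanges::start(ex) - 1L
    end1 <- GenomicRanges::end(ex)
    # transcript rows without any exon child
    is_tx <- !is.na(mc$type) & as.character(mc$type) %in% c("transcript", "mRNA")
    tx_ids <- unique(as.character(getcol(S4Vectors::mcols(gr[is_tx]), "transcript_id")))
  } else {
    parents <- getcol(exm, "Parent")
    if (is.null(parents)) .stopf("GFF3 exon feature lacking a Parent attribute in '%s'", path)
    plen <- lengths(parents)
    if (any(plen == 0L)) .stopf("GFF3 exon with empty Parent attribute in '%s'", path)
    idx <- rep(seq_along(ex), plen)
    tid <- as.character(unlist(parents))
    chrom <- as.character(GenomicRanges::seqnames(ex))[idx]
    strand <- as.character(GenomicRanges::strand(ex))[idx]
    start0 <- (GenomicRanges::start(ex) - 1L)[idx]
    end1 <- GenomicRanges::end(ex)[idx]

    # resolve transcript -> gene through mRNA/transcript and gene records
    typ <- as.character(mc$type)
    is_tx <- !is.na(typ) & typ %in% c("mRNA", "transcript")
    is_gene <- !is.na(typ) & typ == "gene"
    txm <- S4Vectors::mcols(gr[is_tx])
    tx_id_vec <- as.character(getcol(txm, "ID"))
    tx_parent <- getcol(txm, "Parent")
    tx_parent <- if (is.null(tx_parent)) rep(NA_character_, sum(is_tx)) else
      vapply(as.list(tx_parent), function(p) if (length(p)) as.character(p[1L]) else NA_character_, character(1))
    tx_gname <- getcol(txm, "gene_name")
    gm <- S4Vectors::mcols(gr[is_gene])
    gene_id_vec <- as.character(getcol(gm, "ID"))
    gene_name_vec <- getcol(gm, "Name")
    ex_gene_attr <- getcol(exm, "gene")
    ex_gname_attr <- getcol(exm, "gene_name")

    gene <- vapply(seq_along(tid), function(k) {
      i <- idx[k]
      t <- tid[k]
      j <- if (length(tx_id_vec)) match(t, tx_id_vec) else NA_integer_
      gid <- if (!is.na(j)) tx_parent[j] else NA_character_
      gj <- if (!is.na(gid) && length(gene_id_vec)) match(gid, gene_id_vec) else NA_integer_
      .first_ok(
        if (!is.null(ex_gname_attr)) ex_gname_attr[i],
        if (!is.null(ex_gene_attr)) ex_gene_attr[i],
        if (!is.null(tx_gname) && !is.na(j)) tx_gname[j],
        if (!is.null(gene_name_vec) && !is.na(gj)) as.character(gene_name_vec[gj]),
        gid
      )
    }, character(1))
    tx_ids <- tx_id_vec
  }

  chrom <- normalize_chrom(chrom, chr_style)

  # group exons by (transcript id, chrom, strand) in first-appearance order
  key <- paste(tid, chrom, strand, sep = "\r")
  ukey <- unique(key)
  ord <- match(key, ukey)
  utid <- vapply(strsplit(ukey, "\r", fixed = TRUE), `[`, character(1), 1L)

  # transcripts listed in the annotation but having no exon features
  if (length(tx_ids)) {
    orphans <- setdiff(tx_ids[!is.na(tx_ids)], utid)
    if (length(orphans)) {
      .warnf("%d transcript(s) with no exon features excluded (e.g. %s)",
             length(orphans), orphans[1L])
    }
  }

  # suffix-disambiguate a transcript id recurring on other chrom/strand
  if (anyDuplicated(utid)) {
    dups <- unique(utid[duplicated(utid)])
    .warnf("transcript id(s) on multiple chromosomes/strands disambiguated with suffixes: %s",
           paste(dups, collapse = ", "))
    for (d in dups) {
      w <- which(utid == d)
      utid[w[-1L]] <- paste0(d, "_", seq_along(w[-1L]) + 1L)
    }
  }

  first_of <- match(seq_along(ukey), ord)
  keep <- logical(length(ukey))
  rows <- vector("list", length(ukey))
  for (g in seq_along(ukey)) {
    sel <- which(ord == g)
    st <- strand[sel[1L]]
    if (!st %in% c("+", "-")) {
      .warnf("transcript %s excluded: strand '%s' is not '+'/'-'", utid[g], st)
      next
    }
    o <- order(start0[sel])
    rows[[g]] <- list(
      id = utid[g], chrom = chrom[sel[1L]], strand = st,
      starts = start0[sel][o], ends = end1[sel][o], gene = gene[sel[1L]]
    )
    keep[g] <- TRUE
  }
  rows <- rows[keep]
  if (!length(rows)) .stopf("no usable transcripts parsed from '%s'", path)

  transcript_table(
    id = vapply(rows, `[[`, character(1), "id"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    exon_starts = lapply(rows, `[[`, "starts"),
    exon_ends = lapply(rows, `[[`, "ends"),
    gene = vapply(rows, `[[`, character(1), "gene")
  )
}

.TT_COLS <- c("transcript_id", "chrom", "strand", "start", "end",
              "exon_count", "exon_starts", "exon_ends", "gene")

#' Write the 9-column transcript table
#'
#' Emits one tab-separated row per transcript: id, chromosome, strand,
#' transcript start, transcript end, exon count, comma-joined exon starts,
#' comma-joined exon ends, host gene. Coordinates are 0-based half-open.
#' Round-trips losslessly through [read_transcript_table()].
#'
#' @param tt A [transcript_table()].
#' @param path Output path.
#' @param header Write a header line? (default `FALSE`).
#' @export
write_transcript_table <- function(tt, path, header = FALSE) {
  validate_transcript_table(tt)
  if (nrow(tt) == 0L) .stopf("refusing to write an empty transcript table")
  lines <- paste(tt$transcript_id, tt$chrom, tt$strand,
                 tt$start, tt$end, tt$exon_count,
                 .join_ints(tt$exon_starts), .join_ints(tt$exon_ends),
                 tt$gene, sep = "\t")
  if (header) lines <- c(paste(.TT_COLS, collapse = "\t"), lines)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a 9-column transcript table
#'
#' Inverse of [write_transcript_table()]. A header line is detected (start
#' column not numeric) and skipped. Any row without exactly 9 tab-separated
#' columns is a parse error naming the line.
#'
#' @param path Path to a transcript-table TSV.
#' @return A [transcript_table()].
#' @export
read_transcript_table <- function(path) {
  if (!file.exists(path)) .stopf("transcript table not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) .stopf("empty transcript table: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  offset <- 0L
  if (length(fields[[1L]]) >= 4L && is.na(suppressWarnings(as.integer(fields[[1L]][4L])))) {
    fields <- fields[-1L]
    offset <- 1L
    if (!length(fields)) .stopf("transcript table has only a header: %s", path)
  }
  nc <- lengths(fields)
  if (any(nc != 9L)) {
    bad <- which(nc != 9L)[1L]
    .stopf("line %d of '%s' has %d columns, expected 9", bad + offset, path, nc[bad])
  }
  m <- do.call(rbind, fields)
  transcript_table(
    id = m[, 1L], chrom = m[, 2L], strand = m[, 3L],
    exon_starts = .split_ints(m[, 7L]),
    exon_ends = .split_ints(m[, 8L]),
    gene = m[, 9L]
  )
}
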