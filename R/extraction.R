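#' Load a reference genome from FASTA
#'
#' Reads all chromosome sequences into memory (uppercasing soft-masked
#' lowercase runs; `N` and other IUPAC codes are preserved). Header names
#' are truncated at the first whitespace, matching common aligner
#' behaviour.
#'
#' @param path FASTA file (optionally gzip-compressed).
#' @param chr_style Chromosome-name reconciliation, see [normalize_chrom()].
#' @return A named [Biostrings::DNAStringSet].
#' @export
load_genome <- function(path, chr_style = "keep") {
  if (!file.exists(path)) .stopf("genome FASTA not found: %s", path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- normalize_chrom(sub("\\s.*$", "", names(g)), chr_style)
  g
}

#' Reverse-complement a nucleotide string
#'
#' An involution over the IUPAC nucleotide alphabet: `rc(rc(s)) = s`,
#' length-preserving, complementing ambiguity codes.
#'
#' @param seq A single nucleotide string (IUPAC codes allowed).
#' @return The reverse complement, as a character string.
#' @examples
#' reverse_complement("AAAC") # "GTTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  bad <- regexpr("[^ACGTUNRYSWKMBDHVacgtunryswkmbdhv]", seq)
  if (bad > 0L) {
    .stopf("non-nucleotide character '%s' at position %d",
           substr(seq, bad, bad), bad)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

.genome_subseq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    .stopf("chromosome '%s' not in genome (available: %s%s); check --chr-style if the naming differs",
           chrom, paste(utils::head(names(genome), 5), collapse = ", "),
           if (length(genome) > 5) ", ..." else "")
  }
  clen <- length(genome[[chrom]])
  if (end > clen) {
    .stopf("block [%d,%d) exceeds length %d of chromosome '%s'", start, end, clen, chrom)
  }
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

#' Extract the full-length sequence of one classified circRNA
#'
#' Concatenates the genome substring of every block (start + offset, size)
#' in ascending genomic order, then reverse-complements when the
#' orientation strand is `-`. The orientation strand is the circRNA's
#' strand; when that is unknown (`.`) the best transcript's strand is
#' used, and `+` when both are unknown. For exonic records the blocks are
#' the boundary exons clipped to the call, so this is the spliced
#' sequence; for intronic/other records the single block is the raw
#' genomic span.
#'
#' @param rec One classification row (from [classify_calls()]).
#' @param genome A genome as returned by [load_genome()].
#' @param revcomp Emit minus-orientation sequences as their reverse
#'   complement (default). `FALSE` emits genomic plus-strand orientation
#'   for all records (useful for database comparisons).
#' @return A list with `id`, `circ_class`, `sequence`, `length`.
#' @export
extract_sequence <- function(rec, genome, revcomp = TRUE) {
  sizes <- rec$block_sizes[[1L]]
  offsets <- rec$block_offsets[[1L]]
  pieces <- vapply(seq_along(sizes), function(k) {
    s <- rec$start + offsets[k]
    .genome_subseq(genome, rec$chrom, s, s + sizes[k])
  }, character(1))
  seq <- paste(pieces, collapse = "")
  ori <- if (rec$strand %in% c("+", "-")) rec$strand
         else if (rec$transcript_strand %in% c("+", "-")) rec$transcript_strand
         else "+"
  if (revcomp && ori == "-") seq <- reverse_complement(seq)
  list(id = rec$circ_id, circ_class = rec$circ_class,
       sequence = seq, length = nchar(seq))
}

#' Extract sequences for all classified circRNAs
#'
#' @param cls A `circ_classification` data.frame.
#' @param genome A genome as returned by [load_genome()].
#' @param revcomp See [extract_sequence()].
#' @return A data.frame with columns `id`, `circ_class`, `sequence`,
#'   `length`, in classification order.
#' @export
extract_sequences <- function(cls, genome, revcomp = TRUE) {
  recs <- lapply(seq_len(nrow(cls)), function(i) {
    extract_sequence(cls[i, , drop = FALSE], genome, revcomp = revcomp)
  })
  data.frame(
    id = vapply(recs, `[[`, character(1), "id"),
    circ_class = vapply(recs, `[[`, character(1), "circ_class"),
    sequence = vapply(recs, `[[`, character(1), "sequence"),
    length = vapply(recs, `[[`, integer(1), "length"),
    stringsAsFactors = FALSE
  )
}

#' Write circRNA sequences as FASTA
#'
#' Headers are `>{id} class={circ_class} len={length}`; sequence lines wrap
#' at `line_width`. Duplicate ids abort before anything is written.
#'
#' @param seqs Data.frame from [extract_sequences()].
#' @param path Output path.
#' @param line_width Positive wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, line_width = 60L) {
  stopifnot(line_width >= 1L)
  if (anyDuplicated(seqs$id)) {
    .stopf("duplicate sequence id: %s", seqs$id[duplicated(seqs$id)][1L])
  }
  x <- Biostrings::DNAStringSet(seqs$sequence)
  names(x) <- sprintf("%s class=%s len=%d", seqs$id, seqs$circ_class, seqs$length)
  Biostrings::writeXStringSet(x, path, width = as.integer(line_width))
  invisible(path)
}
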