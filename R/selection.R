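#' Candidate transcripts containing a circRNA boundary
#'
#' A transcript is a candidate for a circRNA when it lies on the same
#' chromosome and its genomic span contains the circRNA boundary,
#' boundary-touching included: `transcript.start <= call.start` and
#' `transcript.end >= call.end`. Strand is deliberately not a containment
#' criterion; strand agreement is enforced later, at classification, where
#' it defines the exonic class.
#'
#' @param call A single call: list/one-row data.frame with `chrom`,
#'   `start`, `end`.
#' @param tt A [transcript_table()].
#' @return The candidate rows of `tt`, in table order (possibly empty).
#' @export
candidate_transcripts <- function(call, tt) {
  sel <- tt$chrom == call$chrom & tt$start <= call$start & tt$end >= call$end
  tt[sel, , drop = FALSE]
}

#' Splice length of a transcript
#'
#' Total exon length (the length of the spliced product), as opposed to the
#' genomic span `end - start`.
#'
#' @param t One transcript row (list with `exon_starts`, `exon_ends`).
#' @return Integer number of bases.
#' @export
splice_length <- function(t) {
  sum(t$exon_ends[[1L]] - t$exon_starts[[1L]])
}

#' Exons of a transcript overlapping a circRNA boundary
#'
#' Returns the exons that overlap the half-open interval
#' `[call.start, call.end)`, i.e. `exon.start < call.end` and
#' `exon.end > call.start`, in genomic order. An exon merely touching the
#' boundary (`exon.end == call.start`) does not overlap.
#'
#' @param t One transcript row.
#' @param call A single call with `start`, `end`.
#' @return A data.frame with columns `start`, `end` (possibly 0 rows).
#' @export
exons_in_boundary <- function(t, call) {
  s <- t$exon_starts[[1L]]
  e <- t$exon_ends[[1L]]
  keep <- s < call$end & e > call$start
  data.frame(start = s[keep], end = e[keep])
}

#' Select the best host transcript for one circRNA
#'
#' Implements the two-case selection cascade over the candidates (which
#' must be in annotation-file order):
#'
#' * Exact-boundary case: if any candidate's first-exon start and last-exon
#'   end coincide exactly with the circRNA boundary, the winner is chosen
#'   among those exact matchers by (a) maximum splice length, (b) maximum
#'   genomic span, (c) first in table order.
#' * Otherwise: among all candidates, (a) maximum number of exons
#'   overlapping the boundary, (b) maximum genomic span, (c) first in table
#'   order.
#'
#' The cascade is a pure function of `(call, candidates-in-order)`.
#'
#' @param call A single call with `chrom`, `start`, `end` (and `id` if
#'   available).
#' @param candidates Candidate transcripts in table order, as returned by
#'   [candidate_transcripts()].
#' @return A list with `call_id`, `best` (one-row transcript table, or
#'   `NULL`), `case_used` (`"exact_boundary_match"`,
#'   `"max_exons_in_boundary"`, or `"no_candidate"`), `candidate_count`.
#' @export
select_best_transcript <- function(call, candidates) {
  call_id <- if (!is.null(call$id)) call$id else
    sprintf("%s:%d-%d", call$chrom, call$start, call$end)
  n <- nrow(candidates)
  if (is.null(n) || n == 0L) {
    return(list(call_id = call_id, best = NULL,
                case_used = "no_candidate", candidate_count = 0L))
  }
  exact <- candidates$start == call$start & candidates$end == call$end
  if (any(exact)) {
    pool <- which(exact)
    sl <- vapply(pool, function(i) splice_length(candidates[i, , drop = FALSE]), numeric(1))
    pool <- pool[sl == max(sl)]
    if (length(pool) > 1L) {
      span <- candidates$end[pool] - candidates$start[pool]
      pool <- pool[span == max(span)]
    }
    best <- candidates[pool[1L], , drop = FALSE]
    case <- "exact_boundary_match"
  } else {
    nex <- vapply(seq_len(n), function(i) {
      nrow(exons_in_boundary(candidates[i, , drop = FALSE], call))
    }, integer(1))
    pool <- which(nex == max(nex))
    if (length(pool) > 1L) {
      span <- candidates$end[pool] - candidates$start[pool]
      pool <- pool[span == max(span)]
    }
    best <- candidates[pool[1L], , drop = FALSE]
    case <- "max_exons_in_boundary"
  }
  list(call_id = call_id, best = best, case_used = case, candidate_count = n)
}

#' Select best transcripts for a set of calls
#'
#' Convenience wrapper running [candidate_transcripts()] then
#' [select_best_transcript()] per call, with a per-chromosome index so
#' large annotations are scanned once.
#'
#' @param calls A `circ_calls` data.frame.
#' @param tt A [transcript_table()].
#' @return A list of selection results, one per call, in call order.
#' @export
select_best <- function(calls, tt) {
  by_chrom <- split(seq_len(nrow(tt)), tt$chrom)
  lapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, , drop = FALSE]
    idx <- by_chrom[[call$chrom]]
    if (is.null(idx)) {
      cand <- tt[integer(0), , drop = FALSE]
    } else {
      sub <- tt[idx, , drop = FALSE]
      cand <- sub[sub$start <= call$start & sub$end >= call$end, , drop = FALSE]
    }
    select_best_transcript(call, cand)
  })
}
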