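#' Column presets for common circRNA prediction tools
#'
#' Each preset fixes the column indices of the four required fields
#' (chromosome, start, end, strand; plus an id column where the tool emits
#' one) and the coordinate dialect of that tool's table. No tool is
#' executed; presets only describe file layout.
#'
#' * `ciri`: CIRI/CIRI2 table — id in column 1, chrom 2, start 3, end 4,
#'   strand 11; 1-based inclusive coordinates.
#' * `find_circ`: BED-like — chrom 1, start 2, end 3, name 4, strand 6;
#'   0-based half-open.
#' * `circexplorer`: BED12-like — same first six columns as `find_circ`;
#'   0-based half-open.
#' * `dcc`: CircCoordinates file — chrom 1, start 2, end 3, strand 6;
#'   1-based inclusive.
#'
#' @param preset Preset name.
#' @return A list with elements `cols` (named integer vector) and `dialect`.
#' @export
circ_call_preset <- function(preset = c("ciri", "find_circ", "circexplorer", "dcc")) {
  preset <- match.arg(preset)
  switch(preset,
    ciri = list(cols = c(chrom = 2L, start = 3L, end = 4L, strand = 11L, id = 1L),
                dialect = "one_based"),
    find_circ = list(cols = c(chrom = 1L, start = 2L, end = 3L, strand = 6L, id = 4L),
                     dialect = "bed_like"),
    circexplorer = list(cols = c(chrom = 1L, start = 2L, end = 3L, strand = 6L, id = 4L),
                        dialect = "bed_like"),
    dcc = list(cols = c(chrom = 1L, start = 2L, end = 3L, strand = 6L),
               dialect = "one_based")
  )
}

#' Parse circRNA prediction-tool output into canonical calls
#'
#' Reads a tab/whitespace-separated table of predicted circRNAs and
#' normalizes every record to 0-based half-open coordinates: the
#' `one_based` dialect (CIRI-style 1-based inclusive) maps `(s, e)` to
#' `(s - 1, e)`; the `bed_like` dialect (find_circ-style) passes through
#' unchanged. The base convention differs silently between tools and a
#' wrong guess shifts every downstream sequence by one base, so
#' `dialect = "auto"` refuses to guess and errors with guidance.
#'
#' Records with a missing or unrecognized strand get strand `"."`
#' (unknown) with a warning; records whose interval is empty after
#' normalization are rejected with their line number; duplicate
#' (chrom, start, end, strand) tuples are dropped with a warning.
#'
#' @param path Path to the prediction-tool output.
#' @param dialect `"one_based"`, `"bed_like"`, or `"auto"` (errors).
#' @param cols Named integer vector mapping `chrom`, `start`, `end`,
#'   `strand` (and optionally `id`) to column indices; defaults to columns
#'   1-4 (+5 for id if present). Ignored when `preset` is given.
#' @param preset Optional tool preset, see [circ_call_preset()].
#' @param chr_style Chromosome-name reconciliation, see [normalize_chrom()].
#' @param comment_char Lines starting with this character are skipped.
#' @return A `circ_calls` data.frame with columns `id`, `chrom`, `start`,
#'   `end`, `strand` (`"+"`, `"-"`, or `"."`), in file order. Missing ids
#'   are auto-generated as `chrom:start-end:strand`.
#' @export
parse_circ_calls <- function(path, dialect = c("auto", "one_based", "bed_like"),
                             cols = NULL, preset = NULL, chr_style = "keep",
                             comment_char = "#") {
  dialect <- match.arg(dialect)
  if (!is.null(preset)) {
    p <- circ_call_preset(preset)
    cols <- p$cols
    dialect <- p$dialect
  }
  if (dialect == "auto") {
    .stopf(paste0("dialect = 'auto' refuses to guess the coordinate convention; ",
                  "pass dialect = 'one_based' (CIRI-style 1-based inclusive) or ",
                  "'bed_like' (0-based half-open), or a tool preset"))
  }
  if (!file.exists(path)) .stopf("circRNA call file not found: %s", path)

  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), comment_char)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) .stopf("no circRNA records in '%s'", path)
  fields <- strsplit(lines, "[ \t]+")

  if (is.null(cols)) {
    has_id <- all(lengths(fields) >= 5L)
    cols <- c(chrom = 1L, start = 2L, end = 3L, strand = 4L,
              if (has_id) c(id = 5L))
  }
  need <- c("chrom", "start", "end", "strand")
  if (!all(need %in% names(cols))) {
    .stopf("cols must name at least %s", paste(need, collapse = ", "))
  }
  maxcol <- max(cols[need])

  # header detection: start column not numeric on the first record
  if (length(fields[[1L]]) >= maxcol &&
      is.na(suppressWarnings(as.numeric(fields[[1L]][cols[["start"]]])))) {
    fields <- fields[-1L]
    lineno <- lineno[-1L]
    if (!length(fields)) .stopf("no circRNA records after header in '%s'", path)
  }

  short <- lengths(fields) < maxcol
  if (any(short)) {
    .stopf("line %d of '%s' has %d fields, need at least %d",
           lineno[short][1L], path, lengths(fields)[short][1L], maxcol)
  }

  pick <- function(name) vapply(fields, `[`, character(1), cols[[name]])
  chrom <- normalize_chrom(pick("chrom"), chr_style)
  start <- suppressWarnings(as.integer(pick("start")))
  end <- suppressWarnings(as.integer(pick("end")))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1L]
    .stopf("line %d of '%s': non-numeric start/end", lineno[bad], path)
  }
  strand <- pick("strand")
  bad_strand <- !strand %in% c("+", "-")
  if (any(bad_strand)) {
    .warnf("%d record(s) with missing/unrecognized strand set to unknown ('.')",
           sum(bad_strand))
    strand[bad_strand] <- "."
  }
  if (dialect == "one_based") start <- start - 1L

  id <- if ("id" %in% names(cols)) {
    ifelse(lengths(fields) >= cols[["id"]],
           vapply(fields, function(f) if (length(f) >= cols[["id"]]) f[cols[["id"]]] else "", character(1)),
           "")
  } else rep("", length(fields))
  auto <- !nzchar(id) | id == "."
  id[auto] <- sprintf("%s:%d-%d:%s", chrom[auto], start[auto], end[auto], strand[auto])

  empty <- start >= end
  if (any(empty)) {
    .warnf("%d record(s) rejected: start >= end after normalization (first at line %d)",
           sum(empty), lineno[empty][1L])
  }
  calls <- data.frame(id = id, chrom = chrom, start = start, end = end,
                      strand = strand, stringsAsFactors = FALSE)[!empty, , drop = FALSE]

  dup <- duplicated(calls[, c("chrom", "start", "end", "strand")])
  if (any(dup)) {
    .warnf("%d duplicate (chrom,start,end,strand) record(s) dropped", sum(dup))
    calls <- calls[!dup, , drop = FALSE]
  }
  if (!nrow(calls)) .stopf("no usable circRNA records in '%s'", path)
  if (anyDuplicated(calls$id)) {
    # distinct intervals sharing an input id: keep ids unique for FASTA output
    calls$id <- make.unique(calls$id, sep = "_")
  }
  rownames(calls) <- NULL
  class(calls) <- c("circ_calls", "data.frame")
  calls
}
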