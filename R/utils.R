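#' Normalize chromosome-name style
#'
#' Reference genomes, annotations and circRNA caller outputs frequently
#' disagree on whether chromosome names carry a `"chr"` prefix. This helper
#' applies one reconciliation style; the same style must be applied to all
#' three inputs of a run for coordinates to line up.
#'
#' @param x Character vector of chromosome names.
#' @param style One of `"keep"` (no change), `"add-chr"` (prefix `"chr"`
#'   where absent), `"strip-chr"` (remove a leading `"chr"`).
#' @return Character vector of reconciled names.
#' @examples
#' normalize_chrom(c("1", "chr2"), "add-chr")
#' normalize_chrom(c("1", "chr2"), "strip-chr")
#' @export
normalize_chrom <- function(x, style = c("keep", "add-chr", "strip-chr")) {
  style <- match.arg(style)
  x <- as.character(x)
  switch(style,
    "keep" = x,
    "add-chr" = ifelse(startsWith(x, "chr"), x, paste0("chr", x)),
    "strip-chr" = sub("^chr", "", x)
  )
}

# comma-joined integer list <-> list of integer vectors
.join_ints <- function(v) vapply(v, function(x) paste(x, collapse = ","), character(1))

.split_ints <- function(s) lapply(strsplit(as.character(s), ",", fixed = TRUE), as.integer)

# stable message prefix for condition classes used across the package
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
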