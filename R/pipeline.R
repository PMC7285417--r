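#' Configuration for a full pipeline run
#'
#' @param annotation Path to the GTF/GFF3 annotation, or to a previously
#'   written 9-column transcript table (set `annotation_format =
#'   "transcript_table"` for the latter, enabling two-stage execution).
#' @param genome Path to the reference genome FASTA.
#' @param calls Path to the circRNA prediction-tool output.
#' @param out_dir Output directory.
#' @param annotation_format `"auto"`, `"gtf"`, `"gff3"`, or
#'   `"transcript_table"`.
#' @param calls_dialect `"one_based"` or `"bed_like"` (see
#'   [parse_circ_calls()]; `"auto"` errors by design).
#' @param calls_cols Optional named column map for the calls file.
#' @param calls_preset Optional tool preset name.
#' @param chr_style Chromosome-name reconciliation applied identically to
#'   all three inputs.
#' @param revcomp Emit minus-orientation sequences reverse-complemented.
#' @param header Write header lines on the tabular outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(annotation, genome, calls, out_dir,
                       annotation_format = "auto",
                       calls_dialect = "auto", calls_cols = NULL,
                       calls_preset = NULL, chr_style = "keep",
                       revcomp = TRUE, header = FALSE) {
  cfg <- list(annotation = annotation, genome = genome, calls = calls,
              out_dir = out_dir, annotation_format = annotation_format,
              calls_dialect = calls_dialect, calls_cols = calls_cols,
              calls_preset = calls_preset, chr_style = chr_style,
              revcomp = revcomp, header = header)
  class(cfg) <- "run_config"
  cfg
}

.echo_config <- function(cfg, path) {
  kv <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    v <- if (is.null(v)) "NULL" else paste(
      if (!is.null(names(v))) paste0(names(v), "=", v) else as.character(v),
      collapse = ",")
    paste0(k, "\t", v)
  }, character(1))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(kv, con, sep = "\n")
}

#' Run the full circRNA extraction workflow
#'
#' Executes the three-stage workflow: (1) parse the annotation into the
#' 9-column transcript table; (2) classify every circRNA call against its
#' best transcript into the 15-column classification table; (3) extract
#' full-length sequences from the genome into a FASTA file. The run's
#' configuration is echoed to `config.txt` in the output directory for
#' provenance, and a textual per-class summary is returned.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress the printed summary.
#' @return Invisibly, a list with `paths` (transcript table,
#'   classification, FASTA, config), `summary` (data.frame of class
#'   counts and percentages, plus a total row), and the in-memory
#'   `transcripts`, `classification`, `sequences`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  tt <- if (identical(cfg$annotation_format, "transcript_table")) {
    read_transcript_table(cfg$annotation)
  } else {
    parse_annotation(cfg$annotation, format = cfg$annotation_format,
                     chr_style = cfg$chr_style)
  }

  calls <- parse_circ_calls(cfg$calls, dialect = cfg$calls_dialect,
                            cols = cfg$calls_cols, preset = cfg$calls_preset,
                            chr_style = cfg$chr_style)
  if (nrow(calls) == 0L) .stopf("zero circRNA calls parsed from '%s'", cfg$calls)

  genome <- load_genome(cfg$genome, chr_style = cfg$chr_style)
  miss <- setdiff(unique(calls$chrom), names(genome))
  if (length(miss)) {
    .stopf(paste0("chromosome(s) %s in the calls are absent from the genome; ",
                  "reconcile naming with chr_style ('keep'/'add-chr'/'strip-chr')"),
           paste(miss, collapse = ", "))
  }

  cls <- classify_calls(calls, tt)
  seqs <- extract_sequences(cls, genome, revcomp = cfg$revcomp)

  paths <- list(
    transcript_table = file.path(cfg$out_dir, "transcripts.tsv"),
    classification = file.path(cfg$out_dir, "classification.tsv"),
    fasta = file.path(cfg$out_dir, "circrna.fa"),
    config = file.path(cfg$out_dir, "config.txt")
  )
  write_transcript_table(tt, paths$transcript_table, header = cfg$header)
  write_classification(cls, paths$classification, header = cfg$header)
  write_fasta(seqs, paths$fasta)
  .echo_config(cfg, paths$config)

  smry <- classification_summary(cls)
  if (!quiet) {
    cat(sprintf("%-10s %8s %9s\n", "class", "count", "percent"))
    for (i in seq_len(nrow(smry))) {
      cat(sprintf("%-10s %8d %8.2f%%\n", smry$class[i], smry$count[i], smry$percent[i]))
    }
  }
  invisible(list(paths = paths, summary = smry, transcripts = tt,
                 classification = cls, sequences = seqs))
}

#' Per-class summary of a classification
#'
#' Counts and percentages for exonic / intronic / other plus a total row
#' (counts sum to the total; percentages sum to 100 up to rounding).
#'
#' @param cls A `circ_classification` data.frame.
#' @return A data.frame with columns `class`, `count`, `percent`.
#' @export
classification_summary <- function(cls) {
  classes <- c("exonic", "intronic", "other")
  n <- vapply(classes, function(k) sum(cls$circ_class == k), integer(1))
  total <- nrow(cls)
  data.frame(class = c(classes, "total"),
             count = c(n, total),
             percent = c(100 * n / total, 100),
             stringsAsFactors = FALSE)
}
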