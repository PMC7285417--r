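---
title: "Reconstructing full-length circRNA sequences from back-splice junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing full-length circRNA sequences from back-splice junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fullcirc)
```

## The problem

circRNA prediction tools report, per circRNA, only the two genomic
breakpoints of the back-splice junction (plus a strand). The covalently
closed molecule between those breakpoints is what every downstream
analysis actually consumes, and it cannot be read off the genome
directly: an exonic circRNA is a *spliced* product, so the introns
between its breakpoints must be removed. `fullcirc` infers the internal
structure from the gene annotation alone — no sequencing reads — which
makes it applicable to any species and any prediction tool whose output
carries chromosome, start, end and strand.

The package assumes the prediction calls are correct (no false-positive
filtering) and that an exonic circRNA contains *all* annotated exons of
its host transcript between its breakpoints (no exon skipping). Both
assumptions are the standard ones for annotation-driven reconstruction;
their cost is discussed under Limitations.

## Coordinate model

Everything internal is 0-based half-open (`[start, end)`), the BED
convention. GTF/GFF3 coordinates are 1-based inclusive, so parsing
subtracts 1 from every start and keeps ends as printed; an exon's length
is then `end − start` and splicing is plain concatenation of genome
substrings. circRNA caller tables are normalized the same way: a
`one_based` (CIRI-style) record `(s, e)` becomes `(s − 1, e)`, a
`bed_like` (find_circ-style) record passes through. Because the two
conventions differ silently between tools and an off-by-one here shifts
*every* output base, `parse_circ_calls(dialect = "auto")` refuses to
guess and errors with guidance instead.

## Transcript model

`parse_annotation()` builds one record per transcript — id, chromosome,
strand, span, exon count, ordered exon starts/ends, host gene — from
`exon` feature lines only; `transcript`/`mRNA` parent lines are optional
because the span is defined by the exon extremes and many GTFs lack
them. The table round-trips through a 9-column TSV
(`write_transcript_table()` / `read_transcript_table()`), which also
enables two-stage execution: parse a large annotation once, then reuse
the table across runs.

Design points that were genuinely open:

* **Host gene naming.** Annotations disagree on where the gene name
  lives. The fallback order is `gene_name`, then `gene_id` (GTF); for
  GFF3 a `gene_name`/`gene` attribute, then the `Parent`-resolved gene
  record's `Name`, then its id; else the literal `"NA"`.
* **Degenerate strands.** Exon lines with strand `.` or `?` exclude the
  transcript (with a warning): strand comparison is load-bearing for the
  exonic class, so a strand-less transcript cannot participate safely.
* **Duplicate ids.** A transcript id recurring on another chromosome or
  strand is suffix-disambiguated (`id_2`, ...) rather than dropped.

## Best-transcript selection

Candidates are all transcripts whose span contains the circRNA boundary,
boundary-touching included. Two cases, applied in order, each tie-break
filtering the survivor set:

1. **Exact boundary match** — some candidate's first-exon start and
   last-exon end equal the boundary exactly. Among matchers: maximum
   splice length (sum of exon lengths), then maximum genomic span, then
   first in annotation-file order.
2. **Otherwise** — among all candidates: maximum number of exons
   overlapping the boundary (half-open overlap), then maximum genomic
   span, then file order.

Two readings had to be fixed here. "Maximum transcript length" in the
second case is taken as *genomic span*, not splice length — the first
case lists splice length as a separate, prior criterion, so "transcript
length" must mean something else. And candidacy deliberately ignores
strand: an antisense transcript that contains (or exactly matches) the
boundary can be selected, and the strand test is applied afterwards at
classification, where it demotes the call to "other". The alternative —
strand-filtering the candidate set — would silently reclassify such
calls against whatever sense-strand transcript remains; keeping strand
out of selection makes the antisense case visible in the output (the
best-transcript columns are filled, the class is "other").

The cascade is deterministic; the test suite checks it against an
independent, literally-coded brute-force implementation on 1000 random
instances (≤ 8 candidates, ≤ 6 exons each) and verifies exact-matcher
dominance and insertion monotonicity as separate properties.

## Classification and blocks

With the boundary-overlapping exons of the best transcript, the two
containment flags are `start_flag = [c.start ≥ first exon's start]` and
`end_flag = [c.end ≤ last exon's end]`. The class partition:

* both flags 1, strands agree (or circRNA strand unknown) → **exonic**;
* no overlapping exon and the call lies inside one intron →
  **intronic**;
* everything else, including "no candidate at all" → **other**.

Exonic block structure is BED12-like: each boundary exon intersected
with the call interval, sizes and offsets relative to the call start.
With both flags set, only the first and last block can be clipped; the
`length` column is the sum of block sizes — the spliced length — for
every class (for intronic/other the single block is the whole span, so
this coincides with the genomic length). Intronic status requires
*containment* in a single intron, not exact coincidence with it: with
zero overlapping exons both endpoints necessarily fall between the same
adjacent exon pair of a containing transcript, and containment is the
only reading under which that configuration is always well-defined.

Calls with unknown strand (`.`) may be exonic — the strand test is
waived — and keep `.` in the strand column while sequence orientation
follows the best transcript's strand.

The 15-column classification TSV is: circRNA id, chromosome, start, end,
strand, length, class, block count, block sizes, block offsets, best
transcript, transcript strand, transcript start, transcript end, host
gene.

## Sequence extraction

`extract_sequence()` concatenates the genome substring of every block in
ascending genomic order and reverse-complements when the orientation
strand is minus. The orientation strand is the circRNA's own strand,
falling back to the best transcript's strand, then to plus. Whether
published minus-strand circRNA sequences are reverse-complemented varies
by database, so `revcomp = FALSE` emits genomic plus orientation for
direct database comparisons. Sequences are linearized starting at the
genomic start block — the database convention for representing a circle
as a string — with no rotation options. Soft-masked (lowercase) genome
bases are uppercased on load; `N` and other IUPAC codes pass through
(and reverse-complement correctly).

## The synthetic fixture generator

`generate_fixture()` produces a random genome, a gene annotation
(rendered as both GTF and GFF3), circRNA calls (rendered in both
coordinate dialects) and a ground-truth table, all driven by one seed
through one pseudo-random stream — identical seed and spec give
byte-identical files.

The central design constraint is that **truth must be forced by the
planting geometry**, never computed by the code under test:

* Transcripts within a gene are forced to have pairwise distinct
  (start, end) spans, and genes never overlap, so a call planted on the
  full span of transcript *t* has *t* as its unique exact-boundary
  matcher — the cascade's winner is known without running the cascade.
* Exonic calls with endpoints at internal exon boundaries, or clipped
  inside terminal exons, and all intronic calls are planted only in
  single-transcript genes, where *t* is the *only* candidate. Every
  third gene is forced single-transcript and multi-exon so such genes
  always exist.
* "Other" calls rotate through three geometries: intergenic intervals,
  antisense exact-span matches (which pin the strand rule: the best
  transcript is found, the flags are 1, and the class must still not be
  exonic), and calls straddling a gene's edge into intergenic space (no
  containing transcript).

Truth sequences are computed directly from the planted genome strings.
Realized class counts are one multinomial draw over the requested mix
(defaults 60% exonic, 20% intronic, 20% other — chosen to resemble the
published distributions for well-annotated genomes, where exonic
dominates — over 500 calls on 3 × 100 kb chromosomes with 30 genes, 1–3
transcripts per gene, 1–6 exons of 50–300 bp separated by introns of
50–500 bp; sizes picked so the whole suite runs in seconds while every
code path is exercised). With `boundary_noise > 0` a call's endpoints
are jittered off their construction positions and its truth fields
become `NA`: a jittered class is no longer forced by construction, and
guessing it would put the tested logic inside the oracle.

What the fixtures do *not* emulate: real exon/intron length
distributions, alternative splicing structure shared across isoforms,
repeats and low-complexity sequence, assembly gaps, and incorrect
prediction calls. Passing the truth-recovery suite therefore shows the
machinery is exact under the stated assumptions — it does not validate
those assumptions on real data.

## Numerical and edge-case choices

* Half-open overlap throughout: an exon touching the boundary
  (`exon.end == call.start`) does not overlap, preventing zero-length
  blocks.
* Ties at every cascade step resolve toward annotation-file order,
  making results reproducible across runs and platforms.
* Duplicate (chrom, start, end, strand) calls are deduplicated with a
  warning; records with `start ≥ end` after normalization are rejected
  with their line number.
* Chromosome naming (`chr1` vs `1`) is reconciled by one explicit
  `chr_style` option applied identically to calls, annotation and
  genome; a residual mismatch at extraction is a fatal error naming the
  available chromosomes.

## Limitations

The method inherits the annotation: unannotated exons, novel splice
sites inside the circRNA, and exon skipping are invisible, and no
information on internal splice variants is produced. Intronic and
"other" circRNAs are assumed unspliced. Calls are trusted as given — no
junction-read support, no false-positive filtering. These are the same
trade-offs made by annotation-driven reconstruction generally, and they
are the price of needing no RNA-seq data.
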