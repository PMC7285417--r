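# fullcirc

Full-length circular RNA (circRNA) sequence extraction and classification.

circRNAs are formed by back-splicing: a downstream 3′ splice donor is
joined to an upstream 5′ splice acceptor, producing a covalently closed
RNA circle. Prediction tools (CIRI, find_circ, CIRCexplorer, DCC,
segemehl, MapSplice, ...) detect the two genomic breakpoints of the
back-splice junction but not the sequence between them, which all
downstream work — differential expression, miRNA-sponge analysis, primer
design — needs. `fullcirc` reconstructs that full-length sequence from
three inputs only:

1. the prediction-tool output (chromosome, start, end, strand per
   circRNA; any tool whose table carries these four fields works),
2. the reference genome (FASTA),
3. the gene annotation (GTF or GFF3).

No RNA-seq reads are required, and the method is species-agnostic.

## Method

All coordinates are normalized internally to 0-based half-open intervals
(1-based annotation starts are decremented on parse), so exon length is
`end − start` and splicing is substring concatenation.

For each circRNA call *c* with boundary `[start, end)` on one chromosome:

**Best transcript.** Let *T*<sub>possible</sub> be every annotation
transcript whose span contains the boundary
(`t.start ≤ c.start` and `t.end ≥ c.end`). The best transcript
*T*<sub>best</sub> is chosen by a two-case cascade:

* *Exact-boundary case*: if any candidate's first-exon start and
  last-exon end equal the boundary exactly, choose among those matchers
  by maximum splice length (total exon length), then maximum genomic
  span, then annotation-file order.
* otherwise choose, among all candidates, the one with the most exons
  overlapping the boundary, then maximum genomic span, then file order.

**Classification.** With the boundary-overlapping exons of
*T*<sub>best</sub>, define `Start = 1` iff `c.start ≥` start of the first
such exon and `End = 1` iff `c.end ≤` end of the last such exon. Then

* `Start = End = 1` and the circRNA strand equals the transcript strand
  (or is unknown) → **exonic**; the sequence is the concatenation of the
  boundary exons clipped to the circRNA interval;
* no exon overlaps the boundary and the interval lies inside a single
  intron → **intronic**; the sequence is the genomic span;
* no containing transcript, or any other configuration → **other**; the
  sequence is the genomic span.

Minus-orientation sequences are reverse-complemented by default
(`revcomp = FALSE` keeps genomic plus orientation for database
comparisons).

## Worked example

Everything below runs offline: the fixture generator plants a synthetic
genome, annotation and calls with known truth.

```r
library(fullcirc)
fx <- generate_fixture(fixture_spec(seed = 7, chrom_count = 1, chrom_length = 60000,
                                    gene_count = 9, n_calls = 12), dir = "demo_fx")
cfg <- run_config(annotation = fx$paths$gtf, genome = fx$paths$genome,
                  calls = fx$paths$calls_bed_like, out_dir = "demo_out",
                  calls_dialect = "bed_like")
res <- run_pipeline(cfg)
```

```
class         count   percent
exonic           10    83.33%
intronic          2    16.67%
other             0     0.00%
total            12   100.00%
```

The per-class summary: of the 12 predicted circRNAs, 10 were assembled
from same-strand exons of their best transcript, 2 lie inside a single
intron, and counts sum to the total. The classification table (first
rows, selected columns):

```r
res$classification[1:4, c("circ_id", "chrom", "start", "end", "strand", "length",
                          "circ_class", "block_count", "best_transcript", "host_gene")]
```

```
    circ_id chrom start   end strand length circ_class block_count best_transcript host_gene
1 circ_0001  chr1 15616 16331      -    553     exonic           3           t0012      g008
2 circ_0002  chr1  1436  1504      -     68     exonic           1           t0001      g001
3 circ_0003  chr1 11645 13620      -    907     exonic           4           t0008      g006
4 circ_0004  chr1 19768 20044      +    276     exonic           1           t0014      g009
```

`circ_0001` spans 16331 − 15616 = 715 genomic bases but its full-length
sequence is 553 bases: three exon blocks of its best transcript `t0012`
spliced together (the `length` column is the spliced length for exonic
records). Its sequence is emitted reverse-complemented, since the call is
on the minus strand:

```
>circ_0001 class=exonic len=553
CCCGTAGTAACTTACAGGTAGCCCGTCGTCTTCCACCTAGAATGACGAAGTTTTACGGCG
...
```

Three artifact files land in `demo_out/`: `transcripts.tsv` (the 9-column
transcript model of the annotation), `classification.tsv` (15 columns:
id, chromosome, start, end, strand, length, class, block count, block
sizes, block offsets, best transcript, transcript strand, transcript
start, transcript end, host gene), and `circrna.fa`.

A thin command-line wrapper with subcommands `transcripts`, `classify`,
`extract`, `run`, `fixture` is installed at `inst/cli/fullcirc.R`.

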