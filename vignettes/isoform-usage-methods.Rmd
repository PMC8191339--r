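---
title: "Methods: isoform categorization and differential isoform usage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform categorization and differential isoform usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoscope)
```

`isoscope` analyzes isoform models called from long-read full-length
cDNA data (with their per-sample read counts) against a reference
annotation. This vignette records the package's models, conventions and
numerical choices in one place, and explains what the synthetic data
generator does and does not emulate.

## Coordinate and object conventions

All intervals are stored 0-based, half-open, on a named chromosome with
a strand. GTF and STAR `SJ.out.tab` files are 1-based inclusive at the
interface and converted on read/write; BED is natively 0-based. Exons
of a `transcript_model` are sorted by start, non-overlapping and
separated by at least one intronic base; the splice-junction chain is
derived as the gaps between consecutive exons, so a model with `n`
exons always carries `n - 1` junctions. The 5' end of a minus-strand
model is its highest coordinate; every junction decomposes into one
donor and one acceptor site, with the donor at the higher coordinate on
the minus strand. Chromosome naming is taken literally ("chr1" and "1"
are different sequences; a model on a chromosome missing from the FASTA
is an error, not a silent skip).

## Isoform categories

A multi-exon isoform is compared with the annotation through its
junction chain, in a fixed cascade:

1. **FSM** — some same-strand annotated transcript has the identical
   chain. When several share it, the matched transcript is the one
   minimizing the summed 5' + 3' end distances (deterministic;
   tie-broken lexicographically).
2. **ISM** — the chain is a *consecutive, proper* sub-chain of some
   transcript's chain. An identical chain is always FSM, never ISM, and
   a non-consecutive subset is not ISM.
3. **intergenic** — the span overlaps no annotated gene locus on either
   strand. Gene loci are full transcript spans, not exons.
4. **genic_other** — locus overlap exists only on the opposite strand
   and the model shares no same-strand annotated splice site. This
   single category absorbs antisense/genic-fusion-like cases without
   finer subdivision.
5. **NIC / NNC** — otherwise, NIC if *every* splice site of the model
   appears among the annotated same-chromosome, same-strand sites
   (anywhere, not just the assigned gene: recombining sites of two
   neighboring genes is still "in catalog"); NNC if at least one site is
   unannotated, and those sites are reported with their donor/acceptor
   side.

Mono-exon isoforms carry no junctions, so the chain logic cannot apply;
they are reported separately as `mono_exon_known` (fully inside one
annotated exon), `mono_exon_genic` (locus overlap) or `intergenic`, and
are never merged into the multi-exon categories.

Gene assignment maximizes shared splice sites, then exonic-overlap
bases, then lexicographic gene id — fully deterministic so repeated
runs agree.

## Transcript ends

For FSM isoforms, `d5`/`d3` are absolute distances (nt) from the
isoform's strand-aware ends to the matched transcript's TSS/polyA site,
and `d5_gene_min`/`d3_gene_min` minimize over all transcripts of the
assigned gene — an isoform may match one transcript's chain while using
another's promoter. "Distant" ends are counted with a strict `> 500` nt
rule on the gene-minimum distances.

## CDS containment

Reference peptides are built per gene by splicing each coding
transcript's CDS segments (strand-corrected, applying the GTF frame
offset of the transcript-first segment), translating with the standard
genetic code, trimming the terminal stop and deduplicating. An isoform
contains a full CDS when any of its gene's peptides is a substring of
one of the three forward-frame translations of its spliced sequence.
Choices worth stating:

* Containment is peptide-level, not nucleotide-level, so synonymous
  changes upstream of the annotation cannot break it; internal stops do
  not terminate the scan because whole frames are translated (stops
  render as `*`, `N`-containing codons as `X`).
* Only the three sense-strand frames are searched; strand is resolved
  upstream when the spliced sequence is built.
* Rates per category are computed over multi-exon isoforms of coding
  genes only; isoforms of genes without CDS annotation are flagged
  not-applicable and excluded from denominators.
* Peptides shorter than 2 aa are ignored as degenerate; non-standard
  codes (e.g. selenoproteins) are a documented limitation.

## Novel exons

A novel exon is an exon of an NNC isoform that overlaps **no** annotated
exon at all, on either strand — a purely genomic criterion. Extensions
of annotated exons therefore never qualify. Exons are deduplicated by
exact coordinates; every source isoform is kept with the exon's
transcript position (strand-aware first/middle/last) in that isoform,
and the deduplicated record reports the first-encountered source's
position class while retaining all per-source classes. Under uniform
placement of `k` novel exons over all `E` exons of all `N` observed
isoforms, the expected number of novel first exons is `k * N / E` (and
the same for last exons, by symmetry).

Validation requires the junctions leading into the exon — one for a
terminal exon, both flanking introns for an internal one — to be present
in the short-read junction set. Junction matching ignores strand by
default because nondirectional short-read libraries cannot assign one;
strand-aware matching is a switch. When sources disagree about an exon's
position, each source's own requirement is checked and any fully
supported source validates the exon.

## Differential isoform usage

Counts are summed per condition (replicate collapse is the default; a
switch keeps per-sample columns, which are for display — per-replicate
usage plots — rather than testing). Relative usage is a percentage per
condition column; columns with zero totals are flagged and excluded. A
gene is testable when at least 2 conditions hold at least 50 reads
(both bounds inclusive). The test is Pearson's chi-squared on the raw
count table without continuity correction; all-zero rows/columns are
dropped before computing `df = (r-1)(k-1)`. Applying a contingency test
to a percentage table is statistically incoherent (the totals carry the
information), so counts are the default; a `mode = "percent"` variant
exists for comparison and the mode is recorded in the output.
No minimum-expected-count rule is imposed beyond the read filter, but
results carry `min_expected` and the single-table function warns below
5. Bonferroni correction multiplies by the number of genes actually
tested (not the annotation size) and caps at 1. Effect size is the
maximum over isoforms of the population SD (divide by *n*) of relative
usage across testable conditions; ranking is by p-value, then SD
descending, then gene id.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline consumes:
a random genome; non-overlapping genes on both strands with 1–3
transcripts of 4–8 exons (exons 80–300 bp, introns 150–1000 bp); one
coding transcript per gene whose CDS (ATG, ≥ 40 codons, single terminal
stop, no internal stops) is written into the genome with a 5' UTR of up
to 150 nt; observed isoforms built per category so truth is known by
construction (FSM: copies with end jitter, mostly ≤ 100 nt with a 5%
far tail of 600–1500 nt to exercise the 500-nt end rule; ISM:
consecutive proper truncations; NIC: exon skips re-using annotated
sites, rejected if they collide with an existing chain; NNC: 5–50 nt
splice-site shifts into unannotated positions or injected
intron-interior novel exons of 80–150 bp kept ≥ 30 bp from intron
boundaries and clear of all annotated exons; intergenic: multi-exon
models in annotation gaps with a 200 bp margin); five conditions with
two replicates by default; per gene one usage vector from a symmetric
Dirichlet (concentration 2) shared by all conditions under the null;
switch genes swap their two most-used isoforms' proportions in the
second half of the conditions (or carry an explicitly pinned vector
such as 80/20); multinomial read counts (Poisson or fixed totals, mean
100 per gene per condition) split over replicates; RPM derived from
gene totals; junction files thinned by independent per-junction
dropout (10% by default). One master seed drives everything, with
fixed per-stage offsets so stages can be rerun independently.

What it does **not** emulate: sequencing error and consensus accuracy,
read-length effects, reference bias in isoform calling, multi-mapping
ambiguity (counts are generated at isoform level directly, since
isoform calling is upstream of this package), overlapping genes,
alternative genetic codes, and expression-dependent detection. Passing
the recovery tests therefore demonstrates the correctness of the
implemented logic under clean inputs, not robustness to upstream
artifacts of real data.

Problem sizes used in the shipped tests and calibration were chosen to
characterize behavior well at desk scale: classifier/oracle agreement
over 100 random annotations, truth recovery over 500 isoforms with a
0.4/0.15/0.2/0.15/0.1 category mix, usage-switch detection over 200
two-isoform genes at 500 reads per condition, and 500 global-null
replicates for the family-wise error rate.

## Degenerate inputs and tie-breaks

Zero-length or overlapping exons are rejected with diagnostics, never
silently merged. Genes with zero total reads keep all isoforms in the
minority filter (the 1% rule discards strictly below the threshold, so
an isoform at exactly 1% of its locus survives). Expression bins are
lower-exclusive/upper-inclusive with an open last bin, and empty bins
report `NA` rather than 0. Intergenic locus clustering is single-linkage
on span overlap; spans that merely touch do not merge. All orderings
that could differ between runs (FSM match choice, gene assignment, DIU
ranking) carry explicit deterministic tie-breaks.

## Known limitations

The ISM category does not distinguish 5' from 3' truncations; the
genic_other category is deliberately coarse; junction validation
consumes a junction file rather than recomputing junctions from
alignments; and the chi-squared test's asymptotics can be optimistic
for genes barely past the read filter with many isoforms (the
`min_expected` column exists to audit this).
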