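---
title: "Mapping and annotating expression-array probesets against a genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and annotating expression-array probesets against a genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probemapr)
```

## The problem

Short-oligonucleotide expression arrays measure a target through a
*probeset*: a manufacturer-defined group of (typically 11-20) 25-mer
probes. The probes were designed against the transcript knowledge of
their time, which drifts: genome assemblies are corrected, transcript
models gain and lose exons and UTRs. Interpreting an expression value
therefore requires a current answer to the question *which transcripts
does this probeset actually measure?*

probemapr answers it by realigning the probes themselves, not by chasing
identifiers through external databases. The procedure has two steps:

1. **Mapping.** Every perfect-match probe is placed on the genome at
   every location where it matches with at most one substitution. Probes
   hitting more than 100 locations (repeat-derived probes) are discarded
   outright, even when every hit is exact: such probes carry no target
   information. Placements are labelled *full match* (0 mismatches) or
   *mismatch* (exactly 1). Probes are additionally aligned to spliced
   transcript (cDNA) sequences; hits that straddle exon-exon junctions
   are invisible to the genomic search and are projected back to
   multi-block genomic coordinates.
2. **Annotation.** A probeset is annotated to a transcript when at least
   half of its probes match the transcript's *footprint* — its exons
   plus a 3' extension. With probeset size $s$ and matched-probe count
   $m$, the verdict is $m \ge \lceil s/2 \rceil$. Sizes are taken
   dynamically from the array design, and probes that failed mapping
   (promiscuous, unmapped, ambiguous) still count in the denominator.

### The 3' extension

Array probes are biased toward transcript 3' ends, while annotated 3'
UTRs are often truncated or absent (UTR annotation depends on cDNA
evidence). The footprint therefore extends past the annotated 3' end:

* a transcript with an annotated 3' UTR of length $u$ is considered
  with UTR $2u$ — i.e. extended by $u$ bases beyond its end
  (`utr_multiplier`, default 2);
* a transcript without an annotated UTR is extended by the
  *species extension length*
  $E = \mathrm{round}(\max(\overline{u},\ \mathrm{median}(u)))$
  computed over all annotated 3' UTR lengths of the species,
  transcripts with $u = 0$ excluded. Rounding is to the nearest
  integer, ties upward.

Extensions grow downstream in transcript orientation (rightward on `+`,
leftward on `-`) and are clipped at chromosome boundaries. The
`clip_at_neighbor` flag additionally truncates an extension before the
nearest downstream gene span; it is off by default, matching the
published release behaviour rather than the announced future one, and we
deliberately do not cap the doubled-UTR portion otherwise.

## Why each design choice

**"At least half" with odd sizes.** `ceiling(size / 2)` is the smallest
integer count that satisfies "at least half" read literally; for size 11
that is 6, for size 16 exactly 8.

**Containment, not overlap.** A placement matches only when *every*
alignment block lies inside the footprint and the alignment strand
equals the transcript strand. Probes are 25 nt; allowing partial overlap
would blur the distinction between exonic and intronic placements that
the unannotated-probeset diagnostics depend on.

**Antisense never counts.** A placement inside the footprint but on the
opposite strand is recorded with reason `antisense`; pervasive antisense
transcription is real, but a sense probe cannot hybridise the annotated
transcript. The per-probe reasons (`matched`, `intronic`, `antisense`,
`intergenic`, `promiscuous_discarded`, `unmapped`,
`ambiguous_sequence`) are stored with every (probeset, transcript)
record.

**The aligner.** At a bound of one substitution (no gaps — the rule is
phrased as a base-pair mismatch, and placements with more than one
mismatch are not stored), an exact search is cheap: by the pigeonhole
principle any qualifying placement matches one probe half exactly. We
run two trusted-band dictionary searches (`Biostrings::PDict`, exact
first half / exact second half) and verify candidates by Hamming
distance. This makes heuristic alignment thresholds unnecessary and the
output deterministic; the test suite checks the hit set placement-by-
placement against a naive scan. The reverse strand is searched via the
probe's reverse complement, so a probe and its reverse complement are
distinct probes throughout. Probes containing `N` are excluded as
`ambiguous_sequence`: a mismatch count against an ambiguous base is
undefined.

**The promiscuity cap** counts distinct genomic placements, full-match
and mismatch combined, genome-wide. cDNA junction hits do not count
toward it, and a probe discarded as promiscuous stays suppressed on the
cDNA route as well — a discarded probe must not resurface through a
transcript copy of its repeat.

**Merging the two routes.** A cDNA hit that lies inside one exon
projects to the same genomic placement the genomic search already found;
such duplicates are kept once, labelled genomic. Junction hits (two or
more blocks) are always retained as `cdna_projected`, carrying the
transcript they came from. On the synthetic fixture this consolidation
raises matched-probe counts for exactly the junction-bearing probesets
and never flips a probeset's verdict — junction probes strengthen
existing annotations rather than create new ones, and the test suite
asserts precisely that.

**Coordinates.** Everything internal is 1-based inclusive (the Ensembl
convention); conversion to 0-based half-open happens only when writing
BED12. The spec'd stage handoff via BED was replaced by a full-fidelity
TSV because BED cannot carry match status, source and transcript
without lossy encoding; `hits.bed` is still written for genome
browsers.

## Diagnosing the failures

**Unannotated probesets.** Each probe placement of an unannotated
probeset is classified per associated transcript (a placement can be
exonic on one transcript and intronic on another) into exon, 5' UTR,
3' UTR, intron, intergenic, or *border* when it spans a region
boundary. Border placements take the most-5' region in transcript
orientation: exon→intron is an exon border, intron→exon an intron
border. Category counts are divided by the number of associated
transcripts and centred to sum one, then collapsed to ternary
coordinates (coding = exon + UTRs, border, non-coding = intron +
intergenic). Associated transcripts are all transcripts whose gene span
overlaps at least one placement; a fully intergenic probeset keeps a
divisor of one so the profile stays defined, and a probeset with no
placements at all is placed at the non-coding corner by convention with
a logged note. Probes are counted once per (placement, transcript)
pair; a probe hitting one transcript twice contributes twice, which we
consider the honest reading of per-placement accounting.

Two flags reproduce the published colouring: `putative_coding` (blue)
for probesets with under half their probes mapped but at least half of
the mapped ones in coding regions — probesets that would likely be
annotatable with better mapping — and `noncoding_gene` (red) for
probesets whose mapped probes fall mostly inside gene models with a
non-protein-coding biotype (rRNA, pseudogene, ...). A probe counts as
coding-targeting when at least half of its pair categories are coding;
red takes precedence over blue. The same profiling can be re-run
against an alternative gene set (e.g. EST-based models) for a
side-by-side comparison, keeping the unannotated set defined by the
primary annotation.

**Multi-gene probesets.** For probesets annotated to two or more genes,
all gene pairs are tested: *paralogous* if present in the supplied
paralog table (paralogy is an input here, not inferred), *overlapping*
if the genes' extended spans intersect — strand ignored, since
tail-to-tail neighbours sit on opposite strands. Probesets with three or
more genes inherit the pairwise verdicts: any unexplained pair makes
the probeset unexplained, otherwise mixed relations give `both`. This
follows from analysing pairs, as the vast majority of multi-gene
probesets involve exactly two genes.

**SNP overlap.** A variant overlaps a placement when its position falls
inside an alignment block (the intron gap of a junction placement does
not count). Placements split into four groups: perfect match / mismatch
crossed with SNP / no SNP. Only single-nucleotide variants are used;
indels are skipped with a warning. A probe counts as affected when
*any* of its placements overlaps a SNP (the alternative — counting
per-placement — is noted but not used), and a probeset when any member
probe is affected.

**Annotation comparison.** Two annotation tables (probeset → database →
identifier set) are compared per database over the probesets present in
both; one accession identifier in common connects the annotations.

## The synthetic fixture

No public genome or array files are required anywhere: the
`simulate_*` family generates a genome, gene models, an array design,
variants and a paralog table with a machine-readable planted truth. The
generator's defaults define the study conditions and are not tuned:
two 50 kb chromosomes; 25-mer probes; 11 probes per probeset (the
11-20 range of real designs is enforced); two probesets per intent;
multi-exon genes on both strands with 50 bp 5' UTRs and 3' UTRs drawn
uniformly from 150-340 bp; a quarter of transcripts without an
annotated 3' UTR; 0.2 background SNVs per kb. Planted structures
include a 120-copy repeat family (above the cap) and a 99-copy family
(just below it), paralog pairs (locus duplicated, then lightly mutated
outside the probe windows, ~0.4% cDNA divergence), a same-strand tandem
pair whose second gene starts inside the first gene's doubled-UTR
extension, distant gene pairs sharing a 150 bp exonic block (the
"unexplained" multi-gene case), a tail-to-tail pair with 3' ends about
120 bp apart, and genes whose intron bases adjacent to each junction
are edited so a junction-spanning probe can never be matched
contiguously with one mismatch — this guard is what makes the planted
truth exact rather than probabilistic.

One deliberate geometry note: the planted *overlap* probeset uses a
same-strand tandem pair, not the tail-to-tail pair. A single genomic
placement has one strand, so under sense-strand matching a probeset can
only be annotated to both genes of a pair when the shared window is
sense for both — impossible tail-to-tail. The tail-to-tail pair is
still present in the models to exercise opposite-strand extensions
crossing each other harmlessly.

What the fixture does *not* emulate: realistic base composition and
repeat taxonomy, sequencing errors, alternative splicing within a gene
(one transcript per gene keeps the planted truth unambiguous;
multi-transcript genes are covered by unit tests), and array-specific
probe chemistry. Passing the planted-truth check therefore demonstrates
the correctness of the mapping/annotation logic under the stated rules,
not calibration against any real array.

## Numerical and degenerate-input choices

* Mismatch budgets other than 0/1 are rejected; gapped alignment is out
  of scope by design.
* UTR statistic rounding: nearest integer, ties up
  (`floor(x + 0.5)`), avoiding banker's rounding surprises.
* A transcript whose 3' end abuts the chromosome boundary gets an empty
  extension; footprints are merged interval unions, so an extension
  adjacent to the last exon coalesces with it.
* Duplicate chromosome names, overlapping exons within one transcript,
  out-of-range cDNA offsets and out-of-bounds variants are hard errors;
  an empty genome FASTA is a warning plus an empty result.
* Ordering is deterministic everywhere (placements by chromosome,
  start, strand, probe name), so identical inputs give byte-identical
  outputs; the simulator draws every component from its own labelled
  RNG stream so adding a component does not perturb the others.

## Problem sizes

The shipped tests and the acceptance script run entirely on simulated
data at sizes chosen to exercise every code path while staying
desk-scale: the default fixture (100 kb genome, 28 transcripts, 242
probes in 22 probesets) for end-to-end checks, twenty 10 kb random
fixtures of 60 probes each for the placement-by-placement aligner
oracle, and exhaustive enumeration of probeset sizes 11-20 with all
matched counts for the 50% rule. Published headline percentages tied
to specific genome and array releases are reproduced structurally (the
quantities are computed and reported), not numerically.

## Worked example

```{r example, eval = FALSE}
library(probemapr)

fx <- simulate_fixture(fixture_config(seed = 1), dir = "fixture")
run <- run_pipeline(pipeline_config(
  genome = fx$paths[["genome"]], gtf = fx$paths[["gtf"]],
  probes = fx$paths[["probes"]], vcf = fx$paths[["vcf"]],
  paralogs = fx$paths[["paralogs"]], out_dir = "out"))
run
glance(run)                       # one-row mapping/annotation summary
tidy(run)                         # per-stage record counts
plot_unannotated_ternary(run$profiles)
plot_genes_per_probeset(run$histogram)
```

## Known limitations

* Indels between probe and genome are not modelled; a probe spanning a
  1 bp insertion is reported unmapped.
* Whether the original production pipeline counted its location cap
  per chromosome or genome-wide is not documented; we count genome-wide
  and do not count cDNA hits toward it.
* The ternary profile counts each (placement, transcript) pair once;
  pipelines that deduplicate probes per transcript would shift border
  ratios slightly.
* Annotation comparison requires the two tables to use the same
  database naming; no identifier normalisation is attempted.
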