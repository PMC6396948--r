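---
title: "Detecting RdRP-derived secondary siRNAs from end chemistry and splice junctions"
author: "siRNAtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting RdRP-derived secondary siRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siRNAtrace)
```

## The question and the two assays

RNA-dependent RNA polymerases (RdRPs) amplify RNA interference in
nematodes by copying target mRNAs into short antisense "secondary
siRNAs" — the 22G RNAs: 22 nt long, starting with G, and carrying a 5'
*triphosphate* because they are direct polymerization products rather
than Dicer cleavage products (Dicer leaves a 5' monophosphate). Many
animal genomes retain RdRP genes, so a natural question for any such
lineage is whether those genes actually make secondary siRNAs.
`siRNAtrace` implements two complementary computational assays for this
question, together with the annotation machinery both need.

**Assay 1 — end-chemistry deconvolution.** Standard small RNA-seq only
ligates molecules with a 5' monophosphate and an unblocked 3' end.
Preparing four libraries per sample makes the invisible chemistries
visible:

* **#1** untreated: detects 5'-monoP molecules (miRNA-like), whether or
  not the 3' end is 2'-O-methylated;
* **#2** periodate oxidation: destroys unmethylated (2',3'-diol) 3'
  ends, keeping only 5'-monoP **and** 3'-methylated molecules
  (classical piRNA chemistry);
* **#3** Terminator exonuclease, then phosphatase, then T4 PNK:
  degrades 5'-monoP molecules, then rewrites any surviving 5' end
  (hydroxyl or polyphosphate) to monoP — the library where 5'-triP
  RdRP products surface;
* **#4** the #3 treatment followed by periodate: only non-monoP
  molecules with protected 3' ends remain.

`applyStep()` encodes each enzymatic/chemical step as a total function
on end states, `detectableIn()` composes them, and
`chemistryTruthTable()` enumerates the full 6 states x 4 libraries
table. `inferEndStates()` inverts it: given the set of libraries in
which a population is seen, it returns every compatible chemistry.
Patterns can be ambiguous (detection only in #3 leaves 5'-OH and 5'-triP
open) or impossible (detection in #2 without #1); a detected population
whose joint pattern is impossible is a sign that two chemically distinct
species were pooled under one population label.

```{r chem}
chemistryTruthTable()
inferEndStates(3)
```

Two modelling simplifications are deliberate: `triP` stands for any
phosphate number n >= 2 (the assays cannot count phosphates), and
ligation is binary — we ignore quantitative ligation biases between
3'-OH and 2'-O-methyl ends, as the assay is read qualitatively.
5'-capped or otherwise exotic ends are outside the state space.

**Assay 2 — antisense exon-exon junction reads.** The antisense
sequence of a GT..AG intron reads CT..AC, which is not a donor/acceptor
pair. Therefore no antisense transcription-plus-splicing scenario can
produce a short RNA that is antisense to a *spliced* mRNA across an
exon-exon boundary; such a read must have been templated on the mature
mRNA by an RdRP. `buildJunctionIndex()` extracts, for each adjacent
exon pair, the last `Lmax - m` nt of the upstream exon joined to the
first `Lmax - m` nt of the downstream exon; `findJunctionReads()`
reports reads that cross the breakpoint with at least `m` nt on each
side *and have no contiguous genomic match on either strand*.
`spliceAntisenseValidity()` verifies the logical premise per intron and
flags genes with non-canonical introns as uninformative.
`junctionSummary()` reports whole-transcriptome and per-gene sense and
antisense ppm plus the number of distinct read sequences per gene:
genuine RdRP products are sequence-diverse, whereas one heavily cloned
sequence is the signature of an artifact.

## Annotation and normalization

`classifyReads()` assigns every read its highest-priority matching
category: abundant ncRNA > pre-miRNA hairpin (sense before antisense) >
transcriptome (sense before antisense) > any other genome match >
extragenomic. Ties between sense and antisense within one reference set
go to sense, matching the usual presentation convention. Each read is
counted once, at its best category, even if it matches several
references.

All abundances are *parts per million* (ppm): raw counts x 1e6 divided
by the number of genome-matching reads that do **not** match abundant
ncRNAs, *counting reads of every length* — including those outside the
18-30 nt analysis window. Extragenomic reads never enter the
denominator, so contamination does not dilute ppm values; a zero
denominator is an explicit error, never a silent NaN.

Exact matching is implemented as a per-length hash join: every
reference substring of each query length is tabulated against the
(unique-collapsed) reads. This is exact, deterministic, and fast at the
package's working scale (genomes up to ~100 kb); a bounded one-mismatch
mode using `Biostrings` pattern matching is available via
`maxMismatches = 1`, and the default for classification is 0 because
simulated reads are error-free. Ambiguous bases count as mismatches.

`filterLongOrfTranscripts()` keeps transcripts in which one of the
three 5'-most AUGs opens an ORF of >= 100 codons; the initiator AUG is
counted and the stop codon is not (a convention the filter documents
because "100 codons" is otherwise ambiguous), and an ORF may run off
the transcript end.

## miRNA hairpin filtering and mature calls

A candidate pre-miRNA locus passes `locusFilter()` when

* its dot-bracket structure is an *unbranched* hairpin (all pairing
  arcs nested around a single apical loop),
* the stem holds >= 25 base pairs,
* the folding energy is <= -15 kcal/mol (inclusive at equality),
* 21-23-mers form a strict majority (> 0.5) of its 18-30 nt reads —
  our quantification of "mostly", the weakest reading consistent with
  the word, and configurable,
* read coverage reaches >= 20 ppm on at least one nucleotide, pooled
  over libraries (whether pooled or per-library coverage is intended
  is unstated in the source analysis; pooled is used and documented).

Failures carry machine-readable reason codes (`branched`, `stem`,
`energy`, `size`, `coverage`, `no_data`), and every threshold is
boundary-tested. Structures and energies are *inputs* (from RNAfold or
the fixture generator): the filter, not the folding engine, is what
this package contributes. Fixture energies use a toy -1 kcal/mol per
base pair, fixtures only.

`callMature()` groups reads that share a 5' end when their 3' ends are
trimmed by up to 3 nt or extended with genome-templated nucleotides;
non-templated 3' extensions form separate groups. The modal member is
the major form, counts are pooled within the group, and a call is
flagged low-abundance unless it reaches 10 ppm in at least one stage.
Grouping is idempotent: re-calling on already-grouped reads returns the
same calls.

## Signature detectors

The source observations are qualitative ("narrow size distribution",
"5' bias"); the detectors make them operational with declared,
configurable conventions:

* `sirnaDetector()` calls *siRNA_candidate* iff (narrowness: fraction
  of 18-30 nt reads within modal length +/- 1 nt >= 0.5) **and**
  (binomial enrichment of 5' A or G versus the reference transcriptome
  base composition, p < 0.01 — purine initiation is the common property
  of known RdRP products) **and** (antisense abundance >= 1 ppm).
  Fewer than 50 reads yields "insufficient data". All three sub-scores
  are always reported, so a near-miss is visible.
* `pirnaDetector()` calls *piRNA_like* iff 23-30-mers hold >= 0.5 of
  the 18-30 nt mass and (5'U frequency among 23-30-mers >= 0.5 or
  position-10 A frequency among sense 23-26-mers >= 0.3).
* `crossLibraryReport()` joins each detected population's library
  pattern with `inferEndStates()`, applies Benjamini-Hochberg
  correction at FDR 0.05 across the many (library x population) 5'-bias
  tests, and raises the headline flag when no siRNA candidate appears
  in library #1 or #3 — #3 would catch direct triphosphorylated RdRP
  products, #1 would catch Dicer-processed products of long RdRP
  transcripts, so the two libraries jointly cover both biogenesis
  routes.

The binomial background is the reference transcriptome's base
composition rather than uniform 0.25, which controls for genomic
composition. Phasing/ping-pong overlap statistics beyond the 10A
frequency are out of scope.

## The protein screen and Dollo losses

`evalueGate()` (E <= 1e-2, inclusive) and `domainComplete()` (at most
20% of the profile uncovered at each end, ends tested independently —
the reading of "either end") filter profile-search hits;
`catalyticMotif()` scans for the D-b-D-G-D active site with b in a
configurable bulky-residue set defaulting to {L, I, V, F, M, W, Y} —
the source delegates the definition to cited literature without listing
residues, so the set is an explicit parameter rather than a constant.
`dolloLosses()` places the character's single origin at the most recent
common ancestor of the retaining species and counts the maximal
all-absent subtrees below it — the minimal loss count under Dollo
parsimony, verified in the tests against an exhaustive minimal-change
search over all internal-state assignments on random trees.

## What the synthetic data emulates — and what it does not

`generateGenome()` builds chromosomes from random intergenic spacers
and planted features: spliced genes (2-5 exons of 80-240 nt, GT..AG
introns of 60-200 nt, random strand), three abundant-ncRNA loci, and
five hairpin loci — one passing every miRNA filter and one violating
each (branched; 24 bp stem; dG -14 kcal/mol; a sound structure that
receives no reads). `simulateReads()` draws molecule classes i.i.d.
from the configured mixture:

| class | length | 5' | 3' | source |
|---|---|---|---|---|
| miRNA | 21-23 (mode 22) | monoP | OH | arms of the passing hairpin |
| piRNA_like | 23-30 | monoP | OH (methyl optional) | exonic windows, 5'U p=0.75, sense-10A p=0.5 |
| siRNA_22G | 22, 5'G | triP | OH | antisense exonic/junction windows (junction fraction 0.2) |
| degradation | 15-35 | OH/monoP/triP | OH | intergenic windows |
| contaminant | 18-30 | OH/monoP/triP | OH | random, no genomic match |

The default mixture is 40/30/10/15/5 percent in that order — a
deliberately RdRP-positive condition so that recovery, calibration and
power can all be measured against known truth; RdRP-negative conditions
are obtained by zeroing the siRNA_22G weight. The bias strengths are
package conventions, not measured values: the source data characterises
piRNA biases only qualitatively, so these defaults exist to make
recovery tests meaningful, not to estimate nature. piRNA-like reads are
drawn genome-contiguously (as from unspliced precursor transcripts), so
an RdRP-off mixture contains *no* junction-exclusive antisense reads by
construction; junction-spanning siRNA windows are additionally rejected
if their sequence happens to occur contiguously in the genome (short
overhangs can coincide with intron boundaries), so the
`junction_spanning` ground-truth flag always entails
junction-exclusivity. Degradation fragments are drawn from intergenic
sequence only, which gives every molecule a well-defined expected
annotation category.

Not emulated: sequencing errors and quality scores (qualities are
constant 'I' and reads are emitted pre-trimmed; adapter handling is
upstream of this analysis), polymorphism, ligation biases, expression
heterogeneity across loci, and multi-mapping ambiguity beyond what the
random genome produces. Passing tests therefore demonstrate the
*logic* of the pipeline — category priorities, chemistry composition,
junction exclusivity, threshold boundaries — not robustness to the
noise structure of real libraries.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based closed (`GRanges`) throughout, the
  Bioconductor convention; GFF3 is emitted and read 1-based inclusive.
* Determinism: every sampling routine seeds the R RNG internally and
  restores the caller's RNG state, so identical configurations give
  byte-identical FASTA/GFF3/FASTQ output.
* Minimum junction overhang `m = 3` nt: 1-2 nt overhangs are
  uninformative and often genome-ambiguous. The junction mismatch
  budget is 0 for the genome-exclusion test; hits at 1 mismatch against
  the junction sequences are reported with their mismatch count so they
  can be flagged separately (observed artifact reads in real data
  typically carry a mismatch).
* Reads matching junctions of several genes are counted once per gene
  and flagged `ambiguous`.
* Empty inputs: an empty molecule set writes valid empty FASTQ files
  and a complete (all-zero) report; an empty read class yields a
  flagged-empty logo matrix; a zero ppm denominator is an error.
* Sense wins sense/antisense ties within a reference set; the modal
  length tie in `table()` resolves to the smaller length.

## Problem sizes used by the tests

The shipped test-suite and acceptance script exercise: a 2 x 10 kb
default genome (8 genes) with 10,000-molecule mixtures for end-to-end
recovery; 1 x 6 kb fixtures (5 genes) with 150-200 reads for 20
brute-force junction-oracle comparisons, 100 RdRP-off type-I runs and
10 RdRP-on recall runs; 100 null and 100 planted detector calibration
runs (200 and 500 reads); and 100 random 10-leaf trees for the Dollo
oracle. These sizes were chosen so the whole suite runs in a few
minutes on one CPU while keeping every binomial check well-powered.

## Known limitations

The package consumes externally produced secondary structures, domain
tables and alignments; it does not fold RNA, run profile searches, or
align reads with a production aligner (the bounded-mismatch search is
exact but built for desk-scale fixtures, not full genomes). The
detectors' thresholds are conventions that should be recalibrated
before applying them to a new organism's libraries, and the
cross-library logic assumes the four-library design described above.
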