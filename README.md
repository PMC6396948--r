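# siRNAtrace

Detection of RdRP-derived secondary siRNAs from small RNA sequencing —
end-chemistry deconvolution, hierarchical read annotation, and the
antisense exon–exon-junction test.

## The problem

In nematodes, RNA interference is amplified by RNA-dependent RNA
polymerases (RdRPs) that copy target mRNAs into abundant antisense
"secondary siRNAs" (the 22G RNAs: 22 nt, 5′G, and 5′-*tri*phosphorylated,
because they are direct polymerase products rather than Dicer products).
Many other animal genomes retain RdRP genes, and the question for any
such lineage is whether those genes actually produce secondary siRNAs.
`siRNAtrace` is an R package for researchers analysing small RNA-seq
data who want to answer that question with two orthogonal, testable
assays:

1. **End-chemistry deconvolution.** Four libraries per sample —
   untreated (#1), periodate-oxidised (#2), Terminator exonuclease +
   phosphatase + T4 PNK (#3), and both treatments (#4) — each detect a
   different subset of the six possible end chemistries
   {5′-OH, monoP, triP} × {3′-OH, 2′-O-methyl}. The package encodes each
   treatment step as a transformation on end states, derives the full
   6 × 4 detectability truth table, and inverts cross-library detection
   patterns into the compatible chemistries. A 5′-triP population
   (direct RdRP product) appears in library #3 only; a miRNA in #1 only;
   a methylated piRNA in #1 and #2.

2. **Antisense junction reads.** The antisense of a GT..AG intron is
   CT..AC — not a splice donor/acceptor pair — so a short RNA that is
   antisense to a spliced mRNA *across an exon–exon junction* and
   absent from the genome cannot come from antisense transcription: it
   must have been templated on the mature mRNA by an RdRP. The package
   builds junction references, finds junction-exclusive reads with
   minimum-overhang and genome-exclusion guarantees, and summarises
   per-gene sense/antisense ppm and sequence homogeneity.

Around these sit the supporting analyses: hierarchical read annotation
(abundant ncRNA > pre-miRNA > transcriptome > genome > extragenomic)
with ppm normalisation (counts × 10⁶ / genome-matching non-ncRNA reads
of any length), size spectra and positional nucleotide logos,
siRNA/piRNA signature detectors, pre-miRNA hairpin filtering
(unbranched, ≥ 25 bp stem, ΔG ≤ −15 kcal/mol, mostly 21–23-mers,
≥ 20 ppm) with mature-miRNA calling, protein-screen gates (E ≤ 10⁻²,
≤ 20% domain truncation per end, DbDGD catalytic motif) and a Dollo
parsimony gene-loss counter. A deterministic synthetic-data generator
produces toy genomes and read populations with known classes and end
chemistries, so every stage is tested against ground truth.

## Worked example

```r
library(siRNAtrace)

chemistryTruthTable()
#>   five_prime three_prime  lib1  lib2  lib3  lib4
#> 1         OH          OH FALSE FALSE  TRUE FALSE
#> 2      monoP          OH  TRUE FALSE FALSE FALSE
#> 3       triP          OH FALSE FALSE  TRUE FALSE
#> 4         OH      methyl FALSE FALSE  TRUE  TRUE
#> 5      monoP      methyl  TRUE  TRUE FALSE FALSE
#> 6       triP      methyl FALSE FALSE  TRUE  TRUE

inferEndStates(3)      # detected in library #3 only: two chemistries fit
#>   five_prime three_prime
#> 1         OH          OH
#> 3       triP          OH
```

Row 2 is the miRNA chemistry (library #1 only), row 5 the classical
methylated piRNA (#1 and #2), row 3 the 22G secondary siRNA (#3 only).
The inversion shows the #3-only pattern is ambiguous between 5′-OH and
5′-triP — the library design brackets the chemistry, it does not always
pin it.

`runPipeline()` executes the whole analysis on a simulated study
(default: 2 × 10 kb genome, 8 genes, 2000 molecules of the default
mixture, which *includes* a planted 10% 22G class):

```r
res <- runPipeline(list(seed = 42), quiet = TRUE)
res$stage_counts[, c("library", "total", "premiRNA_sense",
                     "transcriptome_antisense", "extragenomic",
                     "denominator")]
#>   library total premiRNA_sense transcriptome_antisense extragenomic denominator
#> 1       1  1519            813                     293           41        1478
#> 2       2     0              0                       0            0           0
#> 3       3   481              0                     206           74         370
#> 4       4     0              0                       0            0           0
```

Libraries #2 and #4 are empty — no simulated class is both
3′-methylated and non-monoP — mirroring the scarcity of ligatable
material such libraries show when piRNAs are unmethylated. The miRNAs
(813 hairpin-matching reads) appear only in #1; the 22G class appears
only in #3, as transcriptome-antisense reads.

```r
res$mirna[, c("locus_id", "pass", "reasons", "n_reads")]
#>         locus_id  pass          reasons n_reads
#> 1        hp_pass  TRUE                      813
#> 2  hp_short_stem FALSE     stem,no_data       0
#> 3 hp_no_coverage FALSE          no_data       0
#> 4    hp_branched FALSE branched,no_data       0
#> 5 hp_weak_energy FALSE   energy,no_data       0

res$junction_summary$whole
#>           orientation reads      ppm
#> sense           sense     0     0.00
#> antisense   antisense    37 20021.65

res$report$populations
#>                population pattern     compatible_states
#> 1     transcriptome_sense       1              monoP/OH
#> 2 transcriptome_antisense     1,3 chemically impossible
```

Only the planted passing hairpin survives the locus filters; each
violator fails with its reason code. The 37 antisense
junction-exclusive reads (20,022 ppm of the pooled denominator) are the
planted RdRP products — under an RdRP-off mixture
(`class_weights` without `siRNA_22G`) this count is 0 and
`res$report$no_secondary_sirna_evidence` is `TRUE`. The
transcriptome-antisense population is detected in libraries #1 *and*
#3, a jointly impossible chemistry — correctly exposing that it pools
two species: antisense piRNA-like reads (monoP, #1) and 22G RNAs
(triP, #3).

See `vignettes/secondary-sirna-detection.Rmd` for the models,
thresholds, and design decisions, and `?simConfig`, `?classifyReads`,
`?findJunctionReads`, `?locusFilter`, `?sirnaDetector`, `?dolloLosses`
for the individual interfaces.

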