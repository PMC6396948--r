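Package: siRNAtrace
Title: End-Chemistry Deconvolution and Junction Tests for RdRP-Derived
    Small RNAs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to search small RNA-seq data for secondary siRNAs made
    by RNA-dependent RNA polymerases (RdRPs). Implements the four-library
    end-chemistry truth table (periodate oxidation, Terminator
    exonuclease, phosphatase, T4 PNK) and its inverse inference,
    hierarchical read annotation with parts-per-million normalization,
    size spectra and positional nucleotide logos, pre-miRNA hairpin
    filtering with mature miRNA calling, siRNA/piRNA signature detectors,
    an antisense exon-exon junction test for RNA-dependent RNA
    polymerization, protein-screen gates (domain completeness, DbDGD
    catalytic motif) with Dollo parsimony loss counting, and a
    deterministic synthetic-data generator that provides ground-truth
    small RNA populations for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
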