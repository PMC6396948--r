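#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom Biostrings DNAStringSet
#' @importFrom GenomicRanges GRanges GRangesList
NULL

.SMALL_RNA_CLASSES <- c("miRNA", "piRNA_like", "siRNA_22G", "degradation",
                        "contaminant")

.READ_CATEGORIES <- c("abundant_ncRNA", "premiRNA_sense", "premiRNA_antisense",
                      "transcriptome_sense", "transcriptome_antisense",
                      "genome_other", "extragenomic")

#' Simulation configuration
#'
#' Parameters of the synthetic small-RNA study: a toy genome with spliced
#' gene models, planted pre-miRNA hairpins and abundant-ncRNA loci, and a
#' mixture of small RNA molecule classes with known 5'/3' end chemistry.
#' Defaults describe the default study conditions used throughout the
#' package's tests; all biases are explicit parameters because the source
#' populations are only characterised qualitatively in real data.
#'
#' @slot seed integer seed; the generator is fully deterministic given it.
#' @slot n_chromosomes,chrom_length number and minimum length (nt) of
#'   chromosomes.
#' @slot n_genes number of spliced protein-coding gene models.
#' @slot exons_per_gene integer range (min, max) of exons per gene.
#' @slot intron_length integer range (min, max) of intron lengths; introns
#'   are canonical GT..AG on the coding strand.
#' @slot class_weights named numeric, proportions of the five molecule
#'   classes; must be non-negative and sum to 1.
#' @slot reads_per_library number of molecules drawn per simulated sample.
#' @slot mismatch_rate per-nucleotide substitution probability applied to
#'   simulated molecules (0 = error-free).
#' @slot pirna_u5_prob probability that a piRNA-like molecule starts with U.
#' @slot pirna_a10_prob probability that a sense 23-26 nt piRNA-like
#'   molecule carries A at position 10 (ping-pong style bias).
#' @slot pirna_sense_prob probability that a piRNA-like molecule is sense
#'   to its source transcript.
#' @slot pirna_methylated logical; whether piRNA-like molecules carry a
#'   2'-O-methylated 3' end (FALSE by default: lancelet piRNAs are
#'   unmethylated).
#' @slot junction_fraction fraction of siRNA_22G molecules that span an
#'   exon-exon junction in antisense orientation.
#'
#' @export
setClass("SimConfig",
    representation(
        seed = "integer",
        n_chromosomes = "integer",
        chrom_length = "integer",
        n_genes = "integer",
        exons_per_gene = "integer",
        intron_length = "integer",
        class_weights = "numeric",
        reads_per_library = "integer",
        mismatch_rate = "numeric",
        pirna_u5_prob = "numeric",
        pirna_a10_prob = "numeric",
        pirna_sense_prob = "numeric",
        pirna_methylated = "logical",
        junction_fraction = "numeric"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character(0)
    w <- object@class_weights
    if (is.null(names(w)) || !all(names(w) %in% .SMALL_RNA_CLASSES))
        msg <- c(msg, "class_weights must be named with known classes")
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
        msg <- c(msg, "class_weights must be >= 0 and sum to 1")
    if (length(object@exons_per_gene) != 2L ||
        object@exons_per_gene[1] < 2L)
        msg <- c(msg, "exons_per_gene must be a range with min >= 2")
    if (length(object@intron_length) != 2L || object@intron_length[1] < 4L)
        msg <- c(msg, "introns shorter than 4 nt cannot hold GT..AG")
    if (object@mismatch_rate < 0 || object@mismatch_rate > 1)
        msg <- c(msg, "mismatch_rate must be a probability")
    for (p in c(object@pirna_u5_prob, object@pirna_a10_prob,
                object@pirna_sense_prob, object@junction_fraction))
        if (p < 0 || p > 1) msg <- c(msg, "bias parameters are probabilities")
    if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param seed integer seed.
#' @param n_chromosomes,chrom_length,n_genes,exons_per_gene,intron_length
#'   genome layout; see \linkS4class{SimConfig}.
#' @param class_weights named proportions over
#'   \code{c("miRNA","piRNA_like","siRNA_22G","degradation","contaminant")}.
#' @param reads_per_library,mismatch_rate read simulation parameters.
#' @param pirna_u5_prob,pirna_a10_prob,pirna_sense_prob,pirna_methylated,junction_fraction
#'   class-specific sequence-bias and chemistry parameters.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 1, n_genes = 5L)
#' @export
simConfig <- function(seed = 1L,
                      n_chromosomes = 2L,
                      chrom_length = 10000L,
                      n_genes = 8L,
                      exons_per_gene = c(2L, 5L),
                      intron_length = c(60L, 200L),
                      class_weights = c(miRNA = 0.40, piRNA_like = 0.30,
                                        siRNA_22G = 0.10, degradation = 0.15,
                                        contaminant = 0.05),
                      reads_per_library = 2000L,
                      mismatch_rate = 0,
                      pirna_u5_prob = 0.75,
                      pirna_a10_prob = 0.5,
                      pirna_sense_prob = 0.5,
                      pirna_methylated = FALSE,
                      junction_fraction = 0.2) {
    new("SimConfig",
        seed = as.integer(seed),
        n_chromosomes = as.integer(n_chromosomes),
        chrom_length = as.integer(chrom_length),
        n_genes = as.integer(n_genes),
        exons_per_gene = as.integer(exons_per_gene),
        intron_length = as.integer(intron_length),
        class_weights = class_weights,
        reads_per_library = as.integer(reads_per_library),
        mismatch_rate = mismatch_rate,
        pirna_u5_prob = pirna_u5_prob,
        pirna_a10_prob = pirna_a10_prob,
        pirna_sense_prob = pirna_sense_prob,
        pirna_methylated = pirna_methylated,
        junction_fraction = junction_fraction)
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig: seed", object@seed, "|",
        object@n_chromosomes, "chromosomes >=", object@chrom_length, "nt |",
        object@n_genes, "genes\n")
    cat("  class weights:",
        paste(names(object@class_weights),
              signif(object@class_weights, 3), sep = "=", collapse = " "),
        "\n")
})

#' Synthetic genome fixture
#'
#' A toy genome together with its annotation: spliced gene models (exons in
#' transcription order), the spliced transcriptome, abundant-ncRNA loci,
#' and candidate pre-miRNA hairpin loci with dot-bracket structures and
#' folding energies. All sequences are DNA; coordinates are 1-based closed
#' (Bioconductor convention) and exported as standard GFF3.
#'
#' @slot genome \link[Biostrings]{DNAStringSet} of chromosomes.
#' @slot genes \link[GenomicRanges]{GRangesList}: per gene, its exons in
#'   transcription order (metadata column \code{exon_rank}).
#' @slot transcripts spliced transcript sequences, one per gene.
#' @slot ncRNA abundant non-coding RNA reference sequences.
#' @slot ncRNALoci genomic loci of the abundant ncRNAs.
#' @slot hairpins data.frame of candidate pre-miRNA loci: \code{locus_id},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}, \code{sequence},
#'   \code{structure} (dot-bracket), \code{dG} (kcal/mol), \code{role}
#'   (which filter the planted locus is meant to pass or violate).
#' @slot intergenic \link[GenomicRanges]{GRanges} of unannotated intervals
#'   (source of degradation fragments).
#' @slot config the \linkS4class{SimConfig} used.
#' @export
setClass("GenomeFixture",
    representation(
        genome = "DNAStringSet",
        genes = "GRangesList",
        transcripts = "DNAStringSet",
        ncRNA = "DNAStringSet",
        ncRNALoci = "GRanges",
        hairpins = "data.frame",
        intergenic = "GRanges",
        config = "SimConfig"
    )
)

setValidity("GenomeFixture", function(object) {
    msg <- character(0)
    if (!identical(names(object@genes), names(object@transcripts)))
        msg <- c(msg, "gene names and transcript names differ")
    need <- c("locus_id", "chrom", "start", "end", "strand", "sequence",
              "structure", "dG")
    if (!all(need %in% names(object@hairpins)))
        msg <- c(msg, "hairpin table lacks required columns")
    if (nrow(object@hairpins) &&
        any(nchar(object@hairpins$structure) !=
            nchar(object@hairpins$sequence)))
        msg <- c(msg, "hairpin structure/sequence length mismatch")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GenomeFixture", function(object) {
    cat("GenomeFixture:", length(object@genome), "chromosomes (",
        sum(Biostrings::width(object@genome)), "nt ),",
        length(object@genes), "genes,",
        length(object@ncRNA), "abundant ncRNAs,",
        nrow(object@hairpins), "hairpin loci\n")
})

#' @describeIn GenomeFixture chromosome sequences.
#' @param x,object a \code{GenomeFixture}.
#' @export
genomeSeqs <- function(x) x@genome

#' @describeIn GenomeFixture gene models (exons in transcription order).
#' @export
geneModels <- function(x) x@genes

#' @describeIn GenomeFixture spliced transcript sequences.
#' @export
transcriptSeqs <- function(x) x@transcripts

#' @describeIn GenomeFixture abundant ncRNA reference sequences.
#' @export
ncRNASeqs <- function(x) x@ncRNA

#' @describeIn GenomeFixture candidate pre-miRNA hairpin table.
#' @export
hairpinTable <- function(x) x@hairpins

#' Set of simulated small RNA molecules
#'
#' Each molecule carries its RNA sequence, 5' phosphorylation state
#' (\code{OH}, \code{monoP} or \code{triP}), 3' state (\code{OH} or
#' \code{methyl}), true class, genomic origin and the annotation category
#' it is expected to receive — the ground truth every downstream stage is
#' checked against.
#'
#' @slot mol a \link[S4Vectors]{DataFrame} with columns \code{id},
#'   \code{sequence} (RNA, A/C/G/U), \code{five_prime}, \code{three_prime},
#'   \code{true_class}, \code{chrom} (or \code{"none"}), \code{start},
#'   \code{end}, \code{strand}, \code{junction_spanning},
#'   \code{expected_category}.
#' @export
setClass("SmallRNASet", representation(mol = "DataFrame"))

setValidity("SmallRNASet", function(object) {
    m <- object@mol
    need <- c("id", "sequence", "five_prime", "three_prime", "true_class",
              "chrom", "start", "end", "strand", "junction_spanning",
              "expected_category")
    if (!all(need %in% colnames(m)))
        return("missing molecule columns")
    if (!nrow(m)) return(TRUE)
    msg <- character(0)
    len <- nchar(m$sequence)
    if (any(len < 15 | len > 35))
        msg <- c(msg, "molecule lengths must lie in 15..35 nt")
    gel <- m$true_class %in% c("miRNA", "piRNA_like", "siRNA_22G")
    if (any(len[gel] < 18 | len[gel] > 30))
        msg <- c(msg, "miRNA/piRNA/siRNA molecules must lie in 18..30 nt")
    g22 <- m$true_class == "siRNA_22G"
    if (any(g22) && (any(len[g22] != 22L) ||
                     any(substr(m$sequence[g22], 1, 1) != "G") ||
                     any(m$five_prime[g22] != "triP")))
        msg <- c(msg, "siRNA_22G molecules must be 22 nt, 5'G, 5'-triP")
    mir <- m$true_class == "miRNA"
    if (any(mir) && (any(m$five_prime[mir] != "monoP") ||
                     any(m$three_prime[mir] != "OH")))
        msg <- c(msg, "miRNA molecules must be 5'-monoP, 3'-OH")
    if (grepl("[^ACGU]", paste(m$sequence, collapse = "")))
        msg <- c(msg, "sequences must be RNA (A/C/G/U)")
    if (length(msg)) msg else TRUE
})

#' Construct a SmallRNASet
#' @param mol a DataFrame or data.frame of molecule records; see
#'   \linkS4class{SmallRNASet}.
#' @return A \linkS4class{SmallRNASet}.
#' @export
SmallRNASet <- function(mol) {
    new("SmallRNASet", mol = as(mol, "DataFrame"))
}

#' @describeIn SmallRNASet molecule table as a DataFrame.
#' @param x a \code{SmallRNASet}.
#' @export
molecules <- function(x) x@mol

#' @describeIn SmallRNASet molecule RNA sequences.
#' @export
rnaSequence <- function(x) x@mol$sequence

#' @describeIn SmallRNASet 5' end states.
#' @export
fivePrime <- function(x) x@mol$five_prime

#' @describeIn SmallRNASet 3' end states.
#' @export
threePrime <- function(x) x@mol$three_prime

#' @describeIn SmallRNASet true molecule classes.
#' @export
trueClass <- function(x) x@mol$true_class

setMethod("length", "SmallRNASet", function(x) nrow(x@mol))

setMethod("show", "SmallRNASet", function(object) {
    cat("SmallRNASet with", nrow(object@mol), "molecules\n")
    if (nrow(object@mol)) {
        tab <- table(object@mol$true_class)
        cat("  ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
    }
})

setMethod("[", "SmallRNASet", function(x, i, j, ..., drop = TRUE) {
    new("SmallRNASet", mol = x@mol[i, , drop = FALSE])
})
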