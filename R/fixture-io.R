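#' @importFrom Biostrings writeXStringSet readDNAStringSet BStringSet
#' @importFrom utils read.delim
NULL

.fixtureFiles <- function(dir) {
    c(genome = file.path(dir, "genome.fa"),
      transcriptome = file.path(dir, "transcriptome.fa"),
      ncrna = file.path(dir, "ncrna.fa"),
      genes = file.path(dir, "genes.gff3"),
      hairpins = file.path(dir, "hairpins.tsv"),
      truth = file.path(dir, "ground_truth.tsv"),
      lib1 = file.path(dir, "library_1.fastq"),
      lib2 = file.path(dir, "library_2.fastq"),
      lib3 = file.path(dir, "library_3.fastq"),
      lib4 = file.path(dir, "library_4.fastq"))
}

# gene models -> GFF3 gene/mRNA/exon records (1-based inclusive)
.genesToGff <- function(genes) {
    rows <- lapply(names(genes), function(g) {
        ex <- genes[[g]]
        chrom <- as.character(seqnames(ex))[1]
        str <- as.character(strand(ex))[1]
        tid <- paste0(g, ".t1")
        gene <- GRanges(chrom, IRanges(min(start(ex)), max(end(ex))),
                        strand = str)
        mcols(gene) <- S4Vectors::DataFrame(
            type = "gene", ID = g, Parent = NA_character_,
            exon_rank = NA_integer_)
        mrna <- gene
        mcols(mrna) <- S4Vectors::DataFrame(
            type = "mRNA", ID = tid, Parent = g, exon_rank = NA_integer_)
        exg <- ex
        mcols(exg) <- S4Vectors::DataFrame(
            type = "exon",
            ID = paste0(tid, ".exon", seq_along(ex)),
            Parent = tid, exon_rank = mcols(ex)$exon_rank)
        c(gene, mrna, exg)
    })
    gr <- do.call(c, rows)
    mcols(gr)$type <- factor(mcols(gr)$type,
                             levels = c("gene", "mRNA", "exon"))
    mcols(gr)$source <- "siRNAtrace"
    gr
}

#' Write a fixture and its simulated libraries to disk
#'
#' Emits the genome FASTA, gene models as GFF3 (1-based inclusive), the
#' spliced transcriptome and abundant-ncRNA FASTA files, the hairpin table
#' (locus_id, structure, dG_kcal_per_mol), a ground-truth TSV (molecule
#' id, class, end states, origin, expected annotation category, and in
#' which of the four libraries it is detectable), and one pre-trimmed
#' FASTQ per library protocol (constant quality 'I').
#'
#' @param fixture a \linkS4class{GenomeFixture}.
#' @param mols a \linkS4class{SmallRNASet}.
#' @param dir output directory (created if absent).
#' @param overwrite logical; refuse to clobber existing files unless TRUE.
#' @return named character vector of the written paths, invisibly.
#' @export
writeFixture <- function(fixture, mols, dir, overwrite = FALSE) {
    stopifnot(is(fixture, "GenomeFixture"), is(mols, "SmallRNASet"))
    files <- .fixtureFiles(dir)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    clash <- files[file.exists(files)]
    if (length(clash) && !overwrite)
        stop("refusing to overwrite existing files: ",
             paste(basename(clash), collapse = ", "))

    writeXStringSet(fixture@genome, files["genome"])
    writeXStringSet(fixture@transcripts, files["transcriptome"])
    writeXStringSet(fixture@ncRNA, files["ncrna"])
    rtracklayer::export(.genesToGff(fixture@genes), files["genes"],
                        format = "gff3")

    hp <- fixture@hairpins
    hpOut <- data.frame(locus_id = hp$locus_id, chrom = hp$chrom,
                        start = hp$start, end = hp$end, strand = hp$strand,
                        sequence = hp$sequence, structure = hp$structure,
                        dG_kcal_per_mol = hp$dG)
    write.table(hpOut, files["hairpins"], sep = "\t", quote = FALSE,
                row.names = FALSE)

    truth <- as.data.frame(molecules(mols))
    for (i in 1:4)
        truth[[paste0("lib", i)]] <-
            detectableIn(truth$five_prime, truth$three_prime, i)
    write.table(truth, files["truth"], sep = "\t", quote = FALSE,
                row.names = FALSE)

    for (i in 1:4) {
        sub <- applyProtocol(mols, i)
        seqs <- DNAStringSet(.rna2dna(rnaSequence(sub)))
        names(seqs) <- molecules(sub)$id
        writeXStringSet(seqs, files[paste0("lib", i)], format = "fastq",
                        qualities = BStringSet(strrep("I", width(seqs))))
    }
    invisible(files)
}

#' Read gene models back from a GFF3 file
#'
#' @param path GFF3 file with gene/mRNA/exon records as written by
#'   \code{\link{writeFixture}}.
#' @return A \link[GenomicRanges]{GRangesList} of exons per gene in
#'   transcription order.
#' @export
readGff3Genes <- function(path) {
    gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                   error = function(e)
                       stop("GFF3 parse error in ", path, ": ",
                            conditionMessage(e)))
    ex <- gr[mcols(gr)$type == "exon"]
    parent <- vapply(mcols(ex)$Parent, `[`, character(1), 1L)
    gene <- sub("\\.t1$", "", parent)
    grl <- split(ex, gene)
    GRangesList(lapply(grl, function(x) {
        x <- x[order(start(x))]
        if (as.character(strand(x))[1] == "-") x <- rev(x)
        mcols(x) <- S4Vectors::DataFrame(exon_rank = seq_along(x))
        x
    }))
}
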