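#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

.saveRNG <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.restoreRNG <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else {
        assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
}

.randomDNA <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp <- function(x) {
    as.character(reverseComplement(DNAStringSet(x)))
}

# scalar reverse complement without XStringSet overhead (simulator loops)
.rc1 <- function(x) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "",
                       fixed = TRUE)[[1L]]), collapse = "")
}

.dna2rna <- function(x) chartr("Tt", "Uu", x)

.rna2dna <- function(x) chartr("Uu", "Tt", x)

# exon chain (GRanges in transcription order) -> spliced transcript DNA
.spliceExons <- function(genome, exons) {
    chrom <- as.character(GenomeInfoDb::seqnames(exons))
    pieces <- vapply(seq_along(exons), function(i) {
        s <- substr(as.character(genome[[chrom[i]]]),
                    BiocGenerics::start(exons)[i],
                    BiocGenerics::end(exons)[i])
        if (as.character(BiocGenerics::strand(exons))[i] == "-")
            .revcomp(s) else s
    }, character(1))
    paste(pieces, collapse = "")
}
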