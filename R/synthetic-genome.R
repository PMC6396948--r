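#' @importFrom GenomicRanges GRanges GRangesList mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqnames
#' @importFrom BiocGenerics start end strand width
NULL

.HAIRPIN_ROLES <- c("pass", "branched", "short_stem", "weak_energy",
                    "no_coverage")

# A planted hairpin: two perfectly pairing arms around an apical loop.
# The toy folding energy used for fixtures is -1 kcal/mol per base pair;
# the weak_energy violator records a dG of -14 regardless of its stem so
# that it fails the energy filter and nothing else.
.makeHairpin <- function(role) {
    mk <- function(armLen, loopLen, dG = -armLen) {
        arm <- .randomDNA(armLen)
        loop <- .randomDNA(loopLen)
        list(sequence = paste0(arm, loop, .revcomp(arm)),
             structure = paste0(strrep("(", armLen), strrep(".", loopLen),
                                strrep(")", armLen)),
             dG = dG)
    }
    hp <- switch(role,
        pass = mk(30L, 8L),
        no_coverage = mk(28L, 8L),
        short_stem = mk(24L, 8L),
        weak_energy = mk(26L, 8L, dG = -14),
        branched = {
            o <- .randomDNA(5L); a <- .randomDNA(12L); b <- .randomDNA(12L)
            list(sequence = paste0(o, a, .randomDNA(4L), .revcomp(a), "AC",
                                   b, .randomDNA(4L), .revcomp(b),
                                   .revcomp(o)),
                 structure = paste0("(((((", strrep("(", 12), "....",
                                    strrep(")", 12), "..", strrep("(", 12),
                                    "....", strrep(")", 12), ")))))"),
                 dG = -29)
        })
    hp$role <- role
    hp
}

# A spliced gene in transcription orientation: exons interleaved with
# canonical GT..AG introns; the genomic insert is the reverse complement
# for minus-strand genes.
.makeGene <- function(config) {
    k <- sample(seq(config@exons_per_gene[1], config@exons_per_gene[2]), 1L)
    exLens <- sample(80:240, k, replace = TRUE)
    inLens <- sample(seq(config@intron_length[1], config@intron_length[2]),
                     k - 1L, replace = TRUE)
    exSeqs <- vapply(exLens, .randomDNA, character(1))
    inSeqs <- vapply(inLens, function(n) {
        s <- .randomDNA(n)
        paste0("GT", substr(s, 3L, n - 2L), "AG")
    }, character(1))
    pre <- exSeqs[1]
    for (j in seq_len(k - 1L)) pre <- paste0(pre, inSeqs[j], exSeqs[j + 1L])
    preLen <- nchar(pre)
    # exon bounds within the pre-mRNA (transcription orientation)
    preStart <- cumsum(c(1L, head(exLens, -1L) + inLens))
    preEnd <- preStart + exLens - 1L
    strand <- sample(c("+", "-"), 1L)
    insert <- if (strand == "+") pre else .revcomp(pre)
    # map pre-mRNA coords to insert-local coords
    if (strand == "+") {
        locStart <- preStart; locEnd <- preEnd
    } else {
        locStart <- preLen - preEnd + 1L
        locEnd <- preLen - preStart + 1L
    }
    list(insert = insert, strand = strand,
         exon_local_start = locStart, exon_local_end = locEnd,
         transcript = paste(exSeqs, collapse = ""))
}

#' Generate a deterministic toy genome fixture
#'
#' Builds chromosomes by concatenating random intergenic spacers with
#' planted features: spliced gene models (canonical GT..AG introns),
#' abundant-ncRNA loci, and five candidate pre-miRNA hairpin loci — one
#' satisfying every miRNA filter and one violating each of them (branched
#' structure; 24 bp stem; folding energy -14 kcal/mol; a structurally
#' sound locus that receives no reads). Identical configurations yield
#' byte-identical output.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A \linkS4class{GenomeFixture}.
#' @examples
#' fx <- generateGenome(simConfig(seed = 1))
#' @export
generateGenome <- function(config) {
    validObject(config)
    old <- .saveRNG(); on.exit(.restoreRNG(old))
    set.seed(config@seed)

    nchrom <- config@n_chromosomes
    chromNames <- paste0("chr", seq_len(nchrom))
    geneChrom <- rep(seq_len(nchrom), length.out = config@n_genes)
    nNc <- 3L
    ncChrom <- rep(seq_len(nchrom), length.out = nNc)
    hpChrom <- rep(seq_len(nchrom), length.out = length(.HAIRPIN_ROLES))

    chromSeq <- character(nchrom)
    geneRows <- list(); ncRows <- list(); hpRows <- list(); igRows <- list()
    geneIdx <- ncIdx <- hpIdx <- 0L

    for (ci in seq_len(nchrom)) {
        parts <- character(0); pos <- 0L
        addGap <- function(len) {
            parts[[length(parts) + 1L]] <<- .randomDNA(len)
            igRows[[length(igRows) + 1L]] <<-
                data.frame(chrom = chromNames[ci], start = pos + 1L,
                           end = pos + len)
            pos <<- pos + len
        }
        feats <- c(rep("gene", sum(geneChrom == ci)),
                   rep("ncrna", sum(ncChrom == ci)),
                   rep("hairpin", sum(hpChrom == ci)))
        feats <- sample(feats)
        hpRolesHere <- .HAIRPIN_ROLES[hpChrom == ci]
        hpHere <- 0L
        for (f in feats) {
            addGap(sample(150:350, 1L))
            if (f == "gene") {
                geneIdx <- geneIdx + 1L
                g <- .makeGene(config)
                geneRows[[geneIdx]] <- list(
                    id = sprintf("gene%02d", geneIdx),
                    chrom = chromNames[ci], offset = pos, def = g)
                parts[[length(parts) + 1L]] <- g$insert
                pos <- pos + nchar(g$insert)
            } else if (f == "ncrna") {
                ncIdx <- ncIdx + 1L
                s <- .randomDNA(120L)
                ncRows[[ncIdx]] <- data.frame(
                    id = sprintf("ncRNA%02d", ncIdx),
                    chrom = chromNames[ci], start = pos + 1L,
                    end = pos + 120L, sequence = s)
                parts[[length(parts) + 1L]] <- s
                pos <- pos + 120L
            } else {
                hpHere <- hpHere + 1L
                hpIdx <- hpIdx + 1L
                hp <- .makeHairpin(hpRolesHere[hpHere])
                hpRows[[hpIdx]] <- data.frame(
                    locus_id = paste0("hp_", hp$role),
                    chrom = chromNames[ci], start = pos + 1L,
                    end = pos + nchar(hp$sequence), strand = "+",
                    sequence = hp$sequence, structure = hp$structure,
                    dG = hp$dG, role = hp$role)
                parts[[length(parts) + 1L]] <- hp$sequence
                pos <- pos + nchar(hp$sequence)
            }
        }
        if (pos < config@chrom_length) addGap(config@chrom_length - pos)
        else addGap(sample(150:350, 1L))
        chromSeq[ci] <- paste(parts, collapse = "")
    }

    genome <- DNAStringSet(chromSeq)
    names(genome) <- chromNames

    grl <- GRangesList(lapply(geneRows, function(gr) {
        d <- gr$def
        # exon_local_* are in transcription order already (decreasing
        # genomic coordinates for minus-strand genes)
        ex <- GRanges(gr$chrom,
                      IRanges(gr$offset + d$exon_local_start,
                              gr$offset + d$exon_local_end),
                      strand = d$strand)
        mcols(ex)$exon_rank <- seq_along(ex)
        ex
    }))
    names(grl) <- vapply(geneRows, `[[`, character(1), "id")

    transcripts <- DNAStringSet(vapply(geneRows, function(gr)
        gr$def$transcript, character(1)))
    names(transcripts) <- names(grl)

    ncDf <- do.call(rbind, ncRows)
    ncSeqs <- DNAStringSet(ncDf$sequence)
    names(ncSeqs) <- ncDf$id
    ncLoci <- GRanges(ncDf$chrom, IRanges(ncDf$start, ncDf$end))
    names(ncLoci) <- ncDf$id

    hpDf <- do.call(rbind, hpRows)
    rownames(hpDf) <- NULL
    igDf <- do.call(rbind, igRows)
    ig <- GRanges(igDf$chrom, IRanges(igDf$start, igDf$end))

    new("GenomeFixture", genome = genome, genes = grl,
        transcripts = transcripts, ncRNA = ncSeqs, ncRNALoci = ncLoci,
        hairpins = hpDf, intergenic = ig, config = config)
}

#' Spliced transcript sequences from gene models
#'
#' Concatenates the genomic exon sequences of each gene in transcription
#' order (reverse-complemented for minus-strand genes).
#'
#' @param genome a named \link[Biostrings]{DNAStringSet} of chromosomes.
#' @param genes a \link[GenomicRanges]{GRangesList} of exon chains in
#'   transcription order.
#' @return A \link[Biostrings]{DNAStringSet}, one transcript per gene.
#' @export
splicedTranscripts <- function(genome, genes) {
    out <- DNAStringSet(vapply(seq_along(genes), function(i)
        .spliceExons(genome, genes[[i]]), character(1)))
    names(out) <- names(genes)
    out
}
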