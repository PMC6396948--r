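# hand-built two-exon gene: exon1 = genome[101..140], intron GT..AG,
# exon2 = genome[201..240]
make_mini_gene <- function(seed = 11) {
    set.seed(seed)
    base <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
    chrom <- paste0(substr(base, 1, 140),
                    "GT", substr(base, 143, 198), "AG",
                    substr(base, 201, 400))
    genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
    ex <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(101, 201), c(140, 240)), strand = "+")
    S4Vectors::mcols(ex)$exon_rank <- 1:2
    genes <- GenomicRanges::GRangesList(g1 = ex)
    list(genome = genome, genes = genes, chrom = chrom)
}

test_that("junction index contains transcript substrings with breakpoints", {
    fx <- small_fixture()
    idx <- buildJunctionIndex(fx)
    njunc <- sum(vapply(geneModels(fx), length, integer(1)) - 1L)
    expect_equal(nrow(idx), njunc)
    tx <- as.character(transcriptSeqs(fx))
    for (i in seq_len(nrow(idx))) {
        expect_true(grepl(idx$sequence[i], tx[[idx$gene[i]]], fixed = TRUE))
        expect_gt(idx$breakpoint[i], 0)
        expect_lt(idx$breakpoint[i], nchar(idx$sequence[i]))
    }
    # a three-exon gene yields two junctions
    g3 <- names(which(vapply(geneModels(fx), length, integer(1)) == 3L))[1]
    if (!is.na(g3))
        expect_equal(sum(idx$gene == g3), 2L)
})

test_that("short exons truncate junction flanks", {
    mg <- make_mini_gene()
    short <- mg$genes
    # shrink exon 1 to 5 nt
    ex <- short[["g1"]]
    ex1 <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(136, 201), c(140, 240)), strand = "+")
    S4Vectors::mcols(ex1)$exon_rank <- 1:2
    idx <- buildJunctionIndex(mg$genome,
                              GenomicRanges::GRangesList(g1 = ex1))
    expect_equal(idx$breakpoint, 5L)
    expect_equal(nchar(idx$sequence), 5L + 27L)
})

test_that("junction-spanning reads are found; exonic and intronic are not", {
    mg <- make_mini_gene()
    idx <- buildJunctionIndex(mg$genome, mg$genes)
    tx <- paste0(substr(mg$chrom, 101, 140), substr(mg$chrom, 201, 240))
    span <- substr(tx, 31, 52)            # 10/12 split over the junction
    exonic <- substr(tx, 5, 26)           # inside exon 1
    genomic <- substr(mg$chrom, 131, 152) # runs into the intron
    hits <- findJunctionReads(c(span, rc(span), exonic, genomic),
                              idx, mg$genome)
    expect_setequal(hits$orientation, c("sense", "antisense"))
    expect_equal(hits$overhang_left[hits$orientation == "sense"], 10L)
    expect_equal(hits$overhang_right[hits$orientation == "sense"], 12L)
    expect_false(exonic %in% hits$read)
    expect_false(genomic %in% hits$read)
    # every reported hit is junction-exclusive (oracle re-check)
    for (r in unique(hits$read)) {
        expect_equal(oracle_occ(r, as.character(mg$genome)) +
                     oracle_occ(rc(r), as.character(mg$genome)), 0)
    }
})

test_that("hits equal the brute-force oracle on random fixtures", {
    for (seed in c(21, 22)) {
        fx <- small_fixture(seed = seed)
        mols <- simulateReads(fx, simConfig(
            seed = seed, class_weights = c(miRNA = .3, piRNA_like = .3,
                                           siRNA_22G = .3,
                                           contaminant = .1),
            junction_fraction = 0.5), n = 150)
        reads <- chartr("U", "T", rnaSequence(mols))
        idx <- buildJunctionIndex(fx)
        got <- findJunctionReads(reads, idx, genomeSeqs(fx))
        want <- oracle_junction_hits(reads, fx)
        got_key <- sort(paste(got$read, got$gene, got$orientation))
        want_key <- sort(paste(want$read, want$gene, want$orientation))
        expect_identical(got_key, want_key)
    }
})

test_that("antisense splice boundaries cannot mimic donor/acceptor pairs", {
    fx <- small_fixture()
    sv <- spliceAntisenseValidity(fx)
    expect_true(all(sv$introns$canonical))
    expect_false(any(sv$introns$antisense_canonical))
    expect_true(all(sv$genes$rdrp_informative))
    # plant an intron that is canonical on the antisense strand:
    # plus-strand CT..AC reads GT..AG in reverse complement
    mg <- make_mini_gene()
    chrom <- mg$chrom
    substr(chrom, 141, 142) <- "CT"
    substr(chrom, 199, 200) <- "AC"
    genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
    sv2 <- spliceAntisenseValidity(genome, mg$genes)
    expect_false(sv2$introns$canonical)
    expect_true(sv2$introns$antisense_canonical)
    expect_false(sv2$genes$rdrp_informative)
    # intronless gene: no rows, not informative
    ex1 <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(101, 240), strand = "+")
    S4Vectors::mcols(ex1)$exon_rank <- 1L
    sv3 <- spliceAntisenseValidity(genome,
                                   GenomicRanges::GRangesList(solo = ex1))
    expect_equal(nrow(sv3$introns), 0L)
    expect_false(sv3$genes$rdrp_informative)
})

test_that("junction summaries report ppm and sequence homogeneity", {
    empty <- findJunctionReads(character(0),
                               data.frame(gene = character(0),
                                          junction = integer(0),
                                          sequence = character(0),
                                          breakpoint = integer(0)),
                               Biostrings::DNAStringSet(c(chr1 = "ACGT")))
    s0 <- junctionSummary(empty, 1000)
    expect_equal(s0$whole$ppm, c(0, 0))
    expect_equal(nrow(s0$per_gene), 0L)

    fx <- small_fixture()
    idx <- buildJunctionIndex(fx)
    # RdRP-off: no antisense junction-exclusive reads
    off <- simulateReads(fx, simConfig(seed = 31,
                                       class_weights = no_sirna_weights),
                         n = 300)
    h_off <- findJunctionReads(chartr("U", "T", rnaSequence(off)), idx,
                               genomeSeqs(fx))
    s_off <- junctionSummary(h_off, 300)
    expect_equal(s_off$whole$ppm[s_off$whole$orientation == "antisense"], 0)
    # RdRP-on: antisense ppm > 0 with diverse read sequences
    on <- simulateReads(fx, simConfig(seed = 32,
                                      class_weights = c(siRNA_22G = 1),
                                      junction_fraction = 1), n = 100)
    h_on <- findJunctionReads(chartr("U", "T", rnaSequence(on)), idx,
                              genomeSeqs(fx))
    s_on <- junctionSummary(h_on, 100)
    expect_gt(s_on$whole$ppm[s_on$whole$orientation == "antisense"], 0)
    expect_gt(sum(s_on$per_gene$distinct_reads), 1)
    expect_true(all(s_on$top_antisense$orientation == "antisense"))
})
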