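test_that("generation is deterministic and seed-sensitive", {
    f1 <- generateGenome(simConfig(seed = 9))
    f2 <- generateGenome(simConfig(seed = 9))
    expect_identical(as.character(genomeSeqs(f1)),
                     as.character(genomeSeqs(f2)))
    expect_identical(hairpinTable(f1), hairpinTable(f2))
    f3 <- generateGenome(simConfig(seed = 10))
    expect_false(identical(as.character(genomeSeqs(f1)),
                           as.character(genomeSeqs(f3))))
    # byte-identical files on disk
    d1 <- tempfile(); d2 <- tempfile()
    m1 <- simulateReads(f1, n = 50)
    m2 <- simulateReads(f2, n = 50)
    writeFixture(f1, m1, d1)
    writeFixture(f2, m2, d2)
    for (f in c("genome.fa", "genes.gff3", "library_1.fastq"))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
})

test_that("every gene is spliced with canonical GT..AG introns", {
    fx <- generateGenome(simConfig(seed = 1, n_genes = 5L))
    expect_equal(length(geneModels(fx)), 5L)
    expect_true(all(vapply(geneModels(fx), length, integer(1)) >= 2L))
    sv <- spliceAntisenseValidity(fx)
    expect_true(all(sv$introns$canonical))
    # splice consistency against a per-exon oracle
    genomeChar <- as.character(genomeSeqs(fx))
    for (g in names(geneModels(fx))) {
        ex <- geneModels(fx)[[g]]
        pieces <- character(0)
        for (i in seq_along(ex)) {
            p <- substr(genomeChar[[as.character(
                GenomeInfoDb::seqnames(ex))[i]]],
                BiocGenerics::start(ex)[i], BiocGenerics::end(ex)[i])
            if (as.character(BiocGenerics::strand(ex))[i] == "-") p <- rc(p)
            pieces <- c(pieces, p)
        }
        expect_identical(paste(pieces, collapse = ""),
                         as.character(transcriptSeqs(fx)[[g]]))
    }
})

test_that("degenerate mixtures honour class-defining invariants", {
    fx <- small_fixture()
    mir <- simulateReads(fx, simConfig(seed = 2,
                                       class_weights = c(miRNA = 1)),
                         n = 200)
    expect_true(all(fivePrime(mir) == "monoP"))
    expect_true(all(threePrime(mir) == "OH"))
    hp <- hairpinTable(fx)[hairpinTable(fx)$role == "pass", ]
    expect_true(all(vapply(chartr("U", "T", rnaSequence(mir)),
                           function(s) grepl(s, hp$sequence, fixed = TRUE),
                           logical(1))))
    g22 <- simulateReads(fx, simConfig(seed = 2,
                                       class_weights = c(siRNA_22G = 1)),
                         n = 200)
    expect_true(all(nchar(rnaSequence(g22)) == 22L))
    expect_true(all(substr(rnaSequence(g22), 1, 1) == "G"))
    expect_true(all(fivePrime(g22) == "triP"))
})

test_that("class proportions follow the mixture within sampling error", {
    fx <- generateGenome(simConfig(seed = 7))
    n <- 10000L
    mols <- simulateReads(fx, n = n, seed = 7L)
    w <- simConfig()@class_weights
    cnt <- table(factor(trueClass(mols), levels = names(w)))
    for (cl in names(w)) {
        sd3 <- 3 * sqrt(n * w[[cl]] * (1 - w[[cl]]))
        expect_lt(abs(cnt[[cl]] - n * w[[cl]]), sd3 + 1)
    }
})

test_that("piRNA-like molecules carry the configured sequence biases", {
    fx <- small_fixture()
    pir <- simulateReads(fx, simConfig(seed = 5,
                                       class_weights = c(piRNA_like = 1)),
                         n = 1000)
    lens <- nchar(rnaSequence(pir))
    expect_true(all(lens >= 23 & lens <= 30))
    u5 <- mean(substr(rnaSequence(pir), 1, 1) == "U")
    # forced at 0.75 plus ~1/4 natural occurrence among the rest
    expect_gt(u5, 0.70)
    sense <- molecules(pir)$expected_category == "transcriptome_sense"
    mid <- sense & lens >= 23 & lens <= 26
    a10 <- mean(substr(rnaSequence(pir)[mid], 10, 10) == "A")
    expect_gt(a10, 0.45)
})

test_that("contaminants never occur in the genome on either strand", {
    fx <- small_fixture()
    con <- simulateReads(fx, simConfig(seed = 6,
                                       class_weights = c(contaminant = 1)),
                         n = 100)
    genomeChar <- as.character(genomeSeqs(fx))
    for (s in chartr("U", "T", rnaSequence(con))) {
        expect_equal(oracle_occ(s, genomeChar), 0)
        expect_equal(oracle_occ(rc(s), genomeChar), 0)
    }
})

test_that("fixture files round-trip and conserve molecule counts", {
    fx <- small_fixture()
    mols <- simulateReads(fx, n = 120)
    d <- tempfile()
    files <- writeFixture(fx, mols, d)
    expect_error(writeFixture(fx, mols, d), "refusing")
    expect_silent(writeFixture(fx, mols, d, overwrite = TRUE))
    truth <- read.delim(files[["truth"]])
    expect_equal(nrow(truth), 120L)
    # GFF3 + genome reconstruct the emitted transcriptome
    genes2 <- readGff3Genes(files[["genes"]])
    genome2 <- Biostrings::readDNAStringSet(files[["genome"]])
    tx2 <- splicedTranscripts(genome2, genes2)
    tx <- Biostrings::readDNAStringSet(files[["transcriptome"]])
    expect_identical(as.character(tx2)[names(tx)], as.character(tx))
    # per-library FASTQ read counts match the truth table bookkeeping
    for (i in 1:4) {
        fq <- Biostrings::readDNAStringSet(files[[paste0("lib", i)]],
                                           format = "fastq")
        expect_equal(length(fq), sum(truth[[paste0("lib", i)]]))
    }
})

test_that("empty molecule sets yield valid empty outputs", {
    fx <- small_fixture()
    mols <- simulateReads(fx, n = 0)
    expect_equal(length(mols), 0L)
    d <- tempfile()
    files <- writeFixture(fx, mols, d)
    for (i in 1:4) {
        fq <- Biostrings::readDNAStringSet(files[[paste0("lib", i)]],
                                           format = "fastq")
        expect_equal(length(fq), 0L)
    }
})

test_that("invalid configurations are rejected", {
    expect_error(simConfig(intron_length = c(2L, 3L)), "intron")
    expect_error(simConfig(class_weights = c(miRNA = 0.7)), "sum to 1")
    expect_error(simConfig(class_weights = c(foo = 1)), "named")
    fx <- small_fixture()
    empty <- new("GenomeFixture", genome = Biostrings::DNAStringSet(),
                 genes = fx@genes[0], transcripts = fx@transcripts[0],
                 ncRNA = fx@ncRNA, ncRNALoci = fx@ncRNALoci,
                 hairpins = fx@hairpins, intergenic = fx@intergenic,
                 config = fx@config)
    expect_error(simulateReads(empty, n = 10), "empty fixture")
})
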