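make_refs <- function() {
    list(genome = Biostrings::DNAStringSet(c(chr1 = paste0(
             "ACGTACGTGGATCCTTAGGCATCGATCGGGCCTTAAGGTCATGCATGCAT",
             "TTGACCGGTTCAACGGATTCGGAACCTTGGAACGTACGATCGATCCGGAA"))),
         transcripts = Biostrings::DNAStringSet(
             c(t1 = "GGATCCTTAGGCATCGATCGGGCCTTAAGG")),
         hairpins = Biostrings::DNAStringSet(
             c(hp1 = "TTGACCGGTTCAACGGATTCGGAACCTTGG")),
         ncRNA = Biostrings::DNAStringSet(
             c(rna1 = "AACGTACGATCGATCCGGAA")))
}

test_that("mapReads finds sense and antisense hits and nothing else", {
    refs <- make_refs()
    sense_read <- substr(as.character(refs$transcripts[[1]]), 3, 24)
    anti_read <- rc(sense_read)
    set.seed(1)
    random_read <- paste(sample(c("A", "C", "G", "T"), 22, TRUE),
                         collapse = "")
    hits <- mapReads(c(sense_read, anti_read, random_read),
                     refs$transcripts)
    expect_equal(hits$sense, c(TRUE, FALSE, FALSE))
    expect_equal(hits$antisense, c(FALSE, TRUE, FALSE))
    # agreement with the exhaustive scan oracle
    txChar <- as.character(refs$transcripts)
    expect_equal(hits$n_sense[1], oracle_occ(sense_read, txChar))
    expect_equal(oracle_occ(random_read, txChar), 0)
    # one mismatch is found only with a budget
    mm_read <- sense_read
    substr(mm_read, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                     substr(mm_read, 5, 5))[1]
    expect_false(mapReads(mm_read, refs$transcripts, 0)$sense)
    expect_true(mapReads(mm_read, refs$transcripts, 1)$sense)
    # ambiguous bases count as mismatches
    n_read <- sense_read
    substr(n_read, 5, 5) <- "N"
    expect_false(mapReads(n_read, refs$transcripts, 0)$sense)
    expect_true(mapReads(n_read, refs$transcripts, 1)$sense)
})

test_that("classification follows the annotation hierarchy", {
    refs <- make_refs()
    # a read matching both an abundant ncRNA and the genome
    nc_read <- as.character(refs$ncRNA[[1]])
    hp_read <- substr(as.character(refs$hairpins[[1]]), 1, 22)
    tx_read <- substr(as.character(refs$transcripts[[1]]), 1, 22)
    gn_read <- substr(as.character(refs$genome[[1]]), 30, 51)
    set.seed(2)
    ex_read <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
    ann <- classifyReads(c(nc_read, hp_read, tx_read, rc(tx_read),
                           gn_read, ex_read), refs)
    expect_equal(as.character(ann$category),
                 c("abundant_ncRNA", "premiRNA_sense",
                   "transcriptome_sense", "transcriptome_antisense",
                   "genome_other", "extragenomic"))
    expect_equal(ann$orientation,
                 c(NA, "sense", "sense", "antisense", NA, NA))
    # partition: every read gets exactly one category
    expect_false(any(is.na(ann$category)))
    expect_equal(sum(table(ann$category)), 6L)
})

test_that("simulated classes recover their expected categories", {
    fx <- small_fixture()
    mols <- simulateReads(fx, n = 1500)
    ann <- classifyReads(rnaSequence(mols), fx)
    acc <- tapply(as.character(ann$category) ==
                  molecules(mols)$expected_category,
                  trueClass(mols), mean)
    expect_true(all(acc[c("miRNA", "contaminant")] >= 0.99))
    expect_true(all(acc >= 0.99))
})

test_that("ppm normalization uses the genome-matching non-ncRNA total", {
    expect_equal(normalizePpm(1, 10), 1e5)
    expect_error(normalizePpm(5, 0), "denominator")
    refs <- make_refs()
    tx_read <- substr(as.character(refs$transcripts[[1]]), 1, 22)
    gn_read35 <- substr(as.character(refs$genome[[1]]), 10, 44)  # 35 nt
    set.seed(3)
    ex_read <- paste(sample(c("A", "C", "G", "T"), 24, TRUE), collapse = "")
    nc_read <- as.character(refs$ncRNA[[1]])
    ann1 <- classifyReads(rep(tx_read, 4), refs)
    expect_equal(ppmDenominator(ann1), 4L)
    # extragenomic reads change nothing
    ann2 <- classifyReads(c(rep(tx_read, 4), rep(ex_read, 5)), refs)
    expect_equal(ppmDenominator(ann2), 4L)
    sp1 <- sizeSpectrum(ann1, "transcriptome_sense", ppmDenominator(ann1))
    sp2 <- sizeSpectrum(ann2, "transcriptome_sense", ppmDenominator(ann2))
    expect_equal(sp1$ppm, sp2$ppm)
    # an out-of-range genome-matching read enters the denominator
    ann3 <- classifyReads(c(rep(tx_read, 4), gn_read35), refs)
    expect_equal(ppmDenominator(ann3), 5L)
    sp3 <- sizeSpectrum(ann3, "transcriptome_sense", ppmDenominator(ann3))
    expect_true(all(sp3$ppm[sp3$count > 0] < sp1$ppm[sp1$count > 0]))
    # abundant ncRNA reads are excluded from the denominator
    ann4 <- classifyReads(c(rep(tx_read, 4), nc_read), refs)
    expect_equal(ppmDenominator(ann4), 4L)
})

test_that("size spectra conserve category totals", {
    refs <- make_refs()
    tx <- as.character(refs$transcripts[[1]])
    reads <- c(substr(tx, 1, 22), substr(tx, 2, 23), substr(tx, 3, 24),
               substr(tx, 1, 25))
    ann <- classifyReads(reads, refs)
    denom <- ppmDenominator(ann)
    sp <- sizeSpectrum(ann, "transcriptome_sense", denom)
    expect_equal(sp$count[sp$length == 22], 3L)
    expect_equal(sp$count[sp$length == 25], 1L)
    expect_equal(sum(sp$ppm), normalizePpm(4, denom))
})

test_that("logo matrices report positional frequencies", {
    m <- logoMatrix(c("GAAT", "GCCT", "GGGT"), 4)
    expect_equal(unname(m[1, "G"]), 1)
    expect_equal(unname(m[4, "U"]), 1)
    expect_equal(unname(rowSums(m)), rep(1, 4))
    expect_false(attr(m, "empty"))
    e <- logoMatrix(character(0), 22)
    expect_true(attr(e, "empty"))
    expect_true(all(is.na(e)))
})

test_that("bias statistics detect planted 5' composition biases", {
    set.seed(4)
    rand_tail <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                   collapse = "")
    planted <- vapply(1:200, function(i)
        paste0("T", rand_tail(25)), character(1))
    ann <- S4Vectors::DataFrame(sequence = planted, length = 26L,
                                orientation = "sense")
    bs <- biasStats(ann)
    expect_lt(bs$five_U$p, 1e-10)
    expect_gt(bs$five_U$freq, 0.95)
    expect_false(bs$five_U$undefined)
    empty <- biasStats(S4Vectors::DataFrame(sequence = character(0),
                                            length = integer(0),
                                            orientation = character(0)))
    expect_true(empty$tenth_A$undefined)
})

test_that("long-ORF transcript filter applies the three-AUG rule", {
    codons99 <- strrep("GCT", 99)
    keep100 <- paste0("CC", "ATG", codons99, "TAA", "GG")  # 100 codons
    keep_no_stop <- paste0("ATG", strrep("GCA", 120))
    drop99 <- paste0("ATG", strrep("GCT", 98), "TAA")      # 99 codons
    no_atg <- strrep("GCT", 120)
    # first three AUGs all open short ORFs; the long one is 4th
    fourth <- paste0("ATGTAA", "ATGTAA", "ATGTAA", "CCC",
                     "ATG", codons99, "TAA")
    third <- paste0("ATGTAA", "ATGTAA", "CCC", "ATG", codons99, "TAA")
    tx <- c(a = keep100, b = keep_no_stop, c = drop99, d = no_atg,
            e = fourth, f = third)
    kept <- filterLongOrfTranscripts(tx)
    expect_setequal(names(kept), c("a", "b", "f"))
})
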