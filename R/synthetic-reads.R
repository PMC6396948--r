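#' @importFrom Biostrings vcountPattern
NULL

# per-gene transcript coordinate maps (transcription order)
.txMaps <- function(fixture) {
    lapply(names(fixture@genes), function(g) {
        ex <- fixture@genes[[g]]
        exLens <- width(ex)
        cumEnd <- cumsum(exLens)
        cumStart <- cumEnd - exLens + 1L
        list(gene = g,
             chrom = as.character(seqnames(ex))[1],
             strand = as.character(strand(ex))[1],
             gstart = start(ex), gend = end(ex),
             cumStart = cumStart, cumEnd = cumEnd, nEx = length(ex),
             tx = as.character(fixture@transcripts[[g]]))
    })
}

# transcript position(s) -> genomic position(s)
.txToGenome <- function(map, p) {
    j <- findInterval(p, map$cumStart)
    if (map$strand == "+") map$gstart[j] + (p - map$cumStart[j])
    else map$gend[j] - (p - map$cumStart[j])
}

.molRow <- function(sequence, five, three, class, chrom, start, end, strand,
                    junction = FALSE, expected) {
    data.frame(sequence = sequence, five_prime = five, three_prime = three,
               true_class = class, chrom = chrom, start = as.integer(start),
               end = as.integer(end), strand = strand,
               junction_spanning = junction, expected_category = expected,
               stringsAsFactors = FALSE)
}

# miRNA: a mature read from an arm of the passing hairpin, 21-23 nt
# (mostly 22), fixed 5' ends per arm, 5'-monoP / 3'-OH.
.simMiRNA <- function(hp) {
    L <- nchar(hp$sequence)
    arm <- sample(c("5p", "3p"), 1L)
    len <- sample(21:23, 1L, prob = c(0.15, 0.7, 0.15))
    s <- if (arm == "5p") 3L else (L - 30L + 1L) + 2L
    seq <- substr(hp$sequence, s, s + len - 1L)
    .molRow(seq, "monoP", "OH", "miRNA", hp$chrom, hp$start + s - 1L,
            hp$start + s + len - 2L, "+", expected = "premiRNA_sense")
}

# piRNA-like: 23-30 nt from within a single exon (genome-contiguous, as
# for piRNA-cluster precursors), 5'U with configured probability, 10A for
# sense 23-26-mers with configured probability, 5'-monoP.
.simPiRNA <- function(maps, config) {
    len <- sample(23:30, 1L)
    sense <- stats::runif(1) < config@pirna_sense_prob
    forceU <- stats::runif(1) < config@pirna_u5_prob
    forceA <- sense && len <= 26L && stats::runif(1) < config@pirna_a10_prob
    best <- NULL
    for (try in seq_len(400L)) {
        m <- maps[[sample(length(maps), 1L)]]
        ei <- sample(m$nEx, 1L, prob = m$cumEnd - m$cumStart + 1)
        exW <- m$cumEnd[ei] - m$cumStart[ei] + 1L
        if (exW < len) next
        tp <- m$cumStart[ei] + sample(0:(exW - len), 1L)
        senseSeq <- substr(m$tx, tp, tp + len - 1L)
        read <- if (sense) senseSeq else .rc1(senseSeq)
        gp <- .txToGenome(m, c(tp, tp + len - 1L))
        gstrand <- if (sense) m$strand else setdiff(c("+", "-"), m$strand)
        best <- list(read = read, chrom = m$chrom, start = min(gp),
                     end = max(gp), strand = gstrand)
        if (forceU && substr(read, 1L, 1L) != "T") next
        if (forceA && substr(read, 10L, 10L) != "A") next
        break
    }
    .molRow(best$read, "monoP",
            if (config@pirna_methylated) "methyl" else "OH",
            "piRNA_like", best$chrom, best$start, best$end, best$strand,
            expected = if (sense) "transcriptome_sense"
                       else "transcriptome_antisense")
}

# 22G-like RdRP product: 22 nt, 5'G, 5'-triphosphate, antisense to a
# transcript; a configured fraction spans an exon-exon junction with at
# least 3 nt on each side (junction-exclusive: no contiguous genomic
# counterpart).
.simSiRNA <- function(maps, config, genome) {
    junc <- stats::runif(1) < config@junction_fraction
    best <- NULL
    if (junc) {
        for (try in seq_len(500L)) {
            m <- maps[[sample(length(maps), 1L)]]
            if (m$nEx < 2L) next
            j <- sample(m$nEx - 1L, 1L)
            o <- sample(3:19, 1L)
            b <- m$cumEnd[j]
            tp <- b - o + 1L
            if (tp < m$cumStart[j]) next
            senseSeq <- substr(m$tx, tp, tp + 21L)
            # junction-exclusivity: reject windows whose sequence still
            # occurs contiguously in the genome (short overhangs can
            # coincide with intron boundaries)
            if (sum(vcountPattern(senseSeq, genome)) +
                sum(vcountPattern(.rc1(senseSeq), genome)) > 0L) next
            gp <- .txToGenome(m, c(tp, b, b + 1L, tp + 21L))
            best <- list(seq = senseSeq, chrom = m$chrom, start = min(gp),
                         end = max(gp),
                         strand = setdiff(c("+", "-"), m$strand))
            if (substr(senseSeq, 22L, 22L) == "C") break
        }
        junc <- !is.null(best)
    }
    if (is.null(best)) {
        for (try in seq_len(500L)) {
            m <- maps[[sample(length(maps), 1L)]]
            ei <- sample(m$nEx, 1L, prob = m$cumEnd - m$cumStart + 1)
            exW <- m$cumEnd[ei] - m$cumStart[ei] + 1L
            if (exW < 22L) next
            tp <- m$cumStart[ei] + sample(0:(exW - 22L), 1L)
            senseSeq <- substr(m$tx, tp, tp + 21L)
            gp <- .txToGenome(m, c(tp, tp + 21L))
            best <- list(seq = senseSeq, chrom = m$chrom, start = min(gp),
                         end = max(gp),
                         strand = setdiff(c("+", "-"), m$strand))
            if (substr(senseSeq, 22L, 22L) == "C") break
        }
    }
    read <- .rc1(best$seq)
    if (substr(read, 1L, 1L) != "G")  # rare rejection-sampling failure
        read <- paste0("G", substr(read, 2L, 22L))
    .molRow(read, "triP", "OH", "siRNA_22G", best$chrom, best$start,
            best$end, best$strand, junction = junc,
            expected = "transcriptome_antisense")
}

# degradation fragment: 15-35 nt from intergenic sequence, mixed 5' ends
.simDegradation <- function(fixture, genomeChar) {
    ig <- fixture@intergenic
    len <- sample(15:35, 1L)
    ws <- width(ig)
    ok <- which(ws >= len)
    i <- ok[sample(length(ok), 1L, prob = ws[ok])]
    chrom <- as.character(seqnames(ig))[i]
    s <- start(ig)[i] + sample(0:(ws[i] - len), 1L)
    fwd <- substr(genomeChar[[chrom]], s, s + len - 1L)
    strand <- sample(c("+", "-"), 1L)
    .molRow(if (strand == "+") fwd else .rc1(fwd),
            sample(c("OH", "monoP", "triP"), 1L), "OH", "degradation",
            chrom, s, s + len - 1L, strand, expected = "genome_other")
}

# contaminant: random sequence with no exact match in the fixture genome
.simContaminant <- function(fixture) {
    len <- sample(18:30, 1L)
    for (try in seq_len(100L)) {
        s <- .randomDNA(len)
        if (sum(vcountPattern(s, fixture@genome)) == 0L &&
            sum(vcountPattern(.revcomp(s), fixture@genome)) == 0L)
            break
    }
    .molRow(s, sample(c("OH", "monoP", "triP"), 1L), "OH", "contaminant",
            "none", 0L, 0L, "*", expected = "extragenomic")
}

#' Simulate a population of small RNA molecules
#'
#' Draws molecule classes from the configured mixture and generates each
#' molecule from the fixture with its class-defining sequence features and
#' end chemistry: miRNAs (21-23 nt, 5'-monoP/3'-OH) from the passing
#' hairpin's arms, piRNA-like molecules (23-30 nt, 5'U-biased, sense
#' 23-26-mers 10A-biased) from exonic windows, 22G siRNAs (22 nt, 5'G,
#' 5'-triP, antisense; a configured fraction junction-spanning),
#' intergenic degradation fragments (15-35 nt, mixed 5' ends), and
#' extragenomic contaminants.
#'
#' @param fixture a \linkS4class{GenomeFixture}.
#' @param config a \linkS4class{SimConfig}; defaults to the fixture's.
#' @param n number of molecules.
#' @param seed RNG seed (defaults to \code{config@seed + 1}).
#' @return A \linkS4class{SmallRNASet}.
#' @examples
#' fx <- generateGenome(simConfig(seed = 1))
#' mols <- simulateReads(fx, n = 100)
#' @export
simulateReads <- function(fixture, config = fixture@config,
                          n = config@reads_per_library,
                          seed = config@seed + 1L) {
    stopifnot(is(fixture, "GenomeFixture"))
    if (length(fixture@genome) == 0L || sum(width(fixture@genome)) == 0L)
        stop("empty fixture")
    validObject(config)
    old <- .saveRNG(); on.exit(.restoreRNG(old))
    set.seed(seed)

    if (n == 0L) {
        empty <- .molRow(character(0), character(0), character(0),
                         character(0), character(0), integer(0), integer(0),
                         character(0), logical(0), character(0))
        empty$id <- character(0)
        return(SmallRNASet(empty[, c("id", setdiff(names(empty), "id"))]))
    }
    w <- config@class_weights[config@class_weights > 0]
    classes <- sample(names(w), n, replace = TRUE, prob = w)
    maps <- .txMaps(fixture)
    hp <- fixture@hairpins[fixture@hairpins$role == "pass", ][1L, ]
    genomeChar <- as.character(fixture@genome)

    rows <- vector("list", n)
    for (i in seq_len(n)) {
        rows[[i]] <- switch(classes[i],
            miRNA = .simMiRNA(hp),
            piRNA_like = .simPiRNA(maps, config),
            siRNA_22G = .simSiRNA(maps, config, fixture@genome),
            degradation = .simDegradation(fixture, genomeChar),
            contaminant = .simContaminant(fixture))
    }
    df <- do.call(rbind, rows)
    df$id <- sprintf("mol%06d", seq_len(n))

    if (config@mismatch_rate > 0) {
        df$sequence <- vapply(seq_len(n), function(i) {
            s <- strsplit(df$sequence[i], "")[[1]]
            # position 1 is class-defining for 22G RNAs; never mutated
            from <- if (df$true_class[i] == "siRNA_22G") 2L else 1L
            for (p in seq(from, length(s)))
                if (stats::runif(1) < config@mismatch_rate)
                    s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
            paste(s, collapse = "")
        }, character(1))
    }
    df$sequence <- .dna2rna(df$sequence)
    SmallRNASet(df[, c("id", setdiff(names(df), "id"))])
}
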