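#' @importFrom Biostrings vmatchPattern
NULL

#' Build an exon-exon junction reference index
#'
#' For every adjacent exon pair of every gene, extracts the junction
#' sequence: the last \code{Lmax - m} nt of the upstream exon joined to
#' the first \code{Lmax - m} nt of the downstream exon (truncated at exon
#' boundaries for short exons). Every junction sequence is a substring of
#' the spliced transcript; a read crossing the breakpoint with at least
#' \code{m} nt on each side cannot map contiguously to the genome unless
#' the intron is absent there.
#'
#' @param x a \linkS4class{GenomeFixture}, or a named
#'   \link[Biostrings]{DNAStringSet} genome (then supply \code{genes}).
#' @param genes a \link[GenomicRanges]{GRangesList} of exon chains in
#'   transcription order (ignored when \code{x} is a fixture).
#' @param Lmax maximum read length considered (default 30).
#' @param m minimum overhang in nt (default 3).
#' @return data.frame with columns \code{gene}, \code{junction},
#'   \code{sequence}, \code{breakpoint} (number of nt left of the splice
#'   site within \code{sequence}).
#' @export
buildJunctionIndex <- function(x, genes = NULL, Lmax = 30L, m = 3L) {
    stopifnot(Lmax > 2L * m)
    if (is(x, "GenomeFixture")) {
        tx <- x@transcripts
        genes <- x@genes
    } else {
        tx <- splicedTranscripts(x, genes)
    }
    flank <- Lmax - m
    rows <- lapply(names(genes), function(g) {
        exLens <- width(genes[[g]])
        k <- length(exLens)
        if (k < 2L) return(NULL)
        cumEnd <- cumsum(exLens)
        txs <- as.character(tx[[g]])
        do.call(rbind, lapply(seq_len(k - 1L), function(j) {
            left <- min(flank, exLens[j])
            right <- min(flank, exLens[j + 1L])
            b <- cumEnd[j]
            data.frame(gene = g, junction = j,
                       sequence = substr(txs, b - left + 1L, b + right),
                       breakpoint = left, stringsAsFactors = FALSE)
        }))
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(gene = character(0), junction = integer(0),
                          sequence = character(0), breakpoint = integer(0))
    out
}

.mismatchCount <- function(a, b) {
    sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

# occurrences of one read (already oriented) in the junction sequences,
# keeping only breakpoint-crossing placements with >= m nt overhangs
.junctionPlacements <- function(read, index, m, mm) {
    len <- nchar(read)
    hits <- vmatchPattern(read, DNAStringSet(index$sequence),
                          max.mismatch = mm, fixed = TRUE)
    rows <- list()
    for (j in seq_along(hits)) {
        st <- BiocGenerics::start(hits[[j]])
        for (s in st) {
            if (s < 1L || s + len - 1L > nchar(index$sequence[j])) next
            b <- index$breakpoint[j]
            overL <- b - s + 1L
            overR <- s + len - 1L - b
            if (overL < m || overR < m) next
            nmm <- .mismatchCount(read,
                                  substr(index$sequence[j], s, s + len - 1L))
            rows[[length(rows) + 1L]] <- data.frame(
                gene = index$gene[j], junction = index$junction[j],
                overhang_left = overL, overhang_right = overR,
                mismatches = nmm, stringsAsFactors = FALSE)
        }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
}

#' Find junction-exclusive reads
#'
#' Selects the 18-30 nt reads that map across an exon-exon junction
#' (crossing the breakpoint with at least \code{m} nt on each side) while
#' failing to map anywhere on the genome on either strand — the
#' operational signature of RNA templated on a spliced transcript when
#' found in antisense orientation.
#'
#' @param reads character vector of read sequences.
#' @param index junction index from \code{\link{buildJunctionIndex}}.
#' @param genome a \link[Biostrings]{DNAStringSet} of chromosomes.
#' @param m minimum overhang (default 3; must match the index).
#' @param maxMismatches mismatch budget for the junction match (default
#'   0; hits with mismatches > 0 are reported with their count so they
#'   can be flagged separately).
#' @param genomeMaxMismatches mismatch budget for the genome-exclusion
#'   test (default 0).
#' @return data.frame of hits: \code{read}, \code{count} (input
#'   multiplicity of the read), \code{gene}, \code{junction},
#'   \code{orientation}, \code{overhang_left}, \code{overhang_right},
#'   \code{mismatches}, \code{ambiguous} (read hits junctions of more
#'   than one gene).
#' @export
findJunctionReads <- function(reads, index, genome, m = 3L,
                              maxMismatches = 0L,
                              genomeMaxMismatches = 0L) {
    empty <- data.frame(read = character(0), count = integer(0),
                        gene = character(0), junction = integer(0),
                        orientation = character(0),
                        overhang_left = integer(0),
                        overhang_right = integer(0),
                        mismatches = integer(0), ambiguous = logical(0))
    seqs <- toupper(.rna2dna(as.character(reads)))
    seqs <- seqs[nchar(seqs) >= 18L & nchar(seqs) <= 30L]
    if (!length(seqs) || !nrow(index)) return(empty)
    tab <- table(seqs)
    u <- names(tab)

    occ <- .orientOcc(u, genome, genomeMaxMismatches)
    u <- u[occ$sense == 0L & occ$antisense == 0L]
    if (!length(u)) return(empty)

    rows <- list()
    for (r in u) {
        for (ori in c("sense", "antisense")) {
            q <- if (ori == "sense") r else .revcomp(r)
            pl <- .junctionPlacements(q, index, m, maxMismatches)
            if (is.null(pl)) next
            pl <- pl[order(pl$gene, pl$junction, pl$mismatches), ]
            # one record per (read, gene): best placement, flagged
            # ambiguous when several genes' junctions are hit
            best <- pl[!duplicated(pl$gene), , drop = FALSE]
            best$read <- r
            best$count <- as.integer(tab[[r]])
            best$orientation <- ori
            rows[[length(rows) + 1L]] <- best
        }
    }
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    nGenes <- tapply(out$gene, out$read, function(g) length(unique(g)))
    out$ambiguous <- as.vector(nGenes[out$read] > 1L)
    rownames(out) <- NULL
    out[, names(empty)]
}

#' Check that antisense junction reads cannot arise from splicing
#'
#' For each intron, verifies that its boundaries are a canonical GT..AG
#' donor/acceptor pair in the transcription orientation and that the
#' antisense strand of the intron does not itself form a canonical pair
#' (the antisense of GT..AG reads CT..AC, so no antisense spliceform can
#' produce antisense junction-spanning reads). Genes carrying
#' non-canonical or antisense-spliceable introns are flagged as
#' uninformative for RdRP inference.
#'
#' @param x a \linkS4class{GenomeFixture}, or a genome
#'   \link[Biostrings]{DNAStringSet} (then supply \code{genes}).
#' @param genes exon chains in transcription order.
#' @return list with \code{introns} (per-intron table: donor, acceptor,
#'   canonical, antisense_canonical, valid) and \code{genes} (per-gene:
#'   n_introns, all_canonical, rdrp_informative).
#' @export
spliceAntisenseValidity <- function(x, genes = NULL) {
    if (is(x, "GenomeFixture")) {
        genome <- x@genome
        genes <- x@genes
    } else genome <- x
    rows <- lapply(names(genes), function(g) {
        ex <- genes[[g]]
        k <- length(ex)
        if (k < 2L) return(NULL)
        chrom <- as.character(genome[[as.character(seqnames(ex))[1L]]])
        str <- as.character(strand(ex))[1L]
        do.call(rbind, lapply(seq_len(k - 1L), function(j) {
            if (str == "+") {
                iseq <- substr(chrom, end(ex)[j] + 1L, start(ex)[j + 1L] - 1L)
            } else {
                iseq <- .revcomp(substr(chrom, end(ex)[j + 1L] + 1L,
                                        start(ex)[j] - 1L))
            }
            n <- nchar(iseq)
            donor <- substr(iseq, 1L, 2L)
            acceptor <- substr(iseq, n - 1L, n)
            anti <- .revcomp(iseq)
            data.frame(gene = g, intron = j, donor = donor,
                       acceptor = acceptor,
                       canonical = donor == "GT" && acceptor == "AG",
                       antisense_canonical =
                           substr(anti, 1L, 2L) == "GT" &&
                           substr(anti, n - 1L, n) == "AG",
                       stringsAsFactors = FALSE)
        }))
    })
    introns <- do.call(rbind, rows)
    if (is.null(introns))
        introns <- data.frame(gene = character(0), intron = integer(0),
                              donor = character(0), acceptor = character(0),
                              canonical = logical(0),
                              antisense_canonical = logical(0))
    introns$valid <- introns$canonical & !introns$antisense_canonical
    geneTab <- do.call(rbind, lapply(names(genes), function(g) {
        sub <- introns[introns$gene == g, , drop = FALSE]
        data.frame(gene = g, n_introns = nrow(sub),
                   all_canonical = all(sub$canonical),
                   rdrp_informative = nrow(sub) > 0L && all(sub$valid))
    }))
    list(introns = introns, genes = geneTab)
}

#' Summarize junction hits per gene and transcriptome-wide
#'
#' Produces the per-orientation read totals (ppm) for the whole
#' transcriptome, the top genes by sense and by antisense junction read
#' coverage, and per gene the number of distinct read sequences — the
#' sequence-homogeneity statistic (genuine RdRP products are diverse;
#' artifacts share identical 5'/3' ends).
#'
#' @param hits output of \code{\link{findJunctionReads}}.
#' @param denominator ppm denominator (see \code{\link{ppmDenominator}}).
#' @param topN how many genes to list per orientation (default 10).
#' @return list with \code{whole} (orientation, reads, ppm),
#'   \code{per_gene}, \code{top_sense}, \code{top_antisense}.
#' @export
junctionSummary <- function(hits, denominator, topN = 10L) {
    oris <- c("sense", "antisense")
    whole <- data.frame(
        orientation = oris,
        reads = vapply(oris, function(o)
            sum(hits$count[hits$orientation == o]), numeric(1)))
    whole$ppm <- normalizePpm(whole$reads, denominator)
    if (!nrow(hits)) {
        pg <- data.frame(gene = character(0), orientation = character(0),
                         reads = numeric(0), ppm = numeric(0),
                         distinct_reads = integer(0),
                         mismatch_hits = numeric(0))
        return(list(whole = whole, per_gene = pg,
                    top_sense = pg, top_antisense = pg))
    }
    key <- interaction(hits$gene, hits$orientation, drop = TRUE)
    pg <- do.call(rbind, lapply(split(hits, key), function(h)
        data.frame(gene = h$gene[1L], orientation = h$orientation[1L],
                   reads = sum(h$count),
                   ppm = normalizePpm(sum(h$count), denominator),
                   distinct_reads = length(unique(h$read)),
                   mismatch_hits = sum(h$count[h$mismatches > 0L]))))
    rownames(pg) <- NULL
    top <- function(o) {
        sub <- pg[pg$orientation == o, , drop = FALSE]
        utils::head(sub[order(-sub$reads), , drop = FALSE], topN)
    }
    list(whole = whole, per_gene = pg,
         top_sense = top("sense"), top_antisense = top("antisense"))
}
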