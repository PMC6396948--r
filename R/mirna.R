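#' @importFrom Biostrings matchPattern
NULL

#' Parse a dot-bracket secondary structure
#'
#' @param structure dot-bracket string (characters \code{().}).
#' @return list with \code{unbranched} (TRUE when all pairing arcs are
#'   nested around a single apical loop, i.e. every opening bracket
#'   precedes every closing one), \code{stem_bp} (total base pairs) and
#'   \code{loop_span} (unpaired nt in the apical loop; NA for branched
#'   structures).
#' @examples
#' parseHairpin("((((....))))")
#' @export
parseHairpin <- function(structure) {
    stopifnot(is.character(structure), length(structure) == 1L)
    if (grepl("[^().]", structure))
        stop("structure may only contain '(', ')' and '.'")
    ch <- strsplit(structure, "")[[1L]]
    depth <- cumsum((ch == "(") - (ch == ")"))
    if (any(depth < 0L) || depth[length(depth)] != 0L)
        stop("unbalanced dot-bracket string")
    opens <- which(ch == "(")
    closes <- which(ch == ")")
    unbranched <- length(opens) == 0L ||
        max(opens) < min(closes)  # no '(' after any ')': single loop
    loop <- if (unbranched && length(opens))
        min(closes) - max(opens) - 1L else NA_integer_
    list(unbranched = unbranched, stem_bp = length(opens),
         loop_span = loop)
}

#' Pre-miRNA locus filter
#'
#' A candidate locus passes when its structure is an unbranched hairpin
#' with at least 25 base pairs in the stem, the predicted folding energy
#' is at most -15 kcal/mol, 21-23-mers form a strict majority of its
#' 18-30 nt reads, and read coverage reaches at least 20 ppm on some
#' nucleotide. All thresholds are inclusive exactly as stated.
#'
#' @param structure dot-bracket string.
#' @param dG folding energy, kcal/mol.
#' @param read_lengths integer vector, one entry per locus read (weighted
#'   input can be expanded by the caller).
#' @param max_coverage_ppm maximum per-nucleotide read coverage in ppm.
#' @param min_stem,max_dG,min_coverage,size_range,size_majority
#'   thresholds (defaults 25 bp, -15 kcal/mol, 20 ppm, 21-23 nt, > 0.5).
#' @return list with \code{pass} and \code{reasons} (character vector
#'   among \code{"branched"}, \code{"stem"}, \code{"energy"},
#'   \code{"size"}, \code{"coverage"}, \code{"no_data"}).
#' @export
locusFilter <- function(structure, dG, read_lengths, max_coverage_ppm,
                        min_stem = 25L, max_dG = -15,
                        min_coverage = 20, size_range = c(21L, 23L),
                        size_majority = 0.5) {
    hp <- parseHairpin(structure)
    reasons <- character(0)
    if (!hp$unbranched) reasons <- c(reasons, "branched")
    if (hp$stem_bp < min_stem) reasons <- c(reasons, "stem")
    if (dG > max_dG) reasons <- c(reasons, "energy")
    lens <- read_lengths[read_lengths >= 18L & read_lengths <= 30L]
    if (length(lens) == 0L || is.na(max_coverage_ppm)) {
        reasons <- c(reasons, "no_data")
    } else {
        frac <- mean(lens >= size_range[1L] & lens <= size_range[2L])
        if (frac <= size_majority) reasons <- c(reasons, "size")
        if (max_coverage_ppm < min_coverage)
            reasons <- c(reasons, "coverage")
    }
    list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Ortholog similarity gate
#'
#' @param evalue Blast E-value(s), >= 0.
#' @param cutoff inclusive threshold (default 1e-6).
#' @return logical vector: E <= cutoff.
#' @export
orthologGate <- function(evalue, cutoff = 1e-6) {
    stopifnot(all(evalue >= 0))
    evalue <= cutoff
}

# place reads on a locus sequence (exact match, first occurrence);
# unplaced reads carry NA
.placeReads <- function(seqs, locusSeq) {
    vapply(seqs, function(s) {
        h <- matchPattern(s, locusSeq)
        if (length(h)) BiocGenerics::start(h)[1L] else NA_integer_
    }, integer(1), USE.NAMES = FALSE)
}

#' Per-nucleotide read coverage of a hairpin locus
#'
#' @param seqs read sequences (DNA or RNA).
#' @param counts read multiplicities (recycled).
#' @param locusSeq the locus sequence (DNA).
#' @return list with \code{coverage} (counts per nucleotide),
#'   \code{placed} (data.frame sequence, start, length, count for reads
#'   matching the locus in sense orientation).
#' @export
hairpinCoverage <- function(seqs, counts = 1L, locusSeq) {
    seqs <- toupper(.rna2dna(as.character(seqs)))
    counts <- rep_len(as.numeric(counts), length(seqs))
    L <- nchar(locusSeq)
    cov <- numeric(L)
    # collapse to unique sequences, prefilter with the fast dictionary
    # matcher, and place only the sequences that occur in the locus
    agg <- tapply(counts, seqs, sum)
    u <- names(agg)
    u <- u[nchar(u) <= L]
    hit <- u[.countOcc(u, DNAStringSet(locusSeq)) > 0L]
    start <- .placeReads(hit, locusSeq)
    cnt <- as.numeric(agg[hit])
    for (i in seq_along(hit)) {
        idx <- start[i]:(start[i] + nchar(hit[i]) - 1L)
        cov[idx] <- cov[idx] + cnt[i]
    }
    list(coverage = cov,
         placed = data.frame(sequence = hit, start = start,
                             length = nchar(hit), count = cnt,
                             stringsAsFactors = FALSE)[order(-cnt), ])
}

#' Apply the locus filter to every hairpin of a fixture
#'
#' @param hairpins hairpin table (as in \code{\link{hairpinTable}} or the
#'   fixture TSV; needs \code{locus_id}, \code{sequence},
#'   \code{structure}, and \code{dG} or \code{dG_kcal_per_mol}).
#' @param reads read sequences (e.g. library #1 reads).
#' @param denominator ppm denominator of the read set.
#' @param ... thresholds passed to \code{\link{locusFilter}}.
#' @return data.frame: locus_id, pass, reasons (comma-separated),
#'   max_coverage_ppm, n_reads.
#' @export
filterHairpins <- function(hairpins, reads, denominator, ...) {
    dG <- if ("dG" %in% names(hairpins)) hairpins$dG
          else hairpins$dG_kcal_per_mol
    rows <- lapply(seq_len(nrow(hairpins)), function(i) {
        hc <- hairpinCoverage(reads, 1L, hairpins$sequence[i])
        maxPpm <- if (nrow(hc$placed))
            normalizePpm(max(hc$coverage), denominator) else NA_real_
        res <- locusFilter(hairpins$structure[i], dG[i],
                           rep(hc$placed$length, hc$placed$count),
                           maxPpm, ...)
        data.frame(locus_id = hairpins$locus_id[i], pass = res$pass,
                   reasons = paste(res$reasons, collapse = ","),
                   max_coverage_ppm = maxPpm,
                   n_reads = sum(hc$placed$count),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Call mature miRNAs from a hairpin's reads
#'
#' Reads sharing a 5' end are grouped when their 3' ends are trimmed
#' versions (up to 3 nt) of the group's major form or genome-templated
#' extensions of it; non-templated 3' extensions form separate groups.
#' The modal (most abundant) member is the major form, counts are pooled
#' over the group, and an arm call is flagged low-abundance unless it
#' reaches 10 ppm in at least one stage.
#'
#' @param hairpin list or one-row data.frame with \code{sequence} and
#'   \code{structure}.
#' @param reads data.frame with \code{sequence} and optional
#'   \code{count} (default 1) and \code{stage} (default "s1").
#' @param denominators named vector of ppm denominators per stage; when
#'   NULL, raw counts are reported and the abundance flag is skipped.
#' @param flank3 genomic sequence 3' of the hairpin (used to recognise
#'   templated extensions running off the locus).
#' @param min_ppm abundance floor (default 10 ppm in >= 1 stage).
#' @return list with one element per arm ("5p", "3p"); each is a list
#'   with \code{major}, \code{ppm} (per stage), \code{count},
#'   \code{low_abundance}. Arms without reads are absent.
#' @export
callMature <- function(hairpin, reads, denominators = NULL, flank3 = "",
                       min_ppm = 10) {
    hpSeq <- toupper(.rna2dna(as.character(hairpin$sequence)))
    st <- parseHairpin(as.character(hairpin$structure))
    if (!st$unbranched)
        stop("callMature expects an unbranched hairpin")
    ch <- strsplit(as.character(hairpin$structure), "")[[1L]]
    loopStart <- max(which(ch == "(")) + 1L
    loopEnd <- min(which(ch == ")")) - 1L
    loopMid <- (loopStart + loopEnd) / 2

    if (!nrow(reads)) return(list())
    reads$sequence <- toupper(.rna2dna(reads$sequence))
    if (is.null(reads$count)) reads$count <- 1L
    if (is.null(reads$stage)) reads$stage <- "s1"
    ext <- paste0(hpSeq, toupper(.rna2dna(flank3)))

    # aggregate identical (sequence, stage)
    agg <- stats::aggregate(count ~ sequence + stage, reads, sum)
    useq <- unique(agg$sequence)
    start <- .placeReads(useq, ext)
    templated <- !is.na(start)
    # non-templated reads: place by their longest matching prefix
    for (i in which(!templated)) {
        s <- useq[i]
        for (cut in seq_len(nchar(s) - 10L)) {
            h <- matchPattern(substr(s, 1L, nchar(s) - cut), ext)
            if (length(h)) { start[i] <- BiocGenerics::start(h)[1L]; break }
        }
    }
    placed <- !is.na(start)
    useq <- useq[placed]; start <- start[placed]
    templated <- templated[placed]
    if (!length(useq)) return(list())
    totals <- vapply(useq, function(s)
        sum(agg$count[agg$sequence == s]), numeric(1))

    # group within each 5' end
    group <- rep(NA_integer_, length(useq))
    gid <- 0L
    for (p in unique(start)) {
        idx <- which(start == p)
        tIdx <- idx[templated[idx]]
        while (length(tIdx)) {
            gid <- gid + 1L
            major <- tIdx[which.max(totals[tIdx])]
            members <- tIdx[nchar(useq[tIdx]) >= nchar(useq[major]) - 3L]
            group[members] <- gid
            tIdx <- setdiff(tIdx, members)
        }
        for (i in idx[!templated[idx]]) { gid <- gid + 1L; group[i] <- gid }
    }

    stages <- unique(agg$stage)
    calls <- list()
    for (g in unique(group)) {
        gi <- which(group == g)
        major <- gi[which.max(totals[gi])]
        arm <- if ((start[major] + nchar(useq[major]) / 2) <= loopMid)
            "5p" else "3p"
        stageCnt <- vapply(stages, function(sg)
            sum(agg$count[agg$sequence %in% useq[gi] & agg$stage == sg]),
            numeric(1))
        calls[[length(calls) + 1L]] <- list(
            arm = arm, major = .dna2rna(useq[major]),
            count = sum(totals[gi]), stageCounts = stageCnt)
    }
    out <- list()
    for (arm in c("5p", "3p")) {
        armCalls <- Filter(function(cc) cc$arm == arm, calls)
        if (!length(armCalls)) next
        best <- armCalls[[which.max(vapply(armCalls, `[[`, numeric(1),
                                           "count"))]]
        ppm <- if (!is.null(denominators))
            best$stageCounts * 1e6 / denominators[stages] else NULL
        out[[arm]] <- list(
            major = best$major, count = best$count, ppm = ppm,
            low_abundance = if (is.null(ppm)) NA else all(ppm < min_ppm))
    }
    out
}
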