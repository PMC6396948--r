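#' @importFrom Biostrings letterFrequency
#' @importFrom stats binom.test
NULL

# Exact occurrence counts per query across the forward strands of a
# reference set, computed one query length at a time: every reference
# substring of that length is extracted and matched against the queries
# (hash join), so memory stays bounded by one length's substring pool.
# Queries with ambiguous bases never match a pool of A/C/G/T substrings,
# i.e. ambiguity counts as a mismatch.
.countOccExact <- function(seqs, refChar) {
    out <- integer(length(seqs))
    if (!length(seqs) || !length(refChar)) return(out)
    for (L in unique(nchar(seqs))) {
        idx <- which(nchar(seqs) == L)
        pool <- unlist(lapply(refChar, function(s) {
            n <- nchar(s)
            if (n >= L) substring(s, 1:(n - L + 1L), L:n) else character(0)
        }), use.names = FALSE)
        u <- unique(seqs[idx])
        tab <- tabulate(match(pool, u), nbins = length(u))
        out[idx] <- tab[match(seqs[idx], u)]
    }
    out
}

# Occurrence counts of each sequence across a reference set (forward
# strand of the references only); the bounded-mismatch path scans per
# read with fixed = TRUE so ambiguous bases count as mismatches.
.countOcc <- function(seqs, refs, mm = 0L) {
    n <- length(seqs)
    out <- integer(n)
    if (n == 0L || length(refs) == 0L) return(out)
    if (mm == 0L) return(.countOccExact(seqs, as.character(refs)))
    for (i in seq_len(n))
        out[i] <- sum(vcountPattern(seqs[i], refs, max.mismatch = mm,
                                    fixed = TRUE))
    out
}

# sense/antisense occurrence counts for unique sequences (one shared
# substring pool per length in the exact case)
.orientOcc <- function(seqs, refs, mm = 0L) {
    if (mm == 0L) {
        n <- length(seqs)
        cnt <- .countOccExact(c(seqs, .revcomp(seqs)), as.character(refs))
        list(sense = cnt[seq_len(n)], antisense = cnt[n + seq_len(n)])
    } else {
        list(sense = .countOcc(seqs, refs, mm),
             antisense = .countOcc(.revcomp(seqs), refs, mm))
    }
}

#' Map reads against a reference set on both strands
#'
#' A read "matches" a reference when it occurs at least once within the
#' mismatch budget; antisense means its reverse complement occurs.
#'
#' @param reads character vector of read sequences (DNA or RNA; upper
#'   case). Ambiguous bases count as mismatches.
#' @param refs a \link[Biostrings]{DNAStringSet} of references.
#' @param maxMismatches 0 (default) or 1.
#' @return A \link[S4Vectors]{DataFrame} with per-read occurrence counts
#'   \code{n_sense}, \code{n_antisense} and logicals \code{sense},
#'   \code{antisense}.
#' @export
mapReads <- function(reads, refs, maxMismatches = 0L) {
    stopifnot(maxMismatches %in% 0:1)
    seqs <- toupper(.rna2dna(as.character(reads)))
    u <- unique(seqs)
    occ <- .orientOcc(u, refs, maxMismatches)
    i <- match(seqs, u)
    DataFrame(sequence = seqs,
              n_sense = occ$sense[i], n_antisense = occ$antisense[i],
              sense = occ$sense[i] > 0L, antisense = occ$antisense[i] > 0L)
}

.asReferences <- function(x) {
    if (is(x, "GenomeFixture")) {
        hp <- DNAStringSet(x@hairpins$sequence)
        names(hp) <- x@hairpins$locus_id
        list(genome = x@genome, transcripts = x@transcripts,
             hairpins = hp, ncRNA = x@ncRNA)
    } else {
        stopifnot(is.list(x),
                  all(c("genome", "transcripts", "hairpins", "ncRNA") %in%
                      names(x)))
        x
    }
}

#' Hierarchically classify small RNA reads
#'
#' Assigns each read the highest-priority matching category: abundant
#' ncRNA (either orientation), then pre-miRNA hairpin (sense before
#' antisense), then transcriptome (sense before antisense), then any
#' other genome match, and finally extragenomic for reads matching
#' nothing. Reads are collapsed to unique sequences before matching.
#'
#' @param reads character vector of read sequences (any length; reads
#'   outside 18-30 nt are classified too, as the ppm denominator needs
#'   them).
#' @param references a \linkS4class{GenomeFixture} or a list with
#'   elements \code{genome}, \code{transcripts}, \code{hairpins},
#'   \code{ncRNA} (DNAStringSets).
#' @param maxMismatches 0 (default) or 1.
#' @return A \link[S4Vectors]{DataFrame} with columns \code{sequence}
#'   (DNA), \code{length}, \code{category}, \code{orientation}
#'   (\code{"sense"}/\code{"antisense"}/\code{NA}), \code{genome_match}
#'   and \code{ncrna_match}.
#' @export
classifyReads <- function(reads, references, maxMismatches = 0L) {
    refs <- .asReferences(references)
    seqs <- toupper(.rna2dna(as.character(reads)))
    u <- unique(seqs)

    nc <- .orientOcc(u, refs$ncRNA, maxMismatches)
    hp <- .orientOcc(u, refs$hairpins, maxMismatches)
    tx <- .orientOcc(u, refs$transcripts, maxMismatches)
    gn <- .orientOcc(u, refs$genome, maxMismatches)

    ncHit <- nc$sense > 0L | nc$antisense > 0L
    gnHit <- gn$sense > 0L | gn$antisense > 0L
    cat <- rep("extragenomic", length(u))
    ori <- rep(NA_character_, length(u))
    set <- function(idx, category, orientation = NA_character_) {
        fresh <- idx & cat == "extragenomic"
        cat[fresh] <<- category
        ori[fresh] <<- orientation
    }
    set(ncHit, "abundant_ncRNA")
    set(hp$sense > 0L, "premiRNA_sense", "sense")
    set(hp$antisense > 0L, "premiRNA_antisense", "antisense")
    set(tx$sense > 0L, "transcriptome_sense", "sense")
    set(tx$antisense > 0L, "transcriptome_antisense", "antisense")
    set(gnHit, "genome_other")

    i <- match(seqs, u)
    DataFrame(sequence = seqs, length = nchar(seqs),
              category = factor(cat, levels = .READ_CATEGORIES)[i],
              orientation = ori[i],
              genome_match = gnHit[i], ncrna_match = ncHit[i])
}

#' ppm normalization denominator
#'
#' The number of genome-matching reads that do not match abundant
#' non-coding RNAs, counting reads of every length (including those
#' shorter than 18 or longer than 30 nt). Extragenomic reads never enter
#' the denominator.
#'
#' @param annotated output of \code{\link{classifyReads}}.
#' @return integer count.
#' @export
ppmDenominator <- function(annotated) {
    sum(annotated$genome_match & !annotated$ncrna_match)
}

#' Convert raw counts to parts per million
#'
#' @param counts numeric vector of raw read counts.
#' @param denominator the \code{\link{ppmDenominator}} of the library.
#' @return counts * 1e6 / denominator.
#' @export
normalizePpm <- function(counts, denominator) {
    if (length(denominator) != 1L || is.na(denominator) || denominator <= 0)
        stop("ppm denominator must be a single positive count")
    counts * 1e6 / denominator
}

#' Size spectrum of an annotation category
#'
#' @param annotated output of \code{\link{classifyReads}}.
#' @param categories character vector of categories to include.
#' @param denominator ppm denominator.
#' @param lengths read lengths to tabulate (default 18:30).
#' @return data.frame with columns \code{length}, \code{count},
#'   \code{ppm}.
#' @export
sizeSpectrum <- function(annotated, categories, denominator,
                         lengths = 18:30) {
    sel <- annotated$category %in% categories &
        annotated$length %in% lengths
    cnt <- table(factor(annotated$length[sel], levels = lengths))
    data.frame(length = lengths, count = as.integer(cnt),
               ppm = normalizePpm(as.integer(cnt), denominator))
}

#' Positional nucleotide frequency matrix (sequence logo)
#'
#' @param seqs character vector of read sequences.
#' @param sizeClass read length to analyse.
#' @return numeric matrix positions x c("A","C","G","U") of relative
#'   frequencies (rows sum to 1); attribute \code{empty} is TRUE and all
#'   cells NA when no read has that length.
#' @export
logoMatrix <- function(seqs, sizeClass) {
    seqs <- toupper(.rna2dna(as.character(seqs)))
    seqs <- seqs[nchar(seqs) == sizeClass]
    nts <- c("A", "C", "G", "T")
    m <- matrix(NA_real_, nrow = sizeClass, ncol = 4,
                dimnames = list(seq_len(sizeClass), c("A", "C", "G", "U")))
    if (length(seqs)) {
        chars <- do.call(rbind, strsplit(seqs, ""))
        for (p in seq_len(sizeClass)) {
            cnt <- table(factor(chars[, p], levels = nts))
            m[p, ] <- as.numeric(cnt) / sum(cnt)
        }
    }
    attr(m, "empty") <- length(seqs) == 0L
    m
}

#' Base composition of a reference set
#'
#' @param refs a \link[Biostrings]{DNAStringSet}.
#' @return named frequencies over c("A","C","G","U").
#' @export
baseComposition <- function(refs) {
    cnt <- colSums(letterFrequency(refs, c("A", "C", "G", "T")))
    freq <- cnt / sum(cnt)
    names(freq) <- c("A", "C", "G", "U")
    freq
}

.enrichP <- function(k, n, p0) {
    if (n == 0L) return(NA_real_)
    binom.test(k, n, p = p0, alternative = "greater")$p.value
}

#' Positional sequence-bias statistics
#'
#' Computes the 5' nucleotide frequencies per size class, the frequency
#' of adenosine at position 10 among sense-oriented 23-26-mers (the
#' ping-pong signature position), and the frequency of a 5' uridine among
#' 23-30-mers, each with a one-sided binomial enrichment p-value against
#' a reference base composition.
#'
#' @param annotated output of \code{\link{classifyReads}} (or any
#'   DataFrame with \code{sequence}, \code{length}, \code{orientation}).
#' @param background named base frequencies (A/C/G/U), e.g. from
#'   \code{\link{baseComposition}}; default uniform.
#' @return list with elements \code{first_nt} (data.frame size x
#'   nucleotide: count, freq, p), \code{tenth_A} and \code{five_U}
#'   (lists: n, count, freq, p; freq is NA with \code{undefined = TRUE}
#'   when no read qualifies).
#' @export
biasStats <- function(annotated,
                      background = c(A = .25, C = .25, G = .25, U = .25)) {
    seqs <- as.character(annotated$sequence)
    len <- annotated$length
    first <- substr(seqs, 1L, 1L)
    sizes <- sort(unique(len[len >= 18 & len <= 30]))
    firstNt <- do.call(rbind, lapply(sizes, function(s) {
        f <- first[len == s]
        n <- length(f)
        do.call(rbind, lapply(c("A", "C", "G", "T"), function(nt) {
            k <- sum(f == nt)
            rna <- chartr("T", "U", nt)
            data.frame(size = s, nt = rna, n = n, count = k, freq = k / n,
                       p = .enrichP(k, n, background[[rna]]))
        }))
    }))
    stat <- function(sel, pos, nt, bg) {
        n <- sum(sel)
        k <- if (n) sum(substr(seqs[sel], pos, pos) == nt) else 0L
        list(n = n, count = k, freq = if (n) k / n else NA_real_,
             p = .enrichP(k, n, bg), undefined = n == 0L)
    }
    sense <- !is.na(annotated$orientation) & annotated$orientation == "sense"
    list(first_nt = firstNt,
         tenth_A = stat(sense & len >= 23 & len <= 26 & len >= 10, 10L, "A",
                        background[["A"]]),
         five_U = stat(len >= 23 & len <= 30, 1L, "T", background[["U"]]))
}

# codons from position pos to the first in-frame stop (stop excluded);
# the initiator codon counts. Runs to the sequence end if no stop.
.orfCodons <- function(s, pos) {
    sub <- substr(s, pos, nchar(s))
    n <- nchar(sub) %/% 3L
    if (n == 0L) return(0L)
    starts <- 3L * (seq_len(n) - 1L) + 1L
    cods <- substring(sub, starts, starts + 2L)
    stopAt <- which(cods %in% c("TAA", "TAG", "TGA"))
    if (length(stopAt)) stopAt[1L] - 1L else n
}

#' Keep transcripts with a long 5'-proximal open reading frame
#'
#' A transcript is kept when any of its three 5'-most AUG codons opens an
#' ORF of at least \code{minCodons} codons (the initiator AUG counts, the
#' stop codon does not; the ORF may run off the transcript end).
#'
#' @param transcripts named character vector or
#'   \link[Biostrings]{DNAStringSet}.
#' @param minCodons minimum ORF length in codons (default 100).
#' @param nStarts how many 5'-most AUGs to try (default 3).
#' @return the kept subset, same type as the input.
#' @export
filterLongOrfTranscripts <- function(transcripts, minCodons = 100L,
                                     nStarts = 3L) {
    seqs <- toupper(.rna2dna(as.character(transcripts)))
    keep <- vapply(seqs, function(s) {
        atg <- gregexpr("ATG", s, fixed = TRUE)[[1L]]
        if (atg[1L] == -1L) return(FALSE)
        any(vapply(utils::head(atg, nStarts), function(p)
            .orfCodons(s, p) >= minCodons, logical(1)))
    }, logical(1), USE.NAMES = FALSE)
    transcripts[keep]
}
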