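#' @importFrom stats p.adjust
NULL

.insufficient <- function(kind) {
    list(verdict = "insufficient data", kind = kind,
         narrowness = NA_real_, modal_length = NA_integer_,
         first_nt = NA_character_, fold = NA_real_, p_value = NA_real_,
         antisense_ppm = NA_real_, mass_23_30 = NA_real_,
         u5_freq = NA_real_, a10_freq = NA_real_)
}

#' Secondary-siRNA signature detector
#'
#' Calls a population an siRNA candidate when it shows (i) a narrow size
#' distribution — at least half of its 18-30 nt reads within 1 nt of the
#' modal length, (ii) significant 5'-purine initiation bias — binomial
#' enrichment of A or G at position 1 against the reference base
#' composition at p < 0.01 (RdRPs initiate on purines; the known
#' metazoan RdRP products are 22G and 26G RNAs), and (iii) antisense
#' abundance of at least 1 ppm. All three sub-scores are always
#' reported.
#'
#' @param reads data.frame with \code{sequence} (DNA or RNA) and
#'   \code{length}; typically the antisense transcriptome-matching reads
#'   of one library.
#' @param antisense_ppm abundance of the population in ppm.
#' @param background named base frequencies (A/C/G/U) of the reference
#'   transcriptome (controls for genomic composition).
#' @param min_reads minimum population size (default 50; below it the
#'   verdict is "insufficient data").
#' @param narrowness_min,p_max,ppm_min thresholds (defaults 0.5, 0.01,
#'   1 ppm).
#' @return list: verdict ("siRNA_candidate" or "none" or "insufficient
#'   data"), narrowness, modal_length, first_nt, fold, p_value,
#'   antisense_ppm.
#' @export
sirnaDetector <- function(reads, antisense_ppm,
                          background = c(A = .25, C = .25, G = .25,
                                         U = .25),
                          min_reads = 50L, narrowness_min = 0.5,
                          p_max = 0.01, ppm_min = 1) {
    if (nrow(reads) < min_reads) return(.insufficient("siRNA"))
    seqs <- toupper(.rna2dna(reads$sequence))
    len <- reads$length
    sel <- len >= 18L & len <= 30L
    lens <- len[sel]
    modal <- as.integer(names(which.max(table(lens))))
    narrowness <- mean(abs(lens - modal) <= 1L)
    first <- substr(seqs[sel], 1L, 1L)
    n <- length(first)
    pv <- c(A = .enrichP(sum(first == "A"), n, background[["A"]]),
            G = .enrichP(sum(first == "G"), n, background[["G"]]))
    nt <- names(which.min(pv))
    freq <- mean(first == chartr("U", "T", nt))
    res <- list(verdict = "none", kind = "siRNA",
                narrowness = narrowness, modal_length = modal,
                first_nt = nt, fold = freq / background[[nt]],
                p_value = unname(pv[nt]), antisense_ppm = antisense_ppm)
    if (narrowness >= narrowness_min && res$p_value < p_max &&
        antisense_ppm >= ppm_min)
        res$verdict <- "siRNA_candidate"
    res
}

#' piRNA signature detector
#'
#' Calls a population piRNA-like when 23-30-mers hold at least half of
#' its 18-30 nt read mass and either the 5' uridine frequency among
#' 23-30-mers reaches 0.5 or the position-10 adenosine frequency among
#' sense 23-26-mers reaches 0.3 (the ping-pong by-product).
#'
#' @param reads data.frame with \code{sequence}, \code{length} and
#'   \code{orientation} ("sense"/"antisense"/NA).
#' @param min_reads,mass_min,u5_min,a10_min thresholds (defaults 50,
#'   0.5, 0.5, 0.3).
#' @return list: verdict ("piRNA_like"/"none"/"insufficient data"),
#'   mass_23_30, u5_freq, a10_freq, modal_length.
#' @export
pirnaDetector <- function(reads, min_reads = 50L, mass_min = 0.5,
                          u5_min = 0.5, a10_min = 0.3) {
    if (nrow(reads) < min_reads) return(.insufficient("piRNA"))
    seqs <- toupper(.rna2dna(reads$sequence))
    len <- reads$length
    sel <- len >= 18L & len <= 30L
    mass <- mean(len[sel] >= 23L)
    long <- sel & len >= 23L
    u5 <- if (any(long)) mean(substr(seqs[long], 1L, 1L) == "T")
          else NA_real_
    senseMid <- sel & len >= 23L & len <= 26L &
        !is.na(reads$orientation) & reads$orientation == "sense"
    a10 <- if (any(senseMid)) mean(substr(seqs[senseMid], 10L, 10L) == "A")
           else NA_real_
    verdict <- if (mass >= mass_min &&
                   ((!is.na(u5) && u5 >= u5_min) ||
                    (!is.na(a10) && a10 >= a10_min))) "piRNA_like"
               else "none"
    list(verdict = verdict, kind = "piRNA", mass_23_30 = mass,
         u5_freq = u5, a10_freq = a10,
         modal_length = as.integer(names(which.max(table(len[sel])))))
}

#' Join per-library verdicts with chemical end-state inference
#'
#' For every population detected in at least one library, reads its
#' cross-library detection pattern through the treatment truth table
#' (\code{\link{inferEndStates}}) to name the compatible end
#' chemistries. First-nucleotide p-values are Benjamini-Hochberg
#' adjusted across populations; an siRNA candidate must survive at
#' FDR 0.05. The headline configuration of interest — no siRNA
#' candidate in library #1 or #3 — is flagged when it holds: direct
#' RdRP products (5'-triP) would surface in #3, Dicer-processed
#' products of long RdRP transcripts in #1.
#'
#' @param verdicts data.frame with one row per (library, population):
#'   columns \code{library}, \code{population}, \code{verdict},
#'   \code{p_value} (NA for piRNA rows).
#' @return list: \code{populations} (pattern, compatible end states,
#'   adjusted p), \code{no_secondary_sirna_evidence},
#'   \code{missing_libraries}.
#' @export
crossLibraryReport <- function(verdicts) {
    missing <- setdiff(1:4, unique(verdicts$library))
    if (length(missing))
        warning("missing libraries: ", paste(missing, collapse = ", "),
                "; report is partial")
    verdicts$p_adj <- p.adjust(verdicts$p_value, method = "BH")
    verdicts$detected <- verdicts$verdict %in%
        c("siRNA_candidate", "piRNA_like")
    verdicts$detected[verdicts$verdict == "siRNA_candidate" &
                      !is.na(verdicts$p_adj) & verdicts$p_adj > 0.05] <-
        FALSE
    pops <- unique(verdicts$population[verdicts$detected])
    popRows <- lapply(pops, function(p) {
        libs <- sort(unique(verdicts$library[verdicts$population == p &
                                             verdicts$detected]))
        states <- inferEndStates(libs)
        data.frame(population = p,
                   pattern = paste(libs, collapse = ","),
                   compatible_states = if (nrow(states))
                       paste(paste0(states$five_prime, "/",
                                    states$three_prime), collapse = ";")
                   else "chemically impossible",
                   stringsAsFactors = FALSE)
    })
    populations <- if (length(popRows)) do.call(rbind, popRows)
        else data.frame(population = character(0), pattern = character(0),
                        compatible_states = character(0))
    sirnaAny <- any(verdicts$detected &
                    verdicts$verdict == "siRNA_candidate" &
                    verdicts$library %in% c(1L, 3L))
    list(populations = populations, verdicts = verdicts,
         no_secondary_sirna_evidence = !sirnaAny,
         missing_libraries = missing)
}
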