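#' @importFrom utils write.table
NULL

.FIVE_STATES <- c("OH", "monoP", "triP")
.THREE_STATES <- c("OH", "methyl")
.CHEM_STEPS <- c("periodate_oxidation", "terminator_exonuclease",
                 "phosphatase", "pnk_phosphorylation")

# Fixed step composition of the four treatment regimes. Library #3 applies
# Terminator exonuclease, then phosphatase, then T4 PNK; #4 adds periodate
# oxidation after those three (treatment order matters: PNK before
# periodate, so 5'-rescued molecules still face the 3' test).
.PROTOCOL_STEPS <- list(
    `1` = character(0),
    `2` = "periodate_oxidation",
    `3` = c("terminator_exonuclease", "phosphatase", "pnk_phosphorylation"),
    `4` = c("terminator_exonuclease", "phosphatase", "pnk_phosphorylation",
            "periodate_oxidation")
)

#' Library preparation protocol
#'
#' One of the four small RNA-seq treatment regimes: #1 untreated (standard
#' protocol), #2 periodate oxidation, #3 Terminator exonuclease +
#' phosphatase + T4 PNK, #4 all of the above. The step list is fixed per
#' id; protocols differ only in which 5'/3' end chemistries survive to
#' adapter ligation.
#'
#' @slot id protocol id, 1..4.
#' @slot steps ordered character vector of chemical steps.
#' @export
setClass("LibraryProtocol",
         representation(id = "integer", steps = "character"))

setValidity("LibraryProtocol", function(object) {
    if (!object@id %in% 1:4) return("protocol id must be 1..4")
    if (!identical(object@steps, .PROTOCOL_STEPS[[as.character(object@id)]]))
        return("steps do not match the fixed protocol definition")
    TRUE
})

#' @describeIn LibraryProtocol constructor from a protocol id.
#' @param id integer in 1..4.
#' @export
libraryProtocol <- function(id) {
    id <- as.integer(id)
    stopifnot(length(id) == 1L, id %in% 1:4)
    new("LibraryProtocol", id = id, steps = .PROTOCOL_STEPS[[as.character(id)]])
}

setMethod("show", "LibraryProtocol", function(object) {
    cat(sprintf("LibraryProtocol #%d: %s\n", object@id,
                if (length(object@steps)) paste(object@steps, collapse = " -> ")
                else "(untreated)"))
})

#' Enumerate the six small RNA end states
#'
#' All combinations of 5' state (hydroxyl, monophosphate, or poly/triP —
#' the assays cannot count phosphates beyond one, so \code{triP} stands
#' for any n >= 2) and 3' state (free 2',3'-diol vs 2'-O-methyl).
#'
#' @return data.frame with columns \code{five_prime}, \code{three_prime}.
#' @export
endStates <- function() {
    expand.grid(five_prime = .FIVE_STATES, three_prime = .THREE_STATES,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Apply one chemical step to an end state
#'
#' Step semantics: periodate oxidation destroys (renders non-ligatable)
#' molecules with an unmodified 3' end and spares 2'-O-methylated ones;
#' Terminator exonuclease degrades 5'-monophosphorylated molecules only;
#' phosphatase strips mono- and polyphosphates to 5'-OH; T4 PNK
#' phosphorylates 5'-OH to 5'-monoP. Total function: every (state, step)
#' pair yields a new state or \code{DESTROYED}.
#'
#' @param five_prime,three_prime character vectors of end states
#'   (recycled to common length).
#' @param step one of \code{"periodate_oxidation"},
#'   \code{"terminator_exonuclease"}, \code{"phosphatase"},
#'   \code{"pnk_phosphorylation"}.
#' @return data.frame with columns \code{five_prime}, \code{three_prime},
#'   \code{destroyed} (logical). Destroyed molecules keep their last state
#'   for bookkeeping but are flagged.
#' @examples
#' applyStep("monoP", "OH", "periodate_oxidation")$destroyed  # TRUE
#' @export
applyStep <- function(five_prime, three_prime, step) {
    step <- match.arg(step, .CHEM_STEPS)
    n <- max(length(five_prime), length(three_prime))
    five <- rep_len(as.character(five_prime), n)
    three <- rep_len(as.character(three_prime), n)
    stopifnot(all(five %in% .FIVE_STATES), all(three %in% .THREE_STATES))
    destroyed <- rep(FALSE, n)
    if (step == "periodate_oxidation") {
        destroyed <- three == "OH"
    } else if (step == "terminator_exonuclease") {
        destroyed <- five == "monoP"
    } else if (step == "phosphatase") {
        five[five %in% c("monoP", "triP")] <- "OH"
    } else { # pnk_phosphorylation
        five[five == "OH"] <- "monoP"
    }
    data.frame(five_prime = five, three_prime = three, destroyed = destroyed,
               stringsAsFactors = FALSE)
}

#' Is a molecule with a given end state detectable in a library?
#'
#' Applies the protocol's steps in order and requires the surviving
#' molecule to carry a 5' monophosphate — the ligation requirement of the
#' standard small RNA-seq protocol.
#'
#' @param five_prime,three_prime end state vectors (recycled).
#' @param protocol a \linkS4class{LibraryProtocol} or protocol id.
#' @return logical vector.
#' @examples
#' detectableIn("monoP", "OH", 1)   # TRUE: a miRNA in library #1
#' detectableIn("triP", "OH", 3)    # TRUE: a 22G RNA in library #3
#' @export
detectableIn <- function(five_prime, three_prime, protocol) {
    if (!is(protocol, "LibraryProtocol")) protocol <- libraryProtocol(protocol)
    n <- max(length(five_prime), length(three_prime))
    st <- data.frame(five_prime = rep_len(as.character(five_prime), n),
                     three_prime = rep_len(as.character(three_prime), n),
                     destroyed = rep(FALSE, n), stringsAsFactors = FALSE)
    for (step in protocol@steps) {
        res <- applyStep(st$five_prime, st$three_prime, step)
        res$destroyed <- res$destroyed | st$destroyed
        st <- res
    }
    !st$destroyed & st$five_prime == "monoP"
}

#' The 6 x 4 end-state detectability truth table
#'
#' @return data.frame with the six end states and logical columns
#'   \code{lib1}..\code{lib4}: in which libraries a molecule with that
#'   chemistry is sequenced.
#' @examples
#' chemistryTruthTable()
#' @export
chemistryTruthTable <- function() {
    tab <- endStates()
    for (i in 1:4)
        tab[[paste0("lib", i)]] <-
            detectableIn(tab$five_prime, tab$three_prime, i)
    tab
}

#' Invert a cross-library detection pattern into end states
#'
#' Given the set of libraries in which a population is detected, returns
#' every end chemistry whose full detection pattern equals that set. An
#' empty result means the pattern is chemically impossible (e.g. detection
#' in #2 without #1).
#'
#' @param pattern integer vector, subset of 1:4 (may be empty).
#' @return data.frame of compatible end states (possibly 0 rows).
#' @examples
#' inferEndStates(1)        # monoP / OH: the miRNA chemistry
#' inferEndStates(3)        # ambiguous: 5'-OH or 5'-triP, unmethylated
#' inferEndStates(c(2, 3))  # impossible: 0 rows
#' @export
inferEndStates <- function(pattern) {
    pattern <- sort(unique(as.integer(pattern)))
    stopifnot(all(pattern %in% 1:4))
    tab <- chemistryTruthTable()
    mat <- as.matrix(tab[, paste0("lib", 1:4)])
    want <- 1:4 %in% pattern
    keep <- apply(mat, 1L, function(row) identical(unname(row), want))
    tab[keep, c("five_prime", "three_prime"), drop = FALSE]
}

#' Pass simulated molecules through a library protocol
#'
#' Retains the molecules whose end chemistry survives the protocol and is
#' ligatable, i.e. the reads that the corresponding sequencing library
#' would contain.
#'
#' @param molecules a \linkS4class{SmallRNASet}.
#' @param protocol a \linkS4class{LibraryProtocol} or id.
#' @param sample_fraction optional per-molecule retention probability
#'   (default 1: keep every detectable molecule).
#' @param seed optional seed for the subsampling step.
#' @return A \linkS4class{SmallRNASet} of the surviving molecules.
#' @export
applyProtocol <- function(molecules, protocol, sample_fraction = 1,
                          seed = NULL) {
    stopifnot(is(molecules, "SmallRNASet"))
    keep <- detectableIn(fivePrime(molecules), threePrime(molecules),
                         protocol)
    out <- molecules[keep]
    if (sample_fraction < 1 && length(out)) {
        if (!is.null(seed)) {
            old <- .saveRNG(); on.exit(.restoreRNG(old))
            set.seed(seed)
        }
        out <- out[stats::runif(length(out)) < sample_fraction]
    }
    out
}

#' Export the chemistry truth table as TSV
#'
#' @param path output file.
#' @return the table, invisibly.
#' @export
writeTruthTable <- function(path) {
    tab <- chemistryTruthTable()
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(tab)
}
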