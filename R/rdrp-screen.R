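#' @importFrom ape getMRCA
NULL

.BULKY_DEFAULT <- c("L", "I", "V", "F", "M", "W", "Y")
.AA_CHARS <- "ACDEFGHIKLMNPQRSTVWY"

#' Profile-search E-value gate
#'
#' @param evalue E-value(s) from a profile search, >= 0.
#' @param cutoff inclusive threshold (default 1e-2).
#' @return logical vector: E <= cutoff.
#' @export
evalueGate <- function(evalue, cutoff = 1e-2) {
    stopifnot(all(evalue >= 0))
    evalue <= cutoff
}

#' Domain completeness filter
#'
#' A hit covers the profile completely enough when the alignment leaves
#' at most 20% of the profile uncovered at each end, the two ends tested
#' independently.
#'
#' @param start,end alignment span on the profile (1-based inclusive).
#' @param profile_length profile length.
#' @param tol tolerated truncation fraction per end (default 0.2).
#' @return logical vector.
#' @examples
#' domainComplete(21, 80, 100)  # TRUE: 20 <= 20 at both ends
#' domainComplete(22, 80, 100)  # FALSE
#' @export
domainComplete <- function(start, end, profile_length, tol = 0.2) {
    stopifnot(all(start >= 1), all(end >= start),
              all(end <= profile_length))
    (start - 1) <= tol * profile_length &
        (profile_length - end) <= tol * profile_length
}

#' Scan for the RdRP catalytic motif DbDGD
#'
#' Searches an amino-acid sequence for D-b-D-G-D where b is a bulky
#' residue (default set L, I, V, F, M, W, Y).
#'
#' @param protein amino-acid string (standard 20-letter alphabet).
#' @param bulky residues accepted at the second position.
#' @return list with \code{present} and \code{position} of the first
#'   occurrence (NA when absent).
#' @examples
#' catalyticMotif("MKDLDGDKL")$present  # TRUE
#' @export
catalyticMotif <- function(protein, bulky = .BULKY_DEFAULT) {
    protein <- toupper(protein)
    if (grepl(sprintf("[^%s]", .AA_CHARS), protein))
        stop("protein contains non-amino-acid characters")
    re <- sprintf("D[%s]DGD", paste(bulky, collapse = ""))
    pos <- regexpr(re, protein)
    list(present = pos[1L] > 0L,
         position = if (pos[1L] > 0L) as.integer(pos[1L]) else NA_integer_)
}

#' Combine the screen gates over a domain-hit table
#'
#' @param hits data.frame with columns \code{protein}, \code{evalue},
#'   \code{start}, \code{end}, \code{profile_length}.
#' @param proteins named character vector of amino-acid sequences (for
#'   the catalytic-motif scan; optional).
#' @param evalue_cutoff,tol,bulky gate parameters.
#' @return the hit table with logical columns \code{evalue_pass},
#'   \code{complete}, \code{motif_present} (NA when no sequence given)
#'   and \code{candidate} (all gates passed).
#' @export
screenRdrp <- function(hits, proteins = NULL, evalue_cutoff = 1e-2,
                       tol = 0.2, bulky = .BULKY_DEFAULT) {
    hits$evalue_pass <- evalueGate(hits$evalue, evalue_cutoff)
    hits$complete <- domainComplete(hits$start, hits$end,
                                    hits$profile_length, tol)
    hits$motif_present <- if (is.null(proteins)) NA else
        vapply(as.character(hits$protein), function(p)
            if (p %in% names(proteins))
                catalyticMotif(proteins[[p]], bulky)$present
            else NA, logical(1), USE.NAMES = FALSE)
    hits$candidate <- hits$evalue_pass & hits$complete &
        (is.na(hits$motif_present) | hits$motif_present)
    hits
}

#' Count gene losses under Dollo parsimony
#'
#' Under a single-gain (Dollo) model the character originates at the
#' most recent common ancestor of the species that retain it; the
#' minimal number of losses is the number of maximal all-absent subtrees
#' below that origin.
#'
#' @param tree a rooted \link[ape]{phylo} tree.
#' @param presence named logical vector over the tree's tip labels
#'   (TRUE = species has the gene).
#' @return list with \code{origin} (node number; the tip itself when one
#'   species is present, NA when none), \code{n_losses} and
#'   \code{loss_branches} (labels/ids of the subtree roots where the
#'   character was lost).
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' dolloLosses(tr, c(A = TRUE, B = FALSE, C = TRUE, D = FALSE))$n_losses
#' @export
dolloLosses <- function(tree, presence) {
    stopifnot(inherits(tree, "phylo"))
    if (is.null(names(presence)) ||
        !all(tree$tip.label %in% names(presence)))
        stop("presence must be named and cover every leaf")
    pres <- as.logical(presence[tree$tip.label])
    ntip <- length(tree$tip.label)
    presentTips <- which(pres)
    if (length(presentTips) == 0L)
        return(list(origin = NA_integer_, n_losses = 0L,
                    loss_branches = character(0)))
    origin <- if (length(presentTips) == 1L) presentTips
              else getMRCA(tree, presentTips)

    nnode <- ntip + tree$Nnode
    absent <- rep(TRUE, nnode)
    absent[seq_len(ntip)] <- !pres
    edge <- ape::reorder.phylo(tree, "postorder")$edge
    for (k in seq_len(nrow(edge)))
        absent[edge[k, 1L]] <- absent[edge[k, 1L]] && absent[edge[k, 2L]]

    parent <- integer(nnode)
    parent[edge[, 2L]] <- edge[, 1L]
    inClade <- function(v) {
        while (v != origin && parent[v] != 0L) {
            v <- parent[v]
            if (v == origin) return(TRUE)
        }
        v == origin
    }
    lossNodes <- integer(0)
    for (v in seq_len(nnode)) {
        if (v == origin || parent[v] == 0L) next
        if (absent[v] && !absent[parent[v]] && inClade(v))
            lossNodes <- c(lossNodes, v)
    }
    labels <- vapply(lossNodes, function(v)
        if (v <= ntip) tree$tip.label[v] else paste0("node", v),
        character(1))
    list(origin = origin, n_losses = length(lossNodes),
         loss_branches = labels)
}
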