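# Independent brute-force oracles used to cross-check the package's
# search and parsimony code, plus small fixture builders.

rc <- function(x) {
    vapply(x, function(s)
        paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]),
              collapse = ""), character(1), USE.NAMES = FALSE)
}

# exhaustive substring scan: occurrences of `read` across `seqs`
# (forward orientation of the sequences only)
oracle_occ <- function(read, seqs) {
    L <- nchar(read)
    sum(vapply(seqs, function(s) {
        n <- nchar(s)
        if (n < L) return(0L)
        sum(substring(s, 1:(n - L + 1L), L:n) == read)
    }, numeric(1)))
}

# brute-force junction-exclusive hits, defined straight from the rule:
# a read (18-30 nt) hits gene g in some orientation when it (or its
# reverse complement) occurs in g's spliced transcript crossing an
# exon-exon boundary with >= m nt on each side, and the read has no
# occurrence in the genome on either strand. Returns unique
# (read, gene, orientation) rows.
oracle_junction_hits <- function(reads, fixture, m = 3L) {
    genomeChar <- as.character(genomeSeqs(fixture))
    tx <- as.character(transcriptSeqs(fixture))
    genes <- geneModels(fixture)
    boundaries <- lapply(names(genes), function(g) {
        w <- GenomicRanges::width(genes[[g]])
        cumsum(w)[-length(w)]
    })
    names(boundaries) <- names(genes)
    reads <- unique(chartr("Uu", "Tt", toupper(reads)))
    reads <- reads[nchar(reads) >= 18 & nchar(reads) <= 30]
    out <- list()
    for (r in reads) {
        if (oracle_occ(r, genomeChar) + oracle_occ(rc(r), genomeChar) > 0)
            next
        for (g in names(tx)) {
            b <- boundaries[[g]]
            if (!length(b)) next
            for (ori in c("sense", "antisense")) {
                q <- if (ori == "sense") r else rc(r)
                s <- tx[[g]]
                n <- nchar(s)
                L <- nchar(q)
                if (n < L) next
                starts <- which(substring(s, 1:(n - L + 1L), L:n) == q)
                crossing <- any(vapply(starts, function(st)
                    any(b - st + 1L >= m & st + L - 1L - b >= m),
                    logical(1)))
                if (crossing)
                    out[[length(out) + 1L]] <-
                        data.frame(read = r, gene = g, orientation = ori)
            }
        }
    }
    if (length(out)) unique(do.call(rbind, out))
    else data.frame(read = character(0), gene = character(0),
                    orientation = character(0))
}

# exhaustive single-gain (Dollo) minimal-change search: enumerate every
# presence/absence assignment to internal nodes, keep assignments with
# at most one gain (parent absent -> child present) starting from an
# absent root state, and return the minimal number of losses
oracle_dollo_losses <- function(tree, presence) {
    ntip <- length(tree$tip.label)
    nint <- tree$Nnode
    pres <- as.logical(presence[tree$tip.label])
    if (!any(pres)) return(0L)
    edge <- tree$edge
    best <- Inf
    for (code in 0:(2^nint - 1L)) {
        states <- c(pres, as.logical(bitwAnd(code %/%
            2^(seq_len(nint) - 1L), 1L)))
        gains <- 0L; losses <- 0L
        for (k in seq_len(nrow(edge))) {
            a <- states[edge[k, 1L]]; b <- states[edge[k, 2L]]
            if (!a && b) gains <- gains + 1L
            if (a && !b) losses <- losses + 1L
        }
        root <- setdiff(edge[, 1L], edge[, 2L])[1L]
        if (states[root]) gains <- gains + 1L  # gain on the root branch
        if (gains <= 1L && losses < best) best <- losses
    }
    as.integer(best)
}

# independent nesting check for dot-bracket strings: recover the arcs
# with a stack and test that consecutive arcs (by opening position)
# always nest, i.e. the structure is one chain of stacked pairs around
# a single loop
oracle_unbranched <- function(db) {
    ch <- strsplit(db, "")[[1L]]
    stack <- integer(0)
    arcs <- NULL
    for (i in seq_along(ch)) {
        if (ch[i] == "(") stack <- c(stack, i)
        else if (ch[i] == ")") {
            arcs <- rbind(arcs, c(stack[length(stack)], i))
            stack <- stack[-length(stack)]
        }
    }
    if (is.null(arcs)) return(TRUE)
    arcs <- arcs[order(arcs[, 1L]), , drop = FALSE]
    all(diff(arcs[, 1L]) > 0 & diff(arcs[, 2L]) < 0)
}

# a random balanced dot-bracket string (not necessarily unbranched)
random_dotbracket <- function(n = 20L) {
    out <- character(0)
    depth <- 0L
    remaining_open <- sample(2:6, 1L)
    while (remaining_open > 0L || depth > 0L) {
        choices <- c(if (remaining_open > 0L) "(",
                     if (depth > 0L) ")", ".")
        c1 <- sample(choices, 1L)
        if (c1 == "(") { depth <- depth + 1L
                         remaining_open <- remaining_open - 1L }
        if (c1 == ")") depth <- depth - 1L
        out <- c(out, c1)
    }
    paste(out, collapse = "")
}

small_fixture <- function(seed = 3L, ...) {
    generateGenome(simConfig(seed = seed, n_chromosomes = 1L,
                             chrom_length = 6000L, n_genes = 5L, ...))
}

no_sirna_weights <- c(miRNA = 0.45, piRNA_like = 0.35,
                      degradation = 0.15, contaminant = 0.05)
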