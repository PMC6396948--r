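#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml
NULL

.defaultThresholds <- function() {
    list(max_mismatches = 0L, junction_m = 3L, junction_Lmax = 30L,
         junction_mismatches = 1L, min_stem = 25L, max_dG = -15,
         min_coverage = 20, mature_min_ppm = 10, sirna_min_reads = 50L,
         sirna_narrowness = 0.5, sirna_p = 0.01, sirna_ppm = 1,
         pirna_mass = 0.5, pirna_u5 = 0.5, pirna_a10 = 0.3, topN = 10L)
}

.popReads <- function(ann, categories) {
    sel <- !is.na(ann$category) & ann$category %in% categories &
        ann$length >= 18L & ann$length <= 30L
    data.frame(sequence = as.character(ann$sequence[sel]),
               length = ann$length[sel],
               orientation = ann$orientation[sel],
               stringsAsFactors = FALSE)
}

#' Run the full analysis on a simulated study
#'
#' End-to-end workflow: generate (or accept) a genome fixture, simulate
#' a molecule population, pass it through the four library chemistries,
#' hierarchically annotate each library's reads, compute size spectra
#' and bias statistics, filter hairpin loci and call mature miRNAs, scan
#' exon-exon junctions, run the siRNA/piRNA signature detectors per
#' library and orientation, and join everything into a cross-library
#' chemistry report. Per-stage read counts are logged and all tables
#' written to \code{out_dir} alongside a JSON summary and a markdown
#' report. Fully deterministic for a fixed seed.
#'
#' @param config a list or path to a YAML file; recognised elements:
#'   \code{seed}, \code{out_dir}, \code{simulation} (arguments to
#'   \code{\link{simConfig}}), \code{thresholds} (overrides of the
#'   module defaults).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the fixture, molecules, per-library
#'   annotations, spectra, miRNA calls, junction summary, signature
#'   verdicts and the cross-library report.
#' @export
runPipeline <- function(config = list(), quiet = FALSE) {
    if (is.character(config)) config <- read_yaml(config)
    seed <- config$seed %||% 1L
    th <- utils::modifyList(.defaultThresholds(),
                            config$thresholds %||% list())
    simArgs <- config$simulation %||% list()
    simArgs$seed <- seed
    cfg <- do.call(simConfig, simArgs)
    say <- function(...) if (!quiet) message(...)

    say("generating fixture (seed ", seed, ")")
    fixture <- generateGenome(cfg)
    mols <- simulateReads(fixture)
    say("simulated ", length(mols), " molecules")

    bg <- baseComposition(fixture@transcripts)
    stageCounts <- list()
    libs <- list()
    verdictRows <- list()
    for (i in 1:4) {
        sub <- applyProtocol(mols, i)
        ann <- classifyReads(rnaSequence(sub), fixture,
                             maxMismatches = th$max_mismatches)
        denom <- ppmDenominator(ann)
        tab <- table(ann$category)
        stageCounts[[i]] <- data.frame(
            library = i, total = length(sub),
            as.list(tab), denominator = denom, check.names = FALSE)
        say(sprintf("library #%d: %d reads ligated, %d in denominator",
                    i, length(sub), denom))
        spectra <- if (denom > 0) list(
            premiRNA = sizeSpectrum(ann, c("premiRNA_sense",
                                           "premiRNA_antisense"), denom),
            tx_sense = sizeSpectrum(ann, "transcriptome_sense", denom),
            tx_antisense = sizeSpectrum(ann, "transcriptome_antisense",
                                        denom)) else NULL
        bias <- biasStats(ann, bg)
        for (ori in c("sense", "antisense")) {
            pop <- .popReads(ann, paste0("transcriptome_", ori))
            ppm <- if (denom > 0) normalizePpm(nrow(pop), denom) else 0
            sv <- sirnaDetector(pop, if (ori == "antisense") ppm else 0,
                                bg, th$sirna_min_reads,
                                th$sirna_narrowness, th$sirna_p,
                                th$sirna_ppm)
            pv <- pirnaDetector(pop, th$sirna_min_reads, th$pirna_mass,
                                th$pirna_u5, th$pirna_a10)
            verdictRows[[length(verdictRows) + 1L]] <- data.frame(
                library = i, population = paste0("transcriptome_", ori),
                kind = "siRNA", verdict = sv$verdict,
                p_value = sv$p_value, modal_length = sv$modal_length,
                narrowness = sv$narrowness, stringsAsFactors = FALSE)
            verdictRows[[length(verdictRows) + 1L]] <- data.frame(
                library = i, population = paste0("transcriptome_", ori),
                kind = "piRNA", verdict = pv$verdict, p_value = NA_real_,
                modal_length = pv$modal_length, narrowness = NA_real_,
                stringsAsFactors = FALSE)
        }
        libs[[i]] <- list(molecules = sub, annotated = ann,
                          denominator = denom, spectra = spectra,
                          bias = bias)
    }

    say("miRNA hairpin filtering (library #1 reads)")
    lib1 <- libs[[1L]]
    mirna <- filterHairpins(fixture@hairpins,
                            as.character(lib1$annotated$sequence),
                            lib1$denominator,
                            min_stem = th$min_stem, max_dG = th$max_dG,
                            min_coverage = th$min_coverage)
    mature <- list()
    for (id in mirna$locus_id[mirna$pass]) {
        hp <- fixture@hairpins[fixture@hairpins$locus_id == id, ]
        hc <- hairpinCoverage(as.character(lib1$annotated$sequence), 1L,
                              hp$sequence)
        mature[[id]] <- callMature(
            hp, data.frame(sequence = hc$placed$sequence,
                           count = hc$placed$count, stage = "lib1"),
            denominators = c(lib1 = lib1$denominator),
            min_ppm = th$mature_min_ppm)
    }

    say("junction scan (pooled libraries)")
    idx <- buildJunctionIndex(fixture, Lmax = th$junction_Lmax,
                              m = th$junction_m)
    pooled <- unlist(lapply(libs, function(l)
        as.character(l$annotated$sequence)))
    pooledDenom <- sum(vapply(libs, `[[`, numeric(1), "denominator"))
    hits <- findJunctionReads(pooled, idx, fixture@genome,
                              m = th$junction_m,
                              maxMismatches = th$junction_mismatches)
    jsum <- junctionSummary(hits, max(pooledDenom, 1L), th$topN)
    validity <- spliceAntisenseValidity(fixture)

    verdicts <- do.call(rbind, verdictRows)
    report <- crossLibraryReport(verdicts)
    say(if (report$no_secondary_sirna_evidence)
        "no secondary siRNA evidence (no candidate in library #1 or #3)"
        else "secondary siRNA candidate population detected")

    out <- list(fixture = fixture, molecules = mols, libraries = libs,
                stage_counts = do.call(rbind, stageCounts),
                mirna = mirna, mature = mature,
                junction_index = idx, junction_hits = hits,
                junction_summary = jsum, splice_validity = validity,
                verdicts = verdicts, report = report)
    if (!is.null(config$out_dir)) .writeRunOutputs(out, config$out_dir)
    invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeRunOutputs <- function(out, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    w <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
    w(out$stage_counts, "stage_counts.tsv")
    w(out$mirna, "mirna_loci.tsv")
    w(out$verdicts, "signature_verdicts.tsv")
    w(out$junction_hits, "junction_hits.tsv")
    w(out$junction_summary$per_gene, "junction_per_gene.tsv")
    w(out$splice_validity$introns, "splice_validity.tsv")
    for (i in 1:4)
        w(as.data.frame(out$libraries[[i]]$annotated),
          sprintf("annotation_lib%d.tsv", i))
    write_json(list(
        no_secondary_sirna_evidence =
            out$report$no_secondary_sirna_evidence,
        populations = out$report$populations,
        junction_whole = out$junction_summary$whole,
        mirna_pass = out$mirna$locus_id[out$mirna$pass]),
        file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    md <- c("# Small RNA analysis report", "",
            "## Per-stage read counts", "",
            paste(utils::capture.output(print(out$stage_counts)),
                  collapse = "\n"), "",
            "## Junction summary (whole transcriptome)", "",
            paste(utils::capture.output(print(out$junction_summary$whole)),
                  collapse = "\n"), "",
            "## Signature verdicts", "",
            paste(utils::capture.output(print(out$verdicts)),
                  collapse = "\n"), "",
            sprintf("Secondary siRNA evidence: %s",
                    if (out$report$no_secondary_sirna_evidence)
                        "none" else "candidate population present"))
    writeLines(md, file.path(dir, "report.md"))
    invisible(NULL)
}
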