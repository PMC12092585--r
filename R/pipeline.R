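## End-to-end orchestration: simulate (optional) -> peak calling ->
## quantification -> differential (both marks) -> RNA-seq DE ->
## classification -> integration, with deterministic outputs under a
## single seed.

#' Differential analysis of one promoter mark (peak-based)
#'
#' Per mark sample: peaks are called against IgG and against input,
#' intersected (vs-IgG coordinates kept), and blacklist-filtered; the
#' per-sample peaks are merged into one feature set, fragments are counted
#' by midpoint, library sizes come from deduplicated spike-in counts, and
#' the exact conditional test compares knockout to control. Gene-level
#' calls use promoter-window overlap.
#'
#' @param markSim output of \code{\link{simulateCutrun}} (or an equivalent
#'   list with \code{samples}, \code{spikein}, \code{conditions}).
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param blacklist \code{GRanges} of excluded regions.
#' @param pcut,fdrCut,fcCut peak and differential thresholds.
#' @return list with \code{peaks} (per sample), \code{features},
#'   \code{counts}, \code{norm}, \code{diff}, \code{genes}
#'   (decreased/increased gene ids).
#' @export
analyzePromoterMark <- function(markSim, annotation,
                                blacklist = GRanges(), pcut = 1e-5,
                                fdrCut = 0.05, fcCut = 1.5) {
    dedup <- lapply(markSim$samples, deduplicate)
    markIds <- names(markSim$conditions)
    igg <- dedup[[grep("_IgG$", names(dedup))]]
    input <- dedup[[grep("_input$", names(dedup))]]
    chromSizes <- chromSizes(annotation)
    peaks <- lapply(markIds, function(id) {
        vsIgg <- callPeaks(dedup[[id]], igg, chromSizes = chromSizes,
                           pcut = pcut)
        vsInput <- callPeaks(dedup[[id]], input, chromSizes = chromSizes,
                             pcut = pcut)
        filterBlacklist(intersectPeakSets(vsIgg, vsInput), blacklist)
    })
    names(peaks) <- markIds
    features <- mergePeaksAcrossSamples(peaks)
    spikeCounts <- vapply(lapply(markSim$spikein[markIds], deduplicate),
                          length, integer(1))
    norm <- spikeinLibrarySizes(spikeCounts)
    counts <- buildCountTable(dedup[markIds], features,
                              librarySizes = spikeCounts)
    diff <- exactCountTest(counts,
                           factor(markSim$conditions[markIds],
                                  levels = c("control", "knockout")),
                           norm = norm)
    genes <- callDifferentialGenes(diff, features = features,
                                   windows = promoterWindows(annotation),
                                   fdrCut = fdrCut, fcCut = fcCut)
    list(peaks = peaks, features = features, counts = counts, norm = norm,
         diff = diff, genes = genes)
}

#' Differential analysis of one gene-body mark (enriched-region normalized)
#'
#' Fragments are counted over gene bodies for the mark samples and both
#' controls; the binomial enrichment test against both controls defines
#' the common significant gene set whose fragment totals become the
#' library sizes; the exact conditional test then compares knockout to
#' control, and genes map to features by identity.
#'
#' @inheritParams analyzePromoterMark
#' @return list with \code{features}, \code{counts}, \code{norm},
#'   \code{significantGenes}, \code{diff}, \code{genes}.
#' @export
analyzeBodyMark <- function(markSim, annotation, fdrCut = 0.05,
                            fcCut = 1.5) {
    dedup <- lapply(markSim$samples, deduplicate)
    markIds <- names(markSim$conditions)
    iggId <- grep("_IgG$", names(dedup), value = TRUE)
    inputId <- grep("_input$", names(dedup), value = TRUE)
    bodies <- geneBodies(annotation)
    counts <- buildCountTable(dedup, bodies)
    enr <- binomialEnrichmentLibrarySizes(counts, markSamples = markIds,
                                          iggId = iggId, inputId = inputId)
    markCounts <- countTable(
        assay(counts, "counts")[, markIds, drop = FALSE],
        librarySizes = enr$norm@librarySizes)
    diff <- exactCountTest(markCounts,
                           factor(markSim$conditions[markIds],
                                  levels = c("control", "knockout")),
                           norm = enr$norm)
    genes <- callDifferentialGenes(diff, fdrCut = fdrCut, fcCut = fcCut)
    list(features = bodies, counts = markCounts, norm = enr$norm,
         significantGenes = enr$significantGenes, diff = diff,
         genes = genes)
}

#' DEG sets from per-contrast results at given thresholds
#'
#' A gene qualifies only when it passes the thresholds in every contrast
#' with a shared direction.
#'
#' @param results named list of \code{DataFrame}s from
#'   \code{\link{exactCountTest}} (one per knockout contrast).
#' @param fdrCut,fcCut thresholds (fold change linear scale).
#' @return list with \code{down} and \code{up} gene-id vectors.
#' @export
degSets <- function(results, fdrCut = 0.05, fcCut = 2) {
    lfcCut <- log2(fcCut)
    down <- lapply(results, function(r)
        r$feature_id[r$fdr <= fdrCut & r$log2fc <= -lfcCut])
    up <- lapply(results, function(r)
        r$feature_id[r$fdr <= fdrCut & r$log2fc >= lfcCut])
    list(down = sort(Reduce(intersect, down)),
         up = sort(Reduce(intersect, up)))
}

#' Run the full integrative pipeline on a simulated experiment
#'
#' Executes peak calling, quantification, both differential analyses, the
#' RNA-seq differential expression, the five-cluster classification,
#' direct-target calling, TF-target annotation and the summary report.
#' Deterministic: the same config yields identical results.
#'
#' @param config a \linkS4class{SimulationConfig}, or a path to a YAML
#'   file of \code{\link{simulationConfig}} arguments.
#' @param sim optionally a pre-built \code{\link{simulateExperiment}}
#'   output (the config is then ignored).
#' @param outDir optional directory for on-disk artifacts (peaks, counts,
#'   differential tables, cluster table, report, manifest).
#' @param markFdr,markFc CUT&RUN differential thresholds.
#' @param degFdr,degFc RNA-seq DEG thresholds (headline DEG definition).
#' @param directFc fold-change threshold for the RNA-down set entering
#'   direct-target calling.
#' @return list with the per-stage results: \code{sim}, \code{k4},
#'   \code{k36}, \code{rna}, \code{clusters}, \code{directTargets},
#'   \code{tfTargets}, \code{report}.
#' @export
runPipeline <- function(config = simulationConfig(), sim = NULL,
                        outDir = NULL, markFdr = 0.05, markFc = 1.5,
                        degFdr = 0.05, degFc = 2, directFc = 1.5) {
    if (is.character(config)) {
        args <- yaml::read_yaml(config)
        if (!is.null(args$chromSizes))
            args$chromSizes <- unlist(args$chromSizes)
        if (!is.null(args$classFractions))
            args$classFractions <- unlist(args$classFractions)
        config <- do.call(simulationConfig, args)
    }
    if (is.null(sim)) sim <- simulateExperiment(config)
    annotation <- sim$annotation

    k4 <- analyzePromoterMark(sim$k4, annotation, fdrCut = markFdr,
                              fcCut = markFc)
    k36 <- analyzeBodyMark(sim$k36, annotation, fdrCut = markFdr,
                           fcCut = markFc)
    rna <- rnaseqDE(sim$rnaseq$counts, sim$rnaseq$condition,
                    controlLevel = "control", fdrCut = degFdr,
                    fcCut = degFc)
    rnaDown <- degSets(rna$results, fdrCut = degFdr, fcCut = directFc)$down

    universe <- geneIds(annotation)
    clusters <- classifyGenes(k4$genes$decreased, k36$genes$decreased,
                              k4$genes$increased, k36$genes$increased,
                              universe)
    direct <- directTargets(rnaDown, k4$genes$decreased,
                            k36$genes$decreased)
    tfTargets <- annotateTfTargets(sim$tfPeaks, annotation)
    overlapUniverse <- intersect(universe, rna$universe)
    report <- summaryReport(clusters, directTargets = direct,
                            tfTargets = tfTargets, rnaDown = rnaDown,
                            overlapUniverse = overlapUniverse)
    out <- list(sim = sim, k4 = k4, k36 = k36, rna = rna,
                clusters = clusters, directTargets = direct,
                tfTargets = tfTargets, rnaDown = rnaDown, report = report)
    if (!is.null(outDir)) .writePipelineArtifacts(out, outDir)
    out
}

.writeDiffTsv <- function(diff, path) {
    utils::write.table(as.data.frame(diff), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
}

.writePipelineArtifacts <- function(out, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(out$k4$peaks))
        writePeaksBed(out$k4$peaks[[id]],
                      file.path(outDir, paste0("peaks_", id, ".bed")))
    writeCounts(out$k4$counts, file.path(outDir, "counts_H3K4me3.tsv"))
    writeCounts(out$k36$counts, file.path(outDir, "counts_H3K36me3.tsv"))
    .writeDiffTsv(out$k4$diff, file.path(outDir, "diff_H3K4me3.tsv"))
    .writeDiffTsv(out$k36$diff, file.path(outDir, "diff_H3K36me3.tsv"))
    for (ko in names(out$rna$results))
        .writeDiffTsv(out$rna$results[[ko]],
                      file.path(outDir, paste0("rnaseq_", ko, ".tsv")))
    utils::write.table(as.data.frame(out$clusters),
                       file.path(outDir, "clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(out$sim$truth),
                       file.path(outDir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    rep <- out$report
    rep$fisherK4 <- rep$fisherK4[c("intersection", "pvalue")]
    rep$fisherK36 <- rep$fisherK36[c("intersection", "pvalue")]
    yaml::write_yaml(lapply(rep, function(x)
        if (is.numeric(x) || is.integer(x)) as.list(x) else x),
        file.path(outDir, "report.yaml"))
    manifest <- list(
        seed = out$sim$config@seed,
        nGenes = out$sim$config@nGenes,
        samples = names(out$sim$k4$samples),
        files = list.files(outDir))
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
    invisible(outDir)
}
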