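## Sliding-window local-Poisson peak calling against a control sample, in
## the spirit of MACS: per window the null is Poisson with a local rate
## taken as the maximum of the genome-wide background rate and the (depth-
## scaled) control rate in the same window, floored at a small constant.

#' Call peaks against a control sample
#'
#' Tiles each chromosome with \code{windowSize}-bp windows every \code{step}
#' bp, counts fragment midpoints per window, and tests each window's count
#' against Poisson(lambda_local) where \code{lambda_local = max(lambda_bg,
#' lambda_ctrl, lambdaFloor)}; \code{lambda_bg = N_s * windowSize /
#' genome_length} and \code{lambda_ctrl} is the control midpoint count in
#' the window scaled by \code{N_s / N_c}. Windows with upper-tail p below
#' \code{pcut} are merged when separated by at most \code{mergeGap} bp; a
#' merged peak keeps its best window p-value and the summed
#' observed/expected enrichment of its significant windows.
#'
#' @param sample,control deduplicated \linkS4class{FragmentSet}s.
#' @param chromSizes named chromosome lengths; defaults to the sample's
#'   seqlengths.
#' @param windowSize window width in bp.
#' @param step window spacing in bp.
#' @param pcut Poisson p-value cutoff.
#' @param mergeGap maximum gap (bp) between significant windows merged into
#'   one peak.
#' @param lambdaFloor lower bound on the local Poisson rate.
#' @return a \code{GRanges} of peaks with \code{pvalue},
#'   \code{fold_enrichment} and \code{control_id} metadata columns.
#' @export
callPeaks <- function(sample, control, chromSizes = NULL, windowSize = 500,
                      step = 100, pcut = 1e-5, mergeGap = 100,
                      lambdaFloor = 0.25) {
    if (is.null(chromSizes)) {
        chromSizes <- seqlengths(sample)
        if (!length(chromSizes) || any(is.na(chromSizes)))
            stop("chromSizes needed (sample has no seqlengths)")
    }
    emptyPeaks <- GRanges(seqinfo = Seqinfo(names(chromSizes),
                                            as.integer(chromSizes)))
    mcols(emptyPeaks) <- DataFrame(pvalue = numeric(0),
                                   fold_enrichment = numeric(0),
                                   control_id = character(0))
    if (!length(sample)) return(emptyPeaks)
    nS <- length(sample)
    nC <- length(control)
    if (!nC) warning("empty control: using genome background rate only")
    genomeLength <- sum(as.numeric(chromSizes))
    lambdaBg <- nS * windowSize / genomeLength

    windows <- .tileWindows(chromSizes, windowSize, step)
    k <- countOverlaps(windows, .midpoints(sample))
    lambdaCtrl <- if (nC) {
        countOverlaps(windows, .midpoints(control)) * nS / nC
    } else 0
    lambdaLocal <- pmax(lambdaBg, lambdaCtrl, lambdaFloor)
    p <- stats::ppois(k - 1L, lambdaLocal, lower.tail = FALSE)

    sig <- which(p < pcut)
    if (!length(sig)) return(emptyPeaks)
    sigWin <- windows[sig]
    peaks <- GenomicRanges::reduce(sigWin, min.gapwidth = mergeGap + 1L)
    hit <- findOverlaps(peaks, sigWin)
    byPeak <- factor(S4Vectors::queryHits(hit), levels = seq_along(peaks))
    peaks$pvalue <- as.numeric(tapply(p[sig][S4Vectors::subjectHits(hit)],
                                      byPeak, min))
    kTot <- tapply(k[sig][S4Vectors::subjectHits(hit)], byPeak, sum)
    lamTot <- tapply(lambdaLocal[sig][S4Vectors::subjectHits(hit)], byPeak,
                     sum)
    peaks$fold_enrichment <- as.numeric(kTot / lamTot)
    peaks$control_id <- sampleId(control)
    seqlengths(peaks) <- chromSizes[seqlevels(peaks)]
    peaks
}

## windows tiling [0, len) per chromosome, last window truncated at the end
.tileWindows <- function(chromSizes, windowSize, step) {
    si <- Seqinfo(names(chromSizes), as.integer(chromSizes))
    grs <- lapply(names(chromSizes), function(chr) {
        len <- chromSizes[[chr]]
        starts0 <- seq.int(0L, max(0L, len - 1L), by = step)
        GRanges(chr, IRanges(starts0 + 1L,
                             pmin(starts0 + windowSize, len)),
                seqinfo = si)
    })
    do.call(c, grs)
}

## fragment midpoints as width-1 ranges (0-based midpoint = (s0+e0) %/% 2)
.midpoints <- function(x) {
    m1 <- (start(x) - 1L + end(x)) %/% 2L + 1L
    GRanges(seqnames(x), IRanges(m1, width = 1L))
}

#' Keep peaks supported by both control comparisons
#'
#' Retains peaks called against IgG iff they overlap (by at least 1 bp) a
#' peak called against input; the retained coordinates are the vs-IgG ones.
#'
#' @param vsIgg,vsInput peak \code{GRanges} from \code{\link{callPeaks}}.
#' @return the filtered vs-IgG peaks.
#' @export
intersectPeakSets <- function(vsIgg, vsInput) {
    vsIgg[countOverlaps(vsIgg, vsInput) > 0L]
}

#' Remove peaks overlapping blacklisted regions
#'
#' @param peaks peak \code{GRanges}.
#' @param blacklist \code{GRanges} of artifact-prone regions.
#' @return peaks with no overlap (>= 1 bp) with the blacklist.
#' @export
filterBlacklist <- function(peaks, blacklist) {
    if (!length(blacklist)) return(peaks)
    peaks[countOverlaps(peaks, blacklist) == 0L]
}

#' Merge peak sets across samples into one feature set
#'
#' Union of all intervals with overlapping or abutting peaks coalesced;
#' the merged intervals become the counting features for differential
#' analysis.
#'
#' @param peakList list of peak \code{GRanges}.
#' @return a \code{GRanges} of merged intervals named \code{peak_1, ...}.
#' @export
mergePeaksAcrossSamples <- function(peakList) {
    merged <- GenomicRanges::reduce(
        do.call(c, lapply(unname(peakList), granges)))
    names(merged) <- sprintf("peak_%d", seq_along(merged))
    merged
}

#' Read a BED3+ interval file as a GRanges
#' @param path BED path (0-based half-open on disk).
#' @return a \code{GRanges}.
#' @export
readBed <- function(path) {
    if (file.size(path) == 0) return(GRanges())
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    if (!nrow(dt)) return(GRanges())
    GRanges(as.character(dt[[1]]), IRanges(dt[[2]] + 1L, dt[[3]]))
}

#' Write peaks as BED6+ (p-value and enrichment in columns 7-8)
#' @param peaks peak \code{GRanges} from \code{\link{callPeaks}}.
#' @param path output path.
#' @export
writePeaksBed <- function(peaks, path) {
    dt <- data.table::data.table(
        chrom = as.character(seqnames(peaks)),
        start = start(peaks) - 1L, end = end(peaks),
        name = sprintf("peak_%d", seq_along(peaks)),
        score = 0L, strand = ".",
        pvalue = signif(peaks$pvalue, 6),
        fold_enrichment = signif(peaks$fold_enrichment, 6))
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
    invisible(path)
}
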