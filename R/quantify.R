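#' Count fragments per feature by midpoint
#'
#' A fragment is assigned to every feature containing its midpoint. On a
#' non-overlapping (merged) feature set the assignment is unique; if
#' features overlap one another a fragment can be counted once per
#' containing feature, and a warning says so.
#'
#' @param frags a deduplicated \linkS4class{FragmentSet}.
#' @param features a \code{GRanges} of counting features (merged peaks,
#'   promoters or gene bodies).
#' @return named integer vector of counts, parallel to \code{features}.
#' @export
countFragments <- function(frags, features) {
    if (length(features) > 1L &&
        !isDisjoint(features))
        warning("overlapping features: midpoints counted once per ",
                "containing feature")
    counts <- countOverlaps(features, .midpoints(frags))
    names(counts) <- if (!is.null(names(features))) names(features)
                     else features$gene_id
    counts
}

#' Build a count table over features for a set of samples
#'
#' @param fragmentSets named list of deduplicated
#'   \linkS4class{FragmentSet}s.
#' @param features counting features (\code{GRanges}).
#' @param librarySizes optional per-sample library sizes; defaults to the
#'   total fragment count of each sample.
#' @return a count table (\code{SummarizedExperiment}), see
#'   \code{\link{countTable}}.
#' @export
buildCountTable <- function(fragmentSets, features, librarySizes = NULL) {
    m <- vapply(fragmentSets, countFragments, integer(length(features)),
                features = features)
    if (length(features) == 1L) m <- matrix(m, nrow = 1L,
                                            dimnames = list(NULL, names(fragmentSets)))
    rownames(m) <- if (!is.null(names(features))) names(features)
                   else features$gene_id
    if (is.null(librarySizes))
        librarySizes <- vapply(fragmentSets, length, integer(1))
    countTable(m, librarySizes = librarySizes)
}

#' Scaled signal track from fragments
#'
#' Each fragment is resized to \code{resizeTo} bp around its midpoint
#' (default 151 bp: -75 to +75 bp), per-base coverage is computed,
#' multiplied by \code{1e6 / librarySize}, and averaged within
#' \code{binWidth}-bp bins.
#'
#' @param frags a deduplicated \linkS4class{FragmentSet}.
#' @param librarySize the normalization denominator (spike-in count,
#'   enriched-region count, or total fragments).
#' @param chromSizes named chromosome lengths; defaults to the fragments'
#'   seqlengths.
#' @param binWidth resolution in bp.
#' @param resizeTo fixed fragment length for coverage.
#' @return a \linkS4class{SignalTrack}.
#' @export
makeTrack <- function(frags, librarySize, chromSizes = NULL, binWidth = 10,
                      resizeTo = 151) {
    if (is.null(chromSizes)) {
        chromSizes <- seqlengths(frags)
        if (!length(chromSizes) || any(is.na(chromSizes)))
            stop("chromSizes needed (fragments have no seqlengths)")
    }
    scale <- 1e6 / librarySize
    half <- (resizeTo - 1L) %/% 2L
    if (length(frags)) {
        m1 <- (start(frags) - 1L + end(frags)) %/% 2L + 1L
        gr <- GRanges(seqnames(frags),
                      IRanges(pmax(m1 - half, 1L), m1 + (resizeTo - 1L - half)))
        gr <- GRanges(seqnames(gr),
                      IRanges(start(gr),
                              pmin(end(gr),
                                   chromSizes[as.character(seqnames(gr))])))
        cov <- GenomicRanges::coverage(gr, width = chromSizes)
    } else {
        cov <- RleList(lapply(chromSizes, function(len) Rle(0L, len)),
                       compress = FALSE)
    }
    binned <- RleList(lapply(names(chromSizes), function(chr) {
        v <- cov[[chr]] * scale
        len <- chromSizes[[chr]]
        starts <- seq.int(1L, len, by = binWidth)
        ends <- pmin(starts + binWidth - 1L, len)
        means <- viewMeans(Views(v, starts, ends))
        Rle(means, ends - starts + 1L)
    }), compress = FALSE)
    names(binned) <- names(chromSizes)
    new("SignalTrack", values = binned, binWidth = binWidth,
        librarySize = as.numeric(librarySize))
}

#' Average replicate tracks
#' @param tracks list of \linkS4class{SignalTrack}s on identical bins.
#' @return the mean \linkS4class{SignalTrack}.
#' @export
averageTracks <- function(tracks) {
    stopifnot(length(tracks) >= 1L)
    vals <- Reduce(`+`, lapply(tracks, trackValues)) / length(tracks)
    new("SignalTrack", values = vals, binWidth = tracks[[1]]@binWidth,
        librarySize = mean(vapply(tracks, function(t) t@librarySize,
                                  numeric(1))))
}

#' Write a SignalTrack as bedGraph
#'
#' One row per non-zero fixed-width bin, sorted by chromosome then start,
#' 0-based half-open, values trimmed to 6 significant digits.
#'
#' @param track a \linkS4class{SignalTrack}.
#' @param path output path.
#' @export
writeBedGraph <- function(track, path) {
    bw <- track@binWidth
    rows <- lapply(sort(names(trackValues(track))), function(chr) {
        v <- trackValues(track)[[chr]]
        len <- length(v)
        starts0 <- seq.int(0L, len - 1L, by = bw)
        vals <- as.numeric(v[starts0 + 1L])
        keep <- vals != 0
        data.table::data.table(
            chrom = rep(chr, sum(keep)), start = starts0[keep],
            end = pmin(starts0[keep] + bw, len),
            value = signif(vals[keep], 6))
    })
    writeLines("track type=bedGraph", path)
    dt <- data.table::rbindlist(rows)
    if (nrow(dt))
        data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                           append = TRUE)
    invisible(path)
}

#' Metagene matrix over scaled gene bodies with fixed flanks
#'
#' Builds the standard TSS-to-TES matrix: 20 upstream bins of 100 bp, 60
#' body bins spanning the longest transcript scaled to equal widths, and 20
#' downstream bins of 100 bp; 100 columns in all. Bin values are mean
#' scaled coverage (so a constant track yields a constant matrix whatever
#' the gene length). Minus-strand genes are flipped so column 1 is always
#' the 5' flank. Replicate tracks are averaged first.
#'
#' @param tracks list of replicate \linkS4class{SignalTrack}s.
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param upstreamBins,bodyBins,downstreamBins bin counts per segment.
#' @param flankBinWidth width of each flank bin (bp).
#' @return numeric matrix, genes x 100, rownames \code{gene_id}.
#' @export
metaMatrix <- function(tracks, annotation, upstreamBins = 20, bodyBins = 60,
                       downstreamBins = 20, flankBinWidth = 100) {
    if (is(tracks, "SignalTrack")) tracks <- list(tracks)
    avg <- averageTracks(tracks)
    vals <- trackValues(avg)
    tt <- .tssTes(annotation)
    nb <- upstreamBins + bodyBins + downstreamBins
    out <- matrix(0, nrow = length(tt$tx), ncol = nb,
                  dimnames = list(names(tt$tx), NULL))
    for (i in seq_along(tt$tx)) {
        chr <- as.character(seqnames(tt$tx))[i]
        len <- length(vals[[chr]])
        L <- abs(tt$tes0[i] - tt$tss0[i])
        meta <- c(seq(-upstreamBins * flankBinWidth, 0,
                      by = flankBinWidth)[-(upstreamBins + 1)],
                  seq(0, L, length.out = bodyBins + 1)[-(bodyBins + 1)],
                  seq(L, L + downstreamBins * flankBinWidth,
                      by = flankBinWidth))
        dir <- if (tt$minus[i]) -1 else 1
        b <- tt$tss0[i] + dir * meta   # genomic boundary per meta boundary
        lo0 <- floor(pmin(b[-length(b)], b[-1]))
        hi0 <- ceiling(pmax(b[-length(b)], b[-1]))
        lo0 <- pmax(lo0, 0); hi0 <- pmin(hi0, len)
        ok <- hi0 > lo0
        if (any(ok)) {
            vm <- viewMeans(Views(vals[[chr]], lo0[ok] + 1L, hi0[ok]))
            row <- numeric(nb); row[ok] <- vm
            out[i, ] <- row
        }
    }
    out
}

#' Per-group mean metagene profiles
#' @param mat a matrix from \code{\link{metaMatrix}}.
#' @param groups factor or character vector of group labels named by (or
#'   parallel to) the matrix rows.
#' @return matrix groups x columns of column means per group.
#' @export
metaProfiles <- function(mat, groups) {
    if (!is.null(names(groups))) groups <- groups[rownames(mat)]
    g <- factor(groups)
    t(vapply(levels(g), function(lv) colMeans(mat[g == lv, , drop = FALSE]),
             numeric(ncol(mat))))
}

#' Heatmap row order: cluster blocks, then descending promoter signal
#'
#' Orders genes first by cluster (C1..C5), then within each cluster by
#' descending mean control signal in a +/- \code{flank} bp window around
#' the TSS, ties broken by gene id.
#'
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param clusters named cluster labels per gene.
#' @param track the control \linkS4class{SignalTrack} used for ordering.
#' @param flank half-width of the TSS window (bp).
#' @return character vector of gene ids in display order.
#' @export
heatmapOrder <- function(annotation, clusters, track, flank = 1000) {
    tt <- .tssTes(annotation)
    vals <- trackValues(track)
    sig <- vapply(seq_along(tt$tx), function(i) {
        chr <- as.character(seqnames(tt$tx))[i]
        len <- length(vals[[chr]])
        lo0 <- max(tt$tss0[i] - flank, 0)
        hi0 <- min(tt$tss0[i] + flank, len)
        if (hi0 <= lo0) return(0)
        viewMeans(Views(vals[[chr]], lo0 + 1L, hi0))
    }, numeric(1))
    ids <- names(tt$tx)
    cl <- clusters[ids]
    ids[order(cl, -sig, ids)]
}
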