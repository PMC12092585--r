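#' Read mapped fragments from a BED or BEDPE file
#'
#' BED rows (chrom, start, end, ...) are taken as fragment spans directly.
#' BEDPE rows are collapsed to the outer span of the mate pair
#' (min start, max end) and must be intra-chromosomal. Coordinates are
#' 0-based half-open on disk. Malformed rows (start >= end, negative
#' coordinates, inter-chromosomal pairs) are dropped with a warning naming
#' their line numbers; the dropped line numbers are kept in
#' \code{metadata(x)$rowErrors}.
#'
#' @param path file path (plain or gzipped).
#' @param genomeTag \code{"target"} or \code{"spikein"}.
#' @param sampleId sample identifier; defaults to the file base name.
#' @param format \code{"auto"}, \code{"bed"} or \code{"bedpe"}.
#' @return a \linkS4class{FragmentSet} with \code{deduplicated = FALSE}.
#' @export
readFragments <- function(path, genomeTag = "target",
                          sampleId = sub("\\.(bed|bedpe)(\\.gz)?$", "",
                                         basename(path)),
                          format = c("auto", "bed", "bedpe")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("cannot read fragment file: ", path)
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    if (format == "auto") {
        format <- if (ncol(dt) >= 6L && is.numeric(dt[[5]]) &&
                      is.numeric(dt[[6]]) && !is.numeric(dt[[4]]))
            "bedpe" else "bed"
    }
    if (format == "bedpe") {
        if (ncol(dt) < 6L) stop("BEDPE needs >= 6 columns")
        chrom <- as.character(dt[[1]])
        start0 <- pmin(dt[[2]], dt[[5]])
        end0 <- pmax(dt[[3]], dt[[6]])
        bad <- dt[[2]] < 0 | dt[[5]] < 0 | dt[[2]] >= dt[[3]] |
               dt[[5]] >= dt[[6]] | chrom != as.character(dt[[4]])
    } else {
        if (ncol(dt) < 3L) stop("BED needs >= 3 columns")
        chrom <- as.character(dt[[1]])
        start0 <- dt[[2]]
        end0 <- dt[[3]]
        bad <- start0 < 0 | start0 >= end0
    }
    bad <- which(bad)
    if (length(bad)) {
        warning(length(bad), " malformed row(s) dropped from ", basename(path),
                " (lines ", paste(utils::head(bad, 10), collapse = ", "),
                if (length(bad) > 10) ", ..." else "", ")")
        chrom <- chrom[-bad]; start0 <- start0[-bad]; end0 <- end0[-bad]
    }
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0))
    metadata(gr)$rowErrors <- bad
    FragmentSet(gr, sampleId = sampleId, genomeTag = genomeTag,
                deduplicated = FALSE)
}

#' Collapse PCR duplicates
#'
#' Retains exactly one fragment per distinct span (chromosome and both
#' endpoints): paired-end duplicates share the full fragment span, not just
#' one end. Idempotent and insensitive to input order.
#'
#' @param x a \linkS4class{FragmentSet}.
#' @return the deduplicated \linkS4class{FragmentSet} (sorted).
#' @export
deduplicate <- function(x) {
    gr <- BiocGenerics::unique(BiocGenerics::sort(granges(x)))
    FragmentSet(gr, sampleId = sampleId(x), genomeTag = genomeTag(x),
                deduplicated = TRUE)
}

#' Write fragments as BEDPE
#'
#' Each fragment is emitted as a mate pair covering its two ends (mate
#' length \code{readLength}, or the full span for shorter fragments), so
#' that \code{readFragments} recovers the identical outer spans.
#'
#' @param x a \linkS4class{FragmentSet}.
#' @param path output path.
#' @param readLength mate length in bp.
#' @export
writeFragmentsBedpe <- function(x, path, readLength = 50L) {
    s0 <- start(x) - 1L
    e0 <- end(x)
    rl <- pmin(readLength, width(x))
    dt <- data.table::data.table(
        chrom1 = as.character(seqnames(x)), start1 = s0, end1 = s0 + rl,
        chrom2 = as.character(seqnames(x)), start2 = e0 - rl, end2 = e0,
        name = sprintf("frag%d", seq_along(x)), score = 0L,
        strand1 = "+", strand2 = "-")
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' Count tables over genomic features
#'
#' A count table is a \code{SummarizedExperiment} with a single
#' \code{counts} assay (features x samples, non-negative integers) and a
#' \code{library_size} column in \code{colData}. Library sizes are the
#' normalization denominators and default to column totals until a
#' \code{\link{NormalizationSpec}} replaces them.
#'
#' @param counts integer matrix with rownames (features) and colnames
#'   (samples).
#' @param librarySizes positive numeric vector per sample; defaults to
#'   column sums.
#' @return a \code{SummarizedExperiment}.
#' @export
countTable <- function(counts, librarySizes = colSums(counts)) {
    counts <- as.matrix(counts)
    stopifnot(all(counts >= 0), all(librarySizes > 0),
              length(librarySizes) == ncol(counts))
    SummarizedExperiment(
        assays = list(counts = counts),
        colData = DataFrame(library_size = as.numeric(librarySizes),
                            row.names = colnames(counts)))
}

#' @rdname countTable
#' @param x a count table.
#' @export
librarySizes <- function(x) {
    stats::setNames(colData(x)$library_size, colnames(x))
}

#' Count-table TSV round trip
#'
#' The on-disk format is a TSV whose first column is \code{feature_id} and
#' whose header row carries the sample ids, preceded by a single comment
#' line \code{#library_size} with the per-sample library sizes, so
#' \code{readCounts(writeCounts(x))} reproduces \code{x} exactly.
#'
#' @param x a count table (\code{SummarizedExperiment}).
#' @param path TSV path.
#' @export
writeCounts <- function(x, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("#library_size", format(librarySizes(x),
                                               scientific = FALSE,
                                               trim = TRUE)),
                     collapse = "\t"), con)
    writeLines(paste(c("feature_id", colnames(x)), collapse = "\t"), con)
    m <- assay(x, "counts")
    utils::write.table(data.frame(feature_id = rownames(m), m,
                                  check.names = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    invisible(path)
}

#' @rdname writeCounts
#' @export
readCounts <- function(path) {
    first <- readLines(path, n = 1L)
    libSizes <- NULL
    skip <- 0L
    if (startsWith(first, "#library_size")) {
        libSizes <- as.numeric(strsplit(first, "\t")[[1]][-1])
        skip <- 1L
    }
    dt <- data.table::fread(path, header = TRUE, sep = "\t", skip = skip)
    m <- as.matrix(dt[, -1])
    storage.mode(m) <- "integer"
    rownames(m) <- as.character(dt[[1]])
    if (is.null(libSizes)) libSizes <- colSums(m)
    countTable(m, librarySizes = libSizes)
}
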