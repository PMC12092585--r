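## Gene model arithmetic. All windows are defined on 0-based half-open
## boundary coordinates relative to the TSS of the longest transcript, then
## materialised as 1-based GRanges. The TSS of a gene is the boundary
## coordinate at its 5' edge: for "+" genes the 0-based start, for "-" genes
## the 0-based (exclusive) end. Windows mirror exactly about that boundary,
## so a "-" gene's window is the numeric reflection of the "+" window.

#' Longest transcript per gene
#'
#' Selects, for each gene, the transcript of maximal length to represent the
#' gene in every window computation; ties are broken by the smallest start
#' coordinate so the choice is deterministic.
#'
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @return a \code{GRanges} with one row per gene, named by \code{gene_id}.
#' @export
longestTranscript <- function(annotation) {
    txl <- transcripts(annotation)
    stopifnot(all(S4Vectors::elementNROWS(txl) >= 1L))
    flat <- unlist(txl, use.names = FALSE)
    grp <- rep(seq_along(txl), S4Vectors::elementNROWS(txl))
    ## order by group, then decreasing width, then increasing start; first
    ## row per group wins
    o <- order(grp, -width(flat), start(flat))
    keep <- o[!duplicated(grp[o])]
    keep <- keep[order(grp[keep])]
    out <- flat[keep]
    names(out) <- geneIds(annotation)
    out$gene_id <- geneIds(annotation)
    out
}

## 0-based TSS/TES boundary coordinates of the longest transcript
.tssTes <- function(annotation) {
    tx <- longestTranscript(annotation)
    minus <- as.character(strand(tx)) == "-"
    tss0 <- ifelse(minus, end(tx), start(tx) - 1L)
    tes0 <- ifelse(minus, start(tx) - 1L, end(tx))
    list(tx = tx, tss0 = tss0, tes0 = tes0, minus = minus)
}

## materialise 0-based half-open [start0, end0) windows as clipped GRanges
.windows0 <- function(template, start0, end0) {
    sl <- seqlengths(template)[as.character(seqnames(template))]
    start0 <- pmax(start0, 0)
    end0 <- pmin(end0, sl)
    gr <- GRanges(seqnames(template), IRanges(start0 + 1L, end0),
                  strand = strand(template), seqinfo = seqinfo(template))
    names(gr) <- names(template)
    gr$gene_id <- template$gene_id
    gr
}

#' Strand-aware TSS windows
#'
#' \code{promoterWindows} returns the promoter of each gene, defined as
#' \code{upstream} bp before to \code{downstream} bp after the TSS of its
#' longest transcript (default -1000 bp to +500 bp). \code{targetWindows}
#' is the wider window used to call a gene a target of a TF peak set
#' (default -5 kb to +1 kb). Both are strand-aware -- "upstream" is against
#' the direction of transcription -- and clipped to chromosome bounds.
#'
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param upstream,downstream extent in bp on either side of the TSS.
#' @return a \code{GRanges} of windows, one per gene.
#' @export
promoterWindows <- function(annotation, upstream = 1000, downstream = 500) {
    tt <- .tssTes(annotation)
    start0 <- ifelse(tt$minus, tt$tss0 - downstream, tt$tss0 - upstream)
    end0 <- ifelse(tt$minus, tt$tss0 + upstream, tt$tss0 + downstream)
    .windows0(tt$tx, start0, end0)
}

#' @rdname promoterWindows
#' @export
targetWindows <- function(annotation, upstream = 5000, downstream = 1000) {
    promoterWindows(annotation, upstream = upstream, downstream = downstream)
}

#' Gene bodies (TSS to TES of the longest transcript)
#'
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @return a \code{GRanges} spanning TSS to TES per gene, in genomic order.
#' @export
geneBodies <- function(annotation) {
    tt <- .tssTes(annotation)
    .windows0(tt$tx, pmin(tt$tss0, tt$tes0), pmax(tt$tss0, tt$tes0))
}

#' Read a six-column gene BED file as a GenomeAnnotation
#'
#' Columns: chrom, start (0-based), end (exclusive), gene_id, score
#' (ignored), strand. Each gene gets a single transcript equal to its BED
#' interval.
#'
#' @param path BED file path.
#' @param chromSizes named vector of chromosome lengths, or a path to a
#'   two-column TSV (chrom, length).
#' @return a \linkS4class{GenomeAnnotation}.
#' @export
readGeneBed <- function(path, chromSizes) {
    if (is.character(chromSizes)) chromSizes <- readChromSizes(chromSizes)
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    if (ncol(dt) < 6L) stop("gene BED needs 6 columns (incl. name, strand)")
    data.table::setnames(dt, 1:6, c("chrom", "start", "end", "gene_id",
                                    "score", "strand"))
    bad <- which(dt$start < 0 | dt$start >= dt$end |
                 !dt$strand %in% c("+", "-"))
    if (length(bad))
        stop("malformed gene BED rows: ", paste(bad, collapse = ", "))
    gr <- GRanges(dt$chrom, IRanges(dt$start + 1L, dt$end),
                  strand = dt$strand, gene_id = dt$gene_id,
                  seqinfo = Seqinfo(names(chromSizes),
                                    as.integer(chromSizes)))
    GenomeAnnotation(gr)
}

#' Read gene/transcript models from a GTF file
#'
#' Uses \code{transcript} features grouped by their \code{gene_id}
#' attribute; GTF 1-based starts are converted to the internal convention.
#'
#' @param path GTF file path.
#' @param chromSizes named vector or two-column TSV path of chromosome sizes.
#' @return a \linkS4class{GenomeAnnotation}.
#' @export
readGtf <- function(path, chromSizes) {
    if (is.character(chromSizes)) chromSizes <- readChromSizes(chromSizes)
    dt <- data.table::fread(path, header = FALSE, sep = "\t", quote = "",
        col.names = c("chrom", "source", "feature", "start", "end", "score",
                      "strand", "frame", "attr"))
    dt <- dt[dt$feature == "transcript", ]
    if (!nrow(dt)) stop("no transcript features in GTF")
    gid <- sub('.*gene_id "([^"]+)".*', "\\1", dt$attr)
    tx <- GRanges(dt$chrom, IRanges(dt$start, dt$end), strand = dt$strand,
                  seqinfo = Seqinfo(names(chromSizes),
                                    as.integer(chromSizes)))
    txl <- S4Vectors::split(tx, factor(gid, levels = unique(gid)))
    span <- unlist(range(txl))
    genes <- GRanges(seqnames(span), ranges(span), strand = strand(span),
                     gene_id = names(txl), seqinfo = seqinfo(tx))
    GenomeAnnotation(genes, transcripts = txl)
}

#' Read a two-column chromosome-sizes TSV
#' @param path TSV with columns chrom, length.
#' @return named integer vector.
#' @export
readChromSizes <- function(path) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    stats::setNames(as.integer(dt[[2]]), as.character(dt[[1]]))
}
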