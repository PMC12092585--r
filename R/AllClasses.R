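#' @import methods
#' @import GenomicRanges
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- Rle runValue
#' @importFrom BiocGenerics unique sort start end width strand
#' @importFrom IRanges IRanges Views viewMeans viewSums RleList
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqnames Seqinfo seqinfo sortSeqlevels
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' FragmentSet: deduplicatable paired-end fragment intervals for one sample
#'
#' A \code{FragmentSet} is a \linkS4class{GRanges} of sequenced fragment
#' spans (unstranded: a paired-end fragment covers both strands) carrying
#' the sample identity, which genome the fragments mapped to (the target
#' genome under study or the exogenous spike-in genome), and whether PCR
#' duplicates have been collapsed.
#'
#' @slot sampleId single sample identifier.
#' @slot genomeTag either \code{"target"} or \code{"spikein"}.
#' @slot deduplicated \code{TRUE} once \code{\link{deduplicate}} has run;
#'   duplicate fragments share both endpoints, i.e. the full span.
#' @export
setClass("FragmentSet",
    contains = "GRanges",
    representation(
        sampleId = "character",
        genomeTag = "character",
        deduplicated = "logical"
    ),
    prototype(sampleId = NA_character_, genomeTag = "target",
              deduplicated = FALSE)
)

setValidity("FragmentSet", function(object) {
    msg <- NULL
    if (length(object@sampleId) != 1L)
        msg <- c(msg, "sampleId must be a single string")
    if (!object@genomeTag %in% c("target", "spikein"))
        msg <- c(msg, "genomeTag must be 'target' or 'spikein'")
    if (length(object@deduplicated) != 1L || is.na(object@deduplicated))
        msg <- c(msg, "deduplicated must be TRUE or FALSE")
    if (length(object) && any(width(object) < 1L))
        msg <- c(msg, "fragment width must be >= 1")
    if (isTRUE(object@deduplicated) && anyDuplicated(object) > 0L)
        msg <- c(msg, "deduplicated set contains duplicate fragments")
    if (is.null(msg)) TRUE else msg
})

#' Construct a FragmentSet
#'
#' @param gr a \code{GRanges} of fragment spans (strand is ignored and reset
#'   to \code{"*"}).
#' @param sampleId sample identifier.
#' @param genomeTag \code{"target"} or \code{"spikein"}.
#' @param deduplicated whether the fragments are already duplicate-free.
#' @return a \linkS4class{FragmentSet}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 280))
#' FragmentSet(gr, sampleId = "K4_ctrl_rep1")
#' @export
FragmentSet <- function(gr, sampleId = NA_character_, genomeTag = "target",
                        deduplicated = FALSE) {
    strand(gr) <- "*"
    new("FragmentSet", gr, sampleId = as.character(sampleId),
        genomeTag = genomeTag, deduplicated = deduplicated)
}

setMethod("show", "FragmentSet", function(object) {
    cat(sprintf("FragmentSet '%s' (%s genome): %d fragments, %s\n",
        object@sampleId, object@genomeTag, length(object),
        if (object@deduplicated) "deduplicated" else "with duplicates"))
    callNextMethod()
})

#' @export
sampleId <- function(x) x@sampleId
#' @export
genomeTag <- function(x) x@genomeTag
#' @export
isDeduplicated <- function(x) x@deduplicated

#' GenomeAnnotation: gene models with their transcripts and chromosome sizes
#'
#' Holds one \code{GRanges} row per gene (the span of its transcripts, with
#' strand and a \code{gene_id} metadata column) and a \code{GRangesList} of
#' transcript intervals named by gene. Chromosome lengths are carried as
#' \code{seqlengths}; every derived window is clipped against them. All
#' downstream windows (promoters, extended TSS windows, gene bodies) are
#' computed from the longest transcript of each gene.
#'
#' @slot genes \code{GRanges}, one row per gene.
#' @slot transcripts \code{GRangesList} parallel to \code{genes}.
#' @export
setClass("GenomeAnnotation",
    representation(genes = "GRanges", transcripts = "GRangesList"))

setValidity("GenomeAnnotation", function(object) {
    msg <- NULL
    ids <- object@genes$gene_id
    if (is.null(ids)) return("genes must carry a gene_id metadata column")
    if (anyDuplicated(ids)) msg <- c(msg, "gene_ids must be unique")
    if (length(object@transcripts) != length(object@genes))
        msg <- c(msg, "transcripts must be parallel to genes")
    sl <- seqlengths(object@genes)
    if (any(is.na(sl))) msg <- c(msg, "all chromosome lengths must be known")
    if (length(object@genes) &&
        any(end(object@genes) > sl[as.character(seqnames(object@genes))]))
        msg <- c(msg, "gene beyond chromosome end")
    if (length(object@transcripts) &&
        any(S4Vectors::elementNROWS(object@transcripts) == 0L))
        msg <- c(msg, "every gene needs at least one transcript")
    if (is.null(msg)) TRUE else msg
})

#' Construct a GenomeAnnotation
#'
#' @param genes \code{GRanges} with a \code{gene_id} column and strand.
#' @param transcripts optional \code{GRangesList} of transcript intervals per
#'   gene; defaults to one transcript per gene equal to the gene span.
#' @param chromSizes named vector of chromosome lengths (bp); may be omitted
#'   when \code{genes} already has seqlengths.
#' @return a \linkS4class{GenomeAnnotation}.
#' @export
GenomeAnnotation <- function(genes, transcripts = NULL, chromSizes = NULL) {
    if (!is.null(chromSizes)) {
        genes <- GRanges(seqnames(genes), ranges(genes), strand = strand(genes),
            gene_id = genes$gene_id,
            seqinfo = Seqinfo(names(chromSizes), as.integer(chromSizes)))
    }
    if (is.null(transcripts)) {
        tx <- GRanges(seqnames(genes), ranges(genes), strand = strand(genes),
                      seqinfo = seqinfo(genes))
        transcripts <- S4Vectors::split(tx, seq_along(genes))
    }
    names(transcripts) <- genes$gene_id
    new("GenomeAnnotation", genes = genes, transcripts = transcripts)
}

setMethod("show", "GenomeAnnotation", function(object) {
    sl <- seqlengths(object@genes)
    cat(sprintf("GenomeAnnotation: %d genes on %d chromosome(s) (%s bp)\n",
        length(object@genes), length(sl),
        format(sum(as.numeric(sl)), big.mark = ",", scientific = FALSE)))
})

#' @export
genes <- function(x) x@genes
#' @export
transcripts <- function(x) x@transcripts
#' @export
geneIds <- function(x) x@genes$gene_id
#' @export
chromSizes <- function(x) seqlengths(x@genes)

#' SignalTrack: scaled per-base coverage at fixed bin resolution
#'
#' Per-base scaled coverage values stored run-length encoded, piecewise
#' constant within fixed-width bins (10 bp by default). Values are coverage
#' of midpoint-resized fragments times \code{1e6 / librarySize}.
#'
#' @slot values \code{RleList}, one per-base \code{Rle} per chromosome.
#' @slot binWidth bin width in bp.
#' @slot librarySize the library size used for scaling.
#' @export
setClass("SignalTrack",
    representation(values = "RleList", binWidth = "numeric",
                   librarySize = "numeric"))

setValidity("SignalTrack", function(object) {
    msg <- NULL
    if (object@binWidth < 1) msg <- c(msg, "binWidth must be >= 1")
    if (object@librarySize <= 0) msg <- c(msg, "librarySize must be > 0")
    if (any(vapply(object@values, function(v) any(runValue(v) < 0), logical(1))))
        msg <- c(msg, "track values must be >= 0")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "SignalTrack", function(object) {
    cat(sprintf(
        "SignalTrack: %d chromosome(s), %g bp bins, library size %g\n",
        length(object@values), object@binWidth, object@librarySize))
})

#' @export
trackValues <- function(x) x@values
#' @export
binWidth <- function(x) x@binWidth
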