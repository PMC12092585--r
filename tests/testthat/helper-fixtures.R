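suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
    library(S4Vectors)
})

## tiny hand-built annotation: genes given as (chrom, strand, tss0, tes0)
## boundary coordinates with a single transcript each
makeAnnotation <- function(df, chromSizes) {
    start0 <- pmin(df$tss, df$tes)
    end0 <- pmax(df$tss, df$tes)
    gr <- GRanges(df$chrom, IRanges(start0 + 1L, end0), strand = df$strand,
                  gene_id = df$gene_id,
                  seqinfo = Seqinfo(names(chromSizes),
                                    as.integer(chromSizes)))
    GenomeAnnotation(gr)
}

## fragments from explicit 0-based [start, end) intervals
makeFragments <- function(chrom, start0, end0, chromSizes = NULL,
                          sampleId = "s", genomeTag = "target") {
    si <- if (is.null(chromSizes)) NULL
          else Seqinfo(names(chromSizes), as.integer(chromSizes))
    gr <- if (is.null(si)) GRanges(chrom, IRanges(start0 + 1L, end0))
          else GRanges(chrom, IRanges(start0 + 1L, end0), seqinfo = si)
    FragmentSet(gr, sampleId = sampleId, genomeTag = genomeTag)
}

## 0-based half-open interval of a GRanges row, for readable assertions
interval0 <- function(gr, i = 1L) c(start(gr)[i] - 1L, end(gr)[i])

smallConfig <- function(...) {
    simulationConfig(nGenes = 30L, chromSizes = c(chrT = 6e5),
                     fragmentsPerSample = 20000L, ...)
}
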