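Package: cutrundelta
Title: Spike-In Normalized Differential Analysis of CUT&RUN Histone Marks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential analysis of CUT&RUN histone-modification profiles
    between conditions, from deduplicated paired-end fragments to gene-level
    classification. Implements sliding-window local-Poisson peak calling
    against IgG and input controls with blacklist filtering, fragment
    quantification over merged peaks, promoters and gene bodies, spike-in and
    binomial-enrichment library-size normalization, an exact conditional
    beta-binomial count test with Benjamini-Hochberg correction, RNA-seq
    differential expression with median-of-ratios size factors, five-cluster
    gene classification by direction of change of H3K4me3 and H3K36me3,
    direct-target calling with Fisher overlap statistics, scaled signal
    tracks and metagene matrices, and a synthetic fragment and count
    generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
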