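#' Classify genes into the five change clusters
#'
#' Partition of the gene universe by direction of change of the two marks
#' upon knockout: C1 both marks decreased; C2 only the promoter mark
#' (H3K4me3) decreased; C3 only the gene-body mark (H3K36me3) decreased;
#' C4 no decrease but an increase in either mark; C5 no change. A gene
#' decreased in one mark and increased in the other is placed by its
#' decrease (C2/C3): decreases drive the downstream target calls, so they
#' take precedence.
#'
#' @param decK4,decK36,incK4,incK36 gene-id vectors (subsets of
#'   \code{universe}).
#' @param universe all annotated gene ids.
#' @return a \code{DataFrame} with \code{gene_id}, \code{cluster} and the
#'   per-gene direction flags; clusters partition the universe.
#' @export
classifyGenes <- function(decK4, decK36, incK4, incK36, universe) {
    sets <- list(decK4, decK36, incK4, incK36)
    if (!all(unlist(sets) %in% universe))
        stop("direction sets must be subsets of the universe")
    d4 <- universe %in% decK4
    d36 <- universe %in% decK36
    i4 <- universe %in% incK4
    i36 <- universe %in% incK36
    cluster <- ifelse(d4 & d36, "C1",
               ifelse(d4, "C2",
               ifelse(d36, "C3",
               ifelse(i4 | i36, "C4", "C5"))))
    DataFrame(gene_id = universe,
              cluster = factor(cluster, levels = paste0("C", 1:5)),
              dec_k4 = d4, dec_k36 = d36, inc_k4 = i4, inc_k36 = i36,
              row.names = universe)
}

#' Direct-target genes
#'
#' Genes both transcriptionally downregulated and losing at least one of
#' the two marks: \code{rnaDown} intersected with the union of the two
#' decreased-mark sets.
#'
#' @param rnaDown downregulated DEGs (required in every knockout contrast).
#' @param decK4,decK36 decreased-mark gene sets.
#' @param combine \code{"union"} (default) or \code{"intersection"} of the
#'   mark sets.
#' @return sorted gene-id vector.
#' @export
directTargets <- function(rnaDown, decK4, decK36,
                          combine = c("union", "intersection")) {
    combine <- match.arg(combine)
    marks <- if (combine == "union") base::union(decK4, decK36)
             else intersect(decK4, decK36)
    sort(intersect(rnaDown, marks))
}

#' Two-sided Fisher's exact test for the overlap of two gene sets
#'
#' Tests the 2x2 table (in both / A only / B only / neither) against the
#' hypergeometric null. The two-sided p-value sums the probabilities of
#' all tables no more likely than the observed one (minimum-likelihood
#' convention). Fold enrichment is observed over expected intersection
#' \code{|A||B|/M}.
#'
#' @param a,b gene-id vectors (subsets of \code{universe}).
#' @param universe the common gene universe.
#' @return list with \code{nA}, \code{nB}, \code{M}, \code{intersection},
#'   \code{expected}, \code{foldEnrichment}, \code{pvalue}.
#' @export
fisherOverlap <- function(a, b, universe) {
    if (!all(a %in% universe) || !all(b %in% universe))
        stop("sets must be subsets of the universe")
    a <- base::unique(a); b <- base::unique(b)
    M <- length(base::unique(universe))
    nA <- length(a); nB <- length(b)
    x <- length(intersect(a, b))
    kLo <- max(0L, nA + nB - M)
    kHi <- min(nA, nB)
    k <- kLo:kHi
    lp <- stats::dhyper(k, nA, M - nA, nB, log = TRUE)
    lpObs <- lp[k == x]
    p <- min(1, sum(exp(lp[lp <= lpObs + 1e-7])))
    expected <- nA * nB / M
    list(nA = nA, nB = nB, M = M, intersection = x, expected = expected,
         foldEnrichment = if (expected > 0) x / expected else NA_real_,
         pvalue = p)
}

#' Genes targeted by a TF peak set
#'
#' A gene is a target when any peak overlaps (>= 1 bp) its extended TSS
#' window (-5 kb to +1 kb by default, strand-aware).
#'
#' @param peaks \code{GRanges} of TF binding peaks.
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param upstream,downstream window extent around the TSS (bp).
#' @return sorted gene-id vector.
#' @export
annotateTfTargets <- function(peaks, annotation, upstream = 5000,
                              downstream = 1000) {
    if (!length(peaks)) return(character(0))
    win <- targetWindows(annotation, upstream = upstream,
                         downstream = downstream)
    sort(base::unique(names(win)[countOverlaps(win, peaks) > 0L]))
}

#' Format a percentage the way the report prints it
#'
#' Rounded to one decimal; the decimal is dropped when it is zero, so 2.95
#' prints as \code{3} and 5.31 as \code{5.3}.
#'
#' @param x fraction in [0, 1].
#' @return numeric percentage (3, 5.3, ...).
#' @export
percentValue <- function(x) {
    p <- round(100 * x, 1)
    ifelse(p == round(p), round(p), p)
}

#' Integration summary report
#'
#' Assembles the headline arithmetic of the analysis: per-cluster sizes
#' and percentages of the gene universe, the decreased-H3K4me3 (C1 + C2)
#' and decreased-H3K36me3 (C1 + C3) gene counts and percentages, the
#' number of direct targets and the fraction of them bound by the TF, and
#' the Fisher overlap statistics between the downregulated DEGs and each
#' decreased-mark set.
#'
#' @param clusterTable a \code{DataFrame} from \code{\link{classifyGenes}}.
#' @param directTargets gene-id vector from \code{\link{directTargets}}.
#' @param tfTargets gene-id vector from \code{\link{annotateTfTargets}}
#'   (may be empty).
#' @param rnaDown downregulated DEGs used for the overlap tests.
#' @param overlapUniverse universe for the Fisher tests; defaults to the
#'   cluster-table universe.
#' @return list with \code{clusterSizes}, \code{clusterPercent},
#'   \code{universeSize}, \code{nDecK4}, \code{pctDecK4}, \code{nDecK36},
#'   \code{pctDecK36}, \code{nDirect}, \code{nDirectTf}, \code{pctDirectTf},
#'   \code{fisherK4}, \code{fisherK36}.
#' @export
summaryReport <- function(clusterTable, directTargets = character(0),
                          tfTargets = character(0),
                          rnaDown = character(0), overlapUniverse = NULL) {
    sizes <- table(clusterTable$cluster)
    M <- nrow(clusterTable)
    nDecK4 <- sum(sizes[c("C1", "C2")])
    nDecK36 <- sum(sizes[c("C1", "C3")])
    nDirect <- length(directTargets)
    nDirectTf <- length(intersect(directTargets, tfTargets))
    if (is.null(overlapUniverse)) overlapUniverse <- clusterTable$gene_id
    decK4 <- intersect(clusterTable$gene_id[clusterTable$dec_k4],
                       overlapUniverse)
    decK36 <- intersect(clusterTable$gene_id[clusterTable$dec_k36],
                        overlapUniverse)
    rnaDown <- intersect(rnaDown, overlapUniverse)
    fisherK4 <- if (length(rnaDown) && length(decK4))
        fisherOverlap(rnaDown, decK4, overlapUniverse) else NULL
    fisherK36 <- if (length(rnaDown) && length(decK36))
        fisherOverlap(rnaDown, decK36, overlapUniverse) else NULL
    list(clusterSizes = stats::setNames(as.integer(sizes), names(sizes)),
         clusterPercent = stats::setNames(percentValue(as.integer(sizes) / M),
                                          names(sizes)),
         universeSize = M,
         nDecK4 = as.integer(nDecK4), pctDecK4 = percentValue(nDecK4 / M),
         nDecK36 = as.integer(nDecK36),
         pctDecK36 = percentValue(nDecK36 / M),
         nDirect = nDirect, nDirectTf = nDirectTf,
         pctDirectTf = if (nDirect > 0) percentValue(nDirectTf / nDirect)
                       else NA_real_,
         fisherK4 = fisherK4, fisherK36 = fisherK36)
}

#' Build a summary report directly from printed cluster sizes
#'
#' Convenience front-end for re-deriving the headline percentages from a
#' vector of cluster sizes (C1..C5) alone, without per-gene flags: a
#' synthetic cluster table with that composition is built and passed to
#' \code{\link{summaryReport}}.
#'
#' @param sizes integer vector of five cluster sizes, in C1..C5 order.
#' @return see \code{\link{summaryReport}}.
#' @export
summaryFromClusterSizes <- function(sizes) {
    stopifnot(length(sizes) == 5L)
    ids <- sprintf("g%d", seq_len(sum(sizes)))
    cl <- rep(paste0("C", 1:5), times = sizes)
    ct <- DataFrame(gene_id = ids,
                    cluster = factor(cl, levels = paste0("C", 1:5)),
                    dec_k4 = cl %in% c("C1", "C2"),
                    dec_k36 = cl %in% c("C1", "C3"),
                    inc_k4 = cl == "C4", inc_k36 = FALSE,
                    row.names = ids)
    summaryReport(ct)
}
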