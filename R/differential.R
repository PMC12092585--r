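## Exact conditional count testing with pluggable library sizes. One test
## engine serves both the CUT&RUN comparisons (spike-in or enriched-region
## library sizes) and the RNA-seq comparisons (median-of-ratios size
## factors): conditioning on the feature total makes the test depend only
## on library-size ratios, so any positive normalization vector plugs in.

#' NormalizationSpec: resolved per-sample library sizes under one mode
#'
#' @slot mode one of \code{"spikein"}, \code{"enriched_regions"},
#'   \code{"total"}, \code{"size_factors"}.
#' @slot librarySizes named positive numeric vector.
#' @export
setClass("NormalizationSpec",
    representation(mode = "character", librarySizes = "numeric"))

setValidity("NormalizationSpec", function(object) {
    msg <- NULL
    if (!object@mode %in% c("spikein", "enriched_regions", "total",
                            "size_factors"))
        msg <- c(msg, "unknown normalization mode")
    if (any(object@librarySizes <= 0))
        msg <- c(msg, "library sizes must be > 0")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "NormalizationSpec", function(object) {
    cat(sprintf("NormalizationSpec (%s): %s\n", object@mode,
        paste(sprintf("%s=%g", names(object@librarySizes),
                      object@librarySizes), collapse = ", ")))
})

#' @export
normMode <- function(x) x@mode

#' Spike-in library sizes
#'
#' Uses each sample's deduplicated spike-in fragment count as its library
#' size, so a global loss of target-genome signal between conditions is
#' detectable. Any zero spike-in count is fatal: with essentially no
#' spike-in material recovered (as happens for some marks), use
#' \code{\link{binomialEnrichmentLibrarySizes}} instead.
#'
#' @param spikeCounts named vector of deduplicated spike-in fragment counts
#'   per sample.
#' @return a \linkS4class{NormalizationSpec} with mode \code{"spikein"}.
#' @export
spikeinLibrarySizes <- function(spikeCounts) {
    if (any(spikeCounts <= 0))
        stop("zero spike-in fragment count for sample(s) ",
             paste(names(spikeCounts)[spikeCounts <= 0], collapse = ", "),
             "; spike-in recovery too low -- use ",
             "binomialEnrichmentLibrarySizes() (enriched-regions mode)")
    new("NormalizationSpec", mode = "spikein",
        librarySizes = as.numeric(spikeCounts) |>
            stats::setNames(names(spikeCounts)))
}

#' Enriched-region library sizes via binomial tests against both controls
#'
#' For each mark sample and each control (IgG and input), every gene body
#' is tested for enrichment with an upper-tail binomial test: with
#' \code{k_c} control fragments in the gene out of \code{N_c} total, the
#' null proportion is \code{p0 = (k_c + 0.5) / (N_c + 0.5)} and the p-value
#' is \code{P(Binomial(N_s, p0) >= k_s)}. P-values are BH-adjusted per
#' (sample, control) pair across genes; a gene is significant for a sample
#' when it passes \code{fdrCut} against \emph{both} controls, and the
#' common set is the intersection over all mark samples. Each mark sample's
#' library size is its total fragment count within the common gene set.
#'
#' @param genebodyCounts count table over gene bodies covering the mark
#'   samples and both controls, with total fragment counts as library
#'   sizes.
#' @param markSamples character vector of mark sample names.
#' @param iggId,inputId control sample names.
#' @param fdrCut FDR threshold for per-gene enrichment.
#' @return list with \code{norm} (a \linkS4class{NormalizationSpec}, mode
#'   \code{"enriched_regions"}) and \code{significantGenes}.
#' @export
binomialEnrichmentLibrarySizes <- function(genebodyCounts, markSamples,
                                           iggId, inputId, fdrCut = 0.05) {
    m <- assay(genebodyCounts, "counts")
    N <- librarySizes(genebodyCounts)
    sigPerSample <- lapply(markSamples, function(s) {
        sigBoth <- rep(TRUE, nrow(m))
        for (ctrl in c(iggId, inputId)) {
            p0 <- (m[, ctrl] + 0.5) / (N[[ctrl]] + 0.5)
            p <- stats::pbinom(m[, s] - 1L, size = round(N[[s]]), prob = p0,
                               lower.tail = FALSE)
            sigBoth <- sigBoth & bhFdr(p) <= fdrCut
        }
        sigBoth
    })
    common <- Reduce(`&`, sigPerSample)
    if (!any(common)) {
        perSample <- vapply(sigPerSample, sum, integer(1))
        stop("no gene body significantly enriched in every mark sample ",
             "(per-sample significant counts: ",
             paste(markSamples, perSample, sep = "=", collapse = ", "), ")")
    }
    sizes <- colSums(m[common, markSamples, drop = FALSE])
    list(norm = new("NormalizationSpec", mode = "enriched_regions",
                    librarySizes = as.numeric(sizes) |>
                        stats::setNames(markSamples)),
         significantGenes = rownames(m)[common])
}

## log beta-binomial pmf; rho = 0 degenerates to the binomial
.dbetabinomLog <- function(j, n, pi0, rho) {
    if (rho <= 0) return(stats::dbinom(j, n, pi0, log = TRUE))
    a <- pi0 * (1 - rho) / rho
    b <- (1 - pi0) * (1 - rho) / rho
    lchoose(n, j) + lbeta(j + a, n - j + b) - lbeta(a, b)
}

## two-sided exact p by minimum-likelihood summation (ties included)
.pTwoSidedBB <- function(yA, n, pi0, rho) {
    if (n == 0L) return(1)
    j <- 0:n
    lp <- .dbetabinomLog(j, n, pi0, rho)
    min(1, sum(exp(lp[lp <= lp[yA + 1L] + 1e-7])))
}

## pooled relative overdispersion of within-group replicate counts.
## Model: y_ij has mean mu_ij = r_i * L_j within a group and variance
## mu_ij + phi * mu_ij^2; phi is the squared-CV excess over counting
## noise, shared across features (and 0 for Poisson-consistent
## replicates). Method of moments on the Pearson statistic
## X2_ig = sum_j (y_ij - muhat_ij)^2 / muhat_ij with the library-size
## weighted rate rhat_i = sum_j y_ij / sum_j L_j, for which
## E[X2_ig] = (m_g - 1) + phi * (sum_j mu_ij - sum_j mu_ij^2 / sum_j
## mu_ij). Pooled over all features and groups with >= 2 replicates,
## floored at 0.
.estimatePhi <- function(m, libSizes, groupIdx) {
    num <- 0
    den <- 0
    for (g in groupIdx) {
        if (length(g) < 2L) next
        L <- libSizes[g]
        mg <- length(g)
        sub <- m[, g, drop = FALSE]
        rhat <- rowSums(sub) / sum(L)
        mu <- outer(rhat, L)
        use <- rhat > 0
        if (!any(use)) next
        x2 <- rowSums((sub[use, , drop = FALSE] -
                       mu[use, , drop = FALSE])^2 /
                      mu[use, , drop = FALSE])
        muTot <- rowSums(mu[use, , drop = FALSE])
        muSq <- rowSums(mu[use, , drop = FALSE]^2)
        num <- num + sum(x2 - (mg - 1))
        den <- den + sum(muTot - muSq / muTot)
    }
    if (den <= 0) return(0)
    max(0, num / den)
}

#' Exact conditional count test between two groups
#'
#' Counts are summed within each group; conditional on the feature total
#' \code{n = y_A + y_B}, the control-group count follows a
#' beta-binomial(\code{n}, \code{pi0}, \code{rho}) null with \code{pi0 =
#' L_A / (L_A + L_B)} from the summed library sizes. The beta-binomial
#' overdispersion is derived from a single pooled method-of-moments
#' estimate of the within-group replicate counts' squared-CV excess
#' \code{phi} (see details), so the test reduces to the exact conditional
#' binomial test when replicates are Poisson-consistent (\code{phi = 0}).
#' Two-sided p-values sum all outcomes no more likely than the observed
#' one; \code{log2fc} is the smoothed knockout-minus-control log ratio
#' \code{log2((y_B + 0.5)/L_B) - log2((y_A + 0.5)/L_A)}; BH-adjusted FDR
#' across features.
#'
#' @details \code{phi} is estimated once from within-group replicate
#' variability pooled over features. Because the test conditions on the
#' \emph{group-summed} total, \code{phi} is mapped per feature to the
#' conditional overdispersion by moment matching: with group-sum variances
#' \code{v_A = n*pi0*(1 + phi_A*n*pi0)} (and likewise B, where
#' \code{phi_A = phi * sum((L_j/L_A)^2)} over group-A replicates), the
#' conditional variance \code{v_A*v_B/(v_A + v_B)} determines \code{rho}
#' through \code{n*pi0*(1-pi0)*(1 + (n-1)*rho)}. With a single replicate
#' per group \code{phi} is 0 (warning).
#'
#' @param counts a count table (\code{\link{countTable}}).
#' @param groups two-level factor (or character) over the samples; the
#'   first level is the reference (control), the second the knockout.
#' @param norm a \linkS4class{NormalizationSpec}, a named numeric vector of
#'   library sizes, or NULL to use the count table's library sizes.
#' @return a \code{DataFrame} with \code{feature_id}, \code{log2fc},
#'   \code{pvalue}, \code{fdr}, \code{mean_norm} (mean counts per million
#'   library units).
#' @export
exactCountTest <- function(counts, groups, norm = NULL) {
    m <- assay(counts, "counts")
    L <- .resolveLibSizes(norm, counts)
    groups <- as.factor(groups)
    stopifnot(nlevels(groups) == 2L, length(groups) == ncol(m))
    idxA <- which(groups == levels(groups)[1])
    idxB <- which(groups == levels(groups)[2])
    stopifnot(length(idxA) >= 1L, length(idxB) >= 1L)
    yA <- rowSums(m[, idxA, drop = FALSE])
    yB <- rowSums(m[, idxB, drop = FALSE])
    LA <- sum(L[idxA]); LB <- sum(L[idxB])
    pi0 <- LA / (LA + LB)
    n <- yA + yB

    if (length(idxA) < 2L && length(idxB) < 2L) {
        warning("single replicate per group: overdispersion set to 0")
        phi <- 0
    } else {
        phi <- .estimatePhi(m, L, list(idxA, idxB))
    }
    phiA <- phi * sum((L[idxA] / LA)^2)
    phiB <- phi * sum((L[idxB] / LB)^2)
    rho <- .conditionalRho(n, pi0, phiA, phiB)

    p <- vapply(seq_along(n), function(i) {
        .pTwoSidedBB(yA[i], n[i], pi0, rho[i])
    }, numeric(1))
    log2fc <- ifelse(n == 0, 0,
                     log2((yB + 0.5) / LB) - log2((yA + 0.5) / LA))
    cpm <- sweep(m, 2, L / 1e6, "/")
    DataFrame(feature_id = rownames(m), log2fc = log2fc, pvalue = p,
              fdr = bhFdr(p), mean_norm = rowMeans(cpm),
              row.names = rownames(m))
}

## per-feature conditional overdispersion by moment matching (see
## exactCountTest details); 0 when phi is 0 or n < 2
.conditionalRho <- function(n, pi0, phiA, phiB) {
    rho <- numeric(length(n))
    ok <- n >= 2 & (phiA > 0 | phiB > 0)
    if (any(ok)) {
        nn <- n[ok]
        vA <- nn * pi0 * (1 + phiA * nn * pi0)
        vB <- nn * (1 - pi0) * (1 + phiB * nn * (1 - pi0))
        vCond <- vA * vB / (vA + vB)
        r <- (vCond / (nn * pi0 * (1 - pi0)) - 1) / (nn - 1)
        rho[ok] <- pmin(pmax(r, 0), 1 - 1e-8)
    }
    rho
}

.resolveLibSizes <- function(norm, counts) {
    L <- if (is.null(norm)) librarySizes(counts)
         else if (is(norm, "NormalizationSpec")) norm@librarySizes
         else norm
    if (!is.null(names(L)) && !is.null(colnames(counts)))
        L <- L[colnames(counts)]
    stopifnot(length(L) == ncol(counts), all(L > 0), !anyNA(L))
    L
}

#' Gene-level differential calls from feature-level results
#'
#' A gene is called decreased when any feature passing \code{fdrCut} with
#' fold change at least \code{fcCut} in the decreasing direction overlaps
#' (>= 1 bp) the gene's window; increased analogously. For promoter-mark
#' analyses the features are merged peaks and the windows are promoters;
#' for gene-body marks pass \code{features = NULL} so features map to genes
#' by id.
#'
#' @param diff a \code{DataFrame} from \code{\link{exactCountTest}}.
#' @param features \code{GRanges} parallel to \code{diff} rows (or NULL for
#'   identity mapping by feature id).
#' @param windows named \code{GRanges} of gene windows (required when
#'   \code{features} is given).
#' @param fdrCut,fcCut significance thresholds (fold change on the linear
#'   scale).
#' @return list with \code{decreased} and \code{increased} gene-id vectors.
#' @export
callDifferentialGenes <- function(diff, features = NULL, windows = NULL,
                                  fdrCut = 0.05, fcCut = 1.5) {
    lfcCut <- log2(fcCut)
    dec <- diff$fdr <= fdrCut & diff$log2fc <= -lfcCut
    inc <- diff$fdr <= fdrCut & diff$log2fc >= lfcCut
    if (is.null(features)) {
        return(list(decreased = diff$feature_id[dec],
                    increased = diff$feature_id[inc]))
    }
    stopifnot(length(features) == nrow(diff), !is.null(windows))
    geneIdsOf <- function(sel) {
        hits <- findOverlaps(features[sel], windows)
        ids <- names(windows)[S4Vectors::subjectHits(hits)]
        sort(base::unique(ids))
    }
    list(decreased = geneIdsOf(dec), increased = geneIdsOf(inc))
}

#' Median-of-ratios size factors
#'
#' Each sample's size factor is the median over genes of its count divided
#' by the gene's geometric mean across samples; genes with a zero count in
#' any sample are excluded from the median.
#'
#' @param m gene x sample count matrix.
#' @return named numeric size factors.
#' @export
medianOfRatios <- function(m) {
    keep <- rowSums(m == 0) == 0
    if (!any(keep)) stop("no gene with all-positive counts for size factors")
    logGeo <- rowMeans(log(m[keep, , drop = FALSE]))
    apply(m[keep, , drop = FALSE], 2, function(col) {
        stats::median(exp(log(col) - logGeo))
    })
}

#' RNA-seq differential expression with per-contrast DEG calling
#'
#' Filters genes with fewer than \code{minCount} fragments in every sample,
#' computes median-of-ratios size factors over the retained genes and all
#' samples, then runs \code{\link{exactCountTest}} for each knockout level
#' against the control. A gene is a DEG only when it passes the (FDR, FC)
#' thresholds in \emph{every} knockout contrast with a shared direction.
#'
#' @param counts a count table of raw gene counts.
#' @param condition factor over samples; \code{controlLevel} names the
#'   reference, every other level is tested against it.
#' @param controlLevel reference condition name.
#' @param minCount exclusion threshold: genes below it in all samples drop.
#' @param fdrCut,fcCut DEG thresholds (fold change linear scale).
#' @return list with \code{results} (per-contrast \code{DataFrame}s),
#'   \code{degDown}, \code{degUp}, \code{sizeFactors}, \code{universe}
#'   (gene ids tested).
#' @export
rnaseqDE <- function(counts, condition, controlLevel = "control",
                     minCount = 10, fdrCut = 0.05, fcCut = 2) {
    m <- assay(counts, "counts")
    condition <- as.factor(condition)
    stopifnot(controlLevel %in% levels(condition))
    keep <- apply(m, 1, max) >= minCount
    if (!any(keep)) stop("all genes filtered at minCount=", minCount)
    m <- m[keep, , drop = FALSE]
    sf <- medianOfRatios(m)
    koLevels <- setdiff(levels(condition), controlLevel)
    results <- lapply(koLevels, function(ko) {
        sel <- condition %in% c(controlLevel, ko)
        ct <- countTable(m[, sel, drop = FALSE], librarySizes = sf[sel])
        exactCountTest(ct, factor(as.character(condition[sel]),
                                  levels = c(controlLevel, ko)),
                       norm = new("NormalizationSpec", mode = "size_factors",
                                  librarySizes = sf[sel]))
    })
    names(results) <- koLevels
    lfcCut <- log2(fcCut)
    downEach <- lapply(results, function(r)
        r$feature_id[r$fdr <= fdrCut & r$log2fc <= -lfcCut])
    upEach <- lapply(results, function(r)
        r$feature_id[r$fdr <= fdrCut & r$log2fc >= lfcCut])
    list(results = results,
         degDown = sort(Reduce(intersect, downEach)),
         degUp = sort(Reduce(intersect, upEach)),
         sizeFactors = sf,
         universe = rownames(m))
}

#' Benjamini-Hochberg step-up FDR adjustment
#' @param p p-values.
#' @return adjusted values in [0, 1].
#' @export
bhFdr <- function(p) stats::p.adjust(p, method = "BH")
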