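## independent oracle: exhaustive two-sided conditional binomial test
oracleCondBinom <- function(yA, n, pi0) {
    if (n == 0) return(1)
    pmf <- choose(n, 0:n) * pi0^(0:n) * (1 - pi0)^(n - (0:n))
    sum(pmf[pmf <= pmf[yA + 1] * (1 + 1e-7)])
}

twoSampleCT <- function(yA, yB, LA = 1000, LB = 1000) {
    m <- matrix(c(yA, yB), nrow = 1,
                dimnames = list("f1", c("a1", "b1")))
    countTable(m + 0L, librarySizes = c(a1 = LA, b1 = LB))
}

test_that("exact test with rho=0 matches exhaustive conditional binomial", {
    grp <- factor(c("control", "knockout"), levels = c("control",
                                                       "knockout"))
    for (n in c(0:12, 20, 35, 50)) {
        for (yA in unique(round(seq(0, n, length.out = 6)))) {
            for (ratio in c(1, 2.5)) {
                ct <- twoSampleCT(yA, n - yA, LA = 1000 * ratio)
                pi0 <- 1000 * ratio / (1000 * ratio + 1000)
                res <- suppressWarnings(exactCountTest(ct, grp))
                expect_equal(res$pvalue, oracleCondBinom(yA, n, pi0),
                             tolerance = 1e-12,
                             label = sprintf("n=%d yA=%d r=%g", n, yA,
                                             ratio))
            }
        }
    }
})

test_that("symmetric null and extreme splits give the textbook p-values", {
    grp <- factor(c("control", "knockout"), levels = c("control",
                                                       "knockout"))
    ## balanced observation at equal library sizes: p = 1
    res <- suppressWarnings(exactCountTest(twoSampleCT(5, 5), grp))
    expect_equal(res$pvalue, 1)
    expect_equal(unname(res$log2fc), 0)
    ## all 10 counts on one side: p = 2 * 0.5^10
    res <- suppressWarnings(exactCountTest(twoSampleCT(0, 10), grp))
    expect_equal(res$pvalue, 2 * 0.5^10, tolerance = 1e-12)
    expect_gt(res$log2fc, 0)
    ## zero total: p = 1, log2fc = 0
    res <- suppressWarnings(exactCountTest(twoSampleCT(0, 0), grp))
    expect_equal(res$pvalue, 1)
    expect_equal(unname(res$log2fc), 0)
})

test_that("single replicate per group warns and uses rho = 0", {
    expect_warning(
        exactCountTest(twoSampleCT(3, 7),
                       factor(c("control", "knockout"))),
        "single replicate")
})

test_that("p-values are invariant to rescaling the library-size vector", {
    set.seed(13)
    m <- matrix(rpois(400, 60), ncol = 4,
                dimnames = list(sprintf("f%d", 1:100),
                                c("c1", "c2", "k1", "k2")))
    L <- c(c1 = 900, c2 = 1100, k1 = 1000, k2 = 950)
    grp <- factor(c("control", "control", "knockout", "knockout"))
    r1 <- exactCountTest(countTable(m, L), grp)
    r10 <- exactCountTest(countTable(m, L * 10), grp)
    expect_equal(r1$pvalue, r10$pvalue, tolerance = 1e-12)
    expect_equal(r1$log2fc, r10$log2fc, tolerance = 1e-12)
})

test_that("spike-in library sizes pass through and reject zeros", {
    spec <- spikeinLibrarySizes(c(a = 1000, b = 1000, c = 500, d = 500))
    expect_equal(normMode(spec), "spikein")
    expect_equal(spec@librarySizes, c(a = 1000, b = 1000, c = 500,
                                      d = 500))
    expect_error(spikeinLibrarySizes(c(a = 1000, b = 0)),
                 "enriched")
})

test_that("binomial enrichment p-value matches the exact tail and Monte Carlo", {
    ## k_s = 30 of N_s = 1000 vs k_c = 10 of N_c = 1000
    p0 <- (10 + 0.5) / (1000 + 0.5)
    want <- sum(choose(1000, 30:1000) * p0^(30:1000) *
                (1 - p0)^(1000 - (30:1000)))
    expect_equal(pbinom(29, 1000, p0, lower.tail = FALSE), want,
                 tolerance = 1e-10)
    set.seed(99)
    mc <- mean(rbinom(1e6, 1000, p0) >= 30)
    expect_equal(want, mc, tolerance = 4 * sqrt(want / 1e6) / want)
})

test_that("binomial enrichment finds planted genes and resists nulls", {
    set.seed(17)
    nGenes <- 200
    ## controls: uniform expectation; mark samples enriched in 40 genes
    base <- rpois(nGenes, 50)
    enriched <- seq_len(40)
    mkSample <- function(boost) {
        mu <- base + ifelse(seq_len(nGenes) %in% enriched, boost, 0)
        rpois(nGenes, mu)
    }
    m <- cbind(s1 = mkSample(300), s2 = mkSample(300),
               igg = rpois(nGenes, base), input = rpois(nGenes, base))
    rownames(m) <- sprintf("g%03d", seq_len(nGenes))
    ct <- countTable(m, librarySizes = colSums(m))
    enr <- binomialEnrichmentLibrarySizes(ct, markSamples = c("s1", "s2"),
                                          iggId = "igg", inputId = "input")
    found <- enr$significantGenes
    expect_gte(length(intersect(found, rownames(m)[enriched])), 36)
    expect_lte(length(setdiff(found, rownames(m)[enriched])), 2)
    expect_equal(normMode(enr$norm), "enriched_regions")
    expect_equal(unname(enr$norm@librarySizes),
                 unname(colSums(m[found, c("s1", "s2")])))

    ## a sample identical to its controls yields no significant genes
    mNull <- cbind(s1 = base, igg = base, input = base)
    rownames(mNull) <- rownames(m)
    ctNull <- countTable(mNull, librarySizes = colSums(mNull))
    expect_error(binomialEnrichmentLibrarySizes(ctNull,
                                                markSamples = "s1",
                                                iggId = "igg",
                                                inputId = "input"),
                 "no gene body")
})

test_that("BH adjustment follows the step-up rule", {
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
    expect_equal(bhFdr(0.03), 0.03)
})

test_that("median-of-ratios matches the independent implementation", {
    set.seed(31)
    ## odd gene count so the median is an exact order statistic in both
    ## implementations
    m <- matrix(rnbinom(101 * 6, mu = 200, size = 5), ncol = 6)
    m <- t(t(m) * c(1, 2, 0.5, 1.5, 1, 0.8))
    storage.mode(m) <- "integer"
    rownames(m) <- sprintf("g%d", 1:101)
    sf <- medianOfRatios(m)
    skip_if_not_installed("DESeq2")
    ref <- DESeq2::estimateSizeFactorsForMatrix(m)
    expect_equal(unname(sf), unname(ref), tolerance = 1e-8)
})

test_that("RNA-seq gene filter drops only genes low in every sample", {
    m <- rbind(allLow = c(9L, 9L, 9L, 9L, 9L, 9L),
               oneOk = c(9L, 9L, 12L, 9L, 9L, 9L),
               high = c(100L, 120L, 90L, 110L, 95L, 105L))
    colnames(m) <- c("control_1", "control_2", "control_3",
                     "ko1_1", "ko1_2", "ko1_3")
    cond <- factor(rep(c("control", "ko1"), each = 3))
    res <- rnaseqDE(countTable(m), cond)
    expect_setequal(res$universe, c("oneOk", "high"))
    expect_error(rnaseqDE(countTable(m["allLow", , drop = FALSE]), cond),
                 "filtered")
})

test_that("identical samples give unit size factors and null p-values", {
    m <- matrix(rep(c(40L, 200L, 1000L), 4), ncol = 4,
                dimnames = list(c("a", "b", "c"), c("c1", "c2", "k1",
                                                    "k2")))
    cond <- factor(c("control", "control", "ko1", "ko1"))
    res <- rnaseqDE(countTable(m), cond)
    expect_equal(unname(res$sizeFactors), rep(1, 4))
    expect_true(all(res$results$ko1$pvalue > 1 - 1e-9))
    expect_equal(res$degDown, character(0))
})

test_that("DEGs require passing every knockout contrast with one direction", {
    mk <- function(lfc2, lfc3) {
        DataFrame(feature_id = c("g1", "g2"),
                  log2fc = c(lfc2, lfc3), pvalue = c(1e-4, 1e-4),
                  fdr = c(1e-3, 1e-3), mean_norm = c(10, 10))
    }
    ## g1 down in both contrasts, g2 down in one and up in the other
    res <- degSets(list(ko1 = mk(-2, -2), ko2 = mk(-3, 2)), fcCut = 2)
    expect_equal(res$down, "g1")
    expect_equal(res$up, character(0))
})

test_that("gene-level differential calls honour thresholds and overlap", {
    features <- GRanges("c", IRanges(c(101, 5001, 9001),
                                     c(200, 5100, 9100)))
    windows <- GRanges("c", IRanges(c(151, 5101), c(250, 5200)))
    names(windows) <- c("gHit", "gMiss")
    diff <- DataFrame(feature_id = c("p1", "p2", "p3"),
                      log2fc = c(-1, -0.4, -2),
                      pvalue = c(1e-4, 1e-4, 1e-4),
                      fdr = c(0.01, 0.01, 0.01),
                      mean_norm = c(5, 5, 5))
    calls <- callDifferentialGenes(diff, features = features,
                                   windows = windows)
    ## p1 (FC 2) overlaps gHit's window by 50 bp; p2 fails FC 1.5;
    ## p3 is significant but overlaps no window
    expect_equal(calls$decreased, "gHit")
    expect_equal(calls$increased, character(0))
    ## 1-bp overlap at the boundary still counts
    edge <- GRanges("c", IRanges(250, 400))
    callsEdge <- callDifferentialGenes(
        DataFrame(feature_id = "e", log2fc = -1, pvalue = 1e-4,
                  fdr = 0.01, mean_norm = 1),
        features = edge, windows = windows)
    expect_equal(callsEdge$decreased, "gHit")
    ## identity mapping for gene-body features
    idCalls <- callDifferentialGenes(diff)
    expect_setequal(idCalls$decreased, c("p1", "p3"))
})
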