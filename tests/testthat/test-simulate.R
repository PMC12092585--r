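test_that("simulated annotation packs non-overlapping stranded genes", {
    cfg <- simulationConfig(nGenes = 50L, chromSizes = c(c1 = 2e6))
    ann <- simulateAnnotation(cfg)
    g <- genes(ann)
    expect_equal(length(g), 50L)
    expect_true(isDisjoint(g))
    ## at least 1 kb between neighbours
    gaps <- start(g)[-1] - end(g)[-length(g)]
    expect_true(all(gaps >= 1000))
    expect_true(all(width(g) >= 2000 & width(g) <= 20000))
    expect_true(all(as.character(strand(g)) %in% c("+", "-")))

    ann2 <- simulateAnnotation(cfg)
    expect_identical(granges(genes(ann)), granges(genes(ann2)))

    tooMany <- simulationConfig(nGenes = 300L, chromSizes = c(c1 = 1e6))
    expect_error(simulateAnnotation(tooMany), "cannot pack")
})

test_that("truth table plants one class per gene at the configured rates", {
    cfg <- smallConfig()
    ann <- simulateAnnotation(cfg)
    truth <- simulateTruth(cfg, ann)
    expect_equal(nrow(truth), 30L)
    expect_true(all(truth$class %in% paste0("C", 1:5)))
    tab <- table(truth$class)
    expect_equal(unname(tab[c("C1", "C2", "C3")]), rep(2L, 3),
                 ignore_attr = TRUE)
    ## planted mark effects follow the class definitions
    lf <- log2(cfg@knockoutLossFactor)
    expect_true(all(truth$k4_lfc[truth$class == "C1"] == -lf))
    expect_true(all(truth$k36_lfc[truth$class == "C2"] == 0))
    expect_true(all(truth$k4_lfc[truth$class == "C5"] == 0))
    ## RNA losses only on mark-loss genes
    expect_true(all(truth$class[truth$rna_lfc != 0] %in%
                    c("C1", "C2", "C3")))
})

test_that("same config reproduces byte-identical fragments and counts", {
    cfg <- smallConfig()
    ann <- simulateAnnotation(cfg)
    truth <- simulateTruth(cfg, ann)
    a <- simulateCutrun(cfg, ann, truth, "H3K4me3")
    b <- simulateCutrun(cfg, ann, truth, "H3K4me3")
    expect_identical(granges(a$samples[[1]]), granges(b$samples[[1]]))
    expect_identical(granges(a$spikein[[1]]), granges(b$spikein[[1]]))
    tmp1 <- withr::local_tempfile(); tmp2 <- withr::local_tempfile()
    writeFragmentsBedpe(a$samples[[1]], tmp1)
    writeFragmentsBedpe(b$samples[[1]], tmp2)
    expect_identical(readLines(tmp1), readLines(tmp2))
    r1 <- simulateRnaseq(cfg, truth)
    r2 <- simulateRnaseq(cfg, truth)
    expect_identical(assay(r1$counts), assay(r2$counts))
})

test_that("promoter fragment counts drop by the loss factor in knockout", {
    ## one affected gene, high enrichment: its promoter counts drop by
    ## the loss factor (up to the small change in total intensity)
    cfg <- simulationConfig(nGenes = 10L, chromSizes = c(c1 = 1e6),
                            fragmentsPerSample = 200000L,
                            enrichmentFactor = 200,
                            classFractions = c(C1 = 0, C2 = 0.1, C3 = 0,
                                               C4 = 0),
                            knockoutLossFactor = 4)
    ann <- simulateAnnotation(cfg)
    truth <- simulateTruth(cfg, ann)
    sim <- simulateCutrun(cfg, ann, truth, "H3K4me3")
    prom <- promoterWindows(ann)
    affected <- truth$gene_id[truth$class == "C2"]
    expect_length(affected, 1L)
    ctrl <- suppressWarnings(countFragments(
        sim$samples[["H3K4me3_control_rep1"]], prom))
    ko <- suppressWarnings(countFragments(
        sim$samples[["H3K4me3_knockout_rep1"]], prom))
    ratio <- ctrl[affected] / ko[affected]
    ## allocation-weight prediction: 4 scaled by the intensity shift
    G <- sum(chromSizes(ann))
    w <- 200 * 1000
    iCtrl <- G + 10 * w
    iKo <- G + 9 * w + w / 4
    expect_equal(unname(ratio), 4 * iKo / iCtrl, tolerance = 0.06)
})

test_that("H3K36me3 midpoint density ramps toward the TES", {
    cfg <- simulationConfig(nGenes = 5L, chromSizes = c(c1 = 5e5),
                            fragmentsPerSample = 100000L,
                            enrichmentFactor = 100,
                            classFractions = c(C1 = 0, C2 = 0, C3 = 0,
                                               C4 = 0))
    ann <- simulateAnnotation(cfg)
    truth <- simulateTruth(cfg, ann)
    sim <- simulateCutrun(cfg, ann, truth, "H3K36me3")
    fs <- sim$samples[["H3K36me3_control_rep1"]]
    bodies <- geneBodies(ann)
    ## compare first and last thirds of each body in transcription order
    tx <- longestTranscript(ann)
    minus <- as.character(strand(tx)) == "-"
    mid0 <- (start(fs) - 1 + end(fs)) %/% 2
    for (i in seq_along(bodies)) {
        s0 <- start(bodies)[i] - 1; e0 <- end(bodies)[i]
        len <- e0 - s0
        inBody <- mid0 >= s0 & mid0 < e0 &
            as.character(seqnames(fs)) == as.character(seqnames(bodies))[i]
        t <- if (minus[i]) (e0 - mid0[inBody]) else (mid0[inBody] - s0)
        early <- sum(t < len / 3)
        late <- sum(t >= 2 * len / 3)
        ## linear ramp: last third carries ~5x the mass of the first
        expect_gt(late, 3 * early)
    }
})

test_that("controls are background-only and spike-in tracks global loss", {
    cfg <- simulationConfig(nGenes = 20L, chromSizes = c(c1 = 1e6),
                            fragmentsPerSample = 100000L,
                            enrichmentFactor = 50,
                            classFractions = c(C1 = 0, C2 = 1, C3 = 0,
                                               C4 = 0),
                            knockoutLossFactor = 2)
    ann <- simulateAnnotation(cfg)
    truth <- simulateTruth(cfg, ann)
    sim <- simulateCutrun(cfg, ann, truth, "H3K4me3")
    ## IgG density at promoters matches the genome average
    igg <- sim$samples[["H3K4me3_IgG"]]
    prom <- promoterWindows(ann)
    inProm <- sum(suppressWarnings(countFragments(igg, prom)))
    expected <- length(igg) * (sum(width(prom)) / 1e6)
    expect_equal(inProm, expected, tolerance = 0.15)
    ## knockout loses global signal, so its spike-in share is larger
    nSpikeCtrl <- length(sim$spikein[["H3K4me3_control_rep1"]])
    nSpikeKo <- length(sim$spikein[["H3K4me3_knockout_rep1"]])
    expect_gt(nSpikeKo, nSpikeCtrl * 1.2)
})

test_that("RNA-seq counts follow the planted NB model", {
    ## Poisson limit: dispersion ~ 0 and no effects -> variance ~ mean
    cfg <- simulationConfig(nGenes = 200L, chromSizes = c(c1 = 5e6),
                            rnaseqDispersion = 1e-4,
                            classFractions = c(C1 = 0, C2 = 0, C3 = 0,
                                               C4 = 0),
                            rnaseqReplicates = 20L)
    ann <- simulateAnnotation(cfg)
    truth <- simulateTruth(cfg, ann)
    rs <- simulateRnaseq(cfg, truth)
    m <- assay(rs$counts)[, rs$condition == "control"]
    sf <- exp(colMeans(log(m + 0.5)))
    norm <- t(t(m) / (sf / mean(sf)))
    ratio <- apply(norm, 1, var) / rowMeans(norm)
    ## variance/mean near 1 on average across genes (Poisson limit)
    expect_equal(median(ratio), 1, tolerance = 0.2)

    ## planted lfc -2: knockout/control normalized ratio ~ 0.25
    cfg2 <- simulationConfig(nGenes = 100L, chromSizes = c(c1 = 2.5e6),
                             rnaseqDispersion = 0.05,
                             rnaseqReplicates = 10L, rnaseqLfc = -2)
    ann2 <- simulateAnnotation(cfg2)
    truth2 <- simulateTruth(cfg2, ann2)
    rs2 <- simulateRnaseq(cfg2, truth2)
    m2 <- assay(rs2$counts)
    sf2 <- medianOfRatios(m2)
    norm2 <- t(t(m2) / sf2)
    planted <- truth2$rna_lfc != 0
    obs <- rowMeans(norm2[planted, rs2$condition != "control"]) /
        rowMeans(norm2[planted, rs2$condition == "control"])
    expect_equal(mean(obs), 0.25, tolerance = 0.08)
})

test_that("spike-in normalization recovers a global loss that total-count misses", {
    ## every gene loses its mark 2-fold: with total-count normalization
    ## the knockout looks almost unchanged, with spike-in sizes the loss
    ## is recovered
    cfg <- simulationConfig(nGenes = 40L, chromSizes = c(c1 = 1.5e6),
                            fragmentsPerSample = 150000L,
                            enrichmentFactor = 200,
                            classFractions = c(C1 = 0, C2 = 1, C3 = 0,
                                               C4 = 0),
                            knockoutLossFactor = 2)
    ann <- simulateAnnotation(cfg)
    truth <- simulateTruth(cfg, ann)
    sim <- simulateCutrun(cfg, ann, truth, "H3K4me3")
    markIds <- names(sim$conditions)
    dedup <- lapply(sim$samples[markIds], deduplicate)
    prom <- promoterWindows(ann)
    cond <- factor(sim$conditions[markIds],
                   levels = c("control", "knockout"))
    spikeSizes <- vapply(lapply(sim$spikein[markIds], deduplicate),
                         length, integer(1))
    ctSpike <- suppressWarnings(buildCountTable(dedup, prom,
                                                librarySizes = spikeSizes))
    resSpike <- exactCountTest(ctSpike, cond)
    totalSizes <- vapply(dedup, length, integer(1))
    ctTotal <- suppressWarnings(buildCountTable(dedup, prom,
                                                librarySizes = totalSizes))
    resTotal <- exactCountTest(ctTotal, cond)
    decSpike <- sum(resSpike$fdr <= 0.05 & resSpike$log2fc <= -log2(1.5))
    decTotal <- sum(resTotal$fdr <= 0.05 & resTotal$log2fc <= -log2(1.5))
    expect_gte(decSpike, 0.9 * 40)
    expect_lte(decTotal, 4)
    ## spike-normalized fold change centres on the planted 2-fold loss
    expect_equal(median(resSpike$log2fc), -1, tolerance = 0.15)
})
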