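## Synthetic CUT&RUN + RNA-seq generator with planted ground truth. The
## generator emulates the statistical structure the analysis assumes: a
## promoter-peaked mark (H3K4me3, Gaussian midpoints around the TSS), a
## gene-body mark ramping toward the TES (H3K36me3, linear density),
## uniform background, background-only IgG/input controls, a constant
## per-cell spike-in so that global signal loss is visible only through
## spike-in normalization, and negative-binomial RNA-seq counts whose
## planted fold changes are linked to the planted mark losses.

#' Simulation configuration
#'
#' All tunables of the synthetic experiment in one validated object.
#' Defaults describe the reference desk-scale experiment: 300
#' non-overlapping genes on two 2.5-Mb chromosomes, 2 CUT&RUN replicates
#' per condition at 200,000 fragments per sample, 8-fold mark enrichment,
#' 4-fold knockout loss on affected genes, 3 RNA-seq replicates for a
#' control and two knockout guides with NB dispersion 0.1.
#'
#' @slot seed integer seed; identical configs give identical output.
#' @slot nGenes number of genes.
#' @slot chromSizes named chromosome lengths of the target genome (bp).
#' @slot spikeChromSizes spike-in genome chromosome lengths (bp).
#' @slot cutrunReplicates replicates per condition per mark.
#' @slot rnaseqReplicates replicates per RNA-seq condition.
#' @slot fragmentsPerSample target-genome fragments drawn per sample.
#' @slot spikeinFraction spike-in material relative to the control
#'   condition's per-cell target signal.
#' @slot enrichmentFactor fold enrichment of a marked region over
#'   background density.
#' @slot knockoutLossFactor fold loss of mark signal on affected genes.
#' @slot classFractions named fractions of genes planted per class
#'   C1..C4 (C5 is the remainder).
#' @slot rnaDownFraction fraction of planted C1-C3 genes also planted as
#'   transcriptionally downregulated.
#' @slot tfBoundFraction fraction of RNA-down mark-loss genes bound by the
#'   simulated TF.
#' @slot fragmentLengthMean,fragmentLengthSd fragment length model (bp),
#'   clipped to [50, 500].
#' @slot promoterSd Gaussian spread of promoter-mark midpoints (bp).
#' @slot rnaseqDispersion NB dispersion of RNA-seq counts.
#' @slot rnaseqLfc planted RNA log2 fold change of downregulated genes.
#' @export
setClass("SimulationConfig", representation(
    seed = "integer", nGenes = "integer", chromSizes = "numeric",
    spikeChromSizes = "numeric", cutrunReplicates = "integer",
    rnaseqReplicates = "integer", fragmentsPerSample = "integer",
    spikeinFraction = "numeric", enrichmentFactor = "numeric",
    knockoutLossFactor = "numeric", classFractions = "numeric",
    rnaDownFraction = "numeric", tfBoundFraction = "numeric",
    fragmentLengthMean = "numeric", fragmentLengthSd = "numeric",
    promoterSd = "numeric", rnaseqDispersion = "numeric",
    rnaseqLfc = "numeric"))

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    fr <- c(object@spikeinFraction, object@classFractions,
            object@rnaDownFraction, object@tfBoundFraction)
    if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must be in [0, 1]")
    if (sum(object@classFractions) > 1)
        msg <- c(msg, "class fractions must sum to <= 1")
    if (object@enrichmentFactor <= 1 || object@knockoutLossFactor <= 1)
        msg <- c(msg, "enrichment and loss factors must be > 1")
    if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' @rdname SimulationConfig-class
#' @param seed,nGenes,chromSizes,spikeChromSizes,cutrunReplicates
#'   see slots.
#' @param rnaseqReplicates,fragmentsPerSample,spikeinFraction see slots.
#' @param enrichmentFactor,knockoutLossFactor,classFractions see slots.
#' @param rnaDownFraction,tfBoundFraction,fragmentLengthMean see slots.
#' @param fragmentLengthSd,promoterSd,rnaseqDispersion,rnaseqLfc see slots.
#' @export
simulationConfig <- function(seed = 1L, nGenes = 300L,
        chromSizes = c(chrS1 = 2.5e6, chrS2 = 2.5e6),
        spikeChromSizes = c(spike_I = 5e5),
        cutrunReplicates = 2L, rnaseqReplicates = 3L,
        fragmentsPerSample = 200000L, spikeinFraction = 0.05,
        enrichmentFactor = 8, knockoutLossFactor = 4,
        classFractions = c(C1 = 0.05, C2 = 0.05, C3 = 0.05, C4 = 0.03),
        rnaDownFraction = 0.6, tfBoundFraction = 0.8,
        fragmentLengthMean = 180, fragmentLengthSd = 30, promoterSd = 200,
        rnaseqDispersion = 0.1, rnaseqLfc = -2) {
    new("SimulationConfig", seed = as.integer(seed),
        nGenes = as.integer(nGenes), chromSizes = chromSizes,
        spikeChromSizes = spikeChromSizes,
        cutrunReplicates = as.integer(cutrunReplicates),
        rnaseqReplicates = as.integer(rnaseqReplicates),
        fragmentsPerSample = as.integer(fragmentsPerSample),
        spikeinFraction = spikeinFraction,
        enrichmentFactor = enrichmentFactor,
        knockoutLossFactor = knockoutLossFactor,
        classFractions = classFractions,
        rnaDownFraction = rnaDownFraction,
        tfBoundFraction = tfBoundFraction,
        fragmentLengthMean = fragmentLengthMean,
        fragmentLengthSd = fragmentLengthSd, promoterSd = promoterSd,
        rnaseqDispersion = rnaseqDispersion, rnaseqLfc = rnaseqLfc)
}

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0(
        "SimulationConfig: seed %d, %d genes, %d frags/sample, ",
        "enrichment x%g, knockout loss x%g\n"),
        object@seed, object@nGenes, object@fragmentsPerSample,
        object@enrichmentFactor, object@knockoutLossFactor))
})

## independent sub-seeds per generator stage so stage calls are
## order-insensitive; kept well below 2^31
.stageSeed <- function(config, stage) {
    offsets <- c(annotation = 11L, truth = 23L, cutrun = 37L, rnaseq = 53L,
                 tf = 71L)
    (config@seed * 1009L + offsets[[stage]]) %% 2147483L
}

#' Simulate a gene annotation
#'
#' Places \code{nGenes} non-overlapping genes with random strand, body
#' lengths uniform in [2 kb, 20 kb] and at least 1 kb between neighbours;
#' each gene gets its body as longest transcript plus occasionally a
#' shorter nested transcript. Fails when the genes cannot be packed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{GenomeAnnotation}.
#' @export
simulateAnnotation <- function(config) {
    set.seed(.stageSeed(config, "annotation"))
    n <- config@nGenes
    sizes <- config@chromSizes
    lens <- round(stats::runif(n, 2000, 20000))
    ## genes per chromosome proportional to its size
    chromOf <- sort(sample(names(sizes), n, replace = TRUE,
                           prob = sizes / sum(sizes)))
    starts0 <- integer(n)
    for (chr in names(sizes)) {
        idx <- which(chromOf == chr)
        if (!length(idx)) next
        need <- sum(lens[idx]) + 1000 * (length(idx) + 1)
        if (need > sizes[[chr]])
            stop("cannot pack ", length(idx), " genes into ", chr,
                 " (need ", need, " bp, have ", sizes[[chr]], ")")
        slack <- sizes[[chr]] - need
        cuts <- sort(stats::runif(length(idx)))
        extra <- floor(diff(c(0, cuts)) * slack)
        gaps <- 1000 + extra
        starts0[idx] <- cumsum(gaps) + cumsum(c(0, lens[idx]))[-(length(idx) + 1)]
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    ids <- sprintf("gene%03d", seq_len(n))
    genes <- GRanges(chromOf, IRanges(starts0 + 1L, starts0 + lens),
                     strand = strand, gene_id = ids,
                     seqinfo = Seqinfo(names(sizes), as.integer(sizes)))
    ## body = longest transcript; some genes carry a shorter nested one
    txl <- lapply(seq_len(n), function(i) {
        tx <- granges(genes[i])
        if (stats::runif(1) < 0.3 && lens[i] > 4000) {
            off <- round(stats::runif(1, 500, lens[i] / 2))
            short <- GRanges(chromOf[i],
                             IRanges(starts0[i] + off + 1L,
                                     starts0[i] + lens[i] - 500L),
                             strand = strand[i], seqinfo = seqinfo(genes))
            tx <- c(tx, short)
        }
        tx
    })
    txl <- GenomicRanges::GRangesList(txl)
    GenomeAnnotation(genes, transcripts = txl)
}

#' Plant per-gene truth classes and effects
#'
#' Assigns each gene one class: C1 (both marks lost in knockout), C2
#' (H3K4me3 lost only), C3 (H3K36me3 lost only), C4 (a mark gained) or C5
#' (no change), by the configured fractions; plants the RNA fold change on
#' a fraction of the C1-C3 genes, and a TF-bound flag enriched among
#' those. Mark log2 fold changes follow the knockout loss factor.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @return a \code{DataFrame} (the truth table), one row per gene, with
#'   \code{class}, \code{k4_lfc}, \code{k36_lfc}, \code{rna_lfc},
#'   \code{tf_bound}.
#' @export
simulateTruth <- function(config, annotation) {
    set.seed(.stageSeed(config, "truth"))
    ids <- geneIds(annotation)
    n <- length(ids)
    counts <- round(config@classFractions * n)
    cls <- rep("C5", n)
    planted <- sample(n, sum(counts))
    cls[planted] <- rep(names(counts), times = counts)
    lf <- log2(config@knockoutLossFactor)
    k4 <- ifelse(cls %in% c("C1", "C2"), -lf, ifelse(cls == "C4", lf, 0))
    k36 <- ifelse(cls %in% c("C1", "C3"), -lf, 0)
    rna <- rep(0, n)
    lossIdx <- which(cls %in% c("C1", "C2", "C3"))
    dn <- sample(lossIdx, round(config@rnaDownFraction * length(lossIdx)))
    rna[dn] <- config@rnaseqLfc
    tf <- rep(FALSE, n)
    tf[dn] <- stats::runif(length(dn)) < config@tfBoundFraction
    tf[-dn] <- stats::runif(n - length(dn)) < 0.1
    DataFrame(gene_id = ids, class = cls, k4_lfc = k4, k36_lfc = k36,
              rna_lfc = rna, tf_bound = tf, row.names = ids)
}

## per-gene allocation weights for one mark/condition; background weight
## is the genome length (density 1 per bp)
.markWeights <- function(config, annotation, truth, mark, condition) {
    tt <- .tssTes(annotation)
    L <- abs(tt$tes0 - tt$tss0)
    base <- if (mark == "H3K4me3") {
        config@enrichmentFactor * 1000
    } else {
        config@enrichmentFactor * L
    }
    lfc <- if (mark == "H3K4me3") truth$k4_lfc else truth$k36_lfc
    w <- rep(base, length.out = length(L))
    if (condition == "knockout") w <- w * 2^lfc
    w
}

#' Simulate CUT&RUN fragments for one mark
#'
#' Draws \code{fragmentsPerSample} fragments per sample by allocating each
#' fragment to uniform background (weight: genome length) or to a gene
#' (weight: enrichment footprint, divided by the loss factor in knockout
#' for affected genes). H3K4me3 midpoints are Normal(TSS, promoterSd);
#' H3K36me3 midpoints ramp linearly from the TSS to the TES of the gene
#' body. Fragment lengths are Normal(180, 30) clipped to [50, 500]. IgG
#' and input samples are background-only. Per-sample spike-in fragments
#' are generated on the spike genome with a count inversely proportional
#' to the condition's total per-cell target intensity, so that a global
#' loss of target signal shows up as a higher spike-in share.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param truth truth table from \code{\link{simulateTruth}}.
#' @param mark \code{"H3K4me3"} or \code{"H3K36me3"}.
#' @return list with \code{samples} (named list of target-genome
#'   \linkS4class{FragmentSet}s for mark replicates, IgG and input),
#'   \code{spikein} (parallel spike-in \linkS4class{FragmentSet}s for the
#'   mark replicates) and \code{conditions} (named condition per mark
#'   sample).
#' @export
simulateCutrun <- function(config, annotation, truth,
                           mark = c("H3K4me3", "H3K36me3")) {
    mark <- match.arg(mark)
    markOff <- if (mark == "H3K4me3") 0L else 1L
    set.seed(.stageSeed(config, "cutrun") + markOff)
    tt <- .tssTes(annotation)
    L <- abs(tt$tes0 - tt$tss0)
    if (mark == "H3K4me3") {
        tooShort <- which(L < 2 * config@promoterSd)
        if (length(tooShort))
            warning(length(tooShort), " gene(s) shorter than twice the ",
                    "promoter spread skipped for enrichment")
    } else tooShort <- integer(0)
    G <- sum(config@chromSizes)
    N <- config@fragmentsPerSample
    chroms <- as.character(seqnames(tt$tx))
    dir <- ifelse(tt$minus, -1, 1)

    intensity <- function(condition) {
        w <- .markWeights(config, annotation, truth, mark, condition)
        w[tooShort] <- 0
        list(w = w, total = G + sum(w))
    }
    ctrlIntensity <- intensity("control")

    drawSample <- function(condition, label) {
        it <- intensity(condition)
        comp <- sample.int(length(it$w) + 1L, N, replace = TRUE,
                           prob = c(G, it$w)) - 1L
        mids <- numeric(N)
        chr <- character(N)
        bg <- comp == 0L
        if (any(bg)) {
            u <- .uniformPositions(config@chromSizes, sum(bg))
            chr[bg] <- u$chr
            mids[bg] <- u$pos
        }
        gi <- comp[!bg]
        if (length(gi)) {
            chr[!bg] <- chroms[gi]
            if (mark == "H3K4me3") {
                mids[!bg] <- stats::rnorm(length(gi), mean = tt$tss0[gi],
                                          sd = config@promoterSd)
            } else {
                t <- L[gi] * sqrt(stats::runif(length(gi)))
                mids[!bg] <- tt$tss0[gi] + dir[gi] * t
            }
        }
        lens <- pmin(pmax(round(stats::rnorm(N, config@fragmentLengthMean,
                                             config@fragmentLengthSd)),
                          50), 500)
        .fragmentsFromMidpoints(chr, mids, lens, config@chromSizes, label)
    }

    drawSpike <- function(condition, label) {
        it <- intensity(condition)
        nSpike <- round(N * config@spikeinFraction *
                        ctrlIntensity$total / it$total)
        u <- .uniformPositions(config@spikeChromSizes, nSpike)
        lens <- pmin(pmax(round(stats::rnorm(nSpike,
                                             config@fragmentLengthMean,
                                             config@fragmentLengthSd)),
                          50), 500)
        .fragmentsFromMidpoints(u$chr, u$pos, lens, config@spikeChromSizes,
                                label, genomeTag = "spikein")
    }

    samples <- list()
    spikes <- list()
    conditions <- character(0)
    for (cond in c("control", "knockout")) {
        for (r in seq_len(config@cutrunReplicates)) {
            id <- sprintf("%s_%s_rep%d", mark, cond, r)
            samples[[id]] <- drawSample(cond, id)
            spikes[[id]] <- drawSpike(cond, id)
            conditions[id] <- cond
        }
    }
    for (ctrl in c("IgG", "input")) {
        id <- sprintf("%s_%s", mark, ctrl)
        u <- .uniformPositions(config@chromSizes, N)
        lens <- pmin(pmax(round(stats::rnorm(N, config@fragmentLengthMean,
                                             config@fragmentLengthSd)),
                          50), 500)
        samples[[id]] <- .fragmentsFromMidpoints(u$chr, u$pos, lens,
                                                 config@chromSizes, id)
    }
    list(samples = samples, spikein = spikes, conditions = conditions)
}

## uniform (chrom, 0-based midpoint) over a genome
.uniformPositions <- function(chromSizes, n) {
    if (n == 0) return(list(chr = character(0), pos = numeric(0)))
    chr <- sample(names(chromSizes), n, replace = TRUE,
                  prob = chromSizes / sum(chromSizes))
    pos <- floor(stats::runif(n) * chromSizes[chr])
    list(chr = chr, pos = pos)
}

## assemble fragments from midpoints and lengths, clipped to chromosomes
.fragmentsFromMidpoints <- function(chr, mids0, lens, chromSizes, sampleId,
                                    genomeTag = "target") {
    start0 <- round(mids0 - lens / 2)
    end0 <- start0 + lens
    maxLen <- chromSizes[chr]
    start0 <- pmax(start0, 0)
    end0 <- pmin(end0, maxLen)
    keep <- end0 - start0 >= 1
    gr <- GRanges(chr[keep], IRanges(start0[keep] + 1L, end0[keep]),
                  seqinfo = Seqinfo(names(chromSizes),
                                    as.integer(chromSizes)))
    FragmentSet(gr, sampleId = sampleId, genomeTag = genomeTag,
                deduplicated = FALSE)
}

#' Simulate the RNA-seq count table
#'
#' Gene counts are negative binomial with mean \code{s_j * mu_g *
#' 2^(rna_lfc_g)} in knockout samples (both guides share the planted
#' effect), NB dispersion from the config, per-sample size factors
#' log-uniform in [0.5, 2], and baseline expression log-normal around 300
#' counts. Conditions are \code{control}, \code{ko1}, \code{ko2} with
#' \code{rnaseqReplicates} samples each.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param truth truth table from \code{\link{simulateTruth}}.
#' @return list with \code{counts} (a count table) and \code{condition}
#'   (factor over its samples).
#' @export
simulateRnaseq <- function(config, truth) {
    set.seed(.stageSeed(config, "rnaseq"))
    n <- nrow(truth)
    reps <- config@rnaseqReplicates
    conds <- c("control", "ko1", "ko2")
    condition <- factor(rep(conds, each = reps), levels = conds)
    mu <- exp(stats::rnorm(n, log(300), 1))
    sf <- exp(stats::runif(length(condition), log(0.5), log(2)))
    isKo <- condition != "control"
    m <- matrix(0L, n, length(condition))
    for (j in seq_along(condition)) {
        mean_j <- sf[j] * mu * 2^(truth$rna_lfc * isKo[j])
        m[, j] <- if (config@rnaseqDispersion > 0) {
            stats::rnbinom(n, mu = mean_j,
                           size = 1 / config@rnaseqDispersion)
        } else stats::rpois(n, mean_j)
    }
    rownames(m) <- truth$gene_id
    colnames(m) <- sprintf("%s_rep%d", condition,
                           rep(seq_len(reps), times = length(conds)))
    list(counts = countTable(m), condition = condition)
}

#' Simulate TF binding peaks at bound promoters
#'
#' Emits one 1-kb peak centred on the TSS of every truth-table gene
#' flagged \code{tf_bound}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param truth truth table.
#' @return a \code{GRanges} of peaks.
#' @export
simulateTfPeaks <- function(config, annotation, truth) {
    set.seed(.stageSeed(config, "tf"))
    tt <- .tssTes(annotation)
    idx <- which(truth$tf_bound)
    if (!length(idx)) return(GRanges())
    start0 <- pmax(tt$tss0[idx] - 500, 0)
    GRanges(as.character(seqnames(tt$tx))[idx],
            IRanges(start0 + 1L, tt$tss0[idx] + 500),
            seqinfo = seqinfo(tt$tx))
}

#' Simulate the full experiment
#'
#' Annotation, truth table, CUT&RUN fragments for both marks, RNA-seq
#' counts and TF peaks, all driven by the single config seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{config}, \code{annotation}, \code{truth},
#'   \code{k4}, \code{k36} (see \code{\link{simulateCutrun}}),
#'   \code{rnaseq}, \code{tfPeaks}.
#' @export
simulateExperiment <- function(config = simulationConfig()) {
    annotation <- simulateAnnotation(config)
    truth <- simulateTruth(config, annotation)
    list(config = config,
         annotation = annotation,
         truth = truth,
         k4 = simulateCutrun(config, annotation, truth, "H3K4me3"),
         k36 = simulateCutrun(config, annotation, truth, "H3K36me3"),
         rnaseq = simulateRnaseq(config, truth),
         tfPeaks = simulateTfPeaks(config, annotation, truth))
}
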