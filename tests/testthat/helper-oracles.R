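## independent brute-force reimplementation of the window test used as an
## oracle: plain loops, explicit Poisson tail sums, manual merging
bruteForcePeaks <- function(sMid0, cMid0, chromLen, windowSize = 500,
                            step = 100, pcut = 1e-5, mergeGap = 100,
                            lambdaFloor = 0.25) {
    nS <- length(sMid0); nC <- length(cMid0)
    lambdaBg <- nS * windowSize / chromLen
    starts0 <- seq(0, chromLen - 1, by = step)
    res <- data.frame(start0 = starts0, end0 = pmin(starts0 + windowSize,
                                                    chromLen))
    res$k <- vapply(seq_len(nrow(res)), function(i)
        sum(sMid0 >= res$start0[i] & sMid0 < res$end0[i]), 0L)
    kc <- vapply(seq_len(nrow(res)), function(i)
        sum(cMid0 >= res$start0[i] & cMid0 < res$end0[i]), 0L)
    res$lambda <- pmax(lambdaBg, if (nC) kc * nS / nC else 0, lambdaFloor)
    ## exact upper tail P(Pois(lambda) >= k) summed term by term
    res$p <- vapply(seq_len(nrow(res)), function(i) {
        if (res$k[i] == 0) return(1)
        1 - sum(dpois(0:(res$k[i] - 1L), res$lambda[i]))
    }, 0)
    sig <- res[res$p < pcut, , drop = FALSE]
    if (!nrow(sig)) return(sig[, c("start0", "end0", "p")])
    ## manual merge of significant windows gapped <= mergeGap
    peaks <- list()
    cur <- sig[1, ]
    curP <- sig$p[1]; curK <- sig$k[1]; curL <- sig$lambda[1]
    if (nrow(sig) > 1) for (i in 2:nrow(sig)) {
        if (sig$start0[i] - cur$end0 <= mergeGap) {
            cur$end0 <- max(cur$end0, sig$end0[i])
            curP <- min(curP, sig$p[i])
            curK <- curK + sig$k[i]; curL <- curL + sig$lambda[i]
        } else {
            peaks[[length(peaks) + 1]] <- data.frame(
                start0 = cur$start0, end0 = cur$end0, p = curP,
                fe = curK / curL)
            cur <- sig[i, ]; curP <- sig$p[i]
            curK <- sig$k[i]; curL <- sig$lambda[i]
        }
    }
    peaks[[length(peaks) + 1]] <- data.frame(start0 = cur$start0,
                                             end0 = cur$end0, p = curP,
                                             fe = curK / curL)
    do.call(rbind, peaks)
}

midFragments <- function(mid0, chromSizes, id = "s") {
    len <- chromSizes[[1]]
    makeFragments(names(chromSizes)[1], pmax(mid0 - 10, 0),
                  pmin(mid0 + 10, len), chromSizes = chromSizes,
                  sampleId = id)
}

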