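# Fixture builders shared across test files. Everything is generated in code.

# Random SpectraSet on a uniform grid.
randomSpectra <- function(n = 20, v = 10, seed = 1, ppm0 = 1.0,
                          step = 0.01) {
    set.seed(seed)
    SpectraSet(matrix(rnorm(n * v), n, v),
               ppm = ppm0 + step * (seq_len(v) - 1))
}

# Peak block embedded in iid-noise flanks. With peakNoiseSd = 0 the block is
# exactly rank-1 (every pairwise correlation is 1, so the directional rules
# pass by their tie-accepting <=/>= and growth is deterministic); a positive
# peakNoiseSd yields realistic correlation gradients across the block.
peakBlockSpectra <- function(n = 50, vPeak = 12, vFlank = 10, seed = 3,
                             noiseSd = 1, peakNoiseSd = 0) {
    set.seed(seed)
    conc <- runif(n, 0.5, 2)
    amp <- 1 + 9 * stats::dnorm(seq(-2.5, 2.5, length.out = vPeak)) /
        stats::dnorm(0)
    x <- cbind(matrix(rnorm(n * vFlank, sd = noiseSd), n),
               outer(conc, amp) +
                   matrix(rnorm(n * vPeak, sd = peakNoiseSd), n),
               matrix(rnorm(n * vFlank, sd = noiseSd), n))
    v <- ncol(x)
    list(s = SpectraSet(x, ppm = 1 + 0.001 * (seq_len(v) - 1)),
         peakIdx = (vFlank + 1):(vFlank + vPeak), conc = conc)
}

# Brute-force all-pairs window-correlation oracle (independent of the
# implementation's lag/rolling-sum path).
bruteWindowCorrs <- function(x, st, method = "pearson") {
    v <- ncol(x)
    vapply(seq_len(v - st + 1L), function(i) {
        r <- suppressWarnings(stats::cor(x[, i:(i + st - 1L)],
                                         method = method))
        r[is.na(r)] <- 0
        mean(r[upper.tri(r)])
    }, numeric(1))
}

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign
# assignments (independent oracle for compareMethodsPaired).
enumSignedRankP <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    rk <- rank(abs(d))
    vObs <- sum(rk[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vAll <- as.vector(signs %*% rk)
    pGe <- mean(vAll >= vObs)
    pLe <- mean(vAll <= vObs)
    min(1, 2 * min(pGe, pLe))
}

# The canned scenario battery is expensive enough to share: computed once per
# test run, on first use.
.batteryCache <- new.env(parent = emptyenv())
scenarioBattery <- function() {
    if (!is.null(.batteryCache$b)) return(.batteryCache$b)
    spec <- plasmaLikeScenario()
    sim <- generateSpectra(spec)
    s <- sim$spectra
    sel <- selectCt(regionWindowCorrs(s, spec$regions$noise, st = 4),
                    regionWindowCorrs(s, spec$regions$signal, st = 4),
                    noiseRegion = spec$regions$noise,
                    signalRegion = spec$regions$signal)
    p <- jbaParams(st = 4, ct = selectedCt(sel))
    res <- list(spec = spec, sim = sim, s = s, sel = sel, params = p,
                jba = runJBA(s, p),
                srv8 = runSRV(s, srvParams(minsize = 8)),
                srv10 = runSRV(s, srvParams(minsize = 10)),
                sb = standardBin(s, sbParams(width_ppm = 0.005)))
    .batteryCache$b <- res
    res
}

# Clusters of `b` whose ppm span intersects the (closed) region.
clustersInRegion <- function(b, lo, hi) {
    rd <- clusterInfo(b)
    which(rd$ppm_end >= lo & rd$ppm_start <= hi)
}
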