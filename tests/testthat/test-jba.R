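test_that("findSeeds keeps local maxima at or above the threshold", {
    mk <- function(r) methods::new("CorrelationSpectrum",
                                   ppmAnchor = seq_along(r) / 100,
                                   rBar = r, st = 4L, method = "pearson")
    ## constant sub-threshold spectrum: nothing
    expect_length(findSeeds(mk(rep(0.5, 9)), ct = 0.834), 0)
    ## two isolated maxima
    expect_equal(findSeeds(mk(c(0.2, 0.9, 0.3, 0.95, 0.4)), 0.834), c(2L, 4L))
    ## plateau: one seed at the run's first anchor
    expect_equal(findSeeds(mk(c(0.1, 0.9, 0.9, 0.9, 0.1)), 0.5), 2L)
    ## edge runs compare against their single neighbour
    expect_equal(findSeeds(mk(c(0.95, 0.4, 0.2)), 0.5), 1L)
    ## raising ct never yields more seeds (monotonicity)
    set.seed(6)
    r <- pmin(1, pmax(-1, cumsum(rnorm(60, sd = 0.2))))
    cs <- mk(r)
    counts <- vapply(seq(-1, 1, by = 0.1),
                     function(ct) length(findSeeds(cs, ct)), integer(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("expandSeed grows over a rank-1 peak and stops at hostile flanks", {
    ## flanks exactly anticorrelated with the peak: cluster stays st wide
    set.seed(7)
    core <- runif(30, 1, 2)
    x <- cbind(-core + rnorm(30, sd = 1e-3), -core + rnorm(30, sd = 1e-3),
               core, core * 2, core * 3, core * 1.5,
               -core + rnorm(30, sd = 1e-3), -core + rnorm(30, sd = 1e-3))
    s <- SpectraSet(x, ppm = 1:8 / 100)
    cl <- expandSeed(s, seed = 3L, jbaParams(st = 4, ct = 0.8))
    expect_equal(cl$start_idx, 3L)
    expect_equal(cl$end_idx, 6L)
    expect_equal(cl$r_bar, 1, tolerance = 1e-12)

    ## a seed at the first window can only grow downfield
    all1 <- SpectraSet(outer(core, rep(1, 6)) * outer(rep(1, 30), 1:6),
                       ppm = 1:6 / 100)
    cl2 <- expandSeed(all1, seed = 1L, jbaParams(st = 4, ct = 0.8))
    expect_equal(c(cl2$start_idx, cl2$end_idx), c(1L, 6L))

    ## seeds overlapping claimed indices are dropped
    expect_null(expandSeed(s, 3L, jbaParams(st = 4, ct = 0.8),
                           occupied = 5L))
})

test_that("an isolated peak is covered exactly, iid flanks excluded", {
    ## the peak block has a high-SNR amplitude gradient; a flank variable
    ## would dilute the cluster's average correlation below ct, so growth
    ## stops deterministically at the peak boundary
    bl <- peakBlockSpectra(n = 50, vPeak = 12, vFlank = 10, seed = 3,
                           peakNoiseSd = 0.2)
    b <- runJBA(bl$s, jbaParams(st = 4, ct = 0.9))
    expect_equal(nrow(b), 1L)
    rd <- clusterInfo(b)
    expect_equal(rd$start_idx, min(bl$peakIdx))
    expect_equal(rd$end_idx, max(bl$peakIdx))
    expect_gte(rd$r_bar, 0.9)
})

test_that("aggregateIntensity computes the documented statistics", {
    x <- rbind(c(1, 2, 3), c(4, 6, 8))
    s <- SpectraSet(rbind(x, x + 1, x * 2), ppm = 1:3 / 10)  # >= 3 samples
    expect_equal(unname(aggregateIntensity(s, 1:3, "sum")[1]), 6)
    expect_equal(unname(aggregateIntensity(s, 1:3, "median")[1]), 2)
    expect_equal(unname(aggregateIntensity(s, 1:3, "max")[1]), 3)
    expect_equal(unname(aggregateIntensity(s, 1:3, "mean")[2]), 6)
})

test_that("mergeNeighbours integrates fragments of one latent signal", {
    set.seed(8)
    conc <- rlnorm(100)
    other <- rlnorm(100)
    mk <- function(blocks) {
        x <- do.call(cbind, blocks) +
            matrix(rnorm(100 * 4 * length(blocks), sd = 1e-3), 100)
        SpectraSet(x, ppm = seq_len(ncol(x)) / 100)
    }
    ## fragment the axis into 4-variable bins, then let merging reunite them
    fragment <- function(s) standardBin(s, sbParams(width_ppm = 0.04))

    ## two adjacent blocks driven by the same concentration: one cluster
    s <- mk(list(outer(conc, c(1, 2, 3, 2)), outer(conc, c(1.5, 2.5, 1.2, 0.8))))
    base <- fragment(s)
    expect_equal(nrow(base), 2L)
    merged <- mergeNeighbours(s, base, jbaParams(st = 4, merge_r = 0.9))
    expect_equal(nrow(merged), 1L)
    expect_equal(clusterInfo(merged)$start_idx, 1L)
    expect_equal(clusterInfo(merged)$end_idx, 8L)

    ## independent concentrations stay unmerged
    s2 <- mk(list(outer(conc, c(1, 2, 3, 2)), outer(other, c(1, 2, 3, 2))))
    m2 <- mergeNeighbours(s2, fragment(s2), jbaParams(st = 4, merge_r = 0.9))
    expect_equal(nrow(m2), 2L)

    ## a chain of three mutually correlated fragments collapses transitively
    s3 <- mk(list(outer(conc, c(1, 2, 3, 2)), outer(conc, c(2, 1, 2, 1)),
                  outer(conc, c(0.5, 1, 2, 1))))
    base3 <- fragment(s3)
    expect_equal(nrow(base3), 3L)
    m3 <- mergeNeighbours(s3, base3, jbaParams(st = 4, merge_r = 0.9))
    expect_equal(nrow(m3), 1L)
    expect_equal(clusterInfo(m3)$n_variables, 12L)

    ## sum aggregation is conserved by the merge
    expect_equal(unname(intensityMatrix(m3)[, 1]),
                 unname(rowSums(intensityMatrix(base3))), tolerance = 1e-12)
})

test_that("runJBA finds nothing in pure iid noise at a stringent threshold", {
    set.seed(10)
    s <- SpectraSet(matrix(rnorm(200 * 500), 200, 500), ppm = 1:500 / 1000)
    b <- runJBA(s, jbaParams(st = 4, ct = 0.834))
    expect_equal(nrow(b), 0L)
})

test_that("runJBA recovers multiple isolated planted peaks", {
    set.seed(11)
    nPk <- 8
    spec <- syntheticSpec(nSamples = 80, ppmLo = 1, ppmHi = 2, step = 0.001,
                          peaks = data.frame(
                              center = seq(1.08, 1.92, length.out = nPk),
                              hwhm = 0.0005,
                              amplitude = 55,
                              factor = seq_len(nPk)),
                          sdLog = 0.4, factorCor = 0, noiseSd = 1,
                          noiseRho = 0, shiftSd = 0, seed = 77)
    sim <- generateSpectra(spec)
    b <- runJBA(sim$spectra, jbaParams(st = 4, ct = 0.6))
    rec <- peakRecovery(b, sim$truth, tol = 2)
    expect_equal(nrow(b), nPk)
    expect_equal(rec$fraction, 1)
    ## seed of each cluster lies inside its planted support
    rd <- clusterInfo(b)
    tp <- sim$truth$peaks
    expect_true(all(rd$seed_idx >= tp$support_start &
                    rd$seed_idx <= tp$support_end + 3))
})

test_that("JBA cluster structure invariants hold on the canned scenario", {
    bat <- scenarioBattery()
    rd <- clusterInfo(bat$jba)
    ## pairwise disjoint, contiguous, ordered
    expect_false(is.unsorted(rd$ppm_start))
    mem <- unlist(as.list(rd$members))
    expect_false(anyDuplicated(mem) > 0)
    expect_true(all(rd$n_variables == rd$end_idx - rd$start_idx + 1))
    ## pre-merge clusters satisfy the size and correlation contracts
    pre <- runJBA(bat$s, jbaParams(st = 4, ct = selectedCt(bat$sel),
                                   merge_r = 1))
    rdp <- clusterInfo(pre)
    expect_true(all(rdp$n_variables >= 4))
    expect_true(all(rdp$r_bar >= selectedCt(bat$sel) - 1e-12))
})

test_that("pearson clustering is invariant to positive affine rescaling", {
    bl <- peakBlockSpectra(n = 40, vPeak = 10, vFlank = 8, seed = 12,
                           peakNoiseSd = 0.5)
    p <- jbaParams(st = 4, ct = 0.85, merge_r = 1)
    b1 <- runJBA(bl$s, p)
    x2 <- intensityMatrix(bl$s)
    set.seed(13)
    x2 <- sweep(x2, 2, runif(ncol(x2), 0.5, 4), `*`)
    x2 <- sweep(x2, 2, rnorm(ncol(x2)), `+`)
    b2 <- runJBA(SpectraSet(x2, ppm = ppm(bl$s)), p)
    expect_equal(clusterInfo(b1)$start_idx, clusterInfo(b2)$start_idx)
    expect_equal(clusterInfo(b1)$end_idx, clusterInfo(b2)$end_idx)
})

test_that("spearman clustering is invariant to monotone transforms", {
    bl <- peakBlockSpectra(n = 40, vPeak = 10, vFlank = 8, seed = 14,
                           peakNoiseSd = 0.5)
    p <- jbaParams(st = 4, ct = 0.85, cm = "spearman", merge_r = 1)
    b1 <- runJBA(bl$s, p)
    x2 <- intensityMatrix(bl$s)
    x2 <- abs(x2)^1.7 * sign(x2)      # strictly increasing, nonlinear
    b2 <- runJBA(SpectraSet(x2, ppm = ppm(bl$s)), p)
    expect_equal(clusterInfo(b1)$start_idx, clusterInfo(b2)$start_idx)
    expect_equal(clusterInfo(b1)$end_idx, clusterInfo(b2)$end_idx)
})

test_that("misaligned split peaks are repaired by gap-tolerant merging", {
    ## a strong peak with per-sample one-point shifts splits at the apex;
    ## merging with a one-step gap allowance reunites the fragments
    spec <- syntheticSpec(nSamples = 120, ppmLo = 1, ppmHi = 1.2,
                          step = 0.001,
                          peaks = data.frame(center = 1.1, hwhm = 0.003,
                                             amplitude = 150, factor = 1),
                          sdLog = 0.6, noiseSd = 1, noiseRho = 0,
                          shiftSd = 0.4, seed = 21)
    sim <- generateSpectra(spec)
    frag <- runJBA(sim$spectra, jbaParams(st = 4, ct = 0.5, merge_r = 1))
    expect_gt(nrow(frag), 1)           # the peak is split at the apex
    rep <- runJBA(sim$spectra, jbaParams(st = 4, ct = 0.5, merge_r = 0.9,
                                         merge_gap_ppm = 0.001))
    expect_lt(nrow(rep), nrow(frag))   # merging reunites fragments
    ## the apex region ends up inside a single cluster
    apex <- which.min(abs(ppm(sim$spectra) - 1.1))
    rd <- clusterInfo(rep)
    covering <- sum(rd$start_idx <= apex & rd$end_idx >= apex + 1)
    expect_equal(covering, 1L)
})
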