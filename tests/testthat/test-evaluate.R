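test_that("crossCorrelate finds perfectly matching features", {
    set.seed(26)
    conc <- rlnorm(30)
    other <- rlnorm(30)
    x <- cbind(outer(conc, c(1, 2, 2, 1)), outer(other, c(2, 3, 3, 2)))
    s <- SpectraSet(x, ppm = 1:8 / 10, sampleIds = sprintf("P%02d", 1:30))
    b <- runJBA(s, jbaParams(st = 4, ct = 0.9))
    met <- cbind(metA = conc, metB = exp(other))   # metB: monotone transform
    rownames(met) <- sampleIds(s)
    cc <- crossCorrelate(b, met)
    expect_equal(cc$table$r_best, c(1, 1))         # Spearman rank invariance
    expect_true(all(cc$table$detected))
    ## ppm of the best match falls inside the driving cluster
    rd <- clusterInfo(b)
    expect_true(cc$table$ppm_best[1] >= rd$ppm_start[1] &&
                cc$table$ppm_best[1] <= rd$ppm_end[1])

    ## a match window with no feature flags the metabolite as not detected
    cc2 <- crossCorrelate(b, met, match = list(metA = c(5, 6)))
    expect_false(cc2$table$detected[1])
    expect_true(is.na(cc2$table$r_best[1]))

    ## restricting to the correct window preserves the match
    cc3 <- crossCorrelate(b, met, match = list(metA = c(0.1, 0.4)))
    expect_equal(cc3$table$r_best[1], 1)
})

test_that("crossCorrelate requires shared samples", {
    s <- randomSpectra(n = 5, v = 6, seed = 27)
    met <- matrix(rnorm(10), 5, 2)
    rownames(met) <- paste0("other_", 1:5)
    expect_error(crossCorrelate(s, met), "shared samples")
})

test_that("cross-correlations are unchanged between sum and mean aggregation", {
    bl <- peakBlockSpectra(n = 40, vPeak = 10, vFlank = 6, seed = 28)
    met <- cbind(m = bl$conc)
    rownames(met) <- sampleIds(bl$s)
    bSum <- runJBA(bl$s, jbaParams(st = 4, ct = 0.85, int = "sum"))
    bMean <- runJBA(bl$s, jbaParams(st = 4, ct = 0.85, int = "mean"))
    expect_equal(crossCorrelate(bSum, met)$table$r_best,
                 crossCorrelate(bMean, met)$table$r_best)
})

test_that("compareMethodsPaired matches exact enumeration", {
    ## all-positive differences, n = 6: two-sided p = 2/64
    a <- c(0.9, 0.8, 0.85, 0.7, 0.95, 0.6)
    b <- a - (1:6) / 10
    res <- compareMethodsPaired(a, b)
    expect_true(res$exact)
    expect_equal(res$p.value, 2 / 64)
    expect_equal(res$p.value, enumSignedRankP(a - b))
    ## swapping the vectors leaves the two-sided p unchanged
    expect_equal(compareMethodsPaired(b, a)$p.value, res$p.value)
    ## random mixed-sign cases agree with the enumeration oracle
    for (seed in 1:4) {
        set.seed(seed)
        d <- round(rnorm(8), 3)
        res2 <- compareMethodsPaired(d, rep(0, 8))
        expect_equal(res2$p.value, enumSignedRankP(d), tolerance = 1e-12)
    }
})

test_that("compareMethodsPaired handles degenerate and ND input", {
    a <- c(0.9, 0.8, 0.85, 0.7, 0.95)
    expect_true(compareMethodsPaired(a, a)$degenerate)
    ## ND pairs are dropped before testing
    b <- c(NA, 0.7, 0.75, 0.6, 0.85)
    res <- compareMethodsPaired(a, b)
    expect_equal(res$n.used, 4L)
    expect_error(compareMethodsPaired(a[1:4], b[1:4]), "at least 5")
    expect_error(compareMethodsPaired(a, b[1:4]), "equal length")
})

test_that("pcaDiagnostics reports variance structure correctly", {
    set.seed(29)
    base <- rnorm(30)
    ## rank-1 matrix: PC1 explains everything
    x <- outer(base, runif(8, 0.5, 2))
    p1 <- pcaDiagnostics(x, "mean_center", n_pc = 3)
    expect_equal(p1$var_explained[1], 1)
    ## orthogonal two-block design with equal variance: PC1 ~ PC2 ~ 50%
    b1 <- scale(rnorm(200)); b2 <- scale(rnorm(200))
    x2 <- cbind(outer(as.vector(b1), rep(1, 5)),
                outer(as.vector(b2), rep(1, 5))) +
        matrix(rnorm(2000, sd = 1e-4), 200)
    p2 <- pcaDiagnostics(x2, "mean_center", n_pc = 4)
    expect_equal(p2$var_explained[1], 0.5, tolerance = 0.05)
    expect_equal(p2$var_explained[2], 0.5, tolerance = 0.05)
    ## cumulative curve is non-decreasing and bounded by 1
    set.seed(30)
    x3 <- matrix(rnorm(40 * 25), 40)
    p3 <- pcaDiagnostics(x3, "unit_variance", n_pc = 10)
    expect_true(all(diff(p3$cum_var) >= -1e-12))
    expect_lte(p3$cum_var[10], 1 + 1e-12)
    ## Hotelling ellipse semi-axes are positive and ordered with variance
    expect_gt(p3$hotelling$a, 0)
    expect_gte(p3$hotelling$a, p3$hotelling$b)
})

test_that("pcaDiagnostics drops zero-variance columns under UV scaling", {
    set.seed(31)
    x <- cbind(matrix(rnorm(60), 20), rep(2, 20))
    expect_warning(p <- pcaDiagnostics(x, "unit_variance", n_pc = 2),
                   "zero-variance")
    expect_equal(p$n_dropped, 1L)
    expect_error(pcaDiagnostics(x, "unit_variance", n_pc = 25), "n_pc")
})
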