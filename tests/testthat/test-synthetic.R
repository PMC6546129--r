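test_that("generation is deterministic given the spec and seed", {
    spec <- syntheticSpec(10, 1, 1.2, 0.002,
                          peaks = data.frame(center = 1.1, hwhm = 0.004,
                                             amplitude = 50, factor = 1),
                          noiseRho = 0.3, seed = 5)
    a <- generateSpectra(spec)
    b <- generateSpectra(spec)
    expect_identical(intensityMatrix(a$spectra), intensityMatrix(b$spectra))
    expect_identical(a$truth$concentrations, b$truth$concentrations)
    ## the generator does not disturb the caller's RNG stream
    set.seed(99); before <- rnorm(3)
    set.seed(99); invisible(generateSpectra(spec)); after <- rnorm(3)
    expect_identical(before, after)
})

test_that("a zero-peak spec yields pure noise that JBA rejects", {
    spec <- syntheticSpec(100, 1, 1.5, 0.001, peaks = NULL,
                          noiseRho = 0, seed = 6)
    sim <- generateSpectra(spec)
    expect_equal(nrow(sim$truth$peaks), 0L)
    ## threshold chosen on a noise sub-region suppresses that whole region
    sub <- regionMask(c(1.0, 1.24))
    noise <- regionWindowCorrs(sim$spectra, sub, st = 4)
    signal <- regionWindowCorrs(sim$spectra, regionMask(c(1.26, 1.5)),
                                st = 4)
    ct <- selectedCt(selectCt(noise, signal))
    b <- runJBA(applyMask(sim$spectra, sub, "select"),
                jbaParams(st = 4, ct = ct))
    expect_equal(nrow(b), 0L)
})

test_that("a noiseless single peak is rank-1 over its support", {
    spec <- syntheticSpec(12, 1, 1.2, 0.002,
                          peaks = data.frame(center = 1.1, hwhm = 0.004,
                                             amplitude = 80, factor = 1),
                          noiseSd = 0, noiseRho = 0, shiftSd = 0, seed = 7)
    sim <- generateSpectra(spec)
    tp <- sim$truth$peaks
    idx <- tp$support_start:tp$support_end
    r <- cor(intensityMatrix(sim$spectra)[, idx])
    expect_equal(max(abs(r - 1)), 0, tolerance = 1e-12)
    ## support matches the 1% apex-fraction cutoff analytically:
    ## |x| <= hw * sqrt(99)
    halfw <- 0.004 * sqrt(99)
    pv <- ppm(sim$spectra)
    expect_true(all(abs(pv[idx] - 1.1) <= halfw + 1e-9))
    expect_true(abs(pv[tp$support_start - 1L] - 1.1) > halfw)
})

test_that("the plasma-like scenario satisfies its contract", {
    spec <- plasmaLikeScenario()
    expect_s3_class(spec, "SyntheticSpec")
    expect_gte(nrow(spec$peaks), 20)
    expect_true(all(spec$peaks$center >= 0.8 & spec$peaks$center <= 5.3))
    expect_equal(spec$noiseRho, 0.5)
    ## two low-amplitude tail peaks
    expect_equal(sum(spec$peaks$amplitude <= 25), 2L)
    bat <- scenarioBattery()
    expect_gte(nrow(bat$sim$truth$peaks), 20)
    ## noise-region windows correlate strictly less than in-peak windows
    noiseMean <- mean(bat$sel@noiseCorrs)
    tp <- bat$sim$truth$peaks
    pv <- ppm(bat$s)
    mains <- tp[tp$amplitude > 25, ]
    peakWins <- regionMask(cbind(pv[mains$support_start],
                                 pv[mains$support_end]))
    peakMean <- mean(regionWindowCorrs(bat$s, peakWins, st = 4))
    expect_gt(peakMean, noiseMean)
})

test_that("misalignment shifts are integer grid moves recorded in truth", {
    spec <- syntheticSpec(50, 1, 1.1, 0.001,
                          peaks = data.frame(center = 1.05, hwhm = 0.003,
                                             amplitude = 60, factor = 1),
                          shiftSd = 0.8, noiseSd = 0, noiseRho = 0, seed = 8)
    sim <- generateSpectra(spec)
    expect_type(sim$truth$shifts, "integer")
    expect_gt(length(unique(sim$truth$shifts)), 1)
    ## a shifted sample's spectrum equals the unshifted profile moved by d
    x <- intensityMatrix(sim$spectra)
    d <- sim$truth$shifts
    i0 <- which(d == 0)[1]; i1 <- which(d == 1)[1]
    ratio <- sim$truth$concentrations[i1, 1] /
        sim$truth$concentrations[i0, 1]
    expect_equal(x[i1, 2:ncol(x)], x[i0, 1:(ncol(x) - 1)] * ratio,
                 tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("syntheticSpec validates its invariants", {
    pk <- data.frame(center = 2, hwhm = 0.01, amplitude = 10, factor = 1)
    expect_error(syntheticSpec(10, 1, 1.5, 0.001, pk), "inside")
    expect_error(syntheticSpec(10, 1, 1.5, -1,
                               transform(pk, center = 1.2)), "step")
    expect_error(syntheticSpec(10, 1, 1.5, 0.001,
                               transform(pk, center = 1.2),
                               noiseRho = 1), "noiseRho")
    expect_error(syntheticSpec(2, 1, 1.5, 0.001,
                               transform(pk, center = 1.2)), "nSamples")
})
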