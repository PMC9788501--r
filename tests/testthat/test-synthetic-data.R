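test_that("default truth matches the published averages and the band design", {
    p <- defaultTruth()
    expect_equal(r1(p), 159.07e6)
    expect_equal(r2(p) / r4(p), 4.76 / 1.49)   # ~3.19
    expect_equal(unname(modelLimits(p)["low"]), 159.07e6)
    # both membrane relaxations lie inside the analysis band
    fc3 <- 1 / (2 * pi * r1(p) * c3(p))
    fc5 <- 1 / (2 * pi * r4(p) * c5(p))
    expect_true(fc3 > 500 && fc3 < 3e5)
    expect_true(fc5 > 500 && fc5 < 3e5)
})

test_that("an event-free configuration yields a constant trajectory", {
    ones <- stats::setNames(rep(1, 5), c("r1", "r2", "r4", "c3", "c5"))
    zero <- stats::setNames(rep(0, 5), c("r1", "r2", "r4", "c3", "c5"))
    tc <- trajectoryConfig(waterMultipliers = ones, relaxRate = zero,
                           hydratedMultipliers = ones, nPlants = 2L)
    tr <- simulateTrajectory(tc)
    expect_true(all(tr$r1_ohm == r1(defaultTruth())))
    expect_true(all(tr$c5_farad == c5(defaultTruth())))
})

test_that("water and light events shape the default trajectories", {
    tr <- simulateTrajectory(trajectoryConfig(nPlants = 1L))
    at <- function(col, h) tr[[col]][tr$hour == h]
    # nothing changes before the water event
    expect_equal(at("r1_ohm", 5), r1(defaultTruth()))
    # rapid rise in resistance, drop in capacitance on water uptake
    expect_gt(at("r1_ohm", 6), at("r1_ohm", 5))
    expect_gt(at("r2_ohm", 6), at("r2_ohm", 5))
    expect_lt(at("c3_farad", 6), at("c3_farad", 5))
    expect_lt(at("c5_farad", 6), at("c5_farad", 5))
    # monotone relaxation once the LED is on
    dec <- tr$hour >= 8
    expect_true(all(diff(tr$r1_ohm[dec]) < 0))
    expect_true(all(diff(tr$r2_ohm[dec]) < 0))
    expect_true(all(diff(tr$c3_farad[dec]) > 0))
    expect_true(all(diff(tr$c5_farad[dec]) > 0))
    # geometric decay toward the hydrated target at the configured rate
    target <- 0.8 * r1(defaultTruth())
    gap <- tr$r1_ohm[dec] - target
    expect_equal(gap / gap[1], exp(-0.15 * (tr$hour[dec] - 8)),
                 tolerance = 1e-12)
    # the vacuole resistance moves only mildly (published "minor changes")
    expect_lt(max(tr$r4_ohm) / min(tr$r4_ohm), 1.2)
})

test_that("zero noise reproduces the exact model spectra", {
    f <- defaultFrequencyGrid(31L)
    tr <- truthRow(defaultTruth())
    se <- simulateMeasurements(tr, f, noiseConfig(pointSd = 0, contactSd = 0,
                                                  nReplicates = 3L), seed = 5)
    z <- dsmImpedance(defaultTruth(), f)
    for (j in 1:3) {
        expect_identical(assay(se, "resistance")[, j], Re(z))
        expect_identical(assay(se, "reactance")[, j], Im(z))
    }
})

test_that("simulated measurements are reproducible and seed-sensitive", {
    tr <- truthRow(defaultTruth())
    f <- defaultFrequencyGrid(21L)
    a <- simulateMeasurements(tr, f, noiseConfig(), seed = 8)
    b <- simulateMeasurements(tr, f, noiseConfig(), seed = 8)
    cc <- simulateMeasurements(tr, f, noiseConfig(), seed = 9)
    expect_identical(assay(a, "resistance"), assay(b, "resistance"))
    expect_identical(assay(a, "reactance"), assay(b, "reactance"))
    expect_false(identical(assay(a, "resistance"), assay(cc, "resistance")))
    expect_true(all(assay(a, "resistance") > 0))
})

test_that("the replicate mean concentrates at the point-noise standard error", {
    f <- defaultFrequencyGrid(101L)
    tr <- truthRow(defaultTruth())
    se <- simulateMeasurements(tr, f,
                               noiseConfig(pointSd = 0.01, contactSd = 0),
                               seed = 13)
    ms <- meanSpectrum(se)
    z <- dsmImpedance(defaultTruth(), f)
    relDev <- (assay(ms, "resistance")[, 1] - Re(z)) / Re(z)
    rms <- sqrt(mean(relDev^2))
    sem <- 0.01 / sqrt(5)
    expect_gt(rms, sem / 2)
    expect_lt(rms, sem * 2)
})

test_that("mean spectra keep the two-dispersion shape of the model", {
    se <- simulateMeasurements(truthRow(defaultTruth()),
                               noise = noiseConfig(), seed = 17)
    ms <- meanSpectrum(se)
    r <- assay(ms, "resistance")[, 1]
    x <- assay(ms, "reactance")[, 1]
    # resistance falls with frequency (allowing for the 1% point noise)
    expect_lt(sum(diff(r) > 0) / length(diff(r)), 0.25)
    expect_gt(r[1], 10 * r[length(r)])
    # reactance is negative with an interior |X| maximum
    expect_true(all(x < 0))
    k <- which.max(-x)
    expect_gt(k, 1L)
    expect_lt(k, length(x))
})
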