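test_that("candidate proposals move one coordinate by a fractional step", {
    center <- DSMParams(100e6, 5e6, 1.5e6, 1e-12, 1e-12)
    cands <- proposeCandidates(center, 0.10)
    expect_length(cands, 15L)   # 5 coordinates x directions (+1, 0, -1)
    # direction 0 reproduces the centre
    zero <- Filter(function(cc) cc$direction == 0L, cands)
    for (cc in zero)
        expect_equal(dsmValues(cc$params), dsmValues(center))
    # +10% on r1 leaves the other four coordinates untouched
    up <- Filter(function(cc) cc$coordinate == "r1" && cc$direction == 1L,
                 cands)[[1]]
    expect_equal(r1(up$params), 110e6)
    expect_equal(dsmValues(up$params)[-1], dsmValues(center)[-1])
})

test_that("out-of-bounds candidates are discarded and reported", {
    bounds <- dsmBounds()
    atFloor <- DSMParams(bounds$rMin, 5e6, 1.5e6, 1e-12, 1e-12)
    cands <- proposeCandidates(atFloor, 0.10)
    disc <- attr(cands, "discarded")
    expect_identical(disc$coordinate, "r1")
    expect_identical(disc$direction, -1L)
    expect_false(any(vapply(cands, function(cc)
        cc$coordinate == "r1" && cc$direction == -1L, logical(1))))
})

test_that("line search doubles the step while the error strictly decreases", {
    # quadratic 1-D surface with minimum at +35% of the starting r1
    r0 <- 100e6
    objective <- function(p) (r1(p) - 1.35 * r0)^2
    # the first alpha = 10% move has already been accepted
    stepped <- DSMParams(1.1 * r0, 5e6, 1.5e6, 1e-12, 1e-12)
    res <- lineSearch(objective, stepped, objective(stepped), "r1", 1L, 0.10)
    # doubled 20% step from 1.1 lands at 1.32 (cumulative 32%); the next
    # 40% doubling overshoots and is rejected
    expect_equal(r1(res$params), 1.32 * r0)
    expect_lt(res$error, objective(stepped))
    # oracle: the accepted point is the best of the doubling sequence
    seqPoints <- c(1.1 * 1.2, 1.1 * 1.2 * 1.4) * r0
    expect_equal(res$error, min((seqPoints - 1.35 * r0)^2))
    # immediately-worse doubling returns the input state
    nearMin <- DSMParams(1.34 * r0, 5e6, 1.5e6, 1e-12, 1e-12)
    res2 <- lineSearch(objective, nearMin, objective(nearMin), "r1", 1L, 0.10)
    expect_equal(r1(res2$params), 1.34 * r0)
    expect_identical(res2$nEvals, 1L)
})

test_that("a start at the global minimum is returned unchanged", {
    f <- defaultFrequencyGrid()
    truth <- defaultTruth()
    zm <- dsmImpedance(truth, f)
    fit <- coordinateSearch(zm, f, truth)
    expect_true(fit@converged)
    expect_identical(fit@nEvals, 1L)
    expect_equal(dsmValues(fittedParams(fit)), dsmValues(truth))
    expect_identical(fit@finalError, 0)
})

test_that("noiseless spectra are recovered within 1% from a distant start", {
    f <- defaultFrequencyGrid()
    truth <- defaultTruth()
    zm <- dsmImpedance(truth, f)
    init <- paramsFromVector(dsmValues(truth) * 1.5)
    fit <- coordinateSearch(zm, f, init, accuracyConfig())
    expect_true(fit@converged)
    expect_true(all(relErrVector(fittedParams(fit), truth) < 0.01))
})

test_that("the accepted-error sequence is strictly decreasing and the search is deterministic", {
    f <- defaultFrequencyGrid()
    truth <- defaultTruth()
    tr <- truthRow(truth)
    se <- simulateMeasurements(tr, f, noiseConfig(), seed = 31)
    zm <- impedanceMatrix(meanSpectrum(se))[, 1]
    init <- paramsFromVector(dsmValues(truth) * c(1.3, 0.7, 1.2, 0.8, 1.4))
    fitA <- coordinateSearch(zm, f, init)
    fitB <- coordinateSearch(zm, f, init)
    expect_identical(dsmValues(fittedParams(fitA)),
                     dsmValues(fittedParams(fitB)))
    expect_identical(fitA@trace, fitB@trace)
    expect_true(all(diff(fitA@trace) < 0))
    expect_lte(fitA@finalError, fitA@initError)
})

test_that("a step-floor exit admits no further improvement at the minimum step", {
    f <- defaultFrequencyGrid()
    tr <- truthRow(defaultTruth())
    se <- simulateMeasurements(tr, f, noiseConfig(), seed = 37)
    zm <- impedanceMatrix(meanSpectrum(se))[, 1]
    cfg <- fitConfig(thresholdMode = "absolute", thresholdValue = 0)
    fit <- coordinateSearch(zm, f, initializeCenter(zm, f, config = cfg), cfg)
    expect_false(fit@converged)
    expect_identical(fit@reason, "step_floor")
    # exhaustive +/- alphaMin probe of all five coordinates
    v <- dsmValues(fittedParams(fit))
    for (nm in names(v)) for (dir in c(1, -1)) {
        cand <- v
        cand[nm] <- cand[nm] * (1 + cfg@alphaMin * dir)
        e <- impedanceError(zm, dsmImpedance(paramsFromVector(cand), f))
        expect_gte(e, fit@finalError)
    }
})

test_that("warm starts extrapolate, reuse, or cold-start as available", {
    f <- defaultFrequencyGrid()
    truth <- defaultTruth()
    zm <- dsmImpedance(truth, f)
    fitCols <- data.frame(hour = c(6, 7), r1_ohm = c(100e6, 110e6),
                          r2_ohm = c(5e6, 5.5e6), r4_ohm = c(2e6, 2.1e6),
                          c3_farad = c(1e-12, 1.1e-12),
                          c5_farad = c(2e-12, 2.2e-12))
    init <- initializeCenter(zm, f, fitCols)
    expect_equal(r1(init), 120e6)
    expect_equal(c3(init), 1.2e-12)
    initOne <- initializeCenter(zm, f, fitCols[1, ])
    expect_equal(dsmValues(initOne),
                 c(r1 = 100e6, r2 = 5e6, r4 = 2e6, c3 = 1e-12, c5 = 2e-12))
    # cold start: R1 read off the low-frequency plateau
    cold <- initializeCenter(zm, f)
    expect_lt(abs(r1(cold) / r1(truth) - 1), 0.05)
})

test_that("fitting a single-hour set equals calling the search directly", {
    f <- defaultFrequencyGrid()
    tr <- truthRow(defaultTruth(), hour = 9)
    se <- simulateMeasurements(tr, f, noiseConfig(), seed = 41)
    fits <- fitTimeseries(se)
    expect_identical(nrow(fits), 1L)
    ms <- meanSpectrum(se)
    zm <- impedanceMatrix(ms)[, 1]
    direct <- coordinateSearch(zm, f, initializeCenter(zm, f))
    expect_equal(fits$r1_ohm, r1(fittedParams(direct)))
    expect_equal(fits$error_ohm, direct@finalError)
})

test_that("a noiseless hourly series is recovered within 1% at every hour", {
    f <- defaultFrequencyGrid(101L)
    tc <- trajectoryConfig(hours = seq(5, 20, by = 3), nPlants = 1L)
    tr <- simulateTrajectory(tc)
    se <- simulateMeasurements(tr, f, noiseConfig(pointSd = 0, contactSd = 0),
                               seed = 1)
    fits <- fitTimeseries(se, accuracyConfig())
    expect_true(all(fits$converged))
    cols <- c("r1_ohm", "r2_ohm", "r4_ohm", "c3_farad", "c5_farad")
    rel <- abs(as.matrix(fits[cols]) / as.matrix(tr[cols]) - 1)
    expect_lt(max(rel), 0.01)
})

test_that("the watering step is visible in the fitted series", {
    f <- defaultFrequencyGrid()
    tc <- trajectoryConfig(hours = 5:8, nPlants = 1L)
    se <- simulateMeasurements(simulateTrajectory(tc), f, noiseConfig(),
                               seed = 47)
    fits <- fitTimeseries(se)
    expect_gt(fits$r1_ohm[fits$hour == 6], fits$r1_ohm[fits$hour == 5])
})
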