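makeReplicateSet <- function(rmat, xmat, f = NULL, plant = 1L, hour = 8) {
    if (is.null(f)) f <- defaultFrequencyGrid(nrow(as.matrix(rmat)))
    n <- ncol(as.matrix(rmat))
    SweepExperiment(rmat, xmat, f, plant = rep(plant, n),
                    hour = rep(hour, n), replicate = seq_len(n))
}

test_that("mean spectrum is the plain arithmetic mean per frequency", {
    f <- defaultFrequencyGrid(9L)
    z <- dsmImpedance(defaultTruth(), f)
    # five identical replicates reproduce the input exactly
    se <- makeReplicateSet(matrix(Re(z), 9, 5), matrix(Im(z), 9, 5), f)
    ms <- meanSpectrum(se)
    expect_identical(ncol(ms), 1L)
    expect_identical(assay(ms, "resistance")[, 1], Re(z))
    expect_identical(assay(ms, "reactance")[, 1], Im(z))
    expect_identical(sweepInfo(ms)$n_replicates, 5L)
    # two replicates with 1 and 3 ohm average to 2
    se2 <- makeReplicateSet(cbind(rep(1, 9), rep(3, 9)),
                            cbind(rep(-1, 9), rep(-2, 9)), f)
    ms2 <- meanSpectrum(se2)
    expect_equal(assay(ms2, "resistance")[, 1], rep(2, 9))
    expect_equal(assay(ms2, "reactance")[, 1], rep(-1.5, 9))
})

test_that("mean matches an independent summation route on noisy replicates", {
    f <- defaultFrequencyGrid(51L)
    z <- dsmImpedance(defaultTruth(), f)
    withr::with_seed(3, {
        eps <- matrix(rnorm(51 * 5, 0, 0.02), 51, 5)
        eta <- matrix(rnorm(51 * 5, 0, 0.02), 51, 5)
    })
    rmat <- Re(z) * (1 + eps)
    xmat <- Im(z) * (1 + eta)
    ms <- meanSpectrum(makeReplicateSet(rmat, xmat, f))
    # second, independent summation: Reduce over columns
    rRef <- Reduce(`+`, lapply(1:5, function(j) rmat[, j])) / 5
    xRef <- Reduce(`+`, lapply(1:5, function(j) xmat[, j])) / 5
    expect_lt(max(abs(assay(ms, "resistance")[, 1] - rRef) / abs(rRef)),
              1e-12)
    expect_lt(max(abs(assay(ms, "reactance")[, 1] - xRef) / abs(xRef)),
              1e-12)
})

test_that("averaging is permutation invariant and linear", {
    f <- defaultFrequencyGrid(21L)
    withr::with_seed(5, {
        rmat <- matrix(runif(21 * 4, 1e5, 1e6), 21, 4)
        xmat <- -matrix(runif(21 * 4, 1e4, 1e5), 21, 4)
    })
    ms <- meanSpectrum(makeReplicateSet(rmat, xmat, f))
    perm <- c(3, 1, 4, 2)
    msPerm <- meanSpectrum(makeReplicateSet(rmat[, perm], xmat[, perm], f))
    expect_equal(assay(ms, "resistance"), assay(msPerm, "resistance"))
    msScaled <- meanSpectrum(makeReplicateSet(2.5 * rmat, 2.5 * xmat, f))
    expect_equal(assay(msScaled, "resistance")[, 1],
                 2.5 * assay(ms, "resistance")[, 1])
})

test_that("the replicate mean is unbiased under the simulator noise model", {
    # single frequency, many replicates: mean converges to truth
    tr <- truthRow(defaultTruth())
    se <- simulateMeasurements(tr, frequencies = c(1000, 2000),
                               noise = noiseConfig(pointSd = 0.05,
                                                   contactSd = 0,
                                                   nReplicates = 1000L),
                               seed = 9)
    ms <- meanSpectrum(se)
    z <- dsmImpedance(defaultTruth(), c(1000, 2000))
    relDev <- abs(assay(ms, "resistance")[1, 1] - Re(z)[1]) / Re(z)[1]
    # 3 standard errors of the mean
    expect_lt(relDev, 3 * 0.05 / sqrt(1000))
})

test_that("grouping averages each (plant, hour) cell separately", {
    f <- defaultFrequencyGrid(5L)
    se <- SweepExperiment(matrix(rep(c(1, 3, 10, 30), each = 5), 5, 4),
                          matrix(-1, 5, 4), f,
                          plant = c(1L, 1L, 2L, 2L),
                          hour = c(8, 8, 8, 8),
                          replicate = c(1L, 2L, 1L, 2L))
    ms <- meanSpectrum(se)
    expect_identical(ncol(ms), 2L)
    expect_equal(assay(ms, "resistance")[1, ], c(p1_h8_mean = 2,
                                                 p2_h8_mean = 20))
    expect_error(meanSpectrum(se[, 0]), "empty")
})
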