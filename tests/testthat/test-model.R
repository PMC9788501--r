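test_that("capacitive reactance follows -1/(2 pi f C)", {
    expect_equal(capacitiveReactance(1000, 159.155e-12), -1e6,
                 tolerance = 1e-5)
    expect_equal(capacitiveReactance(3e5, 1e-9), -530.52, tolerance = 1e-4)
    # proportional to 1/f
    f <- c(500, 1234.5, 3e5)
    expect_equal(capacitiveReactance(2 * f, 1e-10),
                 capacitiveReactance(f, 1e-10) / 2)
    expect_true(all(capacitiveReactance(f, 2.2e-12) < 0))
    expect_error(capacitiveReactance(0, 1e-12), "frequency")
    expect_error(capacitiveReactance(1000, -1e-12), "capacitance")
})

test_that("phase angle is arctan(XC/R) with documented unit conventions", {
    expect_identical(phaseAngle(1, 0), 0)
    expect_equal(phaseAngle(1, -1), -pi / 4)
    expect_equal(phaseAngle(1, -1, degrees = TRUE), -45)
    expect_equal(phaseAngle(1, -sqrt(3), degrees = TRUE), -60)
    expect_error(phaseAngle(0, -1), "resistance")
})

test_that("DSMParams validity rejects non-physical values", {
    expect_error(DSMParams(-1, 1e6, 1e6, 1e-12, 1e-12), "positive")
    expect_error(DSMParams(1e6, 1e6, 1e6, 0, 1e-12), "positive")
    expect_error(DSMParams(Inf, 1e6, 1e6, 1e-12, 1e-12), "finite")
    p <- defaultTruth()
    expect_true(inBounds(p))
    expect_false(inBounds(DSMParams(1, 1e6, 1e6, 1e-12, 1e-12)))
})

test_that("model limits are R1 and the three-resistor parallel sum", {
    expect_equal(unname(modelLimits(DSMParams(3, 3, 3, 1e-12, 1e-12))),
                 c(3, 1))
    # open intracellular path
    lim <- modelLimits(DSMParams(5e6, 1e11, 1e11, 1e-12, 1e-12))
    expect_equal(unname(lim["high"]), 5e6, tolerance = 1e-4)
    # published averages: independent harmonic-sum oracle
    p <- defaultTruth()
    expect_equal(unname(modelLimits(p)["low"]), 159.07e6)
    expect_equal(unname(modelLimits(p)["high"]),
                 1 / (1 / 159.07e6 + 1 / 4.76e6 + 1 / 1.49e6))
    expect_equal(unname(modelLimits(p)["high"]), 1.1267e6, tolerance = 1e-4)
})

test_that("forward model agrees with an independent complex-arithmetic oracle", {
    f <- defaultFrequencyGrid(31L)
    withr::with_seed(7, {
        for (i in 1:100) {
            p <- randomParams()
            z <- dsmImpedance(p, f)
            zo <- oracleDSM(p, f)
            expect_lt(max(Mod(z - zo) / Mod(zo)), 1e-12)
        }
    })
    # the parameterisation used in early reports of the circuit
    p <- DSMParams(159.07e6, 4.76e6, 1.49e6, 100e-12, 1e-9)
    z500 <- dsmImpedance(p, 500)
    expect_lt(Mod(z500 - oracleDSM(p, 500)) / Mod(z500), 1e-12)
    expect_gt(Re(z500), 0)
    expect_lt(Im(z500), 0)
    expect_lt(Mod(z500), 159.07e6)
})

test_that("model spectra are passive and bounded by the extracellular path", {
    f <- defaultFrequencyGrid()
    withr::with_seed(11, {
        for (i in 1:200) {
            p <- randomParams()
            z <- dsmImpedance(p, f)
            expect_true(all(Re(z) > 0))
            expect_true(all(Im(z) <= 0))
            expect_true(all(Mod(z) <= r1(p) * (1 + 1e-12)))
        }
    })
})

test_that("frequency limits are attained and |Z| is monotone on the band", {
    p <- defaultTruth()
    lim <- modelLimits(p)
    expect_lt(abs(Mod(dsmImpedance(p, 1e-6)) - lim["low"]) / lim["low"], 1e-4)
    expect_lt(abs(Mod(dsmImpedance(p, 1e12)) - lim["high"]) / lim["high"],
              1e-4)
    z <- dsmImpedance(p, defaultFrequencyGrid())
    expect_false(is.unsorted(rev(Mod(z))))
})

test_that("extreme frequencies never produce non-finite impedance", {
    p <- DSMParams(1e12, 1e3, 1e3, 1e-13, 1e-6)
    for (f in c(1e-300, 1e-30, 1e-6, 1, 1e12, 1e30)) {
        z <- dsmImpedance(p, f)
        expect_true(is.finite(Re(z)) && is.finite(Im(z)))
    }
    expect_error(dsmImpedance(p, c(100, 100)), "strictly increasing")
    expect_error(dsmImpedance(p, -5), "positive")
})
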