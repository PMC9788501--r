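# Independent oracles and fixture builders shared across the suite.

# Brute-force evaluation of the double-shell ladder, written via a different
# algebraic route (admittance of the tonoplast branch first) than the
# package's nested evaluation.
oracleDSM <- function(params, frequencies) {
    v <- dsmValues(params)
    w <- 2 * pi * frequencies
    y45 <- 1 / (v[["r4"]] + 1 / (1i * w * v[["c5"]]))
    zinner <- 1 / (1 / v[["r2"]] + y45)
    zintra <- 1 / (1i * w * v[["c3"]]) + zinner
    1 / (1 / v[["r1"]] + 1 / zintra)
}

# Seeded random in-bounds parameter set (log-uniform inside the default box,
# kept one decade away from the edges so +/-10% probes stay in bounds).
randomParams <- function() {
    DSMParams(r1 = 10^runif(1, 4, 11), r2 = 10^runif(1, 4, 11),
              r4 = 10^runif(1, 4, 11), c3 = 10^runif(1, -12.5, -7),
              c5 = 10^runif(1, -12.5, -7))
}

paramsFromVector <- function(v) {
    DSMParams(r1 = v[["r1"]], r2 = v[["r2"]], r4 = v[["r4"]],
              c3 = v[["c3"]], c5 = v[["c5"]])
}

# One-row truth table in the fitTimeseries column format.
truthRow <- function(params, plant = 1L, hour = 8) {
    v <- dsmValues(params)
    data.frame(plant = plant, hour = hour, r1_ohm = v[["r1"]],
               r2_ohm = v[["r2"]], r4_ohm = v[["r4"]],
               c3_farad = v[["c3"]], c5_farad = v[["c5"]])
}

# Accuracy-mode configuration for noiseless recovery experiments: threshold
# near zero (the data have no noise floor) and a finer step floor to resolve
# it.
accuracyConfig <- function(...) {
    fitConfig(thresholdValue = 2e-4, alphaMin = 1e-4, ...)
}

relErrVector <- function(fitted, truth) {
    abs(dsmValues(fitted) / dsmValues(truth) - 1)
}
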