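#' Capacitive reactance
#'
#' The reactance of an ideal capacitor, \eqn{X_C = -1/(2\pi f C)}: always
#' strictly negative, halving when the frequency doubles.
#'
#' @param frequency frequency in Hz, strictly positive (vectorised).
#' @param capacitance capacitance in farads, strictly positive.
#' @return reactance in ohms (negative).
#' @examples
#' capacitiveReactance(1000, 159.155e-12)   # ~ -1 MOhm
#' @export
capacitiveReactance <- function(frequency, capacitance) {
    if (any(!is.finite(frequency)) || any(frequency <= 0))
        stop("'frequency' must be strictly positive and finite")
    if (any(!is.finite(capacitance)) || any(capacitance <= 0))
        stop("'capacitance' must be strictly positive and finite")
    -1 / (2 * pi * frequency * capacitance)
}

#' Phase angle of an impedance
#'
#' \eqn{\theta = \arctan(X_C / R)}.  Radians by default; set
#' \code{degrees = TRUE} for human-readable output.
#'
#' @param resistance real part, ohms, strictly positive.
#' @param reactance imaginary part, ohms.
#' @param degrees return degrees instead of radians.
#' @return phase angle (negative for capacitive loads).
#' @examples
#' phaseAngle(1, -1, degrees = TRUE)   # -45
#' @export
phaseAngle <- function(resistance, reactance, degrees = FALSE) {
    if (any(!is.finite(resistance)) || any(resistance <= 0))
        stop("'resistance' must be strictly positive (the quotient XC/R is undefined at R = 0)")
    theta <- atan(reactance / resistance)
    if (degrees) theta * 180 / pi else theta
}

#' Default analysis frequency grid
#'
#' A log-spaced sweep grid covering the analysis band, by default 201 points
#' between 500 Hz and 300 kHz (the instrument can sweep from 20 Hz; the wider
#' band is available by changing \code{fMin}).
#'
#' @param n number of points.
#' @param fMin,fMax band edges, Hz.
#' @return numeric vector of strictly increasing frequencies, Hz.
#' @export
defaultFrequencyGrid <- function(n = 201L, fMin = 500, fMax = 3e5) {
    stopifnot(n >= 2L, fMin > 0, fMax > fMin)
    f <- 10^seq(log10(fMin), log10(fMax), length.out = n)
    f[1] <- fMin
    f[n] <- fMax
    f
}

.checkGrid <- function(frequencies) {
    if (length(frequencies) < 1L)
        stop("frequency grid is empty")
    if (any(!is.finite(frequencies)) || any(frequencies <= 0))
        stop("frequencies must be positive and finite")
    if (is.unsorted(frequencies, strictly = TRUE))
        stop("frequency grid must be strictly increasing with no duplicates")
    invisible(frequencies)
}

#' Double-shell model impedance
#'
#' Forward model of the five-element double-shell equivalent circuit: the
#' extracellular resistor R1 in parallel with the intracellular branch, which
#' is the plasma-membrane capacitor C3 in series with (the cytoplasm resistor
#' R2 in parallel with the series pair tonoplast capacitor C5 + vacuole
#' resistor R4):
#' \deqn{Z(\omega) = \left[\frac{1}{R_1} + \frac{1}{Z_{intra}(\omega)}\right]^{-1},
#'   \quad Z_{intra} = \frac{1}{j\omega C_3} +
#'   \frac{R_2 (R_4 + 1/(j\omega C_5))}{R_2 + R_4 + 1/(j\omega C_5)}.}
#'
#' At low frequency both capacitors block and \eqn{Z \to R_1}; at high
#' frequency they short and \eqn{Z \to (1/R_1 + 1/R_2 + 1/R_4)^{-1}}.  The
#' returned spectrum is passive: \eqn{\mathrm{Re}\,Z > 0},
#' \eqn{\mathrm{Im}\,Z \le 0} and \eqn{|Z| \le R_1} at every frequency.
#' Degenerate reactances at extreme frequencies are resolved through
#' admittances, so in-bounds inputs never produce non-finite output.
#'
#' @param params a \linkS4class{DSMParams} object.
#' @param frequencies strictly increasing positive frequencies, Hz.
#' @return complex vector of impedances, ohms (one per frequency).
#' @examples
#' z <- dsmImpedance(defaultTruth(), defaultFrequencyGrid())
#' head(Re(z)); head(Im(z))
#' @export
dsmImpedance <- function(params, frequencies) {
    stopifnot(is(params, "DSMParams"))
    validObject(params)
    .checkGrid(frequencies)
    .dsmZ(dsmValues(params), 2 * pi * frequencies)
}

## fast path shared with the fitter: v is the named value vector, w = 2*pi*f
.dsmZ <- function(v, w) {
    xc5 <- -1 / (w * v[["c5"]])
    z45 <- complex(real = v[["r4"]], imaginary = xc5)
    ## R2 || (R4 + C5); an open tonoplast branch leaves just R2
    zpar <- ifelse(is.finite(xc5),
                   v[["r2"]] * z45 / (v[["r2"]] + z45),
                   complex(real = v[["r2"]], imaginary = 0))
    xc3 <- -1 / (w * v[["c3"]])
    zintra <- zpar + complex(real = 0, imaginary = xc3)
    yintra <- ifelse(is.finite(xc3) & is.finite(zintra),
                     1 / zintra, complex(real = 0, imaginary = 0))
    1 / (1 / v[["r1"]] + yintra)
}

#' Low- and high-frequency limits of the double-shell model
#'
#' At DC only the extracellular path conducts, so the limit is R1; as
#' frequency grows both membranes short and all three resistors conduct in
#' parallel.  Used to seed cold starts and as an analytic cross-check of the
#' forward model.
#'
#' @param params a \linkS4class{DSMParams} object.
#' @return named numeric: \code{low} = R1 and
#'   \code{high} = \eqn{(1/R_1 + 1/R_2 + 1/R_4)^{-1}}, ohms.
#' @examples
#' modelLimits(defaultTruth())
#' @export
modelLimits <- function(params) {
    stopifnot(is(params, "DSMParams"))
    c(low = params@r1,
      high = 1 / (1 / params@r1 + 1 / params@r2 + 1 / params@r4))
}
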