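#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata
#' @import SummarizedExperiment
NULL

## canonical coordinate order; also the fitter's tie-break order
.dsmParamNames <- c("r1", "r2", "r4", "c3", "c5")

#' Double-shell model parameters
#'
#' One point in the five-dimensional parameter space of the double-shell
#' equivalent circuit of a plant cell: the cell-wall/extracellular-fluid
#' resistance \code{r1}, the cytoplasmic resistance \code{r2}, the vacuole
#' resistance \code{r4} (all in ohms), the plasma-membrane capacitance
#' \code{c3} and the vacuolar-membrane (tonoplast) capacitance \code{c5}
#' (both in farads).
#'
#' All five values must be strictly positive and finite.  Physical bounds
#' (used by the fitter to reject candidate steps) are carried separately in
#' a \code{\link{fitConfig}} via \code{\link{dsmBounds}}.
#'
#' @slot r1 numeric(1), extracellular resistance, ohms.
#' @slot r2 numeric(1), cytoplasmic resistance, ohms.
#' @slot r4 numeric(1), vacuole resistance, ohms.
#' @slot c3 numeric(1), plasma-membrane capacitance, farads.
#' @slot c5 numeric(1), tonoplast capacitance, farads.
#'
#' @seealso \code{\link{DSMParams}}, \code{\link{dsmImpedance}}
#' @exportClass DSMParams
setClass("DSMParams",
    representation(r1 = "numeric", r2 = "numeric", r4 = "numeric",
                   c3 = "numeric", c5 = "numeric"))

setValidity("DSMParams", function(object) {
    v <- c(r1 = object@r1, r2 = object@r2, r4 = object@r4,
           c3 = object@c3, c5 = object@c5)
    if (length(v) != 5L)
        return("each of r1, r2, r4, c3, c5 must be a single numeric value")
    bad <- !is.finite(v) | v <= 0
    if (any(bad))
        return(sprintf("parameter(s) %s must be strictly positive and finite",
                       paste(names(v)[bad], collapse = ", ")))
    TRUE
})

#' Frequency sweep container
#'
#' A \code{SweepExperiment} holds a collection of impedance frequency sweeps
#' as a \linkS4class{SummarizedExperiment}: rows are the frequencies of a
#' shared grid (strictly increasing, in Hz, stored in
#' \code{rowData()$frequency_hz}), columns are individual sweeps annotated in
#' \code{colData()} with \code{plant}, \code{hour} and \code{replicate}
#' indices, and the two assays \code{resistance} and \code{reactance} store
#' the real and imaginary parts of the measured impedance in ohms.
#' Replicate-averaged spectra (see \code{\link{meanSpectrum}}) carry
#' \code{replicate = NA} and an \code{n_replicates} column.
#'
#' @seealso \code{\link{SweepExperiment}}, \code{\link{meanSpectrum}},
#'   \code{\link{readSweeps}}
#' @exportClass SweepExperiment
setClass("SweepExperiment", contains = "SummarizedExperiment")

setValidity("SweepExperiment", function(object) {
    msg <- character()
    if (!all(c("resistance", "reactance") %in% assayNames(object)))
        msg <- c(msg, "assays 'resistance' and 'reactance' are required")
    rd <- rowData(object)
    if (!"frequency_hz" %in% colnames(rd)) {
        msg <- c(msg, "rowData must contain 'frequency_hz'")
    } else {
        f <- rd$frequency_hz
        if (any(!is.finite(f)) || any(f <= 0))
            msg <- c(msg, "frequencies must be positive and finite")
        if (is.unsorted(f, strictly = TRUE))
            msg <- c(msg, "frequency grid must be strictly increasing")
    }
    cd <- colData(object)
    need <- c("plant", "hour", "replicate")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'plant', 'hour', 'replicate'")
    if (length(msg)) msg else TRUE
})

#' Fitting configuration
#'
#' Settings for the coordinate-search fit of the double-shell model to a
#' measured spectrum.  Construct with \code{\link{fitConfig}}.
#'
#' @slot thresholdMode \code{"relative"} (threshold is a fraction of the
#'   summed measured impedance magnitude) or \code{"absolute"} (ohms).
#' @slot thresholdValue numeric(1), stopping threshold in the chosen mode.
#' @slot alphaStart numeric(1), initial fractional step length.
#' @slot alphaMin numeric(1), smallest fractional step length probed.
#' @slot shrinkFactor numeric(1), divisor applied to the step length when a
#'   full screening sweep finds no improvement.
#' @slot maxEvals integer(1), budget of error-function evaluations.
#' @slot errorMetric \code{"modulus"} (sum of complex moduli of the
#'   residuals) or \code{"components"} (sum of absolute real plus absolute
#'   imaginary residuals).
#' @slot free character, the subset of parameters allowed to move.
#' @slot bounds named list with \code{rMin}, \code{rMax}, \code{cMin},
#'   \code{cMax}; see \code{\link{dsmBounds}}.
#' @exportClass FitConfig
setClass("FitConfig",
    representation(thresholdMode = "character", thresholdValue = "numeric",
                   alphaStart = "numeric", alphaMin = "numeric",
                   shrinkFactor = "numeric", maxEvals = "integer",
                   errorMetric = "character", free = "character",
                   bounds = "list"))

setValidity("FitConfig", function(object) {
    msg <- character()
    if (!object@thresholdMode %in% c("relative", "absolute"))
        msg <- c(msg, "thresholdMode must be 'relative' or 'absolute'")
    if (!object@errorMetric %in% c("modulus", "components"))
        msg <- c(msg, "errorMetric must be 'modulus' or 'components'")
    if (!(object@thresholdValue >= 0))
        msg <- c(msg, "thresholdValue must be >= 0")
    if (!(object@alphaMin > 0 && object@alphaMin < object@alphaStart &&
          object@alphaStart < 1))
        msg <- c(msg, "need 0 < alphaMin < alphaStart < 1")
    if (!(object@shrinkFactor > 1))
        msg <- c(msg, "shrinkFactor must be > 1")
    if (object@maxEvals < 1L)
        msg <- c(msg, "maxEvals must be >= 1")
    if (!all(object@free %in% .dsmParamNames) || length(object@free) < 1L)
        msg <- c(msg, "free must be a non-empty subset of r1,r2,r4,c3,c5")
    bn <- c("rMin", "rMax", "cMin", "cMax")
    if (!all(bn %in% names(object@bounds)))
        msg <- c(msg, "bounds must name rMin, rMax, cMin, cMax")
    if (length(msg)) msg else TRUE
})

#' Result of one coordinate-search fit
#'
#' @slot plant integer(1) plant index (NA when fitting a bare spectrum).
#' @slot hour numeric(1) hour index.
#' @slot params \linkS4class{DSMParams}, the estimated circuit parameters.
#' @slot finalError numeric(1), final summed absolute impedance error, ohms.
#' @slot initError numeric(1), error at the starting centre, ohms.
#' @slot nEvals integer(1), number of error evaluations spent.
#' @slot converged logical(1), TRUE iff the threshold was met.
#' @slot reason character(1), one of \code{"threshold"}, \code{"step_floor"},
#'   \code{"budget"}, \code{"failed"}.
#' @slot trace numeric, errors of the accepted iterates (strictly
#'   decreasing), starting at the initial error.
#' @exportClass FitResult
setClass("FitResult",
    representation(plant = "integer", hour = "numeric", params = "DSMParams",
                   finalError = "numeric", initError = "numeric",
                   nEvals = "integer", converged = "logical",
                   reason = "character", trace = "numeric"))

#' Ground-truth trajectory configuration for the simulator
#'
#' Defines how the true circuit parameters of each plant evolve over the
#' monitoring window: a dehydrated baseline, a step response to a
#' water-uptake event, and an exponential relaxation toward a hydrated
#' target once the grow light switches on.  Construct with
#' \code{\link{trajectoryConfig}}.
#'
#' @slot hours numeric, sampled hours (hour-of-day).
#' @slot baseline \linkS4class{DSMParams} for the dehydrated state.
#' @slot waterEventHour numeric(1).
#' @slot waterMultipliers named numeric(5), factor applied to each baseline
#'   parameter from the first sampled hour after the water event.
#' @slot ledEventHour numeric(1).
#' @slot relaxRate named numeric(5), exponential rate (per hour) of the
#'   post-illumination relaxation of each parameter.
#' @slot hydratedMultipliers named numeric(5), the relaxation target as a
#'   factor of baseline.
#' @slot nPlants integer(1).
#' @slot plantJitterSd numeric(1), sd of the per-plant log-normal scale
#'   jitter (0 disables it).
#' @exportClass TrajectoryConfig
setClass("TrajectoryConfig",
    representation(hours = "numeric", baseline = "DSMParams",
                   waterEventHour = "numeric", waterMultipliers = "numeric",
                   ledEventHour = "numeric", relaxRate = "numeric",
                   hydratedMultipliers = "numeric", nPlants = "integer",
                   plantJitterSd = "numeric"))

setValidity("TrajectoryConfig", function(object) {
    msg <- character()
    if (length(object@hours) < 1L || is.unsorted(object@hours, strictly = TRUE))
        msg <- c(msg, "hours must be non-empty and strictly increasing")
    ## events may predate a truncated window (the plant is already watered /
    ## lit) but cannot postdate it
    if (object@waterEventHour > max(object@hours) ||
        object@ledEventHour > max(object@hours))
        msg <- c(msg, "event hours must not lie after the sampled hours")
    if (object@ledEventHour < object@waterEventHour)
        msg <- c(msg, "the LED event cannot precede the water event")
    for (nm in c("waterMultipliers", "hydratedMultipliers", "relaxRate")) {
        v <- slot(object, nm)
        if (!identical(sort(names(v)), sort(.dsmParamNames)))
            msg <- c(msg, sprintf("%s must be named r1,r2,r4,c3,c5", nm))
    }
    if (any(object@waterMultipliers <= 0) || any(object@hydratedMultipliers <= 0))
        msg <- c(msg, "multipliers must be > 0")
    if (any(object@relaxRate < 0))
        msg <- c(msg, "relaxation rates must be >= 0")
    if (object@nPlants < 1L)
        msg <- c(msg, "nPlants must be >= 1")
    if (object@plantJitterSd < 0)
        msg <- c(msg, "plantJitterSd must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Measurement-noise configuration for the simulator
#'
#' @slot pointSd numeric(1), sd of the per-point multiplicative Gaussian
#'   noise applied independently to resistance and reactance.
#' @slot contactSd numeric(1), sd of the per-replicate contact scale (one
#'   scalar multiplying the whole sweep, emulating electrode-contact
#'   variation).
#' @slot nReplicates integer(1), replicate sweeps per (plant, hour).
#' @exportClass NoiseConfig
setClass("NoiseConfig",
    representation(pointSd = "numeric", contactSd = "numeric",
                   nReplicates = "integer"))

setValidity("NoiseConfig", function(object) {
    msg <- character()
    if (object@pointSd < 0 || object@contactSd < 0)
        msg <- c(msg, "noise sds must be >= 0")
    if (object@nReplicates < 1L)
        msg <- c(msg, "nReplicates must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Complete run configuration
#'
#' Bundles the frequency grid specification, the fit, trajectory and noise
#' configurations, and the random seed of one pipeline run.  Round-trips
#' losslessly through YAML via \code{\link{writeRunConfig}} /
#' \code{\link{readRunConfig}}.
#'
#' @slot gridN integer(1), number of sweep points.
#' @slot gridMinHz,gridMaxHz numeric(1), band edges in Hz.
#' @slot fit \linkS4class{FitConfig}.
#' @slot trajectory \linkS4class{TrajectoryConfig}.
#' @slot noise \linkS4class{NoiseConfig}.
#' @slot seed integer(1), master RNG seed.
#' @exportClass RunConfig
setClass("RunConfig",
    representation(gridN = "integer", gridMinHz = "numeric",
                   gridMaxHz = "numeric", fit = "FitConfig",
                   trajectory = "TrajectoryConfig", noise = "NoiseConfig",
                   seed = "integer"))

setValidity("RunConfig", function(object) {
    if (object@gridN < 2L) return("gridN must be >= 2")
    if (!(object@gridMinHz > 0 && object@gridMaxHz > object@gridMinHz))
        return("need 0 < gridMinHz < gridMaxHz")
    TRUE
})

#' Result of a full study run
#'
#' @slot fits data.frame of per-(plant, hour) fit rows (see
#'   \code{\link{fitTimeseries}}).
#' @slot summary data.frame of per-parameter grand means and per-plant means
#'   over converged fits.
#' @slot ratios named numeric: \code{r1_over_r2}, \code{r1_over_r4},
#'   \code{r2_over_r4}, computed from the grand-mean resistances.
#' @slot nExcluded integer(1), number of non-converged fits excluded from the
#'   averages.
#' @slot truth data.frame of generating parameters (simulated runs) or a
#'   zero-row data.frame for file input.
#' @exportClass StudyResult
setClass("StudyResult",
    representation(fits = "data.frame", summary = "data.frame",
                   ratios = "numeric", nExcluded = "integer",
                   truth = "data.frame"))
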