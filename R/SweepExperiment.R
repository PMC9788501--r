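#' Construct a SweepExperiment
#'
#' @param resistance,reactance numeric matrices (frequency x sweep), ohms.
#'   Reactance follows the capacitive sign convention (non-positive for
#'   model-generated spectra).
#' @param frequency shared frequency grid, Hz, strictly increasing.
#' @param plant,hour,replicate per-column annotation vectors; \code{replicate}
#'   may be NA for replicate-averaged spectra.
#' @param nReplicates optional per-column count of replicates averaged into
#'   each sweep (recorded by \code{\link{meanSpectrum}}).
#' @return a \linkS4class{SweepExperiment}.
#' @export
SweepExperiment <- function(resistance, reactance, frequency,
                            plant, hour, replicate,
                            nReplicates = NULL) {
    resistance <- as.matrix(resistance)
    reactance <- as.matrix(reactance)
    .checkGrid(frequency)
    stopifnot(nrow(resistance) == length(frequency),
              identical(dim(resistance), dim(reactance)))
    cd <- DataFrame(plant = as.integer(plant), hour = as.numeric(hour),
                    replicate = as.integer(replicate))
    if (!is.null(nReplicates))
        cd$n_replicates <- as.integer(nReplicates)
    dimnames(resistance) <- dimnames(reactance) <-
        list(NULL, .sweepNames(cd$plant, cd$hour, cd$replicate))
    se <- SummarizedExperiment(
        assays = SimpleList(resistance = resistance, reactance = reactance),
        rowData = DataFrame(frequency_hz = as.numeric(frequency)),
        colData = cd)
    new("SweepExperiment", se)
}

.sweepNames <- function(plant, hour, replicate) {
    ifelse(is.na(replicate),
           sprintf("p%d_h%g_mean", plant, hour),
           sprintf("p%d_h%g_r%d", plant, hour, replicate))
}

#' @describeIn SweepExperiment the shared frequency grid, Hz.
#' @param x a \code{SweepExperiment}.
#' @export
frequencies <- function(x) {
    stopifnot(is(x, "SweepExperiment"))
    rowData(x)$frequency_hz
}

#' @describeIn SweepExperiment complex impedance matrix
#'   (frequency x sweep), \code{resistance + 1i * reactance}.
#' @export
impedanceMatrix <- function(x) {
    stopifnot(is(x, "SweepExperiment"))
    matrix(complex(real = assay(x, "resistance"),
                   imaginary = assay(x, "reactance")),
           nrow = nrow(x), dimnames = dimnames(assay(x, "resistance")))
}

#' @describeIn SweepExperiment sweep annotation (plant, hour, replicate) as a
#'   plain data.frame.
#' @export
sweepInfo <- function(x) {
    stopifnot(is(x, "SweepExperiment"))
    as.data.frame(colData(x))
}

setMethod("show", "SweepExperiment", function(object) {
    cd <- colData(object)
    cat(sprintf("SweepExperiment: %d frequencies x %d sweeps\n",
                nrow(object), ncol(object)))
    f <- rowData(object)$frequency_hz
    cat(sprintf("  band: %.4g Hz - %.4g Hz\n", min(f), max(f)))
    cat(sprintf("  plants: %s | hours: %s | replicates per cell: %s\n",
                paste(sort(unique(cd$plant)), collapse = ","),
                paste(range(cd$hour), collapse = "-"),
                paste(sort(unique(cd$replicate[!is.na(cd$replicate)])),
                      collapse = ",")))
})

#' Average replicate sweeps into mean spectra
#'
#' Collapses the N replicate sweeps of every (plant, hour) cell into one mean
#' spectrum by the plain arithmetic mean of resistance and reactance at each
#' frequency — no trimming, no weighting.  Cells with fewer than the nominal
#' five replicates are averaged over the replicates actually present.
#'
#' @param x a \linkS4class{SweepExperiment} of replicate sweeps.
#' @return a \code{SweepExperiment} with one column per (plant, hour),
#'   \code{replicate = NA} and an \code{n_replicates} colData column.
#' @examples
#' se <- simulateMeasurements(seed = 1)
#' meanSpectrum(se)
#' @export
meanSpectrum <- function(x) {
    stopifnot(is(x, "SweepExperiment"))
    if (ncol(x) == 0L)
        stop("cannot average an empty sweep set")
    cd <- colData(x)
    key <- paste(cd$plant, cd$hour, sep = "\r")
    groups <- split(seq_len(ncol(x)), key)
    ## deterministic output order: plant, then hour
    first <- vapply(groups, `[`, integer(1), 1L)
    ord <- order(cd$plant[first], cd$hour[first])
    groups <- groups[ord]
    rmat <- assay(x, "resistance")
    xmat <- assay(x, "reactance")
    rmean <- vapply(groups, function(j) rowMeans(rmat[, j, drop = FALSE]),
                    numeric(nrow(x)))
    xmean <- vapply(groups, function(j) rowMeans(xmat[, j, drop = FALSE]),
                    numeric(nrow(x)))
    first <- vapply(groups, `[`, integer(1), 1L)
    SweepExperiment(resistance = rmean, reactance = xmean,
                    frequency = frequencies(x),
                    plant = cd$plant[first], hour = cd$hour[first],
                    replicate = NA_integer_,
                    nReplicates = lengths(groups))
}

#' Summed absolute impedance error between two spectra
#'
#' The fitting objective: the sum over the frequency grid of the modulus of
#' the complex difference between measured and estimated impedance,
#' \eqn{Z'_{err} = \sum_f |Z_m(f) - Z_e(f)|}.  Symmetric in its arguments and
#' zero iff the spectra are identical.  The \code{"components"} metric sums
#' \eqn{|\Delta R| + |\Delta X|} instead and is provided for sensitivity
#' analysis only.
#'
#' @param measured,estimated complex impedance vectors on the same frequency
#'   grid, or single-column \linkS4class{SweepExperiment}s (in which case the
#'   grids are checked for identity).
#' @param metric \code{"modulus"} (default) or \code{"components"}.
#' @return error in ohms (non-negative scalar).
#' @examples
#' f <- defaultFrequencyGrid()
#' zm <- dsmImpedance(defaultTruth(), f)
#' impedanceError(zm, zm + complex(real = 3, imaginary = -4))  # 201 * 5
#' @export
impedanceError <- function(measured, estimated,
                           metric = c("modulus", "components")) {
    metric <- match.arg(metric)
    if (is(measured, "SweepExperiment") || is(estimated, "SweepExperiment")) {
        stopifnot(is(measured, "SweepExperiment"),
                  is(estimated, "SweepExperiment"),
                  ncol(measured) == 1L, ncol(estimated) == 1L)
        if (!isTRUE(all.equal(frequencies(measured), frequencies(estimated))))
            stop("frequency grids of 'measured' and 'estimated' differ")
        measured <- impedanceMatrix(measured)[, 1L]
        estimated <- impedanceMatrix(estimated)[, 1L]
    }
    if (length(measured) != length(estimated))
        stop("'measured' and 'estimated' are on different frequency grids ",
             "(lengths ", length(measured), " vs ", length(estimated), ")")
    d <- measured - estimated
    if (metric == "modulus") sum(Mod(d)) else sum(abs(Re(d)) + abs(Im(d)))
}
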