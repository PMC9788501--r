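#' Create a fitting configuration
#'
#' Defaults follow the published search design: screening step lengths from
#' 10\% down to 0.1\% of each parameter's current value (shrunk tenfold
#' whenever a full screening sweep finds no improvement) and a step-doubling
#' line search along the best improving coordinate.  The stopping threshold
#' was never published; the default is set by the noise-floor rule
#' (\code{\link{expectedNoiseFloor}}): stop when the relative misfit falls
#' below twice the expected residual of the replicate mean under the default
#' noise model (\code{2 * expectedNoiseFloor(noiseConfig()) = 0.0075}).
#' Stopping much above the floor leaves the weakly sensed intracellular
#' parameters unresolved; stopping below it cannot converge.  For noiseless
#' data use a tight threshold (e.g. \code{2e-4}) with a smaller
#' \code{alphaMin}.
#'
#' @param thresholdMode \code{"relative"} or \code{"absolute"}.
#' @param thresholdValue stopping threshold (fraction of
#'   \eqn{\sum_f |Z_m(f)|} in relative mode, ohms in absolute mode).
#' @param alphaStart,alphaMin initial / minimum fractional step length.
#' @param shrinkFactor step-length divisor between screening rounds.
#' @param maxEvals budget of error evaluations.
#' @param errorMetric see \code{\link{impedanceError}}.
#' @param free parameters allowed to move (default all five).
#' @param bounds see \code{\link{dsmBounds}}.
#' @return a \linkS4class{FitConfig}.
#' @export
fitConfig <- function(thresholdMode = "relative",
                      thresholdValue = 2 * expectedNoiseFloor(noiseConfig()),
                      alphaStart = 0.10, alphaMin = 0.001,
                      shrinkFactor = 10, maxEvals = 10000L,
                      errorMetric = "modulus",
                      free = c("r1", "r2", "r4", "c3", "c5"),
                      bounds = dsmBounds()) {
    new("FitConfig", thresholdMode = thresholdMode,
        thresholdValue = as.numeric(thresholdValue),
        alphaStart = as.numeric(alphaStart), alphaMin = as.numeric(alphaMin),
        shrinkFactor = as.numeric(shrinkFactor),
        maxEvals = as.integer(maxEvals), errorMetric = errorMetric,
        free = free, bounds = bounds)
}

setMethod("show", "FitConfig", function(object) {
    cat("FitConfig\n")
    cat(sprintf("  threshold: %g (%s) | alpha: %g -> %g (/%g) | budget: %d evals\n",
                object@thresholdValue, object@thresholdMode,
                object@alphaStart, object@alphaMin, object@shrinkFactor,
                object@maxEvals))
    cat(sprintf("  metric: %s | free: %s\n", object@errorMetric,
                paste(object@free, collapse = ",")))
})

.vecInBounds <- function(v, bounds) {
    all(v[c("r1", "r2", "r4")] >= bounds$rMin,
        v[c("r1", "r2", "r4")] <= bounds$rMax,
        v[c("c3", "c5")] >= bounds$cMin,
        v[c("c3", "c5")] <= bounds$cMax)
}

.sumAbs <- function(d, metric) {
    if (metric == "modulus") sum(Mod(d)) else sum(abs(Re(d)) + abs(Im(d)))
}

.thresholdOhm <- function(zm, config) {
    if (config@thresholdMode == "relative")
        config@thresholdValue * sum(Mod(zm))
    else config@thresholdValue
}

#' Propose coordinate-search candidates
#'
#' For every free coordinate and every direction in \code{s = c(+1, 0, -1)},
#' the candidate obtained by moving that single coordinate by
#' \code{alpha * value * direction} (a multiplicative step: \code{alpha} is a
#' fraction of the coordinate's current value, so one dimensionless step
#' length spans megaohm resistances and picofarad capacitances alike).
#' Candidates that leave the parameter bounds are discarded and reported in
#' the \code{"discarded"} attribute.
#'
#' @param center a \linkS4class{DSMParams}, the current search centre.
#' @param alpha fractional step length.
#' @param config a \linkS4class{FitConfig}.
#' @return list of \code{list(params, coordinate, direction)}; the
#'   \code{"discarded"} attribute is a data.frame of rejected
#'   (coordinate, direction) pairs.
#' @export
proposeCandidates <- function(center, alpha, config = fitConfig()) {
    stopifnot(is(center, "DSMParams"), alpha > 0)
    v0 <- dsmValues(center)
    out <- list()
    disc <- list()
    for (nm in intersect(.dsmParamNames, config@free)) {
        for (dir in c(1L, 0L, -1L)) {
            v <- v0
            v[nm] <- v[nm] * (1 + alpha * dir)
            if (.vecInBounds(v, config@bounds)) {
                out[[length(out) + 1L]] <-
                    list(params = .paramsFromValues(v), coordinate = nm,
                         direction = dir)
            } else {
                disc[[length(disc) + 1L]] <-
                    data.frame(coordinate = nm, direction = dir)
            }
        }
    }
    attr(out, "discarded") <-
        if (length(disc)) do.call(rbind, disc)
        else data.frame(coordinate = character(), direction = integer())
    out
}

## step-doubling line search on the named value vector; errFn counts its own
## evaluations through the enclosing environment
.lineSearchVec <- function(errFn, v, e, nm, dir, alpha, bounds, evalsLeft) {
    a <- 2 * alpha
    used <- 0L
    trace <- numeric()
    while (used < evalsLeft) {
        cand <- v
        cand[nm] <- cand[nm] * (1 + a * dir)
        if (!.vecInBounds(cand, bounds))
            break
        ec <- errFn(cand)
        used <- used + 1L
        if (ec < e) {
            v <- cand
            e <- ec
            trace <- c(trace, ec)
            a <- 2 * a
        } else break
    }
    list(v = v, e = e, used = used, trace = trace)
}

#' Step-doubling line search along one coordinate
#'
#' Given that a step of fraction \code{alpha} along \code{coordinate} in
#' \code{direction} has already strictly decreased the error, keep doubling
#' the step (each doubled fraction applied from the newest accepted point)
#' while the error strictly decreases and the bounds hold; return the last
#' improving point.  This is the screening refinement used inside
#' \code{\link{coordinateSearch}}, exposed for inspection and testing.
#'
#' @param objective function taking a \linkS4class{DSMParams} and returning
#'   the scalar error.
#' @param center the already-accepted post-step point (a \code{DSMParams}).
#' @param currentError the error at \code{center}.
#' @param coordinate one of \code{"r1","r2","r4","c3","c5"}.
#' @param direction \code{+1} or \code{-1}.
#' @param alpha the fractional step that produced \code{center}.
#' @param bounds see \code{\link{dsmBounds}}.
#' @return \code{list(params, error, nEvals)} for the last improving point;
#'   the error never exceeds \code{currentError}.
#' @export
lineSearch <- function(objective, center, currentError, coordinate, direction,
                       alpha, bounds = dsmBounds()) {
    stopifnot(is(center, "DSMParams"), coordinate %in% .dsmParamNames,
              direction %in% c(-1, 1), alpha > 0)
    res <- .lineSearchVec(function(v) objective(.paramsFromValues(v)),
                          dsmValues(center), currentError, coordinate,
                          direction, alpha, bounds, Inf)
    list(params = .paramsFromValues(res$v), error = res$e, nEvals = res$used)
}

#' Fit the double-shell model to one measured spectrum
#'
#' The published derivative-free search: at the current step length
#' \code{alpha}, probe every free coordinate in both directions
#' (multiplicative steps, best-improvement acceptance with ties broken in
#' the fixed order r1, r2, r4, c3, c5 and +1 before -1); extend the accepted
#' move by a step-doubling line search; when no probe improves, shrink
#' \code{alpha} tenfold; stop when the summed absolute impedance error drops
#' below the threshold (\code{converged = TRUE}), when \code{alpha} would
#' fall below \code{alphaMin} with no improving move, or when the evaluation
#' budget is spent.  The sequence of accepted errors is strictly decreasing,
#' and the result is deterministic in (measured, init, config).
#'
#' @param measured complex measured impedance vector (typically a replicate
#'   mean), or a single-column \linkS4class{SweepExperiment}.
#' @param frequencies frequency grid, Hz (ignored if \code{measured} is a
#'   \code{SweepExperiment}).
#' @param init starting centre, a \linkS4class{DSMParams} within bounds.
#' @param config a \linkS4class{FitConfig}.
#' @param plant,hour optional annotation carried into the result.
#' @return a \linkS4class{FitResult}.
#' @examples
#' f <- defaultFrequencyGrid()
#' zm <- dsmImpedance(defaultTruth(), f)
#' fit <- coordinateSearch(zm, f, initializeCenter(zm, f))
#' fit
#' @export
coordinateSearch <- function(measured, frequencies = NULL, init,
                             config = fitConfig(),
                             plant = NA_integer_, hour = NA_real_) {
    if (is(measured, "SweepExperiment")) {
        stopifnot(ncol(measured) == 1L)
        frequencies <- rowData(measured)$frequency_hz
        measured <- impedanceMatrix(measured)[, 1L]
    }
    stopifnot(is(init, "DSMParams"))
    .checkGrid(frequencies)
    if (length(measured) != length(frequencies))
        stop("'measured' and 'frequencies' differ in length")
    if (!inBounds(init, config@bounds))
        stop("initial centre violates the parameter bounds")
    w <- 2 * pi * frequencies
    metric <- config@errorMetric
    nev <- 0L
    errFn <- function(v) {
        nev <<- nev + 1L
        .sumAbs(measured - .dsmZ(v, w), metric)
    }
    threshold <- .thresholdOhm(measured, config)
    center <- dsmValues(init)
    e <- errFn(center)
    if (!is.finite(e))
        stop("non-finite impedance error at the initial centre")
    initError <- e
    trace <- e
    alpha <- config@alphaStart
    freeOrdered <- intersect(.dsmParamNames, config@free)
    reason <- "budget"
    repeat {
        if (e < threshold) {
            reason <- "threshold"
            break
        }
        if (nev >= config@maxEvals)
            break
        ## screening sweep: evaluate all +/- probes at the current alpha
        best <- NULL
        bestE <- e
        for (nm in freeOrdered) {
            for (dir in c(1L, -1L)) {
                if (nev >= config@maxEvals) break
                cand <- center
                cand[nm] <- cand[nm] * (1 + alpha * dir)
                if (!.vecInBounds(cand, config@bounds)) next
                ec <- errFn(cand)
                if (ec < bestE) {
                    best <- list(v = cand, nm = nm, dir = dir)
                    bestE <- ec
                }
            }
        }
        if (!is.null(best)) {
            center <- best$v
            e <- bestE
            trace <- c(trace, e)
            ls <- .lineSearchVec(errFn, center, e, best$nm, best$dir, alpha,
                                 config@bounds, config@maxEvals - nev)
            center <- ls$v
            e <- ls$e
            trace <- c(trace, ls$trace)
        } else if (nev < config@maxEvals) {
            alphaNext <- alpha / config@shrinkFactor
            if (alphaNext < config@alphaMin) {
                reason <- "step_floor"
                break
            }
            alpha <- alphaNext
        }
    }
    new("FitResult", plant = as.integer(plant), hour = as.numeric(hour),
        params = .paramsFromValues(center), finalError = e,
        initError = initError, nEvals = nev,
        converged = (reason == "threshold"), reason = reason, trace = trace)
}

setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult (plant %s, hour %s): %s after %d evaluations\n",
                ifelse(is.na(object@plant), "-", object@plant),
                ifelse(is.na(object@hour), "-", object@hour),
                ifelse(object@converged, "converged",
                       paste0("stopped (", object@reason, ")")),
                object@nEvals))
    cat(sprintf("  error: %.6g -> %.6g ohm\n", object@initError,
                object@finalError))
    show(object@params)
})

#' @describeIn coordinateSearch estimated parameters of a fit.
#' @param object a \linkS4class{FitResult}.
#' @export
fittedParams <- function(object) {
    stopifnot(is(object, "FitResult"))
    object@params
}

#' Choose the starting centre for a fit
#'
#' Warm starts across the hourly series: with two or more previous fits the
#' centre is the per-parameter linear extrapolation of the last two (clamped
#' to bounds); with exactly one it is reused as is.  The cold start reads the
#' circuit off the measured curve: R1 from \eqn{|Z|} at the lowest frequency
#' (the extracellular plateau), the high-frequency plateau from \eqn{|Z|} at
#' the highest frequency seeding R2 and R4 (split according to the published
#' average cytoplasm-to-vacuole resistance ratio, ~3.19), and the
#' capacitances from a small log-grid screen choosing the lowest summed
#' absolute impedance error.
#'
#' @param measured complex measured spectrum (or single-column
#'   \linkS4class{SweepExperiment}).
#' @param frequencies frequency grid, Hz.
#' @param previousFits data.frame of earlier fits for the same plant (the
#'   format returned by \code{\link{fitTimeseries}}), or NULL.
#' @param config a \linkS4class{FitConfig} (bounds and error metric are
#'   used).
#' @return a \linkS4class{DSMParams} within bounds.
#' @export
initializeCenter <- function(measured, frequencies = NULL,
                             previousFits = NULL, config = fitConfig()) {
    if (is(measured, "SweepExperiment")) {
        stopifnot(ncol(measured) == 1L)
        frequencies <- rowData(measured)$frequency_hz
        measured <- impedanceMatrix(measured)[, 1L]
    }
    .checkGrid(frequencies)
    bounds <- config@bounds
    cols <- paste0(c("r1", "r2", "r4"), "_ohm")
    cols <- c(cols, paste0(c("c3", "c5"), "_farad"))
    if (!is.null(previousFits) && nrow(previousFits) > 0L) {
        pf <- previousFits[order(previousFits$hour), , drop = FALSE]
        pf <- pf[stats::complete.cases(pf[, cols]), , drop = FALSE]
        if (nrow(pf) >= 2L) {
            last <- unlist(pf[nrow(pf), cols])
            prev <- unlist(pf[nrow(pf) - 1L, cols])
            v <- last + (last - prev)
            names(v) <- .dsmParamNames
            v <- .clampToBounds(v, bounds)
            ## extrapolation can only be used if it stays physical
            if (all(v > 0)) return(.paramsFromValues(v))
        } else if (nrow(pf) == 1L) {
            v <- unlist(pf[1L, cols])
            names(v) <- .dsmParamNames
            return(.paramsFromValues(.clampToBounds(v, bounds)))
        }
    }
    ## cold start from the band edges of the measured curve; the
    ## high-frequency plateau is resistive, and Re(Z) converges to it well
    ## before |Z| does (the residual dispersion at the band top is mostly
    ## reactive), so the plateau is read off the real part
    zmod <- Mod(measured)
    r1 <- min(max(zmod[1L], bounds$rMin), bounds$rMax)
    rHigh <- Re(measured)[length(measured)]
    if (!is.finite(rHigh) || rHigh <= 0)
        rHigh <- zmod[length(zmod)]
    gIntra <- max(1 / rHigh - 1 / r1, 1 / bounds$rMax)
    ratio <- 4.76 / 1.49           # published average R2/R4
    r4v <- (1 + 1 / ratio) / gIntra
    v <- c(r1 = r1, r2 = ratio * r4v, r4 = r4v, c3 = NA_real_, c5 = NA_real_)
    v[c("r1", "r2", "r4")] <- .clampToBounds(
        c(v[c("r1", "r2", "r4")], c3 = bounds$cMin, c5 = bounds$cMin),
        bounds)[c("r1", "r2", "r4")]
    ## screen capacitances on a log grid, keeping the best error pair
    cgrid <- 10^seq(log10(max(bounds$cMin, 1e-13)),
                    log10(min(bounds$cMax, 1e-7)), length.out = 8L)
    w <- 2 * pi * frequencies
    bestE <- Inf
    bestC <- c(cgrid[1L], cgrid[1L])
    for (cc3 in cgrid) {
        for (cc5 in cgrid) {
            vv <- v
            vv[["c3"]] <- cc3
            vv[["c5"]] <- cc5
            e <- .sumAbs(measured - .dsmZ(vv, w), config@errorMetric)
            if (e < bestE) {
                bestE <- e
                bestC <- c(cc3, cc5)
            }
        }
    }
    v[["c3"]] <- bestC[1L]
    v[["c5"]] <- bestC[2L]
    .paramsFromValues(v)
}

#' Fit the hourly series of one or more plants
#'
#' For every plant independently and every hour in ascending order:
#' average the replicate sweeps (\code{\link{meanSpectrum}}), choose a
#' starting centre (\code{\link{initializeCenter}}: cold start at the first
#' hour, warm starts afterwards) and run \code{\link{coordinateSearch}}.
#' A failing hour is reported as a flagged row (NA estimates,
#' \code{converged = FALSE}) and never aborts the series.
#'
#' @param x a \linkS4class{SweepExperiment} of replicate sweeps (or of
#'   already-averaged mean spectra).
#' @param config a \linkS4class{FitConfig}.
#' @return data.frame with one row per (plant, hour): \code{plant},
#'   \code{hour}, \code{r1_ohm}, \code{r2_ohm}, \code{r4_ohm},
#'   \code{c3_farad}, \code{c5_farad}, \code{error_ohm}, \code{n_evals},
#'   \code{converged}.  The full \linkS4class{FitResult} objects are in
#'   \code{attr(, "fitResults")}.
#' @examples
#' se <- simulateMeasurements(seed = 1)
#' fits <- fitTimeseries(se[, sweepInfo(se)$plant == 1])
#' head(fits)
#' @export
fitTimeseries <- function(x, config = fitConfig()) {
    stopifnot(is(x, "SweepExperiment"))
    cd <- colData(x)
    if (any(!is.na(cd$replicate)))
        x <- meanSpectrum(x)
    cd <- colData(x)
    f <- frequencies(x)
    zmat <- impedanceMatrix(x)
    rows <- list()
    results <- list()
    for (p in sort(unique(cd$plant))) {
        idx <- which(cd$plant == p)
        idx <- idx[order(cd$hour[idx])]
        prior <- NULL
        for (j in idx) {
            h <- cd$hour[j]
            row <- data.frame(plant = p, hour = h, r1_ohm = NA_real_,
                              r2_ohm = NA_real_, r4_ohm = NA_real_,
                              c3_farad = NA_real_, c5_farad = NA_real_,
                              error_ohm = NA_real_, n_evals = NA_integer_,
                              converged = FALSE)
            fit <- tryCatch({
                init <- initializeCenter(zmat[, j], f, prior, config)
                coordinateSearch(zmat[, j], f, init, config,
                                 plant = p, hour = h)
            }, error = function(e) {
                warning(sprintf("fit failed for plant %d hour %g: %s",
                                p, h, conditionMessage(e)), call. = FALSE)
                NULL
            })
            if (!is.null(fit)) {
                v <- dsmValues(fit@params)
                row[c("r1_ohm", "r2_ohm", "r4_ohm")] <-
                    as.list(v[c("r1", "r2", "r4")])
                row[c("c3_farad", "c5_farad")] <- as.list(v[c("c3", "c5")])
                row$error_ohm <- fit@finalError
                row$n_evals <- fit@nEvals
                row$converged <- fit@converged
                results[[length(results) + 1L]] <- fit
            }
            rows[[length(rows) + 1L]] <- row
            prior <- do.call(rbind, rows)
            prior <- prior[prior$plant == p, , drop = FALSE]
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "fitResults") <- results
    out
}
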