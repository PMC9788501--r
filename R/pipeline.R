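#' Create a run configuration
#'
#' @param gridN,gridMinHz,gridMaxHz sweep grid: number of log-spaced points
#'   and band edges in Hz (defaults: 201 points, 500 Hz - 300 kHz).
#' @param fit a \linkS4class{FitConfig}.
#' @param trajectory a \linkS4class{TrajectoryConfig}.
#' @param noise a \linkS4class{NoiseConfig}.
#' @param seed master RNG seed of the run.
#' @return a \linkS4class{RunConfig}.
#' @export
runConfig <- function(gridN = 201L, gridMinHz = 500, gridMaxHz = 3e5,
                      fit = fitConfig(), trajectory = trajectoryConfig(),
                      noise = noiseConfig(), seed = 1L) {
    new("RunConfig", gridN = as.integer(gridN),
        gridMinHz = as.numeric(gridMinHz), gridMaxHz = as.numeric(gridMaxHz),
        fit = fit, trajectory = trajectory, noise = noise,
        seed = as.integer(seed))
}

setMethod("show", "RunConfig", function(object) {
    cat(sprintf("RunConfig: %d-point grid %.4g Hz - %.4g Hz | seed %d\n",
                object@gridN, object@gridMinHz, object@gridMaxHz,
                object@seed))
    show(object@fit)
})

#' Summary resistance ratios
#'
#' Ratios of the grand-mean resistances (mean over all converged
#' (plant, hour) fits — ratio of means, not mean of ratios, following how
#' the study reports single average resistances and then their ratios).
#'
#' @param fits data.frame as returned by \code{\link{fitTimeseries}}.
#' @return named numeric: \code{r1_over_r2}, \code{r1_over_r4},
#'   \code{r2_over_r4}.
#' @export
summarizeRatios <- function(fits) {
    conv <- fits[fits$converged & !is.na(fits$r1_ohm), , drop = FALSE]
    if (!nrow(conv))
        stop("no converged fits to summarize")
    m <- colMeans(conv[, c("r1_ohm", "r2_ohm", "r4_ohm")])
    c(r1_over_r2 = unname(m["r1_ohm"] / m["r2_ohm"]),
      r1_over_r4 = unname(m["r1_ohm"] / m["r4_ohm"]),
      r2_over_r4 = unname(m["r2_ohm"] / m["r4_ohm"]))
}

.summaryTable <- function(fits) {
    conv <- fits[fits$converged & !is.na(fits$r1_ohm), , drop = FALSE]
    pars <- c("r1_ohm", "r2_ohm", "r4_ohm", "c3_farad", "c5_farad")
    plants <- sort(unique(fits$plant))
    rows <- lapply(pars, function(pp) {
        row <- data.frame(parameter = pp,
                          grand_mean = mean(conv[[pp]]),
                          stringsAsFactors = FALSE)
        for (p in plants)
            row[[sprintf("plant%d_mean", p)]] <-
                mean(conv[[pp]][conv$plant == p])
        row
    })
    do.call(rbind, rows)
}

#' Run the full monitoring study
#'
#' Orchestrates simulate (or load) -> replicate averaging -> per-plant fits
#' -> summary: the complete pipeline from frequency sweeps to parameter
#' trajectories and the summary resistance ratios.  Plants are processed
#' independently; a per-plant or per-hour failure is flagged, not fatal.
#' Fully reproducible from (config, seed).
#'
#' @param config a \linkS4class{RunConfig}.
#' @param input \code{NULL} to simulate from \code{config}, or the path of a
#'   sweeps CSV (see \code{\link{readSweeps}}).
#' @param outputDir optional directory; when given, \code{sweeps.csv} (for
#'   simulated input), \code{fits.csv} and \code{summary.csv} are written
#'   there deterministically.
#' @return a \linkS4class{StudyResult}.
#' @examples
#' cfg <- runConfig(trajectory = trajectoryConfig(hours = 8:10, nPlants = 1L),
#'                  seed = 3L)
#' res <- runStudy(cfg)
#' studyRatios(res)
#' @export
runStudy <- function(config = runConfig(), input = NULL, outputDir = NULL) {
    stopifnot(is(config, "RunConfig"))
    grid <- defaultFrequencyGrid(config@gridN, config@gridMinHz,
                                 config@gridMaxHz)
    truth <- data.frame()
    if (is.null(input)) {
        truth <- simulateTrajectory(config@trajectory, seed = config@seed)
        sweeps <- simulateMeasurements(truth, grid, config@noise,
                                       seed = config@seed)
    } else {
        sweeps <- readSweeps(input)
    }
    fits <- fitTimeseries(sweeps, config@fit)
    ratios <- summarizeRatios(fits)
    summary <- .summaryTable(fits)
    nExcluded <- sum(!fits$converged | is.na(fits$r1_ohm))
    if (!is.null(outputDir)) {
        dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
        if (is.null(input))
            writeSweeps(sweeps, file.path(outputDir, "sweeps.csv"))
        writeFits(fits, file.path(outputDir, "fits.csv"))
        writeSummary(summary, ratios, nExcluded,
                     file.path(outputDir, "summary.csv"))
    }
    new("StudyResult", fits = fits, summary = summary, ratios = ratios,
        nExcluded = as.integer(nExcluded), truth = truth)
}

#' @describeIn runStudy the per-(plant, hour) fit table of a study.
#' @param x a \linkS4class{StudyResult}.
#' @export
studyFits <- function(x) {
    stopifnot(is(x, "StudyResult"))
    x@fits
}

#' @describeIn runStudy the summary resistance ratios of a study.
#' @export
studyRatios <- function(x) {
    stopifnot(is(x, "StudyResult"))
    x@ratios
}

#' @describeIn runStudy the generating parameter trajectories of a simulated
#'   study (zero rows for file input).
#' @export
studyTruth <- function(x) {
    stopifnot(is(x, "StudyResult"))
    x@truth
}

#' @describeIn runStudy per-parameter grand and per-plant means over
#'   converged fits.
#' @export
studySummary <- function(x) {
    stopifnot(is(x, "StudyResult"))
    x@summary
}

setMethod("show", "StudyResult", function(object) {
    cat(sprintf("StudyResult: %d fits (%d excluded from averages)\n",
                nrow(object@fits), object@nExcluded))
    cat(sprintf("  ratios: R1/R2 = %.3g, R1/R4 = %.3g, R2/R4 = %.3g\n",
                object@ratios[["r1_over_r2"]], object@ratios[["r1_over_r4"]],
                object@ratios[["r2_over_r4"]]))
})

#' Write the study summary CSV
#'
#' Per-parameter grand means and per-plant means, followed by the ratio
#' block and the count of fits excluded from the averages.
#'
#' @param summary data.frame from a \linkS4class{StudyResult}.
#' @param ratios named ratio vector.
#' @param nExcluded number of non-converged fits excluded.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSummary <- function(summary, ratios, nExcluded, path) {
    lines <- paste(names(summary), collapse = ",")
    for (i in seq_len(nrow(summary)))
        lines <- c(lines, paste(c(summary$parameter[i],
                                  .fmtNum(unlist(summary[i, -1L]))),
                                collapse = ","))
    lines <- c(lines,
               sprintf("ratio_%s,%s%s", names(ratios), .fmtNum(ratios),
                       strrep(",", ncol(summary) - 2L)),
               sprintf("n_excluded,%d%s", nExcluded,
                       strrep(",", ncol(summary) - 2L)))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    invisible(path)
}

#' Plot fitted parameter trajectories
#'
#' One panel per circuit parameter, fitted values per plant over the
#' monitoring hours, optionally overlaying the generating truth.  Plots are
#' reporting artifacts only; no computation consumes them.
#'
#' @param fits data.frame from \code{\link{fitTimeseries}}.
#' @param truth optional data.frame from \code{\link{simulateTrajectory}}.
#' @return a ggplot object.
#' @export
plotTrajectories <- function(fits, truth = NULL) {
    pars <- c("r1_ohm", "r2_ohm", "r4_ohm", "c3_farad", "c5_farad")
    long <- do.call(rbind, lapply(pars, function(pp) {
        data.frame(plant = factor(fits$plant), hour = fits$hour,
                   parameter = pp, value = fits[[pp]])
    }))
    gg <- ggplot2::ggplot(long, ggplot2::aes(x = hour, y = value,
                                             colour = plant)) +
        ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
        ggplot2::facet_wrap(~parameter, scales = "free_y") +
        ggplot2::labs(x = "hour of day", y = "fitted value (ohm / farad)")
    if (!is.null(truth) && nrow(truth)) {
        tlong <- do.call(rbind, lapply(pars, function(pp) {
            data.frame(plant = factor(truth$plant), hour = truth$hour,
                       parameter = pp, value = truth[[pp]])
        }))
        gg <- gg + ggplot2::geom_line(data = tlong, linetype = "dashed",
                                      colour = "grey40")
    }
    gg
}

#' Plot resistance and reactance versus frequency
#'
#' The two standard sweep panels (resistance and reactance against log
#' frequency) for a chosen set of sweeps.
#'
#' @param x a \linkS4class{SweepExperiment}.
#' @return a ggplot object.
#' @export
plotSpectra <- function(x) {
    stopifnot(is(x, "SweepExperiment"))
    cd <- sweepInfo(x)
    f <- frequencies(x)
    long <- do.call(rbind, lapply(seq_len(ncol(x)), function(j) {
        data.frame(frequency_hz = f,
                   sweep = colnames(assay(x, "resistance"))[j],
                   resistance = assay(x, "resistance")[, j],
                   reactance = assay(x, "reactance")[, j])
    }))
    long <- rbind(
        data.frame(frequency_hz = long$frequency_hz, sweep = long$sweep,
                   component = "resistance (ohm)", value = long$resistance),
        data.frame(frequency_hz = long$frequency_hz, sweep = long$sweep,
                   component = "reactance (ohm)", value = long$reactance))
    ggplot2::ggplot(long, ggplot2::aes(x = frequency_hz, y = value,
                                       colour = sweep)) +
        ggplot2::geom_line(show.legend = ncol(x) <= 8) +
        ggplot2::scale_x_log10() +
        ggplot2::facet_wrap(~component, scales = "free_y", ncol = 1) +
        ggplot2::labs(x = "frequency (Hz)", y = NULL)
}
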