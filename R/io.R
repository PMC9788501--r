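## Writers emit a fixed column order, '.' decimals, UTF-8, and %.17g numbers
## (exact binary round trip, always >= 12 significant digits), so identical
## inputs give byte-identical files.

.fmtNum <- function(x) sprintf("%.17g", x)

#' Write sweeps to the canonical CSV format
#'
#' One row per (plant, hour, replicate, frequency), ordered ascending on
#' those keys, with header
#' \code{plant,hour,replicate,frequency_hz,resistance_ohm,reactance_ohm}.
#'
#' @param x a \linkS4class{SweepExperiment}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSweeps <- function(x, path) {
    stopifnot(is(x, "SweepExperiment"))
    cd <- colData(x)
    ord <- order(cd$plant, cd$hour, cd$replicate)
    f <- frequencies(x)
    rmat <- assay(x, "resistance")
    xmat <- assay(x, "reactance")
    lines <- "plant,hour,replicate,frequency_hz,resistance_ohm,reactance_ohm"
    for (j in ord) {
        lines <- c(lines, sprintf("%d,%s,%s,%s,%s,%s",
                                  cd$plant[j], .fmtNum(cd$hour[j]),
                                  ifelse(is.na(cd$replicate[j]), "NA",
                                         as.character(cd$replicate[j])),
                                  .fmtNum(f), .fmtNum(rmat[, j]),
                                  .fmtNum(xmat[, j])))
    }
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    invisible(path)
}

.parseError <- function(path, line, what) {
    stop(sprintf("%s: line %d: %s", path, line, what), call. = FALSE)
}

#' Read sweeps from CSV
#'
#' Reads the canonical format written by \code{\link{writeSweeps}} or an
#' instrument-export dialect that may carry \code{#}-prefixed metadata
#' lines, store the reactance as a positive magnitude (sign-normalised to
#' <= 0 on ingest), or report \code{zmod_ohm}/\code{theta_deg} columns
#' (converted to resistance/reactance via \eqn{R = |Z|\cos\theta},
#' \eqn{X_C = |Z|\sin\theta}).  Rows are grouped by (plant, hour,
#' replicate); all sweeps must share one frequency grid, and duplicated
#' (plant, hour, replicate, frequency) keys or non-numeric fields are
#' reported with their line numbers.
#'
#' @param path CSV file path.
#' @param dialect \code{"canonical"} or \code{"instrument"}.
#' @return a \linkS4class{SweepExperiment}.
#' @export
readSweeps <- function(path, dialect = c("canonical", "instrument")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stop("file not found: ", path)
    raw <- readLines(path, encoding = "UTF-8")
    keep <- seq_along(raw)
    if (dialect == "instrument")
        keep <- keep[!startsWith(trimws(raw[keep]), "#")]
    keep <- keep[nzchar(trimws(raw[keep]))]
    if (!length(keep))
        stop(path, ": no data lines")
    df <- utils::read.csv(text = paste(raw[keep], collapse = "\n"),
                          stringsAsFactors = FALSE,
                          colClasses = "character")
    srcLine <- keep[-1L]   # file line of each data row
    need <- c("plant", "hour", "replicate", "frequency_hz")
    polar <- all(c("zmod_ohm", "theta_deg") %in% names(df))
    if (polar) {
        need <- c(need, "zmod_ohm", "theta_deg")
    } else {
        need <- c(need, "resistance_ohm", "reactance_ohm")
    }
    missing <- setdiff(need, names(df))
    if (length(missing))
        stop(path, ": missing column(s) ", paste(missing, collapse = ", "))
    num <- list()
    for (col in setdiff(need, "replicate")) {
        v <- suppressWarnings(as.numeric(df[[col]]))
        bad <- which(is.na(v) & !toupper(trimws(df[[col]])) %in% "NA")
        if (length(bad))
            .parseError(path, srcLine[bad[1L]],
                        sprintf("non-numeric value '%s' in column '%s'",
                                df[[col]][bad[1L]], col))
        num[[col]] <- v
    }
    rep_ <- suppressWarnings(as.integer(df$replicate))
    repNA <- toupper(trimws(df$replicate)) %in% "NA"
    bad <- which(is.na(rep_) & !repNA)
    if (length(bad))
        .parseError(path, srcLine[bad[1L]],
                    sprintf("non-integer replicate '%s'", df$replicate[bad[1L]]))
    if (any(num$frequency_hz <= 0, na.rm = TRUE))
        .parseError(path, srcLine[which(num$frequency_hz <= 0)[1L]],
                    "frequency_hz must be > 0")
    if (polar) {
        th <- num$theta_deg * pi / 180
        resistance <- num$zmod_ohm * cos(th)
        reactance <- num$zmod_ohm * sin(th)
    } else {
        resistance <- num$resistance_ohm
        reactance <- num$reactance_ohm
        if (dialect == "instrument")
            reactance <- -abs(reactance)
    }
    key <- paste(df$plant, df$hour, df$replicate, sep = "\r")
    fkey <- paste(key, num$frequency_hz, sep = "\r")
    dup <- which(duplicated(fkey))
    if (length(dup))
        .parseError(path, srcLine[dup[1L]],
                    "duplicated (plant, hour, replicate, frequency) key")
    groups <- split(seq_len(nrow(df)), key)
    ## order within each sweep by frequency, groups by (plant, hour, rep)
    meta <- data.frame(plant = as.integer(df$plant),
                       hour = num$hour, replicate = rep_)
    first <- vapply(groups, `[`, integer(1), 1L)
    groups <- groups[order(meta$plant[first], meta$hour[first],
                           meta$replicate[first], na.last = TRUE)]
    first <- vapply(groups, `[`, integer(1), 1L)
    grid <- NULL
    rcols <- xcols <- list()
    for (gi in seq_along(groups)) {
        idx <- groups[[gi]]
        idx <- idx[order(num$frequency_hz[idx])]
        f <- num$frequency_hz[idx]
        if (is.null(grid)) {
            grid <- f
        } else if (!identical(length(f), length(grid)) || !all(f == grid)) {
            stop(sprintf(
                "%s: frequency grid of sweep (plant %s, hour %s, replicate %s) differs from the first sweep",
                path, meta$plant[idx[1L]], meta$hour[idx[1L]],
                ifelse(is.na(meta$replicate[idx[1L]]), "NA",
                       meta$replicate[idx[1L]])), call. = FALSE)
        }
        rcols[[gi]] <- resistance[idx]
        xcols[[gi]] <- reactance[idx]
    }
    SweepExperiment(resistance = do.call(cbind, rcols),
                    reactance = do.call(cbind, xcols),
                    frequency = grid,
                    plant = meta$plant[first], hour = meta$hour[first],
                    replicate = meta$replicate[first])
}

#' Write / read fit results as CSV
#'
#' Columns: \code{plant}, \code{hour}, \code{r1_ohm}, \code{r2_ohm},
#' \code{r4_ohm}, \code{c3_farad}, \code{c5_farad}, \code{error_ohm},
#' \code{n_evals}, \code{converged}; one row per (plant, hour), ordered by
#' plant then hour.  An empty result list writes a header-only file.
#'
#' @param fits data.frame as returned by \code{\link{fitTimeseries}}.
#' @param path CSV path.
#' @return \code{writeFits}: \code{path} invisibly; \code{readFits}: the
#'   data.frame.
#' @export
writeFits <- function(fits, path) {
    cols <- c("plant", "hour", "r1_ohm", "r2_ohm", "r4_ohm", "c3_farad",
              "c5_farad", "error_ohm", "n_evals", "converged")
    stopifnot(all(cols %in% names(fits)))
    lines <- paste(cols, collapse = ",")
    if (nrow(fits)) {
        fits <- fits[order(fits$plant, fits$hour), , drop = FALSE]
        lines <- c(lines, sprintf("%d,%s,%s,%s,%s,%s,%s,%s,%s,%s",
                                  fits$plant, .fmtNum(fits$hour),
                                  .fmtNum(fits$r1_ohm), .fmtNum(fits$r2_ohm),
                                  .fmtNum(fits$r4_ohm), .fmtNum(fits$c3_farad),
                                  .fmtNum(fits$c5_farad),
                                  .fmtNum(fits$error_ohm),
                                  ifelse(is.na(fits$n_evals), "NA",
                                         as.character(fits$n_evals)),
                                  ifelse(fits$converged, "TRUE", "FALSE")))
    }
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    invisible(path)
}

#' @rdname writeFits
#' @export
readFits <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    df$plant <- as.integer(df$plant)
    for (col in c("hour", "r1_ohm", "r2_ohm", "r4_ohm", "c3_farad",
                  "c5_farad", "error_ohm"))
        df[[col]] <- as.numeric(df[[col]])
    df$n_evals <- as.integer(df$n_evals)
    df$converged <- as.logical(df$converged)
    df
}

## ---- run configuration (YAML) ----------------------------------------

.CONFIG_SCHEMA <- 1L

.paramsToList <- function(p) as.list(dsmValues(p))

.runConfigToList <- function(x) {
    list(schema_version = .CONFIG_SCHEMA,
         grid = list(n = x@gridN, min_hz = x@gridMinHz, max_hz = x@gridMaxHz),
         seed = x@seed,
         fit = list(threshold_mode = x@fit@thresholdMode,
                    threshold_value = x@fit@thresholdValue,
                    alpha_start = x@fit@alphaStart,
                    alpha_min = x@fit@alphaMin,
                    shrink_factor = x@fit@shrinkFactor,
                    max_evals = x@fit@maxEvals,
                    error_metric = x@fit@errorMetric,
                    free = as.list(x@fit@free),
                    bounds = x@fit@bounds),
         trajectory = list(hours = as.list(x@trajectory@hours),
                           baseline = .paramsToList(x@trajectory@baseline),
                           water_event_hour = x@trajectory@waterEventHour,
                           water_multipliers = as.list(x@trajectory@waterMultipliers),
                           led_event_hour = x@trajectory@ledEventHour,
                           relax_rate = as.list(x@trajectory@relaxRate),
                           hydrated_multipliers = as.list(x@trajectory@hydratedMultipliers),
                           n_plants = x@trajectory@nPlants,
                           plant_jitter_sd = x@trajectory@plantJitterSd),
         noise = list(point_sd = x@noise@pointSd,
                      contact_sd = x@noise@contactSd,
                      n_replicates = x@noise@nReplicates))
}

#' Write / read a run configuration
#'
#' The full run configuration (grid, fit, trajectory, noise, seed)
#' round-trips losslessly through a versioned human-editable YAML file.
#'
#' @param config a \linkS4class{RunConfig}.
#' @param path YAML file path.
#' @return \code{writeRunConfig}: \code{path} invisibly;
#'   \code{readRunConfig}: the \linkS4class{RunConfig}.
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' writeRunConfig(runConfig(seed = 7), p)
#' readRunConfig(p)
#' @export
writeRunConfig <- function(config, path) {
    stopifnot(is(config, "RunConfig"))
    yaml::write_yaml(.runConfigToList(config), path, precision = 17L)
    invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
    lst <- yaml::read_yaml(path)
    if (is.null(lst$schema_version) || lst$schema_version != .CONFIG_SCHEMA)
        stop("unsupported config schema version: ",
             if (is.null(lst$schema_version)) "<missing>" else lst$schema_version)
    nv <- function(x) {
        v <- unlist(x)
        stats::setNames(as.numeric(v), names(v))
    }
    tr <- lst$trajectory
    bl <- nv(tr$baseline)
    runConfig(
        gridN = lst$grid$n, gridMinHz = lst$grid$min_hz,
        gridMaxHz = lst$grid$max_hz, seed = lst$seed,
        fit = fitConfig(thresholdMode = lst$fit$threshold_mode,
                        thresholdValue = lst$fit$threshold_value,
                        alphaStart = lst$fit$alpha_start,
                        alphaMin = lst$fit$alpha_min,
                        shrinkFactor = lst$fit$shrink_factor,
                        maxEvals = lst$fit$max_evals,
                        errorMetric = lst$fit$error_metric,
                        free = unlist(lst$fit$free),
                        bounds = lapply(lst$fit$bounds, as.numeric)),
        trajectory = trajectoryConfig(
            hours = as.numeric(unlist(tr$hours)),
            baseline = .paramsFromValues(bl),
            waterEventHour = tr$water_event_hour,
            waterMultipliers = nv(tr$water_multipliers),
            ledEventHour = tr$led_event_hour,
            relaxRate = nv(tr$relax_rate),
            hydratedMultipliers = nv(tr$hydrated_multipliers),
            nPlants = tr$n_plants,
            plantJitterSd = tr$plant_jitter_sd),
        noise = noiseConfig(pointSd = lst$noise$point_sd,
                            contactSd = lst$noise$contact_sd,
                            nReplicates = lst$noise$n_replicates))
}
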