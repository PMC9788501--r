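#' Construct a double-shell parameter set
#'
#' @param r1,r2,r4 resistances in ohms (extracellular, cytoplasmic, vacuolar).
#' @param c3,c5 capacitances in farads (plasma membrane, tonoplast).
#' @return a \linkS4class{DSMParams} object.
#' @examples
#' p <- DSMParams(r1 = 159.07e6, r2 = 4.76e6, r4 = 1.49e6,
#'                c3 = 0.5e-12, c5 = 5e-12)
#' p
#' @export
DSMParams <- function(r1, r2, r4, c3, c5) {
    new("DSMParams", r1 = as.numeric(r1), r2 = as.numeric(r2),
        r4 = as.numeric(r4), c3 = as.numeric(c3), c5 = as.numeric(c5))
}

#' @rdname DSMParams
#' @param x a \code{DSMParams} object.
#' @return \code{dsmValues} returns the five parameters as a named numeric
#'   vector in the order \code{r1, r2, r4, c3, c5}.
#' @export
dsmValues <- function(x) {
    stopifnot(is(x, "DSMParams"))
    c(r1 = x@r1, r2 = x@r2, r4 = x@r4, c3 = x@c3, c5 = x@c5)
}

## inverse of dsmValues()
.paramsFromValues <- function(v) {
    DSMParams(r1 = v[["r1"]], r2 = v[["r2"]], r4 = v[["r4"]],
              c3 = v[["c3"]], c5 = v[["c5"]])
}

#' @describeIn DSMParams extracellular (cell wall + ECF) resistance, ohms.
#' @export
r1 <- function(x) x@r1
#' @describeIn DSMParams cytoplasmic resistance, ohms.
#' @export
r2 <- function(x) x@r2
#' @describeIn DSMParams vacuole resistance, ohms.
#' @export
r4 <- function(x) x@r4
#' @describeIn DSMParams plasma-membrane capacitance, farads.
#' @export
c3 <- function(x) x@c3
#' @describeIn DSMParams tonoplast capacitance, farads.
#' @export
c5 <- function(x) x@c5

setMethod("show", "DSMParams", function(object) {
    cat("DSMParams (double-shell equivalent circuit)\n")
    cat(sprintf("  R1 = %.4g MOhm   R2 = %.4g MOhm   R4 = %.4g MOhm\n",
                object@r1 / 1e6, object@r2 / 1e6, object@r4 / 1e6))
    cat(sprintf("  C3 = %.4g pF     C5 = %.4g pF\n",
                object@c3 * 1e12, object@c5 * 1e12))
})

#' Physical parameter bounds
#'
#' Default box constraints used by the fitter: resistances in
#' \code{[1e3, 1e12]} ohms, capacitances in \code{[1e-13, 1e-6]} farads.
#'
#' @param rMin,rMax resistance bounds, ohms.
#' @param cMin,cMax capacitance bounds, farads.
#' @return a named list with components \code{rMin}, \code{rMax},
#'   \code{cMin}, \code{cMax}.
#' @export
dsmBounds <- function(rMin = 1e3, rMax = 1e12, cMin = 1e-13, cMax = 1e-6) {
    stopifnot(rMin > 0, rMax > rMin, cMin > 0, cMax > cMin)
    list(rMin = rMin, rMax = rMax, cMin = cMin, cMax = cMax)
}

#' @rdname dsmBounds
#' @param params a \linkS4class{DSMParams} object.
#' @param bounds a bounds list as returned by \code{dsmBounds}.
#' @return \code{inBounds} returns TRUE iff every parameter lies inside the
#'   box (inclusive).
#' @export
inBounds <- function(params, bounds = dsmBounds()) {
    v <- dsmValues(params)
    all(v[c("r1", "r2", "r4")] >= bounds$rMin,
        v[c("r1", "r2", "r4")] <= bounds$rMax,
        v[c("c3", "c5")] >= bounds$cMin,
        v[c("c3", "c5")] <= bounds$cMax)
}

.clampToBounds <- function(v, bounds) {
    v[c("r1", "r2", "r4")] <- pmin(pmax(v[c("r1", "r2", "r4")], bounds$rMin),
                                   bounds$rMax)
    v[c("c3", "c5")] <- pmin(pmax(v[c("c3", "c5")], bounds$cMin), bounds$cMax)
    v
}
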