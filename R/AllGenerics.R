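#' Accessors for replicount classes
#'
#' Small accessor generics used across the package: `traceValues` and
#' `frameInterval` read an [IntensityTrace-class]; `levelTable`,
#' `changePoints`, `levelMeans` and `fittedTrace` read an
#' [Idealization-class]; `nObserved`, `nCensored` and `tauBar` summarize a
#' [LifetimeDataset-class].
#'
#' @param object the object to access.
#' @return The requested component (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("traceValues", function(object) standardGeneric("traceValues"))

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setGeneric("levelTable", function(object) standardGeneric("levelTable"))

#' @rdname accessors
#' @export
setGeneric("changePoints", function(object) standardGeneric("changePoints"))

#' @rdname accessors
#' @export
setGeneric("levelMeans", function(object) standardGeneric("levelMeans"))

#' @rdname accessors
#' @export
setGeneric("fittedTrace", function(object) standardGeneric("fittedTrace"))

#' @rdname accessors
#' @export
setGeneric("nObserved", function(object) standardGeneric("nObserved"))

#' @rdname accessors
#' @export
setGeneric("nCensored", function(object) standardGeneric("nCensored"))

#' @rdname accessors
#' @export
setGeneric("tauBar", function(object) standardGeneric("tauBar"))

#' @rdname accessors
#' @export
setMethod("traceValues", "IntensityTrace", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("frameInterval", "IntensityTrace",
          function(object) object@frameInterval)

#' @rdname accessors
#' @export
setMethod("levelTable", "Idealization", function(object) object@levels)

#' @rdname accessors
#' @export
setMethod("changePoints", "Idealization", function(object) {
    lv <- object@levels
    if (nrow(lv) < 2L) integer() else as.integer(lv$start[-1L])
})

#' @rdname accessors
#' @export
setMethod("levelMeans", "Idealization", function(object) object@levels$mean)

#' @rdname accessors
#' @export
setMethod("fittedTrace", "Idealization", function(object)
    rep(object@levels$mean, object@levels$duration))

#' @rdname accessors
#' @export
setMethod("nObserved", "LifetimeDataset",
          function(object) sum(!object@censored))

#' @rdname accessors
#' @export
setMethod("nCensored", "LifetimeDataset",
          function(object) sum(object@censored))

#' @rdname accessors
#' @export
setMethod("tauBar", "LifetimeDataset", function(object) {
    obs <- object@lifetimes[!object@censored]
    if (length(obs) == 0L) NA_real_ else mean(obs)
})

setMethod("show", "IntensityTrace", function(object) {
    cat(sprintf("IntensityTrace: %d frames, interval %g\n",
                length(object@values), object@frameInterval))
    cat(sprintf("  range [%.3g, %.3g]\n",
                min(object@values), max(object@values)))
})

setMethod("show", "Idealization", function(object) {
    cat(sprintf("Idealization: %d frames, %d level(s)\n",
                object@nFrames, nrow(object@levels)))
    print(utils::head(object@levels, 8L), row.names = FALSE)
    if (nrow(object@levels) > 8L) cat("  ...\n")
})

setMethod("show", "CriticalValueTable", function(object) {
    cat(sprintf(
        "CriticalValueTable: %d lengths in [%d, %d], confidence %.3g (%d sims)\n",
        length(object@lengths), min(object@lengths), max(object@lengths),
        object@confidence, object@nSim))
})

setMethod("show", "PPDD", function(object) {
    cat(sprintf("PPDD: %d kernels on [0, %.3g], grid of %d points\n",
                length(object@centers), max(object@grid),
                length(object@grid)))
})

setMethod("show", "UnitaryStep", function(object) {
    cat(sprintf("UnitaryStep: deltaI = %.4g (peak %.3g, runner-up %.3g)\n",
                object@deltaI, object@peakHeight, object@runnerUpHeight))
})

setMethod("show", "BleachFit", function(object) {
    cat(sprintf("BleachFit: I0 = %.4g, tb = %.4g frames (rms %.3g)%s\n",
                object@i0, object@tb, object@residual,
                if (object@converged) "" else " [not converged]"))
})

setMethod("show", "StoichiometryRecord", function(object) {
    cat(sprintf("StoichiometryRecord: n = %.3g (I0 = %.4g / deltaI = %.4g)\n",
                object@n, object@i0, object@deltaI))
    if (!is.na(object@qcPass))
        cat(sprintf("  QC: %s%s\n", if (object@qcPass) "pass" else "fail",
                    if (length(object@qcReasons))
                        paste0(" (", paste(object@qcReasons, collapse = ", "),
                               ")") else ""))
})

setMethod("show", "MixtureFit", function(object) {
    if (object@degenerate) {
        cat(sprintf(
            "MixtureFit (single component): mu = %.3g, F_L = 0, N = %d\n",
            object@mu2, object@n))
    } else {
        cat(sprintf(
            "MixtureFit: mu = (%.3g, %.3g), sigma = (%.3g, %.3g), F_L = %.3g, N = %d\n",
            object@mu1, object@mu2, object@sigma1, object@sigma2,
            object@fracLow, object@n))
    }
    if (!is.na(object@flError))
        cat(sprintf("  F_L error (bootstrap): %.3g\n", object@flError))
})

setMethod("show", "LifetimeDataset", function(object) {
    cat(sprintf(
        "LifetimeDataset: N = %d (observed %d, censored %d), T = %g min, tauMin = %g min\n",
        length(object@lifetimes), nObserved(object), nCensored(object),
        object@windowT, object@tauMin))
    if (nObserved(object) > 0L)
        cat(sprintf("  mean observed lifetime %.3g min\n", tauBar(object)))
})

setMethod("show", "RateEstimate", function(object) {
    cat(sprintf(
        "RateEstimate: k = %.4g /min (tau = %.3g min), Nc = %.3g per %g min cycle\n",
        object@kHat, object@tauCalc, object@nC, object@cycleLength))
    if (!is.na(object@kError))
        cat(sprintf("  k error (bootstrap): %.3g /min\n", object@kError))
})
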