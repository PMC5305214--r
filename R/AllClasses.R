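#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' IntensityTrace: a background-subtracted focus intensity time series
#'
#' Holds the per-frame focus intensity \eqn{I_F(t)} extracted from an image
#' stack (or simulated), together with the acquisition cadence and optional
#' provenance metadata (focus position, per-frame raw and background
#' intensities).
#'
#' @slot values numeric vector of per-frame intensities (finite).
#' @slot frameInterval time between frames; 1 (frame units) for bleaching
#'   stacks, minutes for time-lapse lifetime acquisitions.
#' @slot metadata list; conventional entries are `position` (row, col),
#'   `cellId`, `iR` and `iB` (per-frame raw and per-pixel background
#'   intensity), `edgeClipped` (logical).
#'
#' @export
setClass("IntensityTrace",
    representation(values = "numeric", frameInterval = "numeric",
                   metadata = "list"),
    prototype(frameInterval = 1, metadata = list()))

setValidity("IntensityTrace", function(object) {
    if (length(object@values) < 1L)
        return("trace must contain at least one frame")
    if (!all(is.finite(object@values)))
        return("trace values must be finite")
    if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
        return("frameInterval must be a single positive number")
    TRUE
})

#' Construct an IntensityTrace
#'
#' @param values numeric vector of per-frame intensities.
#' @param frameInterval time between frames (default 1 frame unit).
#' @param metadata optional provenance list.
#' @return An [IntensityTrace-class] object.
#' @export
IntensityTrace <- function(values, frameInterval = 1, metadata = list()) {
    new("IntensityTrace", values = as.numeric(values),
        frameInterval = frameInterval, metadata = metadata)
}

#' Idealization: piecewise-constant representation of a trace
#'
#' The change-point filters reduce a noisy trace to a sequence of constant
#' intensity levels. Frames are indexed 0-based; level `start` is the frame
#' at which the level begins and `duration` its length in frames. The level
#' `uncertainty` is the Fisher-information standard error of the level mean,
#' `sqrt(variance / duration)`.
#'
#' @slot levels data.frame with columns `start`, `duration`, `mean`,
#'   `variance`, `uncertainty`.
#' @slot nFrames integer trace length.
#'
#' @export
setClass("Idealization",
    representation(levels = "data.frame", nFrames = "integer"))

setValidity("Idealization", function(object) {
    lv <- object@levels
    need <- c("start", "duration", "mean", "variance", "uncertainty")
    if (!all(need %in% names(lv)))
        return(paste("levels must have columns:", paste(need, collapse = ", ")))
    if (nrow(lv) == 0L) return("at least one level required")
    if (sum(lv$duration) != object@nFrames)
        return("level durations must sum to the trace length")
    if (any(lv$duration < 1L)) return("level durations must be >= 1 frame")
    if (!all(lv$start == cumsum(c(0L, lv$duration[-nrow(lv)]))))
        return("levels must partition the trace contiguously from frame 0")
    if (any(lv$variance < 0) || any(lv$uncertainty < 0))
        return("variances and uncertainties must be non-negative")
    TRUE
})

#' Construct an Idealization from level statistics
#'
#' @param levels data.frame with columns `start`, `duration`, `mean`,
#'   `variance` (and optionally `uncertainty`, otherwise derived as
#'   `sqrt(variance/duration)`).
#' @param nFrames trace length in frames.
#' @return An [Idealization-class] object.
#' @export
Idealization <- function(levels, nFrames = sum(levels$duration)) {
    if (is.null(levels$uncertainty))
        levels$uncertainty <- sqrt(levels$variance / levels$duration)
    levels$start <- as.integer(levels$start)
    levels$duration <- as.integer(levels$duration)
    new("Idealization", levels = levels, nFrames = as.integer(nFrames))
}

#' CriticalValueTable: Monte-Carlo calibration of the change-point test
#'
#' Critical values of the maximal generalized log-likelihood-ratio statistic
#' for a single change point in an i.i.d. Gaussian segment (unknown mean and
#' variance), tabulated against segment length and interpolated in between.
#'
#' @slot lengths integer segment lengths covered by the table.
#' @slot critical numeric critical values (confidence-level quantiles of the
#'   null maximal statistic).
#' @slot confidence per-segment confidence level used (default 0.95).
#' @slot nSim Monte-Carlo replicates per length.
#' @slot seed calibration seed.
#' @slot statistic scan statistic the table calibrates ("pooled" or
#'   "local").
#'
#' @export
setClass("CriticalValueTable",
    representation(lengths = "integer", critical = "numeric",
                   confidence = "numeric", nSim = "integer",
                   seed = "integer", statistic = "character"),
    prototype(statistic = "pooled"))

setValidity("CriticalValueTable", function(object) {
    if (length(object@lengths) != length(object@critical))
        return("lengths and critical values must have equal length")
    if (is.unsorted(object@lengths, strictly = TRUE))
        return("lengths must be strictly increasing")
    if (object@confidence <= 0 || object@confidence >= 1)
        return("confidence must be in (0, 1)")
    TRUE
})

#' PPDD: pairwise probability density distribution of idealized levels
#'
#' A Gaussian-kernel mixture over absolute differences between level means.
#' Kernel widths come from the Fisher-information uncertainties of the two
#' levels; kernel weights from the level durations.
#'
#' @slot grid numeric difference axis.
#' @slot density numeric density over the grid (integrates to 1).
#' @slot centers kernel centers (absolute level-mean differences).
#' @slot widths kernel standard deviations.
#' @slot weights normalized kernel weights.
#'
#' @export
setClass("PPDD",
    representation(grid = "numeric", density = "numeric",
                   centers = "numeric", widths = "numeric",
                   weights = "numeric"))

setValidity("PPDD", function(object) {
    if (length(object@grid) != length(object@density))
        return("grid and density must align")
    if (any(object@density < 0)) return("density must be non-negative")
    if (length(object@centers) < 1L) return("at least one kernel required")
    if (abs(sum(object@weights) - 1) > 1e-8)
        return("kernel weights must sum to 1")
    TRUE
})

#' UnitaryStep: the single-fluorophore intensity step
#'
#' The unitary step is read off the spectrum of the PPDD: the period of the
#' largest non-DC spectral peak. Peak diagnostics support the QC rule that
#' the chosen peak must dominate its competitors.
#'
#' @slot deltaI unitary step (intensity units per fluorophore).
#' @slot stepGrid candidate step sizes examined.
#' @slot power spectrum amplitude at each candidate step.
#' @slot peakHeight amplitude of the selected peak.
#' @slot runnerUpHeight amplitude of the strongest competing peak (NA if
#'   none).
#'
#' @export
setClass("UnitaryStep",
    representation(deltaI = "numeric", stepGrid = "numeric",
                   power = "numeric", peakHeight = "numeric",
                   runnerUpHeight = "numeric"))

setValidity("UnitaryStep", function(object) {
    if (object@deltaI <= 0) return("deltaI must be positive")
    if (object@deltaI < min(object@stepGrid) ||
        object@deltaI > max(object@stepGrid))
        return("deltaI must lie inside the searched range")
    TRUE
})

#' BleachFit: exponential fit to a bleaching trace
#'
#' Least-squares fit of \eqn{I(t) = I_0 \exp(-t/t_b)} to the raw
#' background-subtracted intensities; the value at the first frame is the
#' initial focus intensity.
#'
#' @slot i0 initial intensity.
#' @slot tb characteristic bleaching time (frames).
#' @slot residual root-mean-square fit residual.
#' @slot converged logical; FALSE flags a QC problem (non-convergence or a
#'   rate pinned at its bound).
#'
#' @export
setClass("BleachFit",
    representation(i0 = "numeric", tb = "numeric", residual = "numeric",
                   converged = "logical"))

setValidity("BleachFit", function(object) {
    if (object@tb <= 0) return("tb must be positive")
    if (object@i0 < 0) return("i0 must be non-negative")
    TRUE
})

#' StoichiometryRecord: per-focus copy-number estimate with QC flags
#'
#' @slot n estimated copy number (real-valued, never rounded).
#' @slot i0 initial intensity from the exponential fit.
#' @slot deltaI unitary step used.
#' @slot qcPass logical (NA until [qcFilter()] has been applied).
#' @slot qcReasons character vector of failed rules (empty when passing).
#'
#' @export
setClass("StoichiometryRecord",
    representation(n = "numeric", i0 = "numeric", deltaI = "numeric",
                   qcPass = "logical", qcReasons = "character"),
    prototype(qcPass = NA, qcReasons = character()))

#' MixtureFit: unbinned two-Gaussian fit to a copy-number distribution
#'
#' @slot mu1,mu2 component means (copies); `mu1 < mu2`; `mu1` is NA for a
#'   degenerate (single-component) fit.
#' @slot sigma1,sigma2 component standard deviations.
#' @slot fracLow weight of the low-stoichiometry component (F_L).
#' @slot flError parametric-bootstrap standard error of F_L (NA until
#'   [mixtureError()] is run).
#' @slot logLik maximized log-likelihood.
#' @slot n sample size.
#' @slot degenerate logical; TRUE when the fit collapsed to one component.
#'
#' @export
setClass("MixtureFit",
    representation(mu1 = "numeric", mu2 = "numeric", sigma1 = "numeric",
                   sigma2 = "numeric", fracLow = "numeric",
                   flError = "numeric", logLik = "numeric", n = "integer",
                   degenerate = "logical"),
    prototype(flError = NA_real_, degenerate = FALSE))

setValidity("MixtureFit", function(object) {
    if (!object@degenerate && !is.na(object@mu1) &&
        object@mu1 >= object@mu2)
        return("mu1 must be smaller than mu2")
    if (object@fracLow < 0 || object@fracLow > 1)
        return("fracLow must be a fraction")
    TRUE
})

#' LifetimeDataset: right-censored complex lifetimes
#'
#' Lifetimes are measured in minutes; a complex still present in the final
#' frame of the acquisition is censored at the window length T. All
#' observable lifetimes are at least `tauMin`, the shortest lifetime the
#' trajectory rules can resolve.
#'
#' @slot lifetimes numeric lifetimes (minutes); censored entries hold T.
#' @slot censored logical flags.
#' @slot windowT observation window (minutes).
#' @slot tauMin minimum observable lifetime (minutes).
#'
#' @export
setClass("LifetimeDataset",
    representation(lifetimes = "numeric", censored = "logical",
                   windowT = "numeric", tauMin = "numeric"))

setValidity("LifetimeDataset", function(object) {
    if (length(object@lifetimes) != length(object@censored))
        return("lifetimes and censored flags must align")
    if (object@tauMin >= object@windowT)
        return("tauMin must be smaller than the window T")
    if (any(object@lifetimes < object@tauMin - 1e-9))
        return("all lifetimes must be >= tauMin")
    TRUE
})

#' Construct a LifetimeDataset
#'
#' @param lifetimes numeric lifetimes in minutes (censored entries should
#'   hold the window length).
#' @param censored logical; TRUE for complexes persisting the full window.
#' @param windowT observation window (minutes).
#' @param tauMin minimum observable lifetime (minutes).
#' @return A [LifetimeDataset-class] object.
#' @export
LifetimeDataset <- function(lifetimes, censored, windowT, tauMin) {
    new("LifetimeDataset", lifetimes = as.numeric(lifetimes),
        censored = as.logical(censored), windowT = windowT, tauMin = tauMin)
}

#' RateEstimate: censored-exponential disassembly rate
#'
#' @slot kHat maximum-likelihood disassembly rate (1/min).
#' @slot tauCalc calculated mean lifetime, `1/kHat` (minutes).
#' @slot nC conflicts per replication cycle, `kHat * cycleLength`.
#' @slot cycleLength replication-cycle length used for nC (minutes).
#' @slot kError parametric-bootstrap standard error of kHat (NA until
#'   [rateError()] is run).
#'
#' @export
setClass("RateEstimate",
    representation(kHat = "numeric", tauCalc = "numeric", nC = "numeric",
                   cycleLength = "numeric", kError = "numeric"),
    prototype(kError = NA_real_, cycleLength = 40))

setValidity("RateEstimate", function(object) {
    if (object@kHat <= 0) return("kHat must be positive")
    if (abs(object@tauCalc * object@kHat - 1) > 1e-8)
        return("tauCalc must equal 1/kHat")
    TRUE
})
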