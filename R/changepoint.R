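# Log-likelihood-ratio scan for a single change point in a Gaussian
# segment. A split at c puts frames 1..c in the left level and c+1..n in
# the right; both levels must last at least `minDur` frames. Two statistics
# are available. "pooled" (default) assumes a common noise variance within
# the scanned segment: 2*logLR = n*log(RSS0/RSS1), which concentrates the
# test on mean shifts and has markedly better power at short dwell times.
# "local" estimates a separate variance on each side (accommodating
# intensity-dependent noise across the split at the price of power). Both
# are calibrated against the same i.i.d. Gaussian null by Monte Carlo, so
# either choice honours the per-trace confidence level. Zero variances
# (noiseless data) are floored so the statistic diverges rather than NaNs.
cpScan <- function(x, minDur = 2L, statistic = c("pooled", "local")) {
    statistic <- match.arg(statistic)
    n <- length(x)
    if (n < 2L * minDur) return(NULL)
    cs <- cumsum(x); cq <- cumsum(x^2)
    c <- seq.int(minDur, n - minDur)
    n1 <- c; n2 <- n - c
    s1 <- cs[c]; q1 <- cq[c]
    r1 <- q1 - s1^2 / n1
    r2 <- (cq[n] - q1) - (cs[n] - s1)^2 / n2
    rss0 <- cq[n] - cs[n]^2 / n
    if (rss0 <= 0) return(list(split = c, stat = rep(0, length(c))))
    fl <- 1e-12 * rss0
    stat <- if (statistic == "pooled") {
        n * log(rss0 / pmax(r1 + r2, fl))
    } else {
        n * log(rss0 / n) - n1 * log(pmax(r1 / n1, fl / n)) -
            n2 * log(pmax(r2 / n2, fl / n))
    }
    list(split = c, stat = stat)
}

# Max scan statistic under the null for one simulated segment.
nullMaxStat <- function(n, minDur = 2L, statistic = "pooled") {
    sc <- cpScan(stats::rnorm(n), minDur, statistic)
    if (is.null(sc)) -Inf else max(sc$stat)
}

#' Calibrate the change-point acceptance threshold by Monte Carlo
#'
#' For each tabulated segment length, simulates `nSim` i.i.d. Gaussian
#' segments, computes the maximal single-change-point log-likelihood-ratio
#' statistic for each, and stores the `confidence` quantile as the critical
#' value. The filter accepts a split only when the observed statistic
#' exceeds this value, so a full-length null trace admits a (first) change
#' point with probability `1 - confidence` by construction: the per-trace
#' type-I error is controlled at the root test.
#'
#' @param nFrames largest segment length to calibrate (table covers 4 ..
#'   nFrames on a geometric-ish grid; intermediate lengths are interpolated
#'   against log length).
#' @param confidence per-segment confidence level (default 0.95).
#' @param nSim Monte-Carlo replicates per tabulated length (default 10000;
#'   at least 1000 are required for a stable 95% quantile).
#' @param seed integer seed.
#' @param minDur minimum level duration in frames (default 2; a one-frame
#'   level has undefined variance).
#' @param statistic scan statistic to calibrate: `"pooled"` (default) or
#'   `"local"` (see [idealizeCP()]).
#' @return A [CriticalValueTable-class].
#' @export
calibrateThreshold <- function(nFrames = 120L, confidence = 0.95,
                               nSim = 10000L, seed = 1L, minDur = 2L,
                               statistic = c("pooled", "local")) {
    statistic <- match.arg(statistic)
    assertScalar(confidence, "confidence", 1e-6, 1 - 1e-6)
    if (nSim < 1000L)
        stop("nSim too small to estimate the requested quantile reliably")
    lens <- c(4L, 5L, 6L, 8L, 10L, 13L, 17L, 22L, 29L, 38L, 50L, 66L, 90L)
    lens <- sort(unique(c(lens[lens < nFrames], as.integer(nFrames))))
    withSeed(seed, {
        crit <- vapply(lens, function(L) {
            stats::quantile(vapply(seq_len(nSim),
                                   function(i) nullMaxStat(L, minDur,
                                                           statistic),
                                   numeric(1)),
                            confidence, names = FALSE)
        }, numeric(1))
        new("CriticalValueTable", lengths = lens, critical = crit,
            confidence = confidence, nSim = as.integer(nSim),
            seed = as.integer(seed), statistic = statistic)
    })
}

# Interpolated critical value for a segment of length n (log-length linear
# interpolation, clamped at the table's ends).
criticalValue <- function(table, n) {
    stats::approx(log(table@lengths), table@critical, xout = log(n),
                  rule = 2)$y
}

#' Save or load a critical-value table as JSON
#'
#' Calibration is the slow part of the change-point filter; the table can be
#' cached on disk keyed by its own parameters (lengths, confidence, nSim,
#' seed) and reloaded bit-identically.
#'
#' @param table a [CriticalValueTable-class].
#' @param path JSON file path.
#' @return `loadCriticalValueTable` returns the table; the writer its path,
#'   invisibly.
#' @export
saveCriticalValueTable <- function(table, path) {
    jsonlite::write_json(list(lengths = table@lengths,
                              critical = table@critical,
                              confidence = table@confidence,
                              nSim = table@nSim, seed = table@seed,
                              statistic = table@statistic),
                         path, digits = NA, auto_unbox = FALSE)
    invisible(path)
}

#' @rdname saveCriticalValueTable
#' @export
loadCriticalValueTable <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("CriticalValueTable", lengths = as.integer(x$lengths),
        critical = as.numeric(x$critical), confidence = as.numeric(x$confidence),
        nSim = as.integer(x$nSim), seed = as.integer(x$seed),
        statistic = as.character(x$statistic))
}

# Recursive binary segmentation; returns 0-based change-point positions.
cpRecurse <- function(x, offset, table, minDur) {
    n <- length(x)
    if (n < 2L * minDur) return(integer())
    sc <- cpScan(x, minDur, table@statistic)
    if (is.null(sc)) return(integer())
    best <- which.max(sc$stat)  # earliest frame wins ties
    if (sc$stat[best] <= criticalValue(table, n)) return(integer())
    c <- sc$split[best]
    c(cpRecurse(x[seq_len(c)], offset, table, minDur),
      offset + c,
      cpRecurse(x[(c + 1L):n], offset + c, table, minDur))
}

# Build an Idealization from a trace and its 0-based change points.
levelsFromCps <- function(values, cps) {
    n <- length(values)
    starts <- c(0L, sort(as.integer(cps)))
    ends <- c(starts[-1L], n)
    dur <- ends - starts
    mean <- vapply(seq_along(starts), function(i)
        mean(values[(starts[i] + 1L):ends[i]]), numeric(1))
    variance <- vapply(seq_along(starts), function(i) {
        seg <- values[(starts[i] + 1L):ends[i]]
        if (length(seg) > 1L) stats::var(seg) else 0
    }, numeric(1))
    Idealization(data.frame(start = starts, duration = dur, mean = mean,
                            variance = variance), nFrames = n)
}

#' Idealize a trace with the calibrated change-point filter
#'
#' Recursive binary segmentation: on each segment, the split maximizing the
#' two-level versus one-level Gaussian log-likelihood ratio is accepted when
#' the statistic exceeds the Monte-Carlo critical value for that segment
#' length (the table fixes which scan statistic is used — the pooled-variance
#' form by default, which has substantially better power at the short dwell
#' times of a bleaching cascade; a segment-local-variance form is available
#' via [calibrateThreshold()]). Accepted splits are re-tested recursively on
#' both sides with their own lengths. Because the critical value at the full
#' trace length is the `confidence` quantile of the null maximal statistic,
#' the per-trace probability of reporting any change point on a constant
#' trace is `1 - confidence` by construction. Levels never last fewer than
#' 2 frames and ties are broken toward the earliest frame.
#'
#' @param trace an [IntensityTrace-class] (or numeric vector).
#' @param table a [CriticalValueTable-class] from [calibrateThreshold()]
#'   covering the trace length.
#' @param minDur minimum level duration (default 2 frames).
#' @return An [Idealization-class].
#' @export
idealizeCP <- function(trace, table, minDur = 2L) {
    x <- if (is(trace, "IntensityTrace")) traceValues(trace) else
        as.numeric(trace)
    if (length(x) < 4L) {
        warning("trace shorter than 4 frames: returning a single level")
        return(levelsFromCps(x, integer()))
    }
    levelsFromCps(x, cpRecurse(x, 0L, table, as.integer(minDur)))
}

#' Idealize a trace with the BIC-based constant-variance baseline
#'
#' The comparison filter: binary segmentation under a global
#' constant-variance Gaussian model, greedily adding the change point that
#' most reduces the residual sum of squares and accepting it only when the
#' Bayes Information Criterion decreases. With k change points the
#' criterion is `n*log(RSS/n) + (k + 2)*log(n)` (k + 1 level means plus one
#' global variance), so each added step must buy a likelihood gain of
#' `log(n)`; levels may be as short as one frame since the variance is
#' global. Recursion stops at the first rejected split. This criterion has
#' no per-trace error control, which is exactly the weakness the calibrated
#' filter of [idealizeCP()] addresses.
#'
#' @inheritParams idealizeCP
#' @return An [Idealization-class].
#' @export
idealizeKV <- function(trace, minDur = 1L) {
    x <- if (is(trace, "IntensityTrace")) traceValues(trace) else
        as.numeric(trace)
    n <- length(x)
    if (n < 4L) {
        warning("trace shorter than 4 frames: returning a single level")
        return(levelsFromCps(x, integer()))
    }
    segRSS <- function(seg) sum((seg - mean(seg))^2)
    # best single split of one segment: max RSS reduction
    bestSplit <- function(seg) {
        m <- length(seg)
        if (m < 2L * minDur) return(NULL)
        cs <- cumsum(seg); cq <- cumsum(seg^2)
        c <- seq.int(minDur, m - minDur)
        r1 <- cq[c] - cs[c]^2 / c
        r2 <- (cq[m] - cq[c]) - (cs[m] - cs[c])^2 / (m - c)
        rss <- r1 + r2
        i <- which.min(rss)
        list(at = c[i], rss = rss[i])
    }
    bounds <- c(0L, n)            # 0-based segment boundaries
    rss <- segRSS(x)
    k <- 0L
    bic <- n * log(max(rss, 1e-300) / n) + 2 * log(n)
    repeat {
        segs <- Map(function(a, b) x[(a + 1L):b], bounds[-length(bounds)],
                    bounds[-1L])
        cand <- lapply(segs, bestSplit)
        gain <- vapply(seq_along(cand), function(i) {
            if (is.null(cand[[i]])) return(-Inf)
            segRSS(segs[[i]]) - cand[[i]]$rss
        }, numeric(1))
        i <- which.max(gain)
        if (!is.finite(gain[i])) break
        newRSS <- rss - gain[i]
        newBIC <- n * log(max(newRSS, 1e-300) / n) + ((k + 1L) + 2) * log(n)
        if (newBIC >= bic) break
        bounds <- sort(c(bounds, bounds[i] + cand[[i]]$at))
        rss <- newRSS; bic <- newBIC; k <- k + 1L
    }
    levelsFromCps(x, bounds[-c(1L, length(bounds))])
}

#' Detector performance on traces with known ground truth
#'
#' Runs an idealizer over a family of traces and scores it against the
#' ground truth: detection efficiency is the fraction of true change points
#' matched by a detected change point within `tol` frames; the type-I rate
#' is the fraction of truly constant traces in which any change point is
#' reported.
#'
#' @param detector function mapping an [IntensityTrace-class] (or numeric)
#'   to an [Idealization-class].
#' @param traces list of traces.
#' @param truth list (parallel to `traces`) of true 0-based change-point
#'   vectors; `integer()` marks a null trace. True change points at or
#'   beyond the trace length (steps censored by the window) count as
#'   undetectable misses.
#' @param tol matching tolerance in frames (default 2).
#' @return list with `efficiency`, `typeI`, and `stateCounts` (table of
#'   detected level counts).
#' @export
detectionStats <- function(detector, traces, truth, tol = 2L) {
    stopifnot(length(traces) == length(truth))
    nTrue <- 0L; nHit <- 0L; nNull <- 0L; nFalse <- 0L
    states <- integer(length(traces))
    for (i in seq_along(traces)) {
        ideal <- detector(traces[[i]])
        cps <- changePoints(ideal)
        states[i] <- nrow(levelTable(ideal))
        tr <- truth[[i]]
        if (length(tr) == 0L) {
            nNull <- nNull + 1L
            if (length(cps) > 0L) nFalse <- nFalse + 1L
        } else {
            nFrames <- sum(levelTable(ideal)$duration)
            for (t in tr) {
                nTrue <- nTrue + 1L
                if (t < nFrames && length(cps) > 0L &&
                    min(abs(cps - t)) <= tol)
                    nHit <- nHit + 1L
            }
        }
    }
    list(efficiency = if (nTrue > 0L) nHit / nTrue else NA_real_,
         typeI = if (nNull > 0L) nFalse / nNull else NA_real_,
         stateCounts = table(states))
}
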