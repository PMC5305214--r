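#' Simulate a photobleaching intensity trace with known ground truth
#'
#' Each of `nFluorophores` fluorophores survives a geometric number of frames
#' with per-frame bleaching probability `bleachRate`, so the expected dwell
#' of the final one-fluorophore level is `1/bleachRate` frames. The true
#' intensity at frame t is `stepSize` times the number of surviving
#' fluorophores. Gaussian noise is added with a standard deviation of
#' `stepSize/noiseRatio` at the single-fluorophore level; with linear
#' variance scaling the level-m standard deviation is
#' `stepSize/noiseRatio * sqrt(m)`, floored at the one-fluorophore value so
#' the dark level keeps camera/background noise.
#'
#' @param nFluorophores initial fluorophore count (>= 0).
#' @param stepSize intensity per fluorophore (delta-mu, > 0).
#' @param noiseRatio single-fluorophore step-to-noise ratio delta-mu/sigma
#'   (default 2.5, matching the calibration of the imaging conditions).
#' @param bleachRate per-frame bleaching probability (default 1/41).
#' @param nFrames trace length (default 120).
#' @param varianceScaling `"linear"` (variance proportional to intensity) or
#'   `"constant"`.
#' @param seed integer seed (RNG state is local to the call).
#' @return list with `trace` ([IntensityTrace-class]) and `truth`
#'   ([Idealization-class], the noise-free piecewise-constant levels with
#'   their true variances).
#' @export
simulateBleachTrace <- function(nFluorophores, stepSize = 1,
                                noiseRatio = 2.5, bleachRate = 1 / 41,
                                nFrames = 120L, varianceScaling = c("linear",
                                "constant"), seed = NULL) {
    varianceScaling <- match.arg(varianceScaling)
    assertScalar(nFluorophores, "nFluorophores", 0)
    assertScalar(stepSize, "stepSize", lower = 1e-12)
    assertScalar(noiseRatio, "noiseRatio", lower = 1e-12)
    assertScalar(bleachRate, "bleachRate", lower = 1e-12, upper = 1 - 1e-12)
    assertScalar(nFrames, "nFrames", lower = 2)
    withSeed(seed, {
        # lifetime in frames: fluorophore i is visible in frames 0..L_i-1
        life <- if (nFluorophores > 0)
            stats::rgeom(nFluorophores, bleachRate) + 1L else integer()
        surv <- vapply(seq_len(nFrames) - 1L,
                       function(t) sum(life > t), integer(1))
        sigma1 <- stepSize / noiseRatio
        sd <- if (varianceScaling == "linear")
            sigma1 * sqrt(pmax(surv, 1L)) else rep(sigma1, nFrames)
        values <- stepSize * surv + stats::rnorm(nFrames, 0, sd)
        r <- rle(surv)
        dur <- r$lengths
        truth <- Idealization(data.frame(
            start = cumsum(c(0L, dur[-length(dur)])),
            duration = dur,
            mean = stepSize * r$values,
            variance = (if (varianceScaling == "linear")
                sigma1 * sqrt(pmax(r$values, 1L)) else sigma1)^2),
            nFrames = nFrames)
        list(trace = IntensityTrace(values), truth = truth)
    })
}

#' Simulate a constant-mean null trace
#'
#' Independent unit-variance Gaussian noise around a constant mean: the null
#' model under which the change-point filters are calibrated and their
#' per-trace false-positive rates measured.
#'
#' @param nFrames trace length (default 120).
#' @param seed integer seed.
#' @param mean constant trace mean (default 0).
#' @return An [IntensityTrace-class].
#' @export
simulateNullTrace <- function(nFrames = 120L, seed = NULL, mean = 0) {
    assertScalar(nFrames, "nFrames", lower = 2)
    withSeed(seed, IntensityTrace(stats::rnorm(nFrames, mean, 1)))
}

#' Simulate a single final bleaching step
#'
#' One downward transition from intensity `relStep` (in units of the noise
#' standard deviation, which is 1) to 0. The step frame is either fixed at
#' `meanLifetime` or drawn from an exponential with that mean; a draw beyond
#' the window leaves the trace step-free (the step is censored by the
#' acquisition).
#'
#' @param lifetimeMode `"fixed"` or `"exponential"`.
#' @param meanLifetime mean frames at the high level (default 41).
#' @param relStep step size over noise sd, delta-mu/sigma (default 2.5).
#' @param nFrames trace length (default 120).
#' @param seed integer seed.
#' @return list with `trace` ([IntensityTrace-class]) and `stepFrame`, the
#'   0-based frame at which the low level begins (may be >= nFrames when the
#'   step falls outside the window).
#' @export
simulateFinalStep <- function(lifetimeMode = c("fixed", "exponential"),
                              meanLifetime = 41, relStep = 2.5,
                              nFrames = 120L, seed = NULL) {
    lifetimeMode <- match.arg(lifetimeMode)
    assertScalar(meanLifetime, "meanLifetime", lower = 1)
    assertScalar(relStep, "relStep", lower = 1e-12)
    withSeed(seed, {
        stepFrame <- if (lifetimeMode == "fixed") round(meanLifetime)
        else ceiling(stats::rexp(1, 1 / meanLifetime))
        level <- as.numeric(seq_len(nFrames) - 1L < stepFrame) * relStep
        trace <- IntensityTrace(level + stats::rnorm(nFrames))
        list(trace = trace, stepFrame = as.integer(stepFrame))
    })
}

# Render one 2-D Gaussian spot (peak amplitude `amp`, width `b`) onto `img`.
addSpot <- function(img, row, col, amp, b) {
    h <- nrow(img); w <- ncol(img)
    rr <- matrix(seq_len(h) - 1L, h, w)
    cc <- matrix(seq_len(w) - 1L, h, w, byrow = TRUE)
    img + amp * exp(-((rr - row)^2 + (cc - col)^2) / (2 * b^2))
}

# Lay out nCells elliptical cells on a grid; returns a labeled mask.
# Sizes and centers are jittered deterministically by cell index so the
# layout is not periodic (a strictly periodic field would alias the
# drift-registration step, which real fields of cells never do).
layoutCells <- function(shape, nCells) {
    h <- shape[1]; w <- shape[2]
    mask <- matrix(0L, h, w)
    perRow <- ceiling(sqrt(nCells))
    nRows <- ceiling(nCells / perRow)
    ch <- floor(h / nRows); cw <- floor(w / perRow)
    if (ch < 8 || cw < 8)
        stop("image too small for the requested number of cells")
    rr <- matrix(seq_len(h) - 1L, h, w)
    cc <- matrix(seq_len(w) - 1L, h, w, byrow = TRUE)
    for (i in seq_len(nCells)) {
        gr <- (i - 1) %/% perRow; gc <- (i - 1) %% perRow
        jy <- ((i * 7) %% 5 - 2) / 2; jx <- ((i * 3) %% 5 - 2) / 2
        cy <- gr * ch + ch / 2 + jy; cx <- gc * cw + cw / 2 + jx
        ry <- ch / 2 - 2 - ((i * 2) %% 3) / 2
        rx <- cw / 2 - 2 - ((i * 5) %% 3) / 2
        inside <- ((rr - cy) / ry)^2 + ((cc - cx) / rx)^2 <= 1
        mask[inside] <- i
    }
    mask
}

#' Simulate a fluorescence time-lapse stack with planted foci
#'
#' Renders diffraction-limited foci (2-D Gaussians of width `psfWidth`) at
#' scheduled positions inside elliptical cells, over a noisy cell-interior
#' background, with optional global xy drift. The returned ground truth has
#' one row per planted spot per visible frame, including the drifted
#' position and the spot's integrated intensity (2 * pi * amplitude *
#' psfWidth^2).
#'
#' @param imageShape c(rows, cols) in pixels (default c(64, 64)).
#' @param nCells number of cells (default 4).
#' @param psfWidth Gaussian spot width b in pixels (default 1).
#' @param schedule data.frame with columns `cell`, `appear`, `disappear`
#'   (0-based frames, appear < disappear; spot visible in frames
#'   `[appear, disappear)`), `row`, `col` (positions inside the owning
#'   cell), `amplitude` (peak intensity). NULL plants nothing.
#' @param nFrames number of frames (default 10).
#' @param backgroundMean cell-interior mean intensity (default 100).
#' @param backgroundNoise Gaussian noise sd per pixel (default 5).
#' @param driftPerFrame c(row, col) pixel drift per frame (default c(0, 0)).
#' @param pixelSize micrometers per pixel (default 0.16, recorded in the
#'   output metadata).
#' @param frameInterval minutes between frames (default 2).
#' @param seed integer seed.
#' @return list with `stack` (array rows x cols x frames), `masks` (labeled
#'   integer matrix, frame-0 coordinates), and `truth` (data.frame: frame,
#'   cell, row, col, amplitude, integrated), plus `pixelSize` and
#'   `frameInterval`.
#' @export
simulateImageStack <- function(imageShape = c(64L, 64L), nCells = 4L,
                               psfWidth = 1, schedule = NULL, nFrames = 10L,
                               backgroundMean = 100, backgroundNoise = 5,
                               driftPerFrame = c(0, 0), pixelSize = 0.16,
                               frameInterval = 2, seed = NULL) {
    mask <- layoutCells(imageShape, nCells)
    if (!is.null(schedule)) {
        stopifnot(all(schedule$appear < schedule$disappear))
        if (any(schedule$appear < 0 | schedule$disappear > nFrames))
            stop("schedule outside frame range")
        own <- mask[cbind(round(schedule$row) + 1L, round(schedule$col) + 1L)]
        if (any(own != schedule$cell))
            stop("scheduled focus positions must lie inside the owning cell")
    }
    withSeed(seed, {
        h <- imageShape[1]; w <- imageShape[2]
        stack <- array(0, c(h, w, nFrames))
        truth <- list()
        base <- 0.1 * backgroundMean + (backgroundMean - 0.1 *
            backgroundMean) * (mask > 0)
        for (f in seq_len(nFrames)) {
            drift <- (f - 1L) * driftPerFrame
            di <- round(drift)
            # shift the cell background by the integer part of the drift
            img <- matrix(0.1 * backgroundMean, h, w)
            srcR <- seq_len(h) - di[1]; srcC <- seq_len(w) - di[2]
            okR <- srcR >= 1 & srcR <= h; okC <- srcC >= 1 & srcC <= w
            img[okR, okC] <- base[srcR[okR], srcC[okC]]
            if (!is.null(schedule)) {
                vis <- schedule$appear <= (f - 1L) &
                    schedule$disappear > (f - 1L)
                for (s in which(vis)) {
                    pr <- schedule$row[s] + drift[1]
                    pc <- schedule$col[s] + drift[2]
                    img <- addSpot(img, pr, pc, schedule$amplitude[s],
                                   psfWidth)
                    truth[[length(truth) + 1L]] <- data.frame(
                        frame = f - 1L, cell = schedule$cell[s],
                        row = pr, col = pc,
                        amplitude = schedule$amplitude[s],
                        integrated = 2 * pi * schedule$amplitude[s] *
                            psfWidth^2)
                }
            }
            stack[, , f] <- img + matrix(stats::rnorm(h * w, 0,
                backgroundNoise), h, w)
        }
        truth <- if (length(truth)) do.call(rbind, truth) else
            data.frame(frame = integer(), cell = integer(), row = numeric(),
                       col = numeric(), amplitude = numeric(),
                       integrated = numeric())
        list(stack = stack, masks = mask, truth = truth,
             pixelSize = pixelSize, frameInterval = frameInterval)
    })
}

#' Simulate right-censored complex lifetimes
#'
#' Lifetimes follow the shifted exponential p(tau | k) =
#' k exp(-k (tau - tauMin)) for tau >= tauMin, are discretized down to the
#' imaging cadence (the pipeline can only observe frame-quantized
#' lifetimes), and are right-censored at the observation window T.
#'
#' @param kTrue disassembly rate (1/min, > 0).
#' @param nComplexes number of complexes.
#' @param windowT observation window (minutes).
#' @param tauMin minimum observable lifetime (minutes, < windowT).
#' @param frameInterval imaging cadence (minutes, default 2).
#' @param seed integer seed.
#' @return A [LifetimeDataset-class].
#' @export
simulateLifetimes <- function(kTrue, nComplexes, windowT = 22, tauMin = 4,
                              frameInterval = 2, seed = NULL) {
    assertScalar(kTrue, "kTrue", lower = 1e-12)
    assertScalar(nComplexes, "nComplexes", lower = 1)
    if (tauMin >= windowT) stop("tauMin must be smaller than windowT")
    withSeed(seed, {
        tau <- tauMin + floor(stats::rexp(nComplexes, kTrue) /
                              frameInterval) * frameInterval
        cens <- tau >= windowT
        tau[cens] <- windowT
        LifetimeDataset(tau, cens, windowT, tauMin)
    })
}

#' Simulate copy-number samples from a two-Gaussian mixture
#'
#' Draws i.i.d. stoichiometry samples from
#' `fracLow * N(mu1, sigma1^2) + (1 - fracLow) * N(mu2, sigma2^2)`,
#' the population model used for factories carrying one or two replisome
#' complexes.
#'
#' @param mu1,mu2 component means in copies (mu1 < mu2).
#' @param sigma1,sigma2 component standard deviations.
#' @param fracLow weight of the low component, in `[0, 1]`.
#' @param n sample size.
#' @param seed integer seed.
#' @return numeric vector of n draws.
#' @export
simulateStoichiometrySamples <- function(mu1, mu2, sigma1 = 1.2,
                                         sigma2 = 1.5, fracLow = 0.5,
                                         n = 100L, seed = NULL) {
    if (mu1 >= mu2) stop("mu1 must be smaller than mu2")
    assertScalar(fracLow, "fracLow", 0, 1)
    withSeed(seed, {
        low <- stats::runif(n) < fracLow
        stats::rnorm(n, ifelse(low, mu1, mu2), ifelse(low, sigma1, sigma2))
    })
}
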