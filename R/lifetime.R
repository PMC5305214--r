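#' Link scored foci into replisome-complex trajectories
#'
#' Greedy frame-by-frame linking under the trajectory rules: (i) no member
#' focus scores below `memberScoreMin`; (ii) a focus moves at most
#' `maxStepNm` between frames; (iii) the mean trajectory score is at least
#' `meanScoreMin`; (iv) at least one member scores `peakScoreMin` or
#' higher; (v) a trajectory may continue through a single frame with no
#' admissible focus; (vi) trajectories span at least `minFrames` frames;
#' (vii) members localize to the replication factory (optional band rule).
#' Candidate links are sorted by distance and assigned nearest-first; ties
#' break toward the higher-scoring focus, then the lower cell id. Linking
#' never crosses cells.
#'
#' @param foci data.frame of per-frame scored foci (columns `frame`
#'   0-based, `cell`, `row`, `col`, `score`; from [quantifyFrames()] or
#'   simulation).
#' @param pixelSize micrometers per pixel (required: the displacement rule
#'   is physical).
#' @param frameInterval minutes between frames.
#' @param maxStepNm displacement limit in nanometers (default 350).
#' @param memberScoreMin lowest admissible member score (default 3; foci
#'   scoring below it are treated as absent).
#' @param meanScoreMin minimum mean score (default 4).
#' @param peakScoreMin minimum top score (default 5).
#' @param minFrames minimum spanned frames (default 3).
#' @param masks,bandFrac optional labeled masks and band fraction enabling
#'   rule (vii); skipped when `masks` is NULL.
#' @return list with `trajectories` (data.frame: id, cell, start, end,
#'   nFoci, meanScore, maxScore, spanFrames) and `members` (the focus table
#'   with a `trajectory` column; 0 = unassigned).
#' @export
linkTrajectories <- function(foci, pixelSize, frameInterval = 2,
                             maxStepNm = 350, memberScoreMin = 3,
                             meanScoreMin = 4, peakScoreMin = 5,
                             minFrames = 3L, masks = NULL, bandFrac = 0.5) {
    if (missing(pixelSize) || is.null(pixelSize) || is.na(pixelSize))
        stop("pixelSize is required: the displacement rule is in nanometers")
    cols <- c("frame", "cell", "row", "col", "score")
    stopifnot(all(cols %in% names(foci)))
    foci$frame <- as.integer(foci$frame)
    foci <- foci[order(foci$frame), , drop = FALSE]
    foci$trajectory <- rep(0L, nrow(foci))
    if (nrow(foci) == 0L)
        return(list(trajectories = data.frame(id = integer(),
                        cell = integer(), start = integer(),
                        end = integer(), nFoci = integer(),
                        meanScore = numeric(), maxScore = numeric(),
                        spanFrames = integer()),
                    members = foci))
    maxStepPx <- maxStepNm / (pixelSize * 1000)
    adm <- foci$score >= memberScoreMin
    if (!is.null(masks)) {
        inb <- vapply(seq_len(nrow(foci)), function(k)
            inFactoryBand(masks, foci$cell[k], c(foci$row[k], foci$col[k]),
                          bandFrac), logical(1))
        adm <- adm & inb
    }
    # active trajectory state: last position, cell, last frame seen
    tId <- 0L
    active <- list()   # id -> list(row, col, cell, lastFrame)
    for (fr in sort(unique(foci$frame))) {
        idx <- which(foci$frame == fr & adm & foci$trajectory == 0L)
        # drop trajectories that missed more than one frame
        active <- Filter(function(a) fr - a$lastFrame <= 2L, active)
        if (length(idx) && length(active)) {
            cand <- do.call(rbind, lapply(names(active), function(id) {
                a <- active[[id]]
                sameCell <- foci$cell[idx] == a$cell
                d <- sqrt((foci$row[idx] - a$row)^2 +
                          (foci$col[idx] - a$col)^2)
                ok <- sameCell & d <= maxStepPx
                if (!any(ok)) return(NULL)
                data.frame(id = as.integer(id), focus = idx[ok],
                           dist = d[ok], score = foci$score[idx[ok]],
                           cell = foci$cell[idx[ok]])
            }))
            if (!is.null(cand) && nrow(cand)) {
                cand <- cand[order(cand$dist, -cand$score, cand$cell), ]
                usedT <- integer(); usedF <- integer()
                for (k in seq_len(nrow(cand))) {
                    if (cand$id[k] %in% usedT ||
                        cand$focus[k] %in% usedF) next
                    fi <- cand$focus[k]
                    foci$trajectory[fi] <- cand$id[k]
                    active[[as.character(cand$id[k])]] <-
                        list(row = foci$row[fi], col = foci$col[fi],
                             cell = foci$cell[fi], lastFrame = fr)
                    usedT <- c(usedT, cand$id[k])
                    usedF <- c(usedF, fi)
                }
            }
        }
        # remaining admissible foci seed new trajectories
        for (fi in idx[foci$trajectory[idx] == 0L]) {
            tId <- tId + 1L
            foci$trajectory[fi] <- tId
            active[[as.character(tId)]] <-
                list(row = foci$row[fi], col = foci$col[fi],
                     cell = foci$cell[fi], lastFrame = fr)
        }
    }
    traj <- do.call(rbind, lapply(split(foci[foci$trajectory > 0L, ],
                                        foci$trajectory[foci$trajectory > 0L]),
        function(m) data.frame(id = m$trajectory[1], cell = m$cell[1],
                               start = min(m$frame), end = max(m$frame),
                               nFoci = nrow(m), meanScore = mean(m$score),
                               maxScore = max(m$score),
                               spanFrames = as.integer(max(m$frame) -
                                   min(m$frame) + 1L))))
    if (is.null(traj))
        traj <- data.frame(id = integer(), cell = integer(),
                           start = integer(), end = integer(),
                           nFoci = integer(), meanScore = numeric(),
                           maxScore = numeric(), spanFrames = integer())
    keep <- traj$meanScore >= meanScoreMin & traj$maxScore >= peakScoreMin &
        traj$spanFrames >= minFrames
    dropped <- traj$id[!keep]
    foci$trajectory[foci$trajectory %in% dropped] <- 0L
    traj <- traj[keep, , drop = FALSE]
    rownames(traj) <- NULL
    list(trajectories = traj, members = foci)
}

#' Call censored lifetimes from trajectories
#'
#' Lifetime is the spanned time `(end - start) * frameInterval`. A
#' trajectory reaching the final frame is right-censored at the window
#' `T = (nFrames - 1) * frameInterval`; one ending earlier counts as a
#' disassembly only when the focus is absent for at least `minAbsence`
#' subsequent frames (more than two minutes at the 2-minute cadence) —
#' otherwise it is censored at its observed span. Events spanning fewer
#' than 3 frames have been discarded at the linking stage, so the minimum
#' observable lifetime is `tauMin = 2 * frameInterval` (4 min at 2-minute
#' cadence).
#'
#' @param trajectories trajectory summary from [linkTrajectories()].
#' @param nFrames number of frames in the acquisition.
#' @param frameInterval minutes between frames (default 2).
#' @param tauMin minimum observable lifetime (default
#'   `2 * frameInterval`).
#' @param minAbsence frames the focus must stay absent to call disassembly
#'   (default 2).
#' @return A [LifetimeDataset-class].
#' @export
callLifetimes <- function(trajectories, nFrames, frameInterval = 2,
                          tauMin = 2 * frameInterval, minAbsence = 2L) {
    windowT <- (nFrames - 1L) * frameInterval
    if (nrow(trajectories) == 0L)
        return(LifetimeDataset(numeric(), logical(), windowT, tauMin))
    tau <- (trajectories$end - trajectories$start) * frameInterval
    lastFrame <- nFrames - 1L
    censored <- trajectories$end > lastFrame - minAbsence
    tau[censored & tau < windowT] <- windowT  # absence window too short to
                                              # call disassembly: censor at T
    keep <- tau >= tauMin
    LifetimeDataset(tau[keep], censored[keep], windowT, tauMin)
}

#' Censored-exponential disassembly rate (closed-form MLE)
#'
#' Complex lifetimes are modeled as a Poisson disassembly process observed
#' above the resolution floor: `p(tau | k) = k exp(-k (tau - tauMin))`,
#' with complexes surviving the whole window contributing the censored term
#' `Pr(tau >= T) = exp(-k (T - tauMin))`. Maximizing the joint likelihood
#' gives the closed form
#' `k = N_obs / (N_obs (tauBar - tauMin) + N_cens (T - tauMin))`.
#'
#' @param data a [LifetimeDataset-class] with at least one observed
#'   (uncensored) lifetime.
#' @param cycleLength replication-cycle length in minutes used for the
#'   conflicts-per-cycle figure (default 40).
#' @return A [RateEstimate-class].
#' @export
estimateRate <- function(data, cycleLength = 40) {
    nLt <- nObserved(data); nGe <- nCensored(data)
    if (nLt < 1L)
        stop("rate unidentifiable: no uncensored lifetimes")
    tb <- tauBar(data)
    k <- nLt / (nLt * (tb - data@tauMin) + nGe * (data@windowT - data@tauMin))
    new("RateEstimate", kHat = k, tauCalc = 1 / k, nC = k * cycleLength,
        cycleLength = cycleLength)
}

#' Conflicts per replication cycle
#'
#' Scales the disassembly rate by the replication-cycle length:
#' `N_c = k * cycleLength` (default 40 min).
#'
#' @param estimate a [RateEstimate-class] (or a rate in 1/min).
#' @param cycleLength minutes (default 40).
#' @return conflicts per cycle.
#' @export
conflictsPerCycle <- function(estimate, cycleLength = 40) {
    k <- if (is(estimate, "RateEstimate")) estimate@kHat else
        as.numeric(estimate)
    k * cycleLength
}

#' Parametric-bootstrap error of the disassembly rate
#'
#' Simulates `nSim` datasets with the estimated rate and the observed
#' design (same number of complexes, window, resolution floor and frame
#' discretization), re-estimates each, and reports the standard deviation
#' of the re-estimated rates.
#'
#' @param estimate a [RateEstimate-class].
#' @param data the observed [LifetimeDataset-class].
#' @param nSim bootstrap replicates (default 100000).
#' @param seed integer seed.
#' @param frameInterval cadence for discretization (default 2 min).
#' @return the estimate with `kError` filled in.
#' @export
rateError <- function(estimate, data, nSim = 100000L, seed = 1L,
                      frameInterval = 2) {
    n <- length(data@lifetimes)
    k <- estimate@kHat
    tmin <- data@tauMin; tw <- data@windowT
    withSeed(seed, {
        chunk <- 10000L
        ks <- numeric(0)
        done <- 0L
        while (done < nSim) {
            m <- min(chunk, nSim - done)
            draws <- matrix(tmin + floor(stats::rexp(n * m, k) /
                                         frameInterval) * frameInterval,
                            nrow = n)
            cens <- draws >= tw
            nLt <- colSums(!cens)
            sumObs <- colSums(draws * !cens)
            nGe <- n - nLt
            ok <- nLt > 0L
            kstar <- nLt[ok] / (sumObs[ok] - nLt[ok] * tmin +
                                nGe[ok] * (tw - tmin))
            ks <- c(ks, kstar)
            done <- done + m
        }
        estimate@kError <- stats::sd(ks)
        estimate
    })
}

#' Empirical and model survival curves
#'
#' The empirical curve is the fraction of complexes with lifetime at least
#' t (censored complexes hold the terminal value beyond the window); the
#' model curve is the fitted shifted-exponential survival
#' `exp(-k (t - tauMin))`. A Kaplan-Meier option is available when the
#' survival package is installed.
#'
#' @param data a [LifetimeDataset-class].
#' @param estimate a [RateEstimate-class].
#' @param method `"ecdf"` (default) or `"km"`.
#' @return data.frame with `t`, `empirical`, `model`.
#' @export
survivalCurves <- function(data, estimate, method = c("ecdf", "km")) {
    method <- match.arg(method)
    grid <- sort(unique(c(data@tauMin, data@lifetimes)))
    emp <- if (method == "ecdf") {
        vapply(grid, function(t) mean(data@lifetimes >= t), numeric(1))
    } else {
        if (!requireNamespace("survival", quietly = TRUE))
            stop("the survival package is required for method = 'km'")
        sf <- survival::survfit(survival::Surv(data@lifetimes,
                                               !data@censored) ~ 1)
        # P(tau >= t): evaluate the step function just left of t
        stats::approx(c(0, sf$time), c(1, sf$surv), xout = grid - 1e-9,
                      method = "constant", rule = 2)$y
    }
    data.frame(t = grid, empirical = emp,
               model = exp(-estimate@kHat * (grid - data@tauMin)))
}

#' Focus-visibility probability under continuous replication
#'
#' The null model for restart-deficient experiments: replication proceeds
#' uninterrupted for a full cycle of length `cycleLength`, a random segment
#' of which is imaged; conditioned on a focus being visible in the first
#' frame, the probability that it is still visible at frame j is
#' `(cycleLength - j * frameInterval) / cycleLength`.
#'
#' @param cycleLength replication-cycle length (default 40 min).
#' @param frameInterval minutes between frames (default 2).
#' @param nFrames frames imaged (default 10).
#' @return numeric vector of length `nFrames` (frame 0 has probability 1).
#' @export
nullFocusProbability <- function(cycleLength = 40, frameInterval = 2,
                                 nFrames = 10L) {
    j <- seq_len(nFrames) - 1L
    pmax((cycleLength - j * frameInterval) / cycleLength, 0)
}

#' Tracking survival under continuous illumination
#'
#' For the bleaching control (no delay between frames), the fraction of
#' complexes still tracked through m frames, for m = 1 .. nFrames; used to
#' verify that tracking loss from photobleaching alone is small over the
#' experiment's frame count.
#'
#' @param trajectories trajectory summary from [linkTrajectories()].
#' @param nFrames frame count of interest.
#' @return data.frame with `frames` and `fraction`.
#' @export
bleachControlSurvival <- function(trajectories, nFrames) {
    m <- seq_len(nFrames)
    frac <- vapply(m, function(k) mean(trajectories$spanFrames >= k),
                   numeric(1))
    data.frame(frames = m, fraction = frac)
}
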