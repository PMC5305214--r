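fociTable <- function(frames, scores, row = 10, col = 10, cell = 1L) {
    n <- length(frames)
    data.frame(frame = as.integer(frames), cell = rep_len(cell, n),
               row = rep_len(row, n), col = rep_len(col, n),
               score = as.numeric(scores))
}

test_that("trajectory score rules admit and reject as printed", {
    ok <- linkTrajectories(fociTable(0:3, c(5, 4, 4, 3)), pixelSize = 0.16)
    expect_identical(nrow(ok$trajectories), 1L)
    expect_equal(ok$trajectories$meanScore, 4)
    expect_equal(ok$trajectories$maxScore, 5)

    flat <- linkTrajectories(fociTable(0:3, c(4, 4, 4, 4)),
                             pixelSize = 0.16)
    expect_identical(nrow(flat$trajectories), 0L)   # no member scores >= 5

    low <- linkTrajectories(fociTable(0:3, c(5, 3.2, 3.2, 3.2)),
                            pixelSize = 0.16)
    expect_identical(nrow(low$trajectories), 0L)    # mean below 4

    short <- linkTrajectories(fociTable(0:1, c(6, 6)), pixelSize = 0.16)
    expect_identical(nrow(short$trajectories), 0L)  # spans < 3 frames

    none <- linkTrajectories(fociTable(integer(), numeric()),
                             pixelSize = 0.16)
    expect_identical(nrow(none$trajectories), 0L)
    expect_error(linkTrajectories(fociTable(0:3, c(5, 4, 4, 3)),
                                  pixelSize = NULL), "pixelSize")
})

test_that("gap and displacement rules shape the links", {
    gap1 <- linkTrajectories(fociTable(c(0, 1, 3, 4), c(5, 4, 4, 5)),
                             pixelSize = 0.16)
    expect_identical(nrow(gap1$trajectories), 1L)
    expect_identical(gap1$trajectories$spanFrames, 5L)

    gap2 <- linkTrajectories(fociTable(c(0, 1, 4, 5, 6), c(5, 5, 5, 5, 5)),
                             pixelSize = 0.16)
    expect_identical(nrow(gap2$trajectories), 1L)   # 2-frame gap breaks it
    expect_identical(gap2$trajectories$spanFrames, 3L)

    # 3 px at 0.16 um/px = 480 nm > 350 nm: a monotone 3 px/frame walk can
    # never be linked (every candidate, including across a gap, is too far)
    far <- fociTable(0:3, c(6, 6, 6, 6))
    far$col <- c(10, 13, 16, 19)
    expect_identical(nrow(linkTrajectories(far,
                                           pixelSize = 0.16)$trajectories),
                     0L)
    # 2 px/frame = 320 nm stays under the limit: one trajectory
    near <- fociTable(0:3, c(6, 6, 6, 6))
    near$col <- c(10, 12, 14, 16)
    expect_identical(nrow(linkTrajectories(near,
                                           pixelSize = 0.16)$trajectories),
                     1L)

    again <- linkTrajectories(fociTable(c(0, 1, 3, 4), c(5, 4, 4, 5)),
                              pixelSize = 0.16)
    expect_identical(gap1, again)                   # deterministic
})

test_that("trajectories are recovered from planted focus schedules", {
    hits <- 0L
    for (seed in 1:10) {
        sim <- simulateImageStack(imageShape = c(64L, 64L), nCells = 4L,
            psfWidth = 1,
            schedule = data.frame(cell = 1L, appear = 2, disappear = 9,
                                  row = 15, col = 15, amplitude = 120),
            nFrames = 12L, seed = 400 + seed)
        pf <- quantifyFrames(sim$stack, sim$masks)
        lk <- linkTrajectories(pf, pixelSize = 0.16)
        tr <- lk$trajectories[lk$trajectories$cell == 1L, ]
        if (nrow(tr) == 1L && abs(tr$start - 2L) <= 1L &&
            abs(tr$end - 8L) <= 1L)
            hits <- hits + 1L
    }
    expect_gte(hits, 9L)
})

test_that("lifetimes are spans with end-of-series censoring", {
    tr <- data.frame(id = 1:3, cell = 1L, start = c(0L, 2L, 5L),
                     end = c(11L, 7L, 6L), nFoci = c(12L, 6L, 2L),
                     meanScore = 5, maxScore = 6,
                     spanFrames = c(12L, 6L, 2L))
    ds <- callLifetimes(tr, nFrames = 12L, frameInterval = 2)
    # traj 1 reaches the final frame: censored at T = 22
    # traj 2 spans 6 frames and is absent 4 frames after: tau = 10, observed
    # traj 3 spans 2 frames: below tauMin, discarded
    expect_identical(length(ds@lifetimes), 2L)
    expect_identical(ds@windowT, 22)
    expect_true(ds@censored[1])
    expect_equal(ds@lifetimes[2], 10)
    expect_false(ds@censored[2])

    nearEnd <- data.frame(id = 1L, cell = 1L, start = 0L, end = 10L,
                          nFoci = 11L, meanScore = 5, maxScore = 6,
                          spanFrames = 11L)
    ds2 <- callLifetimes(nearEnd, nFrames = 12L, frameInterval = 2)
    expect_true(ds2@censored[1])   # absent for only 1 frame: not a call
})

test_that("the closed-form rate reproduces the published worked examples", {
    wtBs <- estimateRate(datasetFromCounts(296, 31, 10.4, 22, 4))
    expect_equal(round(wtBs@kHat, 2), 0.12)
    expect_equal(round(wtBs@tauCalc, 1), 8.3)
    expect_equal(round(wtBs@nC, 1), 4.8)

    rifBs <- estimateRate(datasetFromCounts(86, 97, 12.9, 22, 4))
    expect_equal(round(rifBs@tauCalc, 1), 29.2)
    expect_equal(round(rifBs@nC, 1), 1.4)

    rpoB <- estimateRate(datasetFromCounts(93, 72, 12.5, 22, 4))
    expect_equal(round(rpoB@tauCalc, 1), 22.4)
    expect_equal(round(rpoB@nC, 1), 1.8)

    wtEc <- estimateRate(datasetFromCounts(171, 46, 9.1, 20, 4))
    expect_equal(round(wtEc@tauCalc, 1), 9.4)
    # the published table prints 4.2; the unrounded value is 4.25
    expect_equal(wtEc@nC, 4.2, tolerance = 0.06 / 4.2)

    rifEc <- estimateRate(datasetFromCounts(42, 35, 12.3, 20, 4))
    expect_equal(round(rifEc@tauCalc, 1), 21.6)
    expect_equal(round(rifEc@nC, 1), 1.8)

    # no censoring and no floor: reduces to the uncensored exponential MLE
    plain <- estimateRate(LifetimeDataset(rep(5, 50), rep(FALSE, 50),
                                          windowT = 100, tauMin = 0))
    expect_equal(plain@kHat, 0.2)
    expect_error(estimateRate(LifetimeDataset(rep(22, 5), rep(TRUE, 5),
                                              22, 4)), "unidentifiable")
})

test_that("the closed form maximizes the censored likelihood", {
    for (seed in 1:5) {
        ds <- simulateLifetimes(0.12, 300, 22, 4, 2, seed = seed)
        est <- estimateRate(ds)
        expect_equal(est@kHat, numericRateOracle(ds),
                     tolerance = 1e-6)
    }
})

test_that("rate estimation ignores ordering and scales with cycle length", {
    ds <- simulateLifetimes(0.1, 200, 22, 4, 2, seed = 3)
    perm <- LifetimeDataset(rev(ds@lifetimes), rev(ds@censored),
                            ds@windowT, ds@tauMin)
    expect_equal(estimateRate(ds)@kHat, estimateRate(perm)@kHat)
    est <- estimateRate(ds)
    expect_equal(conflictsPerCycle(est, 80), 2 * est@nC)
    expect_identical(conflictsPerCycle(0), 0)
    expect_equal(est@tauCalc * est@kHat, 1)
    expect_equal(conflictsPerCycle(0.1207), 4.8, tolerance = 0.01)
})

test_that("bootstrap rate errors match Fisher-information scaling", {
    ds <- simulateLifetimes(0.12, 300, 22, 4, 0.25, seed = 4)
    est <- estimateRate(ds)
    est <- rateError(est, ds, nSim = 3000L, seed = 5, frameInterval = 0.25)
    expect_equal(est@kError, est@kHat / sqrt(nObserved(ds)),
                 tolerance = 0.25)
})

test_that("rate recovery and coverage hold at fine cadence", {
    for (k in c(0.03, 0.12)) {
        ests <- numeric(40); cover <- logical(40)
        for (i in 1:40) {
            ds <- simulateLifetimes(k, 300, 22, 4, frameInterval = 0.25,
                                    seed = 2000 + i)
            est <- estimateRate(ds)
            est <- rateError(est, ds, nSim = 300L, seed = i,
                             frameInterval = 0.25)
            ests[i] <- est@kHat
            cover[i] <- abs(est@kHat - k) <= 2 * est@kError
        }
        expect_equal(median(ests), k, tolerance = 0.05)
        expect_gte(mean(cover), 0.90)
    }
})

test_that("survival curves start at 1 and track the model on model data", {
    # fine cadence: at coarse frame intervals the closed-form rate inherits
    # a discretization bias that shifts the model curve (see the vignette)
    ds <- simulateLifetimes(0.12, 1000, 22, 4, 0.5, seed = 6)
    est <- estimateRate(ds)
    cv <- survivalCurves(ds, est)
    expect_equal(cv$empirical[1], 1)
    expect_equal(cv$model[cv$t == 4], 1)
    expect_lt(max(abs(cv$empirical - cv$model)), 0.05)

    wt <- estimateRate(datasetFromCounts(296, 31, 10.4, 22, 4))
    expect_equal(exp(-wt@kHat * 18), 0.114, tolerance = 0.01)

    skip_if_not_installed("survival")
    km <- survivalCurves(ds, est, method = "km")
    expect_equal(km$empirical[1], 1, tolerance = 1e-9)
})

test_that("the continuous-replication null visibility curve is exact", {
    p <- nullFocusProbability(40, 2, 10L)
    expect_identical(p[1], 1)
    expect_equal(p[10], 0.55)
    expect_true(all(diff(p) < 0))
    # enumeration oracle over uniformly gridded cycle phases
    phases <- seq(0, 40 - 1e-9, by = 0.01)
    enum <- vapply(0:9, function(j) mean(phases + j * 2 < 40), numeric(1))
    expect_equal(p, enum, tolerance = 1e-3)
})

test_that("bleach-control tracking fractions summarize spans", {
    tr <- data.frame(spanFrames = c(12L, 12L, 12L))
    bc <- bleachControlSurvival(tr, 12L)
    expect_true(all(bc$fraction == 1))
    tr2 <- data.frame(spanFrames = c(12L, 12L, 12L, 12L, 12L, 12L, 12L,
                                     12L, 12L, 6L))
    bc2 <- bleachControlSurvival(tr2, 12L)
    expect_gte(bc2$fraction[12], 0.9)
})
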