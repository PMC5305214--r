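stairIdeal <- function(nLevels, step = 1, duration = 20, variance = 0.16) {
    Idealization(data.frame(
        start = seq(0, by = duration, length.out = nLevels),
        duration = duration,
        mean = step * seq(nLevels - 1, 0),
        variance = variance))
}

test_that("PPDD matches a brute-force pair sum and conserves mass", {
    id <- stairIdeal(7)   # 6 -> 0 staircase
    pp <- computePPDD(id, pairWeight = "min")

    lv <- levelTable(id)
    centers <- c(); widths <- c(); weights <- c()
    for (i in 1:(nrow(lv) - 1)) for (j in (i + 1):nrow(lv)) {
        centers <- c(centers, abs(lv$mean[i] - lv$mean[j]))
        widths <- c(widths, sqrt(lv$uncertainty[i]^2 + lv$uncertainty[j]^2))
        weights <- c(weights, min(lv$duration[i], lv$duration[j]))
    }
    weights <- weights / sum(weights)
    dens <- rep(0, length(pp@grid))
    for (k in seq_along(centers))
        dens <- dens + weights[k] * dnorm(pp@grid, centers[k], widths[k])
    dens <- dens / replicount:::trapz(pp@grid, dens)
    expect_equal(pp@density, dens, tolerance = 1e-10)
    expect_equal(replicount:::trapz(pp@grid, pp@density), 1,
                 tolerance = 1e-6)
    # multiplicity bookkeeping: kernels at s, 2s, ..., 6s with counts 6..1
    expect_identical(as.integer(table(round(pp@centers))),
                     as.integer(6:1))
    expect_error(computePPDD(Idealization(data.frame(start = 0,
        duration = 10, mean = 1, variance = 0))), "two levels")
})

test_that("PPDD peaks sit at integer multiples of the true step", {
    set.seed(2)
    s <- simulateBleachTrace(6, stepSize = 1, seed = 11)
    pp <- computePPDD(s$truth)
    for (m in 1:3) {
        near <- which(abs(pp@grid - m) < 0.25)
        far <- which(abs(pp@grid - (m + 0.5)) < 0.2)
        expect_gt(max(pp@density[near]), max(pp@density[far]))
    }
})

test_that("the spectrum recovers exact and noisy unitary steps", {
    id <- stairIdeal(7, step = 100, variance = 100)
    st <- powerSpectrum(computePPDD(id))
    expect_equal(st@deltaI, 100, tolerance = 1 / 2048 * 60)

    two <- Idealization(data.frame(start = c(0, 40), duration = c(40, 80),
                                   mean = c(7.3, 0), variance = 0.09))
    st2 <- powerSpectrum(computePPDD(two), stepRange = c(1, 8))
    expect_equal(st2@deltaI, 7.3, tolerance = 0.02)
    expect_gt(st2@peakHeight, 0)
})

test_that("exponential fits recover the initial intensity", {
    t <- 0:119
    exact <- fitInitialIntensity(100 * exp(-t / 41))
    expect_equal(exact@i0, 100, tolerance = 1e-6)
    expect_equal(exact@tb, 41, tolerance = 1e-6)
    expect_true(exact@converged)

    i0s <- vapply(1:200, function(i)
        fitInitialIntensity(simulateBleachTrace(12, stepSize = 1,
                                                seed = 700 + i)$trace)@i0,
        numeric(1))
    expect_equal(mean(i0s), 12, tolerance = 0.05)
    expect_error(fitInitialIntensity(1:5), "10 frames")
})

test_that("stoichiometry is the plain ratio of intensity to step", {
    fit0 <- new("BleachFit", i0 = 0, tb = 40, residual = 0,
                converged = TRUE)
    expect_identical(estimateStoichiometry(fit0, 51)@n, 0)
    fit <- new("BleachFit", i0 = 612, tb = 40, residual = 0,
               converged = TRUE)
    expect_identical(estimateStoichiometry(fit, 51)@n, 12)
    expect_error(estimateStoichiometry(fit, -1), "positive")
})

test_that("QC gates trip on the documented rules with named reasons", {
    rec <- new("StoichiometryRecord", n = 6, i0 = 300, deltaI = 50,
               qcPass = NA, qcReasons = character())
    ok <- qcFilter(rec, segError = FALSE, ellipticity = 1.0,
                   inVitroStep = 50, firstFrameIntensity = 310,
                   inBand = TRUE)
    expect_true(ok@qcPass)
    expect_length(ok@qcReasons, 0L)

    expect_identical(qcFilter(rec, FALSE, 1.3, 50, NULL, 310,
                              TRUE)@qcReasons, "ellipticity")
    bad3 <- rec; bad3@deltaI <- 150   # 3x the reference step
    expect_identical(qcFilter(bad3, FALSE, 1.0, 50, NULL, 310,
                              TRUE)@qcReasons, "step-size")
    weak <- new("UnitaryStep", deltaI = 50, stepGrid = c(10, 50, 90),
                power = c(0.5, 1, 0.95), peakHeight = 1,
                runnerUpHeight = 0.95)
    expect_identical(qcFilter(rec, FALSE, 1.0, 50, weak, 310,
                              TRUE)@qcReasons, "peak-dominance")
    expect_identical(qcFilter(rec, FALSE, 1.0, 50, NULL, 500,
                              TRUE)@qcReasons, "initial-intensity")
    expect_identical(qcFilter(rec, FALSE, 1.0, 50, NULL, 310,
                              FALSE)@qcReasons, "localization")
    expect_identical(qcFilter(rec, TRUE, 1.0, 50, NULL, 310,
                              TRUE)@qcReasons, "segmentation-error")
    high <- rec; high@n <- 12
    expect_identical(qcFilter(high, FALSE, 1.0, 50, NULL, 310, TRUE,
                              maxCopies = 10)@qcReasons,
                     "high-stoichiometry")
    expect_identical(qcFilter(rec)@qcReasons, "incomplete")
})

test_that("the mixture MLE recovers planted two-population structure", {
    set.seed(3)
    x <- c(rnorm(100, 6, 0.01), rnorm(100, 12, 0.01))
    fit <- fitMixture(x)
    expect_false(fit@degenerate)
    expect_equal(fit@mu1, 6, tolerance = 0.01)
    expect_equal(fit@mu2, 12, tolerance = 0.01)
    expect_equal(fit@fracLow, 0.5, tolerance = 0.01)

    y <- simulateStoichiometrySamples(6.2, 11.2, 1.2, 1.5, 0.41,
                                      n = 5000, seed = 4)
    big <- fitMixture(y)
    expect_equal(big@mu1, 6.2, tolerance = 3 * 1.2 / sqrt(2050) / 6.2)
    expect_equal(big@mu2, 11.2, tolerance = 3 * 1.5 / sqrt(2950) / 11.2)
    expect_equal(big@fracLow, 0.41, tolerance = 3 * 0.012 / 0.41)
    expect_error(fitMixture(rnorm(10)), "20 samples")
})

test_that("the mixture MLE agrees with an independent EM implementation", {
    skip_if_not_installed("mclust")
    withr::local_package("mclust")
    y <- simulateStoichiometrySamples(6, 11, 1.1, 1.4, 0.45, n = 800,
                                      seed = 5)
    ours <- fitMixture(y)
    em <- mclust::Mclust(y, G = 2, modelNames = "V", verbose = FALSE)
    expect_equal(ours@logLik, em$loglik, tolerance = 1e-4)
    expect_equal(sort(c(ours@mu1, ours@mu2)),
                 sort(unname(em$parameters$mean)), tolerance = 0.02)
})

test_that("unimodal samples collapse to a single-component report", {
    set.seed(6)
    fit <- fitMixture(rnorm(300, 11.5, 1.3))
    expect_true(fit@degenerate)
    expect_identical(fit@fracLow, 0)
    expect_true(is.na(fit@mu1))
    expect_equal(fit@mu2, 11.5, tolerance = 0.05)
})

test_that("bootstrap F_L errors shrink like 1/sqrt(N)", {
    fit <- function(n) new("MixtureFit", mu1 = 6, mu2 = 12, sigma1 = 1,
                           sigma2 = 1, fracLow = 0.4, logLik = 0,
                           n = as.integer(n), degenerate = FALSE)
    errs <- vapply(c(100L, 400L, 1600L), function(n)
        mixtureError(fit(n), nSim = 120L, seed = 7)@flError, numeric(1))
    expect_true(all(diff(errs) < 0))
    expect_equal(errs[1] / errs[2], 2, tolerance = 0.35)
    expect_equal(errs[2] / errs[3], 2, tolerance = 0.35)
    # the theoretical binomial scale at N = 400
    expect_equal(errs[2], sqrt(0.4 * 0.6 / 400), tolerance = 0.4)
})

test_that("KDE uses an AMISE-scale bandwidth and normalizes", {
    set.seed(8)
    x <- rnorm(10000)
    kd <- stoichiometryKDE(x)
    expect_equal(kd$bw, 1.06 * 10000^(-1 / 5), tolerance = 0.15)
    expect_equal(replicount:::trapz(kd$x, kd$y), 1, tolerance = 1e-3)
    expect_error(stoichiometryKDE(rep(3, 10)), "zero-variance")
    expect_error(stoichiometryKDE(c(1, 2)), "5 samples")
})

test_that("copy-number estimates are invariant to intensity rescaling", {
    s <- simulateBleachTrace(6, stepSize = 1, seed = 31)
    x <- traceValues(s$trace)
    base <- stoichiometryPipeline(x, sharedTable)
    scaled <- stoichiometryPipeline(7.3 * x, sharedTable)
    expect_false(is.null(base$record))
    expect_equal(scaled$record@deltaI, 7.3 * base$record@deltaI,
                 tolerance = 1e-6)
    expect_equal(scaled$record@n, base$record@n, tolerance = 1e-6)
})

test_that("simulated helicase traces yield copy numbers near truth", {
    est <- c()
    for (i in 1:40) {
        out <- stoichiometryPipeline(
            simulateBleachTrace(6, stepSize = 1, seed = 900 + i)$trace,
            sharedTable, inVitroStep = 1)
        if (!is.null(out$record) && isTRUE(out$record@qcPass))
            est <- c(est, out$record@n)
    }
    expect_gt(length(est), 20)
    expect_equal(mean(est), 6, tolerance = 0.15)
})
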