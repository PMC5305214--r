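# Shared fixtures, built once per test session.

# Calibrated change-point table for 120-frame traces (unit tests; the
# acceptance checks calibrate their own, larger tables).
sharedTable <- calibrateThreshold(120L, 0.95, nSim = 5000L, seed = 101L)

# A lifetime dataset with exact summary statistics (N observed lifetimes all
# equal to tauBar, plus censored complexes), for feeding printed count
# tables into the closed-form estimator.
datasetFromCounts <- function(nObs, nCens, tauBarVal, windowT, tauMin) {
    LifetimeDataset(c(rep(tauBarVal, nObs), rep(windowT, nCens)),
                    c(rep(FALSE, nObs), rep(TRUE, nCens)),
                    windowT = windowT, tauMin = tauMin)
}

# Independent censored log-likelihood maximizer (numerical oracle for the
# closed-form rate estimate).
numericRateOracle <- function(data) {
    obs <- data@lifetimes[!data@censored]
    nGe <- sum(data@censored)
    nll <- function(k) -(sum(log(k) - k * (obs - data@tauMin)) -
                         nGe * k * (data@windowT - data@tauMin))
    stats::optimize(nll, c(1e-6, 10), tol = 1e-12)$minimum
}

# Brute-force single-split scan: recompute the pooled-variance LLR at every
# admissible split with plain means and sums (independent of cpScan's
# cumulative-sum algebra).
bruteForceBestSplit <- function(x, minDur = 2L) {
    n <- length(x)
    rss <- function(v) sum((v - mean(v))^2)
    stats <- vapply(seq.int(minDur, n - minDur), function(c) {
        n * log(rss(x) / (rss(x[1:c]) + rss(x[(c + 1):n])))
    }, numeric(1))
    splits <- seq.int(minDur, n - minDur)
    list(split = splits[which.max(stats)], stat = max(stats))
}
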