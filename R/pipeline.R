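defaultParams <- function() list(
    # thresholds at their published defaults
    confidence = 0.95,       # change-point per-trace confidence
    calibrationSims = 10000, # Monte-Carlo replicates for the threshold
    scoreMin = 2,            # summed-image focus retention
    censusScoreMin = 3,      # snapshot census score floor
    ellipticityMax = 1.2,    # QC rule 2
    stepFactor = 2.5,        # QC rule 3: allowed factor around in vitro step
    peakDominance = 0.10,    # QC rule 4
    i0Tolerance = 0.30,      # QC rule 5
    bandFrac = 0.5,          # replication-factory band (fraction of length)
    maxStepNm = 350,         # trajectory displacement limit
    memberScoreMin = 3, meanScoreMin = 4, peakScoreMin = 5, minFrames = 3,
    pixelSize = 0.16,        # micrometers per pixel
    frameInterval = 2,       # minutes (lifetime acquisitions)
    tauMin = 4,              # minutes
    cycleLength = 40,        # minutes per replication cycle
    inVitroStep = NA,        # reference unitary step for QC rule 3
    errorSims = 10000,       # bootstrap replicates for errors
    diskRadius = 3)

logLine <- function(log, fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", sep = "")
    cat(line, "\n", sep = "", file = log, append = TRUE)
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the stages appropriate to the configured mode and inputs,
#' persisting every intermediate artifact plus a JSON summary and a log
#' that records counts in and out of each filter (so exclusion accounting
#' is auditable). Modes: `"stoichiometry"` (stack + masks, or a trace CSV)
#' and `"lifetime"` (stack + masks, a focus CSV, or a lifetime CSV). All
#' thresholds default to their published values and may be overridden in
#' the config's `params` block; `seed` drives every stochastic step
#' (threshold calibration, bootstrap errors).
#'
#' @param config a YAML file path or an equivalent list with entries
#'   `mode`, `out`, `seed`, `input` (paths: `stack`, `masks`, `traces`,
#'   `foci`, `lifetimes`) and optional `params`.
#' @return invisibly, the summary list (also written to
#'   `<out>/summary.json`).
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(!is.null(config$mode), !is.null(config$out))
    params <- utils::modifyList(defaultParams(), config$params %||% list())
    seed <- config$seed %||% 1L
    out <- config$out
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    log <- file.path(out, "run.log")
    cat("", file = log)
    yaml::write_yaml(config, file.path(out, "config.yaml"))
    logLine(log, "mode=%s seed=%d", config$mode, seed)
    summary <- list(mode = config$mode, seed = seed,
                    params = params)
    inp <- config$input %||% list()
    stageFail <- function(stage, msg)
        stop(sprintf("stage '%s' failed: %s", stage, msg), call. = FALSE)

    if (config$mode == "stoichiometry") {
        traces <- NULL
        if (!is.null(inp$stack)) {
            stack <- tryCatch(readStack(inp$stack), error = function(e)
                stageFail("quantify", paste(inp$stack, ":",
                                            conditionMessage(e))))
            masks <- tryCatch(readMasks(inp$masks), error = function(e)
                stageFail("quantify", paste(inp$masks, ":",
                                            conditionMessage(e))))
            q <- quantifyStack(stack, masks, scoreMin = params$scoreMin,
                               r = params$diskRadius)
            logLine(log, "quantify: %d foci retained (score > %g)",
                    nrow(q$foci), params$scoreMin)
            utils::write.csv(q$foci, file.path(out, "foci.csv"),
                             row.names = FALSE)
            traces <- q$traces
            writeTraces(traces, file.path(out, "traces.csv"))
        } else if (!is.null(inp$traces)) {
            traces <- tryCatch(readTraces(inp$traces), error = function(e)
                stageFail("idealize", conditionMessage(e)))
        } else stageFail("quantify", "no stack or trace input")
        nFrames <- max(vapply(traces, function(t) length(traceValues(t)),
                              numeric(1)))
        table <- calibrateThreshold(nFrames, params$confidence,
                                    nSim = params$calibrationSims,
                                    seed = seed)
        saveCriticalValueTable(table, file.path(out, "cp-threshold.json"))
        results <- lapply(traces, function(tr)
            stoichiometryPipeline(tr, table,
                                  inVitroStep = params$inVitroStep))
        writeIdealizations(lapply(results, `[[`, "idealization"),
                           file.path(out, "idealizations.csv"))
        logLine(log, "idealize: %d traces", length(results))
        rec <- do.call(rbind, lapply(names(results), function(id) {
            r <- results[[id]]$record
            if (is.null(r)) return(NULL)
            data.frame(trace = id, i0 = r@i0, tb = results[[id]]$fit@tb,
                       deltaI = r@deltaI, n = r@n, qcPass = r@qcPass,
                       qcReasons = paste(r@qcReasons, collapse = ";"))
        }))
        if (is.null(rec)) stageFail("stoich", "no unitary step resolved")
        utils::write.csv(rec, file.path(out, "records.csv"),
                         row.names = FALSE)
        pass <- if (all(is.na(rec$qcPass))) rec else
            rec[!isFALSE(rec$qcPass) & (is.na(rec$qcPass) | rec$qcPass), ]
        logLine(log, "stoich QC: %d of %d records retained",
                nrow(pass), nrow(rec))
        summary$nTraces <- length(traces)
        summary$nRecords <- nrow(rec)
        summary$nPassQC <- nrow(pass)
        summary$meanN <- mean(pass$n)
        if (nrow(pass) >= 20L) {
            fit <- fitMixture(pass$n)
            fit <- mixtureError(fit, nSim = params$errorSims, seed = seed)
            summary$mixture <- list(mu1 = fit@mu1, mu2 = fit@mu2,
                                    sigma1 = fit@sigma1,
                                    sigma2 = fit@sigma2,
                                    fracLow = fit@fracLow,
                                    flError = fit@flError, N = fit@n,
                                    degenerate = fit@degenerate)
            kd <- stoichiometryKDE(pass$n)
            utils::write.csv(data.frame(x = kd$x, density = kd$y),
                             file.path(out, "kde.csv"), row.names = FALSE)
            logLine(log, "mixture: mu=(%.3g, %.3g), F_L=%.3g (%.2g)",
                    fit@mu1, fit@mu2, fit@fracLow, fit@flError)
        }
    } else if (config$mode == "lifetime") {
        data <- NULL
        if (!is.null(inp$lifetimes)) {
            data <- tryCatch(readLifetimes(inp$lifetimes,
                                           windowT = params$windowT,
                                           tauMin = params$tauMin),
                             error = function(e)
                                 stageFail("lifetime", conditionMessage(e)))
        } else {
            foci <- if (!is.null(inp$foci)) {
                tryCatch(utils::read.csv(inp$foci), error = function(e)
                    stageFail("lifetime", conditionMessage(e)))
            } else if (!is.null(inp$stack)) {
                stack <- tryCatch(readStack(inp$stack), error = function(e)
                    stageFail("quantify", paste(inp$stack, ":",
                                                conditionMessage(e))))
                masks <- tryCatch(readMasks(inp$masks), error = function(e)
                    stageFail("quantify", conditionMessage(e)))
                q <- quantifyFrames(stack, masks, r = params$diskRadius)
                utils::write.csv(q, file.path(out, "foci.csv"),
                                 row.names = FALSE)
                q
            } else stageFail("lifetime", "no lifetime, focus or stack input")
            nFrames <- (config$nFrames %||% (max(foci$frame) + 1L))
            lk <- linkTrajectories(foci, pixelSize = params$pixelSize,
                                   frameInterval = params$frameInterval,
                                   maxStepNm = params$maxStepNm,
                                   memberScoreMin = params$memberScoreMin,
                                   meanScoreMin = params$meanScoreMin,
                                   peakScoreMin = params$peakScoreMin,
                                   minFrames = params$minFrames)
            logLine(log, "link: %d foci -> %d trajectories", nrow(foci),
                    nrow(lk$trajectories))
            utils::write.csv(lk$trajectories,
                             file.path(out, "trajectories.csv"),
                             row.names = FALSE)
            data <- callLifetimes(lk$trajectories, nFrames = nFrames,
                                  frameInterval = params$frameInterval,
                                  tauMin = params$tauMin)
        }
        writeLifetimes(data, file.path(out, "lifetimes.csv"))
        est <- estimateRate(data, cycleLength = params$cycleLength)
        est <- rateError(est, data, nSim = params$errorSims, seed = seed,
                         frameInterval = params$frameInterval)
        curves <- survivalCurves(data, est)
        utils::write.csv(curves, file.path(out, "survival.csv"),
                         row.names = FALSE)
        logLine(log,
                "rate: k=%.4g/min (+-%.2g), tau=%.3g min, Nc=%.3g",
                est@kHat, est@kError, est@tauCalc, est@nC)
        summary$lifetime <- list(T = data@windowT, tauMin = data@tauMin,
                                 nObserved = nObserved(data),
                                 nCensored = nCensored(data),
                                 tauBar = tauBar(data), kHat = est@kHat,
                                 kError = est@kError,
                                 tauCalc = est@tauCalc, nC = est@nC)
    } else stop("unknown mode: ", config$mode)
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    invisible(summary)
}

#' Render a human-readable report for a completed run
#'
#' Produces a PDF of the run's figures (survival curves for lifetime runs;
#' KDE with mixture overlay and a copy-number histogram for stoichiometry
#' runs) and a plain-text summary table.
#'
#' @param runDir directory produced by [runPipeline()].
#' @return invisibly, the report path.
#' @export
makeReport <- function(runDir) {
    sp <- file.path(runDir, "summary.json")
    if (!file.exists(sp))
        stop("nothing to report: no summary.json in ", runDir)
    s <- jsonlite::read_json(sp, simplifyVector = TRUE)
    pdfPath <- file.path(runDir, "report.pdf")
    grDevices::pdf(pdfPath, width = 6, height = 5)
    on.exit(grDevices::dev.off())
    if (identical(s$mode, "lifetime")) {
        cp <- file.path(runDir, "survival.csv")
        if (!file.exists(cp)) stop("missing artifact: survival.csv")
        cv <- utils::read.csv(cp)
        plot(cv$t, cv$empirical, type = "s", lwd = 2, ylim = c(0, 1),
             xlab = "lifetime (min)", ylab = "survival probability",
             main = sprintf("k = %.3g /min, Nc = %.2g",
                            s$lifetime$kHat, s$lifetime$nC))
        graphics::lines(cv$t, cv$model, lty = 2, col = "grey40", lwd = 2)
        graphics::legend("topright", c("empirical", "model"),
                         lty = c(1, 2), lwd = 2,
                         col = c("black", "grey40"), bty = "n")
    } else if (identical(s$mode, "stoichiometry")) {
        rp <- file.path(runDir, "records.csv")
        if (!file.exists(rp)) stop("missing artifact: records.csv")
        rec <- utils::read.csv(rp)
        keep <- if ("qcPass" %in% names(rec) && !all(is.na(rec$qcPass)))
            rec[!isFALSE(rec$qcPass) & (is.na(rec$qcPass) | rec$qcPass), ]
        else rec
        graphics::hist(keep$n, breaks = 30, freq = FALSE,
                       xlab = "estimated copies", main = "stoichiometry")
        kp <- file.path(runDir, "kde.csv")
        if (file.exists(kp)) {
            kd <- utils::read.csv(kp)
            graphics::lines(kd$x, kd$density, lwd = 2)
        }
        if (!is.null(s$mixture) && !isTRUE(s$mixture$degenerate)) {
            x <- seq(min(keep$n), max(keep$n), length.out = 400)
            graphics::lines(x, s$mixture$fracLow *
                stats::dnorm(x, s$mixture$mu1, s$mixture$sigma1) +
                (1 - s$mixture$fracLow) *
                stats::dnorm(x, s$mixture$mu2, s$mixture$sigma2),
                col = "blue", lwd = 2, lty = 2)
        }
    } else stop("unknown run mode in summary: ", s$mode)
    txt <- file.path(runDir, "report.txt")
    writeLines(c(sprintf("mode: %s", s$mode),
                 utils::capture.output(utils::str(
                     s[setdiff(names(s), "params")]))), txt)
    invisible(pdfPath)
}
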