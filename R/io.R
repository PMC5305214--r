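#' Read and write multi-frame TIFF stacks
#'
#' Stacks are stored as 32-bit float TIFF scaled into `[0, 1]`, with the
#' scale factor and acquisition metadata in a JSON sidecar
#' (`<path>.json`), so arbitrary intensity units round-trip.
#'
#' @param stack numeric array `rows x cols x frames` (or a matrix).
#' @param path TIFF file path.
#' @param metadata optional list stored in the sidecar (e.g. `pixelSize`,
#'   `frameInterval`).
#' @return `readStack` returns the array with the sidecar entries attached
#'   as attributes; `writeStack` the path, invisibly.
#' @export
writeStack <- function(stack, path, metadata = list()) {
    if (length(dim(stack)) == 2L) stack <- array(stack, c(dim(stack), 1L))
    scale <- max(abs(stack), 1e-300)
    frames <- lapply(seq_len(dim(stack)[3]), function(t)
        (stack[, , t] / scale + 1) / 2)   # map into [0,1] allowing negatives
    tiff::writeTIFF(frames, path, bits.per.sample = 32L)
    jsonlite::write_json(c(list(scale = scale), metadata),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
}

#' @rdname writeStack
#' @export
readStack <- function(path) {
    frames <- tiff::readTIFF(path, all = TRUE)
    meta <- jsonlite::read_json(paste0(path, ".json"),
                                simplifyVector = TRUE)
    stack <- array(0, c(dim(frames[[1]]), length(frames)))
    for (t in seq_along(frames))
        stack[, , t] <- (frames[[t]] * 2 - 1) * meta$scale
    for (nm in setdiff(names(meta), "scale"))
        attr(stack, nm) <- meta[[nm]]
    stack
}

#' Read and write labeled cell masks
#'
#' Labels are stored as 16-bit TIFF (up to 65535 cells).
#'
#' @param masks integer label matrix (0 = background).
#' @param path TIFF (or PNG-readable) path.
#' @return `readMasks` the integer matrix; `writeMasks` the path,
#'   invisibly.
#' @export
writeMasks <- function(masks, path) {
    tiff::writeTIFF(masks / 65535, path, bits.per.sample = 16L)
    invisible(path)
}

#' @rdname writeMasks
#' @export
readMasks <- function(path) {
    img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
        if (!requireNamespace("png", quietly = TRUE))
            stop("the png package is required to read PNG masks")
        png::readPNG(path)
    } else tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    matrix(as.integer(round(img * 65535)), nrow(img))
}

#' Read and write intensity traces as CSV
#'
#' Long format: one row per (trace, frame) with columns `trace`, `frame`
#' (0-based), `value`, plus optional `iR` and `iB` provenance columns.
#'
#' @param traces list of [IntensityTrace-class] (or a single one).
#' @param path CSV path.
#' @return `readTraces` a named list of [IntensityTrace-class];
#'   `writeTraces` the path, invisibly.
#' @export
writeTraces <- function(traces, path) {
    if (is(traces, "IntensityTrace")) traces <- list(traces)
    if (is.null(names(traces)) || any(names(traces) == ""))
        names(traces) <- seq_along(traces)
    rows <- lapply(names(traces), function(id) {
        tr <- traces[[id]]
        v <- traceValues(tr)
        d <- data.frame(trace = id, frame = seq_along(v) - 1L, value = v,
                        frameInterval = frameInterval(tr))
        if (!is.null(tr@metadata$iR)) d$iR <- tr@metadata$iR
        if (!is.null(tr@metadata$iB)) d$iB <- tr@metadata$iB
        d
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTraces
#' @export
readTraces <- function(path) {
    d <- utils::read.csv(path)
    stopifnot(all(c("trace", "frame", "value") %in% names(d)))
    lapply(split(d, d$trace), function(g) {
        g <- g[order(g$frame), ]
        meta <- list()
        if (!is.null(g$iR)) meta$iR <- g$iR
        if (!is.null(g$iB)) meta$iB <- g$iB
        IntensityTrace(g$value,
                       frameInterval = if (is.null(g$frameInterval)) 1 else
                           g$frameInterval[1],
                       metadata = meta)
    })
}

#' Read and write idealizations as CSV
#'
#' One row per level: `trace`, `level`, `start`, `duration`, `mean`,
#' `variance`, `uncertainty`.
#'
#' @param idealizations named list of [Idealization-class] (or one).
#' @param path CSV path.
#' @return `readIdealizations` a named list; the writer its path,
#'   invisibly.
#' @export
writeIdealizations <- function(idealizations, path) {
    if (is(idealizations, "Idealization"))
        idealizations <- list(idealizations)
    if (is.null(names(idealizations)) || any(names(idealizations) == ""))
        names(idealizations) <- seq_along(idealizations)
    rows <- lapply(names(idealizations), function(id) {
        lv <- levelTable(idealizations[[id]])
        cbind(trace = id, level = seq_len(nrow(lv)), lv)
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeIdealizations
#' @export
readIdealizations <- function(path) {
    d <- utils::read.csv(path)
    lapply(split(d, d$trace), function(g) {
        g <- g[order(g$start), ]
        Idealization(g[, c("start", "duration", "mean", "variance",
                           "uncertainty")])
    })
}

#' Read and write lifetime tables as CSV
#'
#' Columns `tau` (minutes), `censored` (logical), optional `cell`; window
#' and floor are stored in the header comment-free columns `windowT`,
#' `tauMin` (constant per file).
#'
#' @param data a [LifetimeDataset-class].
#' @param path CSV path.
#' @param windowT,tauMin required by `readLifetimes` when the file lacks
#'   the columns.
#' @return `readLifetimes` a [LifetimeDataset-class]; the writer its path,
#'   invisibly.
#' @export
writeLifetimes <- function(data, path) {
    utils::write.csv(data.frame(tau = data@lifetimes,
                                censored = data@censored,
                                windowT = data@windowT,
                                tauMin = data@tauMin),
                     path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeLifetimes
#' @export
readLifetimes <- function(path, windowT = NULL, tauMin = NULL) {
    d <- utils::read.csv(path)
    stopifnot(all(c("tau", "censored") %in% names(d)))
    wT <- windowT %||% d$windowT[1]
    tm <- tauMin %||% d$tauMin[1]
    if (is.null(wT) || is.null(tm))
        stop("windowT and tauMin must be in the file or given explicitly")
    LifetimeDataset(d$tau, as.logical(d$censored), wT, tm)
}
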