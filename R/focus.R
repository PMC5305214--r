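# Pixels whose centers lie within Euclidean distance r of (row, col)
# (0-based sub-pixel center). 29 pixels at r = 3.
diskPixels <- function(row, col, r, dim) {
    r0 <- max(0L, floor(row - r)):min(dim[1] - 1L, ceiling(row + r))
    c0 <- max(0L, floor(col - r)):min(dim[2] - 1L, ceiling(col + r))
    g <- expand.grid(row = r0, col = c0)
    g <- g[(g$row - row)^2 + (g$col - col)^2 <= r^2, ]
    clipped <- row - r < 0 || row + r > dim[1] - 1L ||
        col - r < 0 || col + r > dim[2] - 1L
    list(idx = cbind(g$row + 1L, g$col + 1L), clipped = clipped)
}

shiftImage <- function(img, dr, dc) {
    h <- nrow(img); w <- ncol(img)
    out <- matrix(0, h, w)
    srcR <- seq_len(h) - dr; srcC <- seq_len(w) - dc
    okR <- srcR >= 1 & srcR <= h; okC <- srcC >= 1 & srcC <= w
    out[okR, okC] <- img[srcR[okR], srcC[okC]]
    out
}

#' Align an image stack against its first frame
#'
#' Corrects xy sample drift: every frame is aligned to frame 0 (not chained
#' frame-to-frame, so registration errors do not accumulate) by the
#' integer-pixel shift maximizing the circular cross-correlation, computed
#' via FFT. The shifts are reported and reused downstream.
#'
#' @param stack numeric array `rows x cols x frames` (>= 2 frames).
#' @param maxShift largest plausible drift in pixels (default a quarter of
#'   the smaller image dimension, capped at 15); the correlation maximum is
#'   searched only within this window, which keeps quasi-periodic cell
#'   layouts from aliasing the registration.
#' @return list with `stack` (aligned, zero-filled borders) and `shifts`
#'   (frames x 2 integer matrix of applied (row, col) shifts).
#' @export
alignStack <- function(stack, maxShift = NULL) {
    stopifnot(length(dim(stack)) == 3L, dim(stack)[3] >= 2L)
    h <- dim(stack)[1]; w <- dim(stack)[2]; nf <- dim(stack)[3]
    if (is.null(maxShift)) maxShift <- min(15L, floor(min(h, w) / 4))
    ref <- stack[, , 1]
    fr <- stats::fft(ref)
    lag <- function(m, n) ifelse(m > n / 2, m - n, m)
    shifts <- matrix(0L, nf, 2L)
    out <- stack
    for (t in 2:nf) {
        img <- stack[, , t]
        if (all(img == 0)) {
            warning(sprintf("frame %d is all zero; assuming zero shift",
                            t - 1L))
            next
        }
        cc <- Re(stats::fft(fr * Conj(stats::fft(img)), inverse = TRUE))
        idx <- arrayInd(seq_along(cc), c(h, w)) - 1L
        dr <- lag(idx[, 1], h); dc <- lag(idx[, 2], w)
        ok <- abs(dr) <= maxShift & abs(dc) <= maxShift
        best <- which(ok)[which.max(cc[ok])]
        shifts[t, ] <- c(dr[best], dc[best])
        out[, , t] <- shiftImage(img, dr[best], dc[best])
    }
    list(stack = out, shifts = shifts)
}

#' Summed image of an aligned stack
#'
#' Per-pixel sum of all frames followed by a Gaussian blur of one pixel
#' standard deviation; foci are located on this high-signal image rather
#' than on individual noisy frames.
#'
#' @param stack aligned array `rows x cols x frames` (a single matrix is
#'   treated as a one-frame stack).
#' @param blurSigma blur standard deviation in pixels (default 1).
#' @return numeric matrix.
#' @export
summedImage <- function(stack, blurSigma = 1) {
    s <- if (length(dim(stack)) == 3L) rowSums(stack, dims = 2L) else stack
    as.matrix(EBImage::gblur(s, sigma = blurSigma))
}

#' Partition the summed image into intensity regions
#'
#' Watershed of the summed image (flooding from its local maxima) restricted
#' to within-cell pixels, so each region contains exactly one intensity
#' maximum and regions outside the cells are discarded. Up to `maxPerCell`
#' regions are kept per cell, in decreasing order of their peak summed
#' intensity.
#'
#' @param summed summed image matrix.
#' @param masks labeled cell-mask matrix (0 = background).
#' @param maxPerCell foci fitted per cell (default 4).
#' @param tolerance watershed tolerance (minimum peak prominence). The
#'   default is twice a robust estimate of the image's pixel noise (median
#'   absolute first difference scaled to a standard deviation), which
#'   suppresses noise-level maxima while keeping genuine foci separate from
#'   the cell-interior plateau.
#' @return list with `regions` (labeled matrix, 0 outside regions) and
#'   `peaks` (data.frame: region, cell, row, col, value — peak pixel
#'   0-based positions).
#' @export
partitionIntensityRegions <- function(summed, masks, maxPerCell = 4L,
                                      tolerance = NULL) {
    stopifnot(all(dim(summed) == dim(masks)))
    if (all(masks == 0)) {
        return(list(regions = matrix(0L, nrow(summed), ncol(summed)),
                    peaks = data.frame(region = integer(), cell = integer(),
                                       row = integer(), col = integer(),
                                       value = numeric())))
    }
    if (is.null(tolerance))
        tolerance <- 2 * stats::mad(diff(as.vector(summed))) / sqrt(2)
    x <- summed - min(summed)
    ws <- EBImage::watershed(EBImage::Image(x), tolerance = tolerance)
    regions <- matrix(as.integer(EBImage::imageData(ws)), nrow(summed))
    regions[masks == 0] <- 0L
    labs <- setdiff(unique(as.vector(regions)), 0L)
    peaks <- do.call(rbind, lapply(labs, function(l) {
        px <- which(regions == l)
        top <- px[which.max(summed[px])]
        ij <- arrayInd(top, dim(summed))
        data.frame(region = l, cell = masks[top], row = ij[1] - 1L,
                   col = ij[2] - 1L, value = summed[top])
    }))
    if (is.null(peaks)) {
        regions[] <- 0L
        return(list(regions = regions,
                    peaks = data.frame(region = integer(), cell = integer(),
                                       row = integer(), col = integer(),
                                       value = numeric())))
    }
    peaks <- peaks[order(peaks$cell, -peaks$value), ]
    keep <- unlist(lapply(split(peaks$region, peaks$cell),
                          function(r) utils::head(r, maxPerCell)))
    regions[!(regions %in% keep)] <- 0L
    peaks <- peaks[peaks$region %in% keep, ]
    rownames(peaks) <- NULL
    list(regions = regions, peaks = peaks)
}

# Least-squares Gaussian fits over a pixel set. Returns NULL on failure.
gaussFit <- function(rows, cols, vals, row0, col0) {
    g0 <- stats::median(vals)
    gg <- max(vals) - g0
    if (gg <= 0) gg <- max(abs(vals - g0), 1e-6)
    # width capped at diffraction-limited scales (a few pixels) so the fit
    # cannot wander off the focus and absorb the cell-interior plateau
    circ <- tryCatch(minpack.lm::nlsLM(
        vals ~ gg * exp(-((rows - r0)^2 + (cols - c0)^2) / (2 * b^2)) + g0,
        start = list(gg = gg, r0 = row0, c0 = col0, b = 1.5, g0 = g0),
        lower = c(gg = 0, r0 = row0 - 3, c0 = col0 - 3, b = 0.3,
                  g0 = -Inf),
        upper = c(gg = Inf, r0 = row0 + 3, c0 = col0 + 3, b = 4,
                  g0 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
    if (is.null(circ)) return(NULL)
    cf <- stats::coef(circ)
    ell <- tryCatch(minpack.lm::nlsLM(
        vals ~ gg * exp(-((rows - r0)^2 / (2 * br^2) +
                          (cols - c0)^2 / (2 * bc^2))) + g0,
        start = list(gg = cf[["gg"]], r0 = cf[["r0"]], c0 = cf[["c0"]],
                     br = cf[["b"]], bc = cf[["b"]], g0 = cf[["g0"]]),
        lower = c(gg = 0, r0 = row0 - 3, c0 = col0 - 3, br = 0.3, bc = 0.3,
                  g0 = -Inf),
        upper = c(gg = Inf, r0 = row0 + 3, c0 = col0 + 3, br = 4, bc = 4,
                  g0 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
    ellipticity <- if (is.null(ell)) NA_real_ else {
        ec <- stats::coef(ell)
        max(ec[["br"]], ec[["bc"]]) / min(ec[["br"]], ec[["bc"]])
    }
    list(amplitude = cf[["gg"]], row = cf[["r0"]], col = cf[["c0"]],
         width = cf[["b"]], background = cf[["g0"]],
         ellipticity = ellipticity)
}

#' Fit a Gaussian focus model inside an intensity region
#'
#' Fits `G(x) = G_G exp(-|x - x0|^2 / 2 b^2) + G_0` by least squares over
#' the union of the intensity region and a 3-pixel disk centered on the
#' region's maximum pixel; an elliptical refit (independent widths along
#' rows and columns) supplies the ellipticity used by the QC rules. The
#' fitted position is retained for all frames.
#'
#' @param summed summed image matrix.
#' @param regions labeled region matrix from [partitionIntensityRegions()].
#' @param regionLabel which region to fit.
#' @param r disk radius in pixels (default 3).
#' @details The fit domain is the union of the intensity region and the
#'   r-pixel disk at the region's maximum, with region pixels farther than
#'   2r from the maximum dropped: a diffraction-limited spot carries no
#'   signal there, and on dim foci an extended domain lets the elliptical
#'   refit absorb cell-scale intensity gradients into spurious ellipticity.
#' @return one-row data.frame: `row`, `col` (0-based sub-pixel), `amplitude`,
#'   `background`, `width`, `ellipticity`, `valid`.
#' @export
fitFocus <- function(summed, regions, regionLabel, r = 3) {
    px <- which(regions == regionLabel)
    if (length(px) == 0L) stop("empty region")
    top <- px[which.max(summed[px])]
    ij <- arrayInd(top, dim(summed)) - 1L
    disk <- diskPixels(ij[1], ij[2], r, dim(summed))
    reg <- arrayInd(px, dim(summed))
    near <- (reg[, 1] - 1L - ij[1])^2 + (reg[, 2] - 1L - ij[2])^2 <=
        (2 * r)^2
    idx <- unique(rbind(reg[near, , drop = FALSE], disk$idx))
    fit <- gaussFit(idx[, 1] - 1L, idx[, 2] - 1L, summed[idx],
                    ij[1], ij[2])
    if (is.null(fit)) {
        return(data.frame(row = ij[1], col = ij[2], amplitude = NA_real_,
                          background = NA_real_, width = NA_real_,
                          ellipticity = NA_real_, valid = FALSE))
    }
    data.frame(row = fit$row, col = fit$col, amplitude = fit$amplitude,
               background = fit$background, width = fit$width,
               ellipticity = fit$ellipticity, valid = TRUE)
}

#' Focus significance score
#'
#' `sigma = I_A / (deltaI * sqrt(A_M))` with `A_M = pi r^2`: the integrated
#' background-subtracted intensity in the r-pixel disk over the expected
#' standard deviation of a sum of `A_M` uncorrelated pixels of noise
#' `deltaI`. The continuous-area constant follows the printed formula even
#' though the pixelized disk holds 29 pixels at r = 3 (the difference in
#' sigma is under 3%).
#'
#' @param iA integrated background-subtracted disk intensity.
#' @param deltaI per-pixel background standard deviation (> 0).
#' @param r disk radius in pixels (default 3).
#' @return the score.
#' @export
focusScore <- function(iA, deltaI, r = 3) {
    if (any(deltaI <= 0)) stop("degenerate background: deltaI must be > 0")
    iA / (deltaI * sqrt(pi * r^2))
}

# Background statistics of one cell with all focus disks excised.
cellBackground <- function(img, masks, cellId, allPositions, r = 3) {
    inCell <- masks == cellId
    if (!is.null(allPositions) && nrow(allPositions) > 0L) {
        for (k in seq_len(nrow(allPositions))) {
            d <- diskPixels(allPositions$row[k], allPositions$col[k], r,
                            dim(img))
            inCell[d$idx] <- FALSE
        }
    }
    vals <- img[inCell]
    if (length(vals) < 2L)
        stop("cell has no background pixels left after excising foci")
    list(iB = mean(vals), deltaI = stats::sd(vals))
}

#' Extract a background-subtracted intensity trace at a fixed position
#'
#' Per frame, the raw focus intensity `I_R` is the pixel sum in the
#' `r`-pixel disk at the (fixed) focus position; the per-pixel cell
#' background `I_B` and its standard deviation `deltaI` come from the cell
#' pixels that remain after excising every focus (mask radius `r`); the
#' focus intensity is `I_F = I_R - A * I_B`, where `A` is by default the
#' number of pixels actually summed (29 at r = 3), making `I_F` exactly
#' invariant under a constant image offset. `areaConvention = "continuous"`
#' uses `A = pi r^2` as in the printed formula.
#'
#' @param stack aligned array `rows x cols x frames`.
#' @param position c(row, col) 0-based focus position.
#' @param masks labeled cell masks.
#' @param cellId the cell owning the focus.
#' @param allPositions data.frame of all focus positions in the cell
#'   (columns `row`, `col`), used for excision; defaults to just
#'   `position`.
#' @param r disk radius (default 3).
#' @param frameInterval trace cadence (default 1 frame unit).
#' @param areaConvention `"pixels"` (default) or `"continuous"`.
#' @return An [IntensityTrace-class]; metadata carries per-frame `iR`,
#'   `iB`, `deltaI`, the position, cell id, and an `edgeClipped` flag when
#'   the disk ran off the image.
#' @export
extractTrace <- function(stack, position, masks, cellId,
                         allPositions = NULL, r = 3, frameInterval = 1,
                         areaConvention = c("pixels", "continuous")) {
    areaConvention <- match.arg(areaConvention)
    if (length(dim(stack)) == 2L) stack <- array(stack, c(dim(stack), 1L))
    if (is.null(allPositions))
        allPositions <- data.frame(row = position[1], col = position[2])
    d <- diskPixels(position[1], position[2], r, dim(stack)[1:2])
    aM <- if (areaConvention == "pixels") nrow(d$idx) else pi * r^2
    nf <- dim(stack)[3]
    iR <- iB <- dI <- numeric(nf)
    for (t in seq_len(nf)) {
        img <- stack[, , t]
        iR[t] <- sum(img[d$idx])
        bg <- cellBackground(img, masks, cellId, allPositions, r)
        iB[t] <- bg$iB; dI[t] <- bg$deltaI
    }
    IntensityTrace(iR - aM * iB, frameInterval = frameInterval,
                   metadata = list(position = position, cellId = cellId,
                                   iR = iR, iB = iB, deltaI = dI,
                                   edgeClipped = d$clipped, r = r,
                                   area = aM))
}

#' Test focus localization against the replication-factory band
#'
#' Active replisomes localize near midcell; the band rule accepts foci whose
#' projection on the cell's long axis (principal component of the mask
#' pixels) falls within the central `bandFrac` of the cell length.
#'
#' @param masks labeled cell masks.
#' @param cellId cell label.
#' @param position c(row, col) 0-based focus position.
#' @param bandFrac central fraction of the long axis accepted (default 0.5).
#' @return logical.
#' @export
inFactoryBand <- function(masks, cellId, position, bandFrac = 0.5) {
    px <- which(masks == cellId)
    if (length(px) == 0L) stop("unknown cell id")
    ij <- arrayInd(px, dim(masks)) - 1L
    ctr <- colMeans(ij)
    ax <- eigen(stats::cov(ij))$vectors[, 1]
    proj <- as.matrix(sweep(ij, 2, ctr)) %*% ax
    p <- sum((position - ctr) * ax)
    half <- bandFrac * (max(proj) - min(proj)) / 2
    p >= -half && p <= half
}

# Detect, fit and score foci in a single image (or summed image).
# Returns one row per retained focus.
detectFoci <- function(image, masks, maxPerCell = 4L, r = 3,
                       scoreMin = 2, blurSigma = 1, tolerance = NULL) {
    # the blurred image drives detection (watershed partition); fits and
    # scores use the raw image, where in-cell backgrounds stay flat up to
    # the cell boundary (blur bleeds the dark exterior into small cells and
    # would bias widths and ellipticities)
    sm <- if (is.null(blurSigma)) image else
        summedImage(image, blurSigma = blurSigma)
    part <- partitionIntensityRegions(sm, masks, maxPerCell = maxPerCell,
                                      tolerance = tolerance)
    if (nrow(part$peaks) == 0L)
        return(data.frame(cell = integer(), row = numeric(),
                          col = numeric(), amplitude = numeric(),
                          width = numeric(), ellipticity = numeric(),
                          iR = numeric(), iB = numeric(),
                          deltaI = numeric(), iF = numeric(),
                          score = numeric()))
    fits <- do.call(rbind, lapply(part$peaks$region, function(l)
        cbind(fitFocus(image, part$regions, l, r = r),
              cell = part$peaks$cell[part$peaks$region == l][1])))
    fits <- fits[fits$valid, , drop = FALSE]
    out <- lapply(seq_len(nrow(fits)), function(k) {
        f <- fits[k, ]
        sib <- fits[fits$cell == f$cell, c("row", "col")]
        d <- diskPixels(f$row, f$col, r, dim(image))
        iR <- sum(image[d$idx])
        bg <- tryCatch(cellBackground(image, masks, f$cell, sib, r),
                       error = function(e) NULL)
        if (is.null(bg) || bg$deltaI <= 0) return(NULL)
        iA <- iR - nrow(d$idx) * bg$iB
        data.frame(cell = f$cell, row = f$row, col = f$col,
                   amplitude = f$amplitude, width = f$width,
                   ellipticity = f$ellipticity, iR = iR, iB = bg$iB,
                   deltaI = bg$deltaI, iF = iA,
                   score = focusScore(iA, bg$deltaI, r))
    })
    out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(out)) out <- data.frame(cell = integer(), row = numeric(),
                                        col = numeric(), score = numeric())
    out[out$score > scoreMin, , drop = FALSE]
}

#' Detect and score foci in every frame of a stack
#'
#' Per-frame focus detection for trajectory building: each frame is blurred,
#' partitioned and fitted independently (foci move over the minutes-long
#' lifetime acquisitions, so a fixed summed-image position is not usable).
#'
#' @param stack array `rows x cols x frames` (already aligned if needed).
#' @param masks labeled cell masks.
#' @param maxPerCell foci per cell per frame (default 4).
#' @param r disk radius (default 3).
#' @param scoreMin detection score floor (default 2, the retention rule).
#' @return data.frame with a 0-based `frame` column plus the columns of the
#'   per-frame focus table (cell, row, col, score, ellipticity, ...).
#' @export
quantifyFrames <- function(stack, masks, maxPerCell = 4L, r = 3,
                           scoreMin = 2) {
    if (length(dim(stack)) == 2L) stack <- array(stack, c(dim(stack), 1L))
    out <- lapply(seq_len(dim(stack)[3]), function(t) {
        f <- detectFoci(stack[, , t], masks, maxPerCell = maxPerCell,
                        r = r, scoreMin = scoreMin)
        if (nrow(f)) cbind(frame = t - 1L, f) else NULL
    })
    out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(out))
        out <- data.frame(frame = integer(), cell = integer(),
                          row = numeric(), col = numeric(),
                          score = numeric(), ellipticity = numeric())
    rownames(out) <- NULL
    out
}

#' Quantify a bleaching stack into focus observations and traces
#'
#' The bleaching pipeline: align the stack against frame 0, locate foci on
#' the blurred summed image (watershed regions restricted to the cell
#' masks, Gaussian fits, scores), retain foci scoring above `scoreMin`, and
#' extract a background-subtracted intensity trace at each fixed focus
#' position.
#'
#' @param stack array `rows x cols x frames`.
#' @param masks labeled cell masks.
#' @param scoreMin summed-image retention score (default 2).
#' @param maxPerCell foci per cell (default 4).
#' @param r disk radius (default 3).
#' @param frameInterval trace cadence (default 1).
#' @return list with `foci` (data.frame incl. summed-image score and
#'   ellipticity), `traces` (list of [IntensityTrace-class], one per
#'   retained focus), `shifts`, `summed`.
#' @export
quantifyStack <- function(stack, masks, scoreMin = 2, maxPerCell = 4L,
                          r = 3, frameInterval = 1) {
    al <- alignStack(stack)
    sm <- summedImage(al$stack)
    # detection and fitting use the blurred summed image; scores use the
    # raw per-pixel sum so that the uncorrelated-noise score model holds
    smRaw <- rowSums(al$stack, dims = 2L)
    foci <- detectFoci(smRaw, masks, maxPerCell = maxPerCell, r = r,
                       scoreMin = scoreMin, blurSigma = 1)
    traces <- lapply(seq_len(nrow(foci)), function(k) {
        sib <- foci[foci$cell == foci$cell[k], c("row", "col")]
        extractTrace(al$stack, c(foci$row[k], foci$col[k]), masks,
                     foci$cell[k], allPositions = sib, r = r,
                     frameInterval = frameInterval)
    })
    list(foci = foci, traces = traces, shifts = al$shifts, summed = sm)
}

#' Focus census on a snapshot image
#'
#' Fraction of cells with at least one qualifying focus: score at or above
#' `scoreMin` (default 3), ellipticity below `ellipticityMax` (default
#' 1.2), and localization inside the replication-factory band. Counting
#' (binomial) error accompanies the fraction.
#'
#' @param image single fluorescence frame.
#' @param masks labeled cell masks.
#' @param scoreMin minimum score (default 3).
#' @param ellipticityMax maximum ellipticity (default 1.2).
#' @param bandFrac factory-band fraction (default 0.5; NA disables the
#'   localization rule).
#' @param r disk radius (default 3).
#' @return list with `fraction`, `error` (binomial SE), `nCells`,
#'   `positive` (cell ids), `foci` (the qualifying focus table).
#' @export
censusFoci <- function(image, masks, scoreMin = 3, ellipticityMax = 1.2,
                       bandFrac = 0.5, r = 3) {
    cells <- setdiff(sort(unique(as.vector(masks))), 0L)
    if (length(cells) == 0L) stop("no cells in the mask")
    f <- detectFoci(image, masks, r = r, scoreMin = 0)
    ok <- f$score >= scoreMin &
        (is.na(f$ellipticity) | f$ellipticity <= ellipticityMax)
    if (!is.na(bandFrac) && nrow(f)) {
        inb <- vapply(seq_len(nrow(f)), function(k)
            inFactoryBand(masks, f$cell[k], c(f$row[k], f$col[k]),
                          bandFrac), logical(1))
        ok <- ok & inb
    }
    f <- f[ok, , drop = FALSE]
    pos <- intersect(cells, unique(f$cell))
    p <- length(pos) / length(cells)
    list(fraction = p, error = sqrt(p * (1 - p) / length(cells)),
         nCells = length(cells), positive = pos, foci = f)
}
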