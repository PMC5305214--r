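flatField <- function(h = 41, w = 41, value = 10) matrix(value, h, w)

spotImage <- function(row, col, amp, b, h = 41, w = 41, background = 10) {
    rr <- matrix(seq_len(h) - 1L, h, w)
    cc <- matrix(seq_len(w) - 1L, h, w, byrow = TRUE)
    background + amp * exp(-((rr - row)^2 + (cc - col)^2) / (2 * b^2))
}

test_that("alignment recovers planted integer shifts against frame 0", {
    base <- spotImage(20, 20, 100, 2)
    ident <- array(rep(base, 3), c(41, 41, 3))
    al <- alignStack(ident)
    expect_true(all(al$shifts == 0L))

    rolled <- array(0, c(41, 41, 2))
    rolled[, , 1] <- base
    rolled[, , 2] <- replicount:::shiftImage(base, 2, 3)
    al2 <- alignStack(rolled)
    expect_identical(al2$shifts[2, ], c(-2L, -3L))
    inner <- 8:34
    expect_equal(al2$stack[inner, inner, 2], base[inner, inner])

    # alignment is to frame 0, not frame-to-frame chaining
    chain <- array(0, c(41, 41, 4))
    for (t in 1:4) chain[, , t] <- replicount:::shiftImage(base, t - 1, t - 1)
    al3 <- alignStack(chain)
    expect_identical(al3$shifts[, 1], c(0L, -1L, -2L, -3L))

    zeros <- array(0, c(41, 41, 2)); zeros[, , 1] <- base
    expect_warning(alignStack(zeros), "zero")
})

test_that("summed image preserves constants and total intensity", {
    const <- summedImage(array(7, c(41, 41, 1)))
    inner <- 8:34
    expect_equal(const[inner, inner], matrix(7, 27, 27), tolerance = 1e-9)

    img <- spotImage(20, 20, 100, 1.5, background = 0)
    blurred <- summedImage(array(img, c(41, 41, 1)))
    expect_equal(sum(blurred), sum(img), tolerance = 1e-3)

    stack <- array(rep(img, 5), c(41, 41, 5))
    expect_equal(rowSums(stack, dims = 2), 5 * img)   # linearity pre-blur
})

test_that("watershed partition isolates peaks inside cells", {
    masks <- matrix(0L, 41, 41); masks[5:37, 5:37] <- 1L
    one <- spotImage(20, 20, 100, 1.5)
    p1 <- partitionIntensityRegions(one, masks, tolerance = 1)
    expect_gte(nrow(p1$peaks), 1L)
    expect_identical(c(p1$peaks$row[1], p1$peaks$col[1]), c(20L, 20L))

    two <- spotImage(20, 14, 100, 1.5) + spotImage(20, 24, 100, 1.5) - 10
    p2 <- partitionIntensityRegions(two, masks, tolerance = 1)
    expect_gte(nrow(p2$peaks), 2L)
    expect_gte(max(p2$peaks$col) - min(p2$peaks$col), 8L)

    expect_true(all(p1$regions[masks == 0] == 0L))
    empty <- partitionIntensityRegions(one, matrix(0L, 41, 41))
    expect_identical(nrow(empty$peaks), 0L)
})

test_that("Gaussian focus fits recover planted parameters within 1%", {
    img <- spotImage(20, 23, 100, 1.5)
    masks <- matrix(1L, 41, 41)
    pt <- partitionIntensityRegions(img, masks, tolerance = 0.5)
    f <- fitFocus(img, pt$regions, pt$peaks$region[1])
    expect_true(f$valid)
    expect_equal(f$row, 20, tolerance = 0.01)
    expect_equal(f$col, 23, tolerance = 0.01)
    expect_equal(f$amplitude, 100, tolerance = 0.01)
    expect_equal(f$width, 1.5, tolerance = 0.01)
    expect_equal(f$ellipticity, 1, tolerance = 0.01)
})

test_that("focus score follows the printed formula", {
    expect_identical(focusScore(0, 5), 0)
    expect_equal(focusScore(106.3, 5, r = 3), 106.3 / (5 * sqrt(9 * pi)),
                 tolerance = 1e-12)
    expect_equal(focusScore(106.3, 5, r = 3), 4.00, tolerance = 0.001)
    expect_error(focusScore(10, 0), "deltaI")
    # pixel-count versus continuous area differ by < 3% in the score
    expect_lt(abs(sqrt(29) / sqrt(9 * pi) - 1), 0.03)
})

test_that("trace extraction subtracts background exactly", {
    masks <- matrix(1L, 41, 41)
    flat <- flatField(value = 13)
    tr <- extractTrace(flat, c(20, 20), masks, 1L)
    expect_lt(abs(traceValues(tr)[1]), 1e-9)       # offset-exact by design

    noisy <- flat + matrix(rnorm(41 * 41, 0, 2), 41)
    t0 <- extractTrace(noisy, c(20, 20), masks, 1L)
    t1 <- extractTrace(noisy + 100, c(20, 20), masks, 1L)
    expect_equal(traceValues(t0), traceValues(t1), tolerance = 1e-9)

    # hand evaluation of the printed continuous-area convention:
    # I_R = 500, I_B = 10  ->  I_F = 500 - pi*9*10 = 217.26
    d <- replicount:::diskPixels(20, 20, 3, c(41, 41))
    img <- matrix(10, 41, 41)
    img[d$idx] <- 500 / nrow(d$idx)              # disk sums to 500 exactly
    trc <- extractTrace(img, c(20, 20), masks, 1L,
                        areaConvention = "continuous")
    expect_equal(traceValues(trc)[1], 500 - pi * 9 * 10, tolerance = 1e-6)
})

test_that("planted spots are recovered in intensity and score scales correctly", {
    masks <- matrix(1L, 41, 41)
    set.seed(11)
    S <- 2 * pi * 40           # integrated intensity, b = 1
    ifs <- vapply(1:30, function(i) {
        img <- spotImage(20, 20, 40, 1) + matrix(rnorm(41 * 41, 0, 1), 41)
        traceValues(extractTrace(img, c(20, 20), masks, 1L))[1]
    }, numeric(1))
    expect_equal(mean(ifs), S * (1 - exp(-9 / 2)), tolerance = 0.05)

    img <- spotImage(20, 20, 40, 1) + matrix(rnorm(41 * 41, 0, 1), 41)
    score1 <- with(list(d = replicount:::diskPixels(20, 20, 3, dim(img))), {
        bg <- replicount:::cellBackground(img, masks, 1L,
                                          data.frame(row = 20, col = 20))
        focusScore(sum(img[d$idx]) - nrow(d$idx) * bg$iB, bg$deltaI)
    })
    score5 <- with(list(d = replicount:::diskPixels(20, 20, 3, dim(img))), {
        bg <- replicount:::cellBackground(5 * img, masks, 1L,
                                          data.frame(row = 20, col = 20))
        focusScore(sum(5 * img[d$idx]) - nrow(d$idx) * bg$iB, bg$deltaI)
    })
    expect_equal(score1, score5, tolerance = 1e-9)
})

test_that("the factory band accepts midcell and rejects polar localizations", {
    masks <- matrix(0L, 21, 61); masks[6:16, 6:56] <- 1L
    expect_true(inFactoryBand(masks, 1L, c(10, 30)))
    expect_false(inFactoryBand(masks, 1L, c(10, 8)))
    expect_error(inFactoryBand(masks, 9L, c(10, 30)), "unknown")
})

test_that("focus detection recalls bright planted spots without false positives", {
    hits <- 0L; fpCells <- 0L; cells <- 0L
    for (seed in 1:10) {
        sim <- simulateImageStack(imageShape = c(64L, 64L), nCells = 4L,
            psfWidth = 1,
            schedule = data.frame(cell = c(1L, 3L), appear = 0,
                                  disappear = 6, row = c(15, 47),
                                  col = c(15, 15), amplitude = 60),
            nFrames = 6L, seed = 300 + seed)
        q <- quantifyStack(sim$stack, sim$masks, scoreMin = 3)
        for (cl in c(1L, 3L)) {
            k <- which(q$foci$cell == cl)
            tr <- if (cl == 1L) c(15, 15) else c(47, 15)
            if (length(k) && min(sqrt((q$foci$row[k] - tr[1])^2 +
                                      (q$foci$col[k] - tr[2])^2)) < 2)
                hits <- hits + 1L
        }
        cells <- cells + 2L
        fpCells <- fpCells + length(intersect(unique(q$foci$cell),
                                              c(2L, 4L)))
    }
    expect_gte(hits / cells, 0.99)       # recall for true score >> 5
    expect_lte(fpCells / (10 * 2), 0.05) # false-positive cells at sigma > 3
})

test_that("snapshot census counts planted cells with binomial error", {
    blank <- simulateImageStack(imageShape = c(48L, 128L), nCells = 10L,
                                nFrames = 1L, seed = 20)
    centroid <- function(cl) {
        ij <- arrayInd(which(blank$masks == cl), dim(blank$masks)) - 1L
        round(colMeans(ij))
    }
    pos <- t(vapply(c(1L, 4L, 6L, 9L), centroid, numeric(2)))
    sched <- data.frame(cell = c(1L, 4L, 6L, 9L), appear = 0,
                        disappear = 1, row = pos[, 1], col = pos[, 2],
                        amplitude = 80)
    sim <- simulateImageStack(imageShape = c(48L, 128L), nCells = 10L,
                              psfWidth = 1, schedule = sched, nFrames = 1L,
                              seed = 21)
    cen <- censusFoci(sim$stack[, , 1], sim$masks, scoreMin = 3,
                      bandFrac = NA)
    expect_equal(cen$nCells, 10L)
    expect_equal(cen$fraction, 0.4, tolerance = 0.25)
    expect_equal(cen$error, sqrt(cen$fraction * (1 - cen$fraction) / 10))
    expect_error(censusFoci(matrix(1, 8, 8), matrix(0L, 8, 8)), "no cells")
})
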