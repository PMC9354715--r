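mapsFrom <- function(eu, ph) {
    new("PigmentMaps", eumelanin = eu, pheomelanin = ph,
        sourceDelays = c(0, 0.5), dcNormalized = FALSE,
        invalidMask = matrix(FALSE, nrow(eu), ncol(eu)))
}

test_that("the eumelanin fraction behaves at its limits", {
    one <- matrix(1, 2, 2); zero <- matrix(0, 2, 2)
    expect_equal(eumelaninFraction(mapsFrom(one, zero), 1e-12),
                 one, tolerance = 1e-9)
    expect_equal(eumelaninFraction(mapsFrom(zero, one)), zero)
    expect_equal(eumelaninFraction(mapsFrom(one, one), 1e-9),
                 0.5 * one, tolerance = 1e-6)
    f <- eumelaninFraction(mapsFrom(matrix(runif(16), 4),
                                    matrix(runif(16), 4)))
    expect_true(all(f >= 0 & f < 1))
})

test_that("segmentation of trivial fraction maps", {
    cfg <- DelineationConfig(minObjectAreaUm2 = 1e-6)
    empty <- segmentTumor(matrix(0, 32, 32), cfg, pixelSizeUm = 1)
    expect_false(any(tumorMask(empty)))
    expect_equal(nrow(empty@boundary), 0L)
    # vertical step edge: boundary within 1 px of the midline
    f <- cbind(matrix(1, 32, 16), matrix(0, 32, 16))
    res <- segmentTumor(f, cfg, pixelSizeUm = 1)
    expect_true(all(abs(range(res@boundary[res@boundary[, 2] > 1 &
                                           res@boundary[, 2] < 32, 2]) -
                        16) <= 1))
})

test_that("raising the threshold never grows the mask", {
    set.seed(13)
    f <- smoothedNoise <- matrix(runif(64 * 64), 64)
    masks <- lapply(c(0.3, 0.5, 0.7), function(thr)
        tumorMask(segmentTumor(f, DelineationConfig(
            fractionThreshold = thr, minObjectAreaUm2 = 1e-9,
            fillHoles = FALSE), pixelSizeUm = 1)))
    expect_true(all(masks[[2]] <= masks[[1]]))
    expect_true(all(masks[[3]] <= masks[[2]]))
})

test_that("small objects are removed and holes filled", {
    f <- matrix(0, 40, 40)
    f[5:30, 5:30] <- 1          # big square
    f[15:20, 15:20] <- 0        # hole
    f[35:36, 35:36] <- 1        # speck (4 px)
    cfg <- DelineationConfig(smoothSigmaUm = 1e-6, minObjectAreaUm2 = 10,
                             fillHoles = TRUE)
    m <- tumorMask(segmentTumor(f, cfg, pixelSizeUm = 1))
    expect_false(any(m[35:36, 35:36]))
    expect_true(all(m[15:20, 15:20]))
})

test_that("mask evaluation computes Dice and boundary distances", {
    a <- matrix(FALSE, 20, 20); a[5:14, 5:14] <- TRUE
    expect_equal(evaluateMask(a, a, 2)$dice, 1)
    expect_equal(evaluateMask(a, a, 2)$hausdorffDistanceUm, 0)
    b <- matrix(FALSE, 20, 20); b[16:19, 16:19] <- TRUE
    expect_equal(evaluateMask(a, b, 1)$dice, 0)
    # half-overlapping equal-area rectangles
    h1 <- matrix(FALSE, 20, 20); h1[1:10, 1:10] <- TRUE
    h2 <- matrix(FALSE, 20, 20); h2[6:15, 1:10] <- TRUE
    expect_equal(evaluateMask(h1, h2, 1)$dice, 0.5)
    # symmetry
    expect_equal(evaluateMask(h1, h2, 1.5), evaluateMask(h2, h1, 1.5))
    # empty-vs-empty is vacuous agreement; empty-vs-nonempty is 0
    e <- matrix(FALSE, 20, 20)
    expect_equal(evaluateMask(e, e, 1)$dice, 1)
    expect_equal(evaluateMask(e, a, 1)$dice, 0)
    expect_error(evaluateMask(a, matrix(FALSE, 5, 5), 1), "dimensions")
})

test_that("boundary distances scale with the pixel size", {
    a <- matrix(FALSE, 20, 20); a[5:10, 5:10] <- TRUE
    b <- matrix(FALSE, 20, 20); b[7:12, 5:10] <- TRUE
    d1 <- evaluateMask(a, b, 1)
    d2 <- evaluateMask(a, b, 0.414)
    expect_equal(d2$hausdorffDistanceUm, 0.414 * d1$hausdorffDistanceUm)
})

test_that("noisy interface phantoms delineate close to truth", {
    ph <- generatePhantom(PhantomSpec(metadata = smallMeta(128L), seed = 7L))
    st <- renderStack(ph, noise = NoiseSpec(0.05, 0.02, 7L))
    maps <- unmixStack(st)
    res <- delineate(maps, DelineationConfig(), pixelSizeUm(st),
                     truth = truthTumorMask(ph))
    expect_gt(diceScore(res), 0.9)
    expect_lt(res@meanBoundaryDistanceUm, 2)
})

test_that("single cells above the noise floor survive segmentation", {
    md <- smallMeta(128L)
    ph <- generatePhantom(PhantomSpec("scattered_cells", md,
                                      cellDensity = 6, seed = 9L))
    st <- renderStack(ph, noise = NoiseSpec(0.02, 0.01, 9L))
    maps <- unmixStack(st)
    f <- eumelaninFraction(maps)
    # unclamped mask: no minimum-area removal
    mask <- tumorMask(segmentTumor(f, DelineationConfig(
        minObjectAreaUm2 = 1e-9), pixelSizeUm(md)))
    truth <- truthTumorMask(ph)
    lab <- EBImage::bwlabel(EBImage::Image(truth * 1))
    labm <- matrix(EBImage::imageData(lab), nrow(truth))
    for (k in seq_len(max(labm)))
        expect_true(any(mask[labm == k]), info = paste("cell", k))
})
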