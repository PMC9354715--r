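# Helper: stack with given delays and constant per-frame values.
constStack <- function(delayVals, frameVals, n = 4L) {
    md <- AcquisitionMetadata(widthPx = n, heightPx = n, fovUm = 10,
                              delays = delayVals)
    ac <- array(rep(frameVals, each = n * n), c(n, n, length(delayVals)))
    new("DelayStack", ac = ac, dc = matrix(1, n, n), metadata = md)
}

test_that("delay-frame selection honors targets and tolerance", {
    st <- renderStack(generatePhantom(PhantomSpec(metadata = smallMeta(8L))),
                      noise = noNoise())
    fr <- selectDelayFrames(st)
    expect_equal(fr$actualDelays, c(0, 0.5))
    st2 <- constStack(c(-0.4, 0.01, 0.48, 2), c(0, 1, -0.2, 0))
    fr2 <- selectDelayFrames(st2)
    expect_equal(fr2$actualDelays, c(0.01, 0.48))
    st3 <- constStack(c(0, 2, 5), c(1, 0.5, 0.1))
    expect_error(selectDelayFrames(st3), "0.5")
})

test_that("two-delay unmixing applies the signed formulas with clamping", {
    toM <- function(x) matrix(x, 1, 1)
    m <- unmixTwoDelay(toM(0.8), toM(0))
    expect_equal(as.numeric(eumelaninMap(m)), 0)
    expect_equal(as.numeric(pheomelaninMap(m)), 0.8)
    m <- unmixTwoDelay(toM(0.5), toM(-0.3))
    expect_equal(as.numeric(eumelaninMap(m)), 0.3)
    expect_equal(as.numeric(pheomelaninMap(m)), 0.2)
    m <- unmixTwoDelay(toM(-0.1), toM(0.05))
    expect_equal(as.numeric(eumelaninMap(m)), 0)
    expect_equal(as.numeric(pheomelaninMap(m)), 0)
    expect_error(unmixTwoDelay(matrix(0, 2, 2), matrix(0, 3, 3)),
                 "dimensions")
})

test_that("unmixed maps are always nonnegative under noise", {
    ph <- generatePhantom(PhantomSpec(metadata = smallMeta(16L)))
    st <- renderStack(ph, noise = NoiseSpec(0.2, 0.05, 3L))
    maps <- unmixStack(st)
    expect_true(all(eumelaninMap(maps) >= 0))
    expect_true(all(pheomelaninMap(maps) >= 0))
})

test_that("DC normalization divides with a floored denominator", {
    r <- dcNormalize(matrix(2), matrix(0.5))
    expect_equal(as.numeric(r$image), 4)
    expect_false(any(r$invalid))
    r2 <- dcNormalize(matrix(1), matrix(0.005), dcFloor = 0.05)
    expect_equal(as.numeric(r2$image), 1 / 0.05)
    expect_true(all(r2$invalid))
    # joint rescaling of AC and DC leaves the ratio unchanged above floor
    set.seed(8)
    ac <- matrix(rnorm(16), 4); dc <- matrix(runif(16, 0.3, 1), 4)
    a <- dcNormalize(ac, dc)$image
    b <- dcNormalize(0.7 * ac, 0.7 * dc)$image
    expect_equal(a, b, tolerance = 1e-12)
    expect_error(dcNormalize(ac, dc, dcFloor = 0), "positive")
})

test_that("pure-pigment stacks unmix onto the right channel", {
    md <- smallMeta(16L)
    pheo <- generatePhantom(PhantomSpec("uniform", md,
                                        uniformLabel = "paracancer"))
    mPh <- unmixStack(renderStack(pheo, noise = noNoise()))
    expect_lt(max(eumelaninMap(mPh)), 0.05 * max(pheomelaninMap(mPh)))
    pure <- manualPhantom(matrix(1, 16, 16), matrix(0, 16, 16), md)
    mEu <- unmixStack(renderStack(pure, noise = noNoise()))
    expect_true(all(eumelaninMap(mEu) > 0))
    zero <- generatePhantom(PhantomSpec("uniform", md,
                                        uniformLabel = "background"))
    mZ <- unmixStack(renderStack(zero, noise = noNoise()))
    expect_true(all(eumelaninMap(mZ) == 0))
    expect_true(all(pheomelaninMap(mZ) == 0))
})

test_that("unmixing commutes with positive scaling of the stack", {
    ph <- generatePhantom(PhantomSpec(metadata = smallMeta(8L)))
    st <- renderStack(ph, noise = NoiseSpec(0.05, 0, 2L))
    m1 <- unmixStack(st, normalize = FALSE)
    st@ac <- st@ac * 2.5
    m2 <- unmixStack(st, normalize = FALSE)
    expect_equal(eumelaninMap(m2), 2.5 * eumelaninMap(m1), tolerance = 1e-12)
    expect_equal(pheomelaninMap(m2), 2.5 * pheomelaninMap(m1),
                 tolerance = 1e-12)
})

test_that("eumelanin crosstalk into the pheomelanin channel is the model residual", {
    md <- smallMeta(8L)
    pure <- manualPhantom(matrix(runif(64, 0.5, 1.5), 8), matrix(0, 8, 8),
                          md)
    st <- renderStack(pure, noise = noNoise())
    maps <- unmixStack(st, normalize = FALSE)
    tr <- convolvedTrace(defaultEumelanin(), defaultIRF(), c(0, 0.5))
    predictedFraction <- max(tr[1] + tr[2], 0) / tr[1]
    i0 <- which(delays(st) == 0)
    s0 <- acArray(st)[, , i0]
    expect_equal(pheomelaninMap(maps) / s0,
                 matrix(predictedFraction, 8, 8), tolerance = 1e-6)
})

test_that("monotone recovery: unmixed eumelanin tracks the true concentration", {
    ph <- generatePhantom(PhantomSpec(metadata = smallMeta(64L)))
    maps <- unmixStack(renderStack(ph, noise = noNoise()))
    tm <- truthTumorMask(ph)
    expect_gt(cor(eumelaninMap(maps)[tm], concEu(ph)[tm],
                  method = "spearman"), 0.95)
})
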