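test_that("default acquisition matches the standard instrument geometry", {
    md <- defaultAcquisition()
    expect_identical(md@widthPx, 512L)
    expect_identical(md@heightPx, 512L)
    expect_equal(md@fovUm, 212)
    expect_true(all(c(0, 0.5) %in% delays(md)))
    expect_false(is.unsorted(delays(md), strictly = TRUE))
    expect_equal(pixelSizeUm(md), 212 / 512)
})

test_that("uniform layouts produce single-class fields", {
    para <- generatePhantom(PhantomSpec("uniform", smallMeta(),
                                        uniformLabel = "paracancer"))
    expect_true(all(concEu(para) == 0))
    expect_true(all(concPh(para) > 0))
    expect_true(all(labelMap(para) == 1L))
    mel <- generatePhantom(PhantomSpec("uniform", smallMeta(),
                                       uniformLabel = "melanoma"))
    expect_true(all(labelMap(mel) == 2L))
    expect_true(all(concEu(mel) > concPh(mel)))
    bare <- generatePhantom(PhantomSpec("uniform", smallMeta(),
                                        uniformLabel = "background"))
    expect_true(all(labelMap(bare) == 0L))
    expect_true(all(concEu(bare) == 0 & concPh(bare) == 0))
})

test_that("choroid-belt cores are melanin-free and ringed by pheomelanin", {
    ph <- generatePhantom(PhantomSpec("choroid_belt", smallMeta(128L),
                                      seed = 3L))
    core <- labelMap(ph) == 0L
    expect_gt(sum(core), 0)
    expect_true(all(concEu(ph)[core] == 0))
    expect_true(all(concPh(ph)[core] == 0))
    # every pixel just outside a core belongs to the pheomelanin belt
    ring <- which(core, arr.ind = TRUE)
    neighbors <- rbind(cbind(ring[, 1] + 1L, ring[, 2]),
                       cbind(ring[, 1] - 1L, ring[, 2]),
                       cbind(ring[, 1], ring[, 2] + 1L),
                       cbind(ring[, 1], ring[, 2] - 1L))
    inside <- neighbors[, 1] >= 1 & neighbors[, 1] <= nrow(core) &
        neighbors[, 2] >= 1 & neighbors[, 2] <= ncol(core)
    neighbors <- neighbors[inside, , drop = FALSE]
    outer <- neighbors[!core[neighbors], , drop = FALSE]
    expect_gt(nrow(outer), 0)
    expect_true(all(concPh(ph)[outer] > 0))
})

test_that("phantoms are seed-reproducible with stable layout", {
    s1 <- generatePhantom(PhantomSpec(seed = 5L, metadata = smallMeta()))
    s1b <- generatePhantom(PhantomSpec(seed = 5L, metadata = smallMeta()))
    expect_identical(concEu(s1), concEu(s1b))
    expect_identical(labelMap(s1), labelMap(s1b))
    s2 <- generatePhantom(PhantomSpec(seed = 6L, metadata = smallMeta()))
    # the wavy interface is deterministic; the texture is not
    expect_identical(labelMap(s1), labelMap(s2))
    expect_false(identical(concEu(s1), concEu(s2)))
})

test_that("tumor truth equals eumelanin dominance in every layout", {
    for (layout in c("two_region_interface", "choroid_belt",
                     "scattered_cells", "uniform")) {
        ph <- generatePhantom(PhantomSpec(layout, smallMeta(64L), seed = 2L))
        expect_identical(truthTumorMask(ph), concEu(ph) > concPh(ph),
                         info = layout)
    }
})

test_that("unknown layouts are rejected", {
    expect_error(PhantomSpec("spiral"), "unknown layout")
})

test_that("rendered stacks carry the expected pigment signatures", {
    md <- smallMeta(16L)
    mel <- generatePhantom(PhantomSpec("uniform", md,
                                       uniformLabel = "melanoma"))
    st <- renderStack(mel, noise = noNoise())
    i0 <- which(delays(st) == 0); i5 <- which(delays(st) == 0.5)
    expect_true(all(acArray(st)[, , i0] > 0))
    expect_true(all(acArray(st)[, , i5] < 0))
    para <- generatePhantom(PhantomSpec("uniform", md,
                                        uniformLabel = "paracancer"))
    stp <- renderStack(para, noise = noNoise())
    # pheomelanin has essentially decayed by 0.5 ps: the bare decay retains
    # < 5% of its zero-delay value; after IRF convolution the rendered
    # ratio equals the model prediction (~12%: the convolution halves the
    # zero-delay peak) and the residual is positive, so none of it leaks
    # into the eumelanin channel
    ph <- defaultPheomelanin()
    expect_lt(abs(decayTrace(ph, 0.5)), 0.05 * decayTrace(ph, 0))
    predicted <- convolvedTrace(ph, defaultIRF(), c(0, 0.5))
    ratio <- acArray(stp)[, , i5] / acArray(stp)[, , i0]
    expect_equal(ratio, matrix(predicted[2] / predicted[1], 16, 16),
                 tolerance = 1e-10)
    expect_true(all(acArray(stp)[, , i5] > 0))
})

test_that("pigment-free phantoms render zero AC and unit DC", {
    bare <- generatePhantom(PhantomSpec("uniform", smallMeta(16L),
                                        uniformLabel = "background"))
    st <- renderStack(bare, noise = NoiseSpec(0.05, 0.02, 1L))
    expect_true(all(acArray(st) == 0))
    expect_true(all(dcImage(st) == 1))
})

test_that("noiseless rendering is linear in concentration at kAbs = 0", {
    md <- smallMeta(8L)
    set.seed(11)
    c1 <- matrix(runif(64), 8); c2 <- matrix(runif(64), 8)
    p1 <- manualPhantom(c1, c2 / 2, md)
    p2 <- manualPhantom(c2, c1 / 3, md)
    p12 <- manualPhantom(c1 + c2, c2 / 2 + c1 / 3, md)
    r <- function(p) acArray(renderStack(p, noise = noNoise(), kAbs = 0))
    expect_equal(r(p12), r(p1) + r(p2), tolerance = 1e-12)
})

test_that("DC transmission decreases with concentration and stays in (0,1]", {
    md <- smallMeta(8L)
    conc <- matrix(seq(0, 4, length.out = 64), 8)
    p <- manualPhantom(conc, 0 * conc, md)
    st <- renderStack(p, noise = noNoise())
    dc <- dcImage(st)
    expect_true(all(dc > 0 & dc <= 1))
    expect_true(all(diff(dc[order(conc)]) <= 0))
    # noisy DC still respects the range invariant
    stn <- renderStack(p, noise = NoiseSpec(0.02, 0.3, 2L))
    expect_true(all(dcImage(stn) > 0 & dcImage(stn) <= 1))
})

test_that("noise seed changes only the noise, deterministically", {
    ph <- generatePhantom(PhantomSpec(metadata = smallMeta(16L)))
    base <- acArray(renderStack(ph, noise = noNoise()))
    r1 <- acArray(renderStack(ph, noise = NoiseSpec(0.05, 0, 1L)))
    r1b <- acArray(renderStack(ph, noise = NoiseSpec(0.05, 0, 1L)))
    r2 <- acArray(renderStack(ph, noise = NoiseSpec(0.05, 0, 2L)))
    expect_identical(r1, r1b)
    expect_false(identical(r1, r2))
    n1 <- as.vector(r1 - base); n2 <- as.vector(r2 - base)
    expect_equal(sd(n1), 0.05 * max(abs(base)), tolerance = 0.05)
    expect_lt(abs(cor(n1, n2)), 0.1)
})

test_that("rendering does not disturb the caller's RNG stream", {
    set.seed(99); before <- .Random.seed
    ph <- generatePhantom(PhantomSpec(metadata = smallMeta(8L), seed = 1L))
    invisible(renderStack(ph, noise = NoiseSpec(0.05, 0.02, 7L)))
    expect_identical(.Random.seed, before)
})

test_that("dimension mismatches between phantom and metadata are caught", {
    ph <- generatePhantom(PhantomSpec(metadata = smallMeta(8L)))
    expect_error(renderStack(ph, metadata = smallMeta(16L)), "match")
})
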