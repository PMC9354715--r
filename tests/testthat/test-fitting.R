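test_that("noiseless single exponentials are recovered to high precision", {
    irf <- defaultIRF()
    d <- seq(-0.5, 2, by = 0.02)
    y <- convolvedTrace(PigmentModel("x", TAComponent(1, 0.15)), irf, d)
    fit <- fitDecay(d, y, irf, FitConfig(1L))
    expect_true(fit@converged)
    expect_equal(lifetimes(fit), 0.15, tolerance = 1e-4)
    expect_equal(amplitudes(fit), 1, tolerance = 1e-4)
})

test_that("two-component fits recover the slow bleach on the coarse grid", {
    irf <- defaultIRF()
    d <- defaultDelayGrid()
    y <- convolvedTrace(defaultEumelanin(), irf, d)
    fit <- fitDecay(d, y, irf, FitConfig(2L))
    expect_true(fit@converged)
    expect_equal(max(lifetimes(fit)), 9.4, tolerance = 0.05)
    a <- amplitudes(fit)
    expect_lt(a[which.max(lifetimes(fit))], 0)
})

test_that("noiseless two-pigment mixtures recover both lifetimes", {
    irf <- defaultIRF()
    d <- defaultDelayGrid()
    for (w in c(0.2, 0.5, 0.8)) {
        y <- w * convolvedTrace(defaultEumelanin(), irf, d) +
            (1 - w) * convolvedTrace(defaultPheomelanin(), irf, d)
        fit <- fitDecay(d, y, irf, FitConfig(2L))
        expect_equal(min(lifetimes(fit)), 0.15, tolerance = 0.05)
        expect_equal(max(lifetimes(fit)), 9.4, tolerance = 0.05)
    }
})

test_that("fits are scale-invariant in amplitude", {
    irf <- defaultIRF()
    d <- defaultDelayGrid()
    y <- convolvedTrace(defaultEumelanin(), irf, d)
    f1 <- fitDecay(d, y, irf, FitConfig(2L))
    f2 <- fitDecay(d, 37 * y, irf, FitConfig(2L))
    expect_equal(lifetimes(f2), lifetimes(f1), tolerance = 1e-6)
    expect_equal(amplitudes(f2), 37 * amplitudes(f1), tolerance = 1e-6)
})

test_that("noisy slow-lifetime recovery stays within 10% in the median", {
    irf <- defaultIRF()
    d <- defaultDelayGrid()
    clean <- convolvedTrace(defaultEumelanin(), irf, d)
    errs <- vapply(0:11, function(s) {
        set.seed(s)
        y <- clean + rnorm(length(d), sd = 0.02 * max(abs(clean)))
        abs(max(lifetimes(fitDecay(d, y, irf, FitConfig(2L)))) - 9.4) / 9.4
    }, numeric(1))
    expect_lt(median(errs), 0.10)
})

test_that("degenerate all-zero traces yield no spurious amplitudes", {
    fit <- fitDecay(defaultDelayGrid(), rep(0, 13), defaultIRF(),
                    FitConfig(2L))
    if (fit@converged) expect_true(all(abs(amplitudes(fit)) < 1e-10))
})

test_that("fits need enough points for the free parameters", {
    expect_error(fitDecay(c(0, 1, 2), c(1, 0.5, 0.2), defaultIRF(),
                          FitConfig(2L)), "at least")
})

test_that("classification follows the lifetime/sign rule", {
    irf <- defaultIRF()
    d <- defaultDelayGrid()
    floors <- list(ampFloor = 0.01, peakFloor = 0.02)
    yEu <- convolvedTrace(defaultEumelanin(), irf, d)
    fEu <- fitDecay(d, yEu, irf, FitConfig(2L))
    expect_equal(classifyPigment(fEu, max(abs(yEu)), floors)@label,
                 "eumelanin")
    expect_gt(classifyPigment(fEu, max(abs(yEu)), floors)@slowNegativeFraction,
              0.2)
    yPh <- convolvedTrace(defaultPheomelanin(), irf, d)
    fPh <- fitDecay(d, yPh, irf, FitConfig(2L))
    expect_equal(classifyPigment(fPh, max(abs(yPh)), floors)@label,
                 "pheomelanin")
    expect_equal(classifyPigment(fEu, 0, floors)@label, "unpigmented")
    bad <- new("TADecayFit", amplitudes = c(1, -1), lifetimes = c(0.1, 5),
               t0 = 0, irfSigma = 80, residualRms = 1, reducedChiSq = 1,
               converged = FALSE, nPointsUsed = 13L)
    expect_equal(classifyPigment(bad, 1, floors)@label, "ambiguous")
})

test_that("noise floors derive from pre-time-zero samples", {
    d <- defaultDelayGrid()
    set.seed(4)
    ac <- array(rnorm(16 * 16 * length(d), sd = 0.03), c(16, 16, length(d)))
    fl <- estimateNoiseFloors(d, ac)
    expect_equal(fl$noiseSigma, 0.03, tolerance = 0.15)
    expect_equal(fl$ampFloor, 3 * fl$noiseSigma)
    expect_equal(fl$peakFloor, 5 * fl$noiseSigma)
})

test_that("fitImage labels homogeneous and two-region stacks correctly", {
    md <- smallMeta(32L)
    para <- generatePhantom(PhantomSpec("uniform", md,
                                        uniformLabel = "paracancer"))
    st <- renderStack(para, noise = noNoise())
    fm <- fitImage(st, config = FitConfig(2L), binning = 8L)
    expect_true(all(fm@labels == "pheomelanin"))
    expect_identical(dim(fm@labels), c(4L, 4L))

    two <- generatePhantom(PhantomSpec("two_region_interface", md))
    st2 <- renderStack(two, noise = noNoise())
    fm2 <- fitImage(st2, config = FitConfig(2L), binning = 8L)
    truth <- truthTumorMask(two)
    for (bi in 1:4) for (bj in 1:4) {
        block <- truth[(bi - 1) * 8 + 1:8, (bj - 1) * 8 + 1:8]
        if (all(block))
            expect_equal(fm2@labels[bi, bj], "eumelanin")
        else if (!any(block))
            expect_equal(fm2@labels[bi, bj], "pheomelanin")
    }
    # repeated runs are identical (no hidden randomness)
    fm2b <- fitImage(st2, config = FitConfig(2L), binning = 8L)
    expect_identical(fm2@labels, fm2b@labels)
    expect_identical(fm2@table, fm2b@table)
})

test_that("full-image binning reduces to a single mean-trace fit", {
    md <- smallMeta(8L)
    mel <- generatePhantom(PhantomSpec("uniform", md,
                                       uniformLabel = "melanoma"))
    st <- renderStack(mel, noise = noNoise())
    fm <- fitImage(st, config = FitConfig(2L), binning = 8L)
    expect_identical(dim(fm@labels), c(1L, 1L))
    meanTrace <- apply(acArray(st), 3, mean)
    direct <- fitDecay(delays(st), meanTrace, defaultIRF(), FitConfig(2L))
    expect_equal(fm@table$tau_slow_ps, max(lifetimes(direct)),
                 tolerance = 1e-8)
})

test_that("non-dividing binning warns and truncates", {
    md <- smallMeta(9L)
    mel <- generatePhantom(PhantomSpec("uniform", md,
                                       uniformLabel = "melanoma"))
    st <- renderStack(mel, noise = noNoise())
    expect_warning(fm <- fitImage(st, config = FitConfig(2L), binning = 4L),
                   "truncated")
    expect_identical(dim(fm@labels), c(2L, 2L))
})

test_that("fit tables export as CSV", {
    md <- smallMeta(8L)
    mel <- generatePhantom(PhantomSpec("uniform", md,
                                       uniformLabel = "melanoma"))
    st <- renderStack(mel, noise = noNoise())
    fm <- fitImage(st, config = FitConfig(2L), binning = 4L)
    path <- withr::local_tempfile(fileext = ".csv")
    writeFitTable(fm, path)
    tab <- read.csv(path)
    expect_identical(names(tab),
                     c("row", "col", "label", "A_fast", "tau_fast_ps",
                       "A_slow", "tau_slow_ps", "t0_ps", "residual_rms",
                       "converged"))
    expect_equal(nrow(tab), 4)
    expect_true(all(tab$label == "eumelanin"))
})
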