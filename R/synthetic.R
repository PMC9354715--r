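# Synthetic tissue phantoms and delay-stack rendering. Phantoms emulate the
# spatial motifs seen in pigmented ocular tissue: a wavy melanoma/paracancer
# interface, choroidal belt structures around melanin-free cores, scattered
# single melanoma cells, and uniform fields for calibration.

# Pheomelanin co-fraction inside melanoma tissue (tumor regions are
# eumelanin-dominant mixtures, not pure eumelanin).
.MELANOMA_PH_FRACTION <- 0.25
.BELT_PH_BOOST <- 2.5
.CELL_DIAMETER_UM <- 10

#' Construct acquisition metadata
#'
#' @param widthPx,heightPx image size in pixels
#' @param fovUm field-of-view edge length in um
#' @param delays strictly increasing interpulse delays in ps
#' @param pumpWavelength,probeWavelength wavelengths in nm
#' @param pumpPowerMw,probePowerMw beam powers in mW (informational)
#' @param pixelDwellUs pixel dwell time in us (informational)
#' @param modulationFrequencyMhz modulation frequency in MHz (informational)
#' @return an [AcquisitionMetadata-class]
#' @export
AcquisitionMetadata <- function(widthPx = 512L, heightPx = 512L, fovUm = 212,
                                delays = defaultDelayGrid(),
                                pumpWavelength = 1040, probeWavelength = 860,
                                pumpPowerMw = 10, probePowerMw = 5,
                                pixelDwellUs = 2,
                                modulationFrequencyMhz = 20) {
    new("AcquisitionMetadata", widthPx = as.integer(widthPx),
        heightPx = as.integer(heightPx), fovUm = as.numeric(fovUm),
        delays = as.numeric(delays),
        pumpWavelength = as.numeric(pumpWavelength),
        probeWavelength = as.numeric(probeWavelength),
        pumpPowerMw = as.numeric(pumpPowerMw),
        probePowerMw = as.numeric(probePowerMw),
        pixelDwellUs = as.numeric(pixelDwellUs),
        modulationFrequencyMhz = as.numeric(modulationFrequencyMhz))
}

#' Default delay-scan grid
#'
#' Thirteen delays from -0.5 to 40 ps, denser around time zero where the
#' fast ESA component evolves, sparser at long delays where only the slow
#' bleach recovery remains. Contains 0 and 0.5 ps exactly — the two frames
#' the two-delay unmixing consumes.
#'
#' @return numeric vector of delays in ps
#' @export
defaultDelayGrid <- function() {
    c(-0.5, -0.25, 0, 0.1, 0.2, 0.3, 0.5, 1, 2, 5, 10, 20, 40)
}

#' Default acquisition geometry
#'
#' The standard acquisition for this instrument class: 512 x 512 pixels over
#' a 212 um field of view, 1040 nm pump at 10 mW, 860 nm probe at 5 mW,
#' 2 us pixel dwell, 20 MHz modulation, and the default delay grid.
#'
#' @return an [AcquisitionMetadata-class]
#' @export
defaultAcquisition <- function() AcquisitionMetadata()

#' Construct a phantom specification
#'
#' @param layout layout identifier: `"two_region_interface"`,
#'   `"choroid_belt"`, `"scattered_cells"` or `"uniform"`
#' @param metadata an [AcquisitionMetadata-class]
#' @param boundaryWaviness sinusoidal boundary amplitude as a fraction of the
#'   field of view
#' @param cellDensity cells per 100x100 um tile (scattered_cells)
#' @param beltWidthUm pheomelanin belt width in um (choroid_belt)
#' @param concentrationSmoothnessUm texture correlation length in um
#' @param uniformLabel tissue label for the uniform layout
#' @param seed integer seed
#' @return a [PhantomSpec-class]
#' @export
PhantomSpec <- function(layout = "two_region_interface",
                        metadata = defaultAcquisition(),
                        boundaryWaviness = 0.06, cellDensity = 8,
                        beltWidthUm = 12, concentrationSmoothnessUm = 8,
                        uniformLabel = "melanoma", seed = 0L) {
    new("PhantomSpec", layout = layout, metadata = metadata,
        boundaryWaviness = as.numeric(boundaryWaviness),
        cellDensity = as.numeric(cellDensity),
        beltWidthUm = as.numeric(beltWidthUm),
        concentrationSmoothnessUm = as.numeric(concentrationSmoothnessUm),
        uniformLabel = uniformLabel, seed = as.integer(seed))
}

#' Construct a noise specification
#'
#' @param additiveSigma AC-channel Gaussian noise s.d. as a fraction of the
#'   stack's peak absolute AC signal
#' @param dcRelativeSigma relative (multiplicative) DC noise s.d.
#' @param seed integer seed for the noise draw
#' @return a [NoiseSpec-class]
#' @export
NoiseSpec <- function(additiveSigma = 0.05, dcRelativeSigma = 0.02,
                      seed = 0L) {
    new("NoiseSpec", additiveSigma = as.numeric(additiveSigma),
        dcRelativeSigma = as.numeric(dcRelativeSigma), seed = as.integer(seed))
}

# Pixel-center coordinate grids in um; x runs along columns, y along rows.
.pixelGrid <- function(md) {
    ps <- pixelSizeUm(md)
    list(x = (seq_len(md@widthPx) - 0.5) * ps,
         y = (seq_len(md@heightPx) - 0.5) * ps, ps = ps)
}

#' Generate a ground-truthed tissue phantom
#'
#' Builds per-pixel eumelanin/pheomelanin concentration maps from the
#' requested spatial layout, multiplied by a positive log-normal texture
#' with the requested correlation length, then derives the label map from
#' per-pixel pigment dominance: melanoma where eumelanin exceeds
#' pheomelanin, background where both are (numerically) zero, paracancer
#' elsewhere. The geometry stream and the texture stream use seeds derived
#' independently from `spec@seed`, so the output is fully reproducible.
#'
#' Layouts: `two_region_interface` puts eumelanin-dominant melanoma on the
#' left of a wavy sinusoidal boundary and pure-pheomelanin paracancer on the
#' right; `choroid_belt` places melanin-free elliptical cores, each ringed by
#' a pheomelanin-rich belt, in a paracancer field; `scattered_cells` sprinkles
#' ~10 um eumelanin-rich cells with Gaussian-feathered edges over a
#' pheomelanin background; `uniform` fills the field with one tissue class.
#'
#' @param spec a [PhantomSpec-class]
#' @return a [TissuePhantom-class]
#' @examples
#' ph <- generatePhantom(PhantomSpec(metadata = AcquisitionMetadata(64, 64)))
#' table(labelMap(ph))
#' @export
generatePhantom <- function(spec) {
    stopifnot(is(spec, "PhantomSpec"))
    validObject(spec)
    md <- spec@metadata
    g <- .pixelGrid(md)
    nr <- md@heightPx; nc <- md@widthPx
    corrPx <- spec@concentrationSmoothnessUm / g$ps

    texEu <- withSeed(deriveSeed(spec@seed, 2L),
                      textureField(nr, nc, corrPx))
    texPh <- withSeed(deriveSeed(spec@seed, 3L),
                      textureField(nr, nc, corrPx))

    # row i ~ y, column j ~ x
    X <- matrix(g$x, nr, nc, byrow = TRUE)
    Y <- matrix(g$y, nr, nc)

    concEu <- matrix(0, nr, nc)
    concPh <- matrix(0, nr, nc)

    if (spec@layout == "two_region_interface") {
        xb <- md@fovUm / 2 + spec@boundaryWaviness * md@fovUm *
            sin(2 * pi * Y / (md@fovUm / 2))
        tumor <- X < xb
        concEu[tumor] <- texEu[tumor]
        concPh[tumor] <- .MELANOMA_PH_FRACTION * texEu[tumor]
        concPh[!tumor] <- texPh[!tumor]
    } else if (spec@layout == "choroid_belt") {
        concPh[] <- texPh
        nCores <- max(1L, round((md@fovUm / 100)^2))
        geom <- withSeed(deriveSeed(spec@seed, 1L), {
            k <- ceiling(sqrt(nCores))
            step <- md@fovUm / k
            idx <- seq_len(nCores) - 1L
            data.frame(
                cx = (idx %% k + 0.5) * step +
                    stats::runif(nCores, -0.1, 0.1) * step,
                cy = (idx %/% k + 0.5) * step +
                    stats::runif(nCores, -0.1, 0.1) * step,
                a = stats::runif(nCores, 0.15, 0.3) * step,
                b = stats::runif(nCores, 0.15, 0.3) * step)
        })
        for (i in seq_len(nrow(geom))) {
            r <- sqrt(((X - geom$cx[i]) / geom$a[i])^2 +
                      ((Y - geom$cy[i]) / geom$b[i])^2)
            core <- r <= 1
            belt <- !core &
                r <= 1 + spec@beltWidthUm / sqrt(geom$a[i] * geom$b[i])
            concPh[core] <- 0
            concEu[core] <- 0
            concPh[belt] <- .BELT_PH_BOOST * texPh[belt]
        }
    } else if (spec@layout == "scattered_cells") {
        concPh[] <- texPh
        nCells <- max(1L, round(spec@cellDensity * (md@fovUm / 100)^2))
        radius <- .CELL_DIAMETER_UM / 2
        geom <- withSeed(deriveSeed(spec@seed, 1L), data.frame(
            cx = stats::runif(nCells, radius, md@fovUm - radius),
            cy = stats::runif(nCells, radius, md@fovUm - radius)))
        feather <- numeric(nr * nc)
        dim(feather) <- c(nr, nc)
        for (i in seq_len(nrow(geom))) {
            r <- sqrt((X - geom$cx[i])^2 + (Y - geom$cy[i])^2)
            # Gaussian-feathered hard disk, ~1 px edge
            feather <- pmax(feather, stats::pnorm((radius - r) / g$ps))
        }
        concEu <- feather * texEu
        concPh <- concPh * (1 - 0.8 * feather)
        # ensure dominance flips exactly where cells sit
        inCell <- feather > 0.5
        concPh[inCell] <- pmin(concPh[inCell],
                               .MELANOMA_PH_FRACTION * concEu[inCell])
        concEu[!inCell & concEu >= concPh] <- 0
    } else {  # uniform
        if (spec@uniformLabel == "melanoma") {
            concEu[] <- texEu
            concPh[] <- .MELANOMA_PH_FRACTION * texEu
        } else if (spec@uniformLabel == "paracancer") {
            concPh[] <- texPh
        }  # background: both stay 0
    }

    labels <- matrix(.LABEL_PARACANCER, nr, nc)
    labels[concEu > concPh] <- .LABEL_MELANOMA
    labels[concEu + concPh < 1e-12] <- .LABEL_BACKGROUND
    new("TissuePhantom", labels = labels, concEu = concEu, concPh = concPh,
        metadata = md)
}

#' Render a pump-probe delay stack from a phantom
#'
#' Forms the noiseless signal as
#' `AC(x, y, tau) = DC(x, y) * (concEu * M_eu(tau) + concPh * M_ph(tau))`
#' where `M_p` is the IRF-convolved trace of pigment model p, and the DC
#' transmission follows a Beer-Lambert law
#' `DC = exp(-kAbs * (concEu + concPh))` with a single lumped extinction
#' coefficient, so heavily pigmented regions transmit less. Additive
#' Gaussian noise (scaled to the stack's peak absolute AC value) is then
#' added to the AC channel and multiplicative log-normal noise to the DC
#' channel; both draws are governed by `noise@seed` only, so the noiseless
#' component is unchanged by the noise seed.
#'
#' @param phantom a [TissuePhantom-class]
#' @param models named list with [PigmentModel-class] elements `eumelanin`
#'   and `pheomelanin`
#' @param irf an [InstrumentResponse-class]
#' @param noise a [NoiseSpec-class]
#' @param metadata an [AcquisitionMetadata-class]; must match the phantom
#'   pixel grid
#' @param kAbs lumped extinction coefficient per unit concentration for the
#'   DC channel
#' @param t0 time-zero offset in ps passed to the trace model
#' @param shotNoiseFraction optional signal-dependent noise: extra s.d.
#'   `shotNoiseFraction * sqrt(|AC| * peak)` per voxel (0 disables; off by
#'   default)
#' @return a [DelayStack-class]
#' @export
renderStack <- function(phantom, models = defaultModels(),
                        irf = defaultIRF(), noise = NoiseSpec(),
                        metadata = acqMetadata(phantom), kAbs = 0.5, t0 = 0,
                        shotNoiseFraction = 0) {
    stopifnot(is(phantom, "TissuePhantom"), is(noise, "NoiseSpec"))
    nr <- metadata@heightPx; nc <- metadata@widthPx
    if (!identical(dim(phantom@labels), c(nr, nc)))
        stop("phantom pixel grid does not match metadata dimensions")
    tEu <- convolvedTrace(models$eumelanin, irf, metadata@delays, t0 = t0)
    tPh <- convolvedTrace(models$pheomelanin, irf, metadata@delays, t0 = t0)
    dc <- exp(-kAbs * (phantom@concEu + phantom@concPh))
    nd <- length(metadata@delays)
    # outer products over the flattened pixel grid; (px, delay) then reshape
    mixed <- as.vector(phantom@concEu) %o% tEu +
        as.vector(phantom@concPh) %o% tPh
    ac <- array(as.vector(dc) * mixed, dim = c(nr, nc, nd))
    peak <- max(abs(ac))
    if (peak > 0 &&
        (noise@additiveSigma > 0 || noise@dcRelativeSigma > 0 ||
         shotNoiseFraction > 0)) {
        withSeed(noise@seed, {
            if (noise@additiveSigma > 0)
                ac <- ac + stats::rnorm(length(ac),
                                        sd = noise@additiveSigma * peak)
            if (shotNoiseFraction > 0)
                ac <- ac + stats::rnorm(length(ac)) * shotNoiseFraction *
                    sqrt(abs(ac) * peak)
            if (noise@dcRelativeSigma > 0)
                dc <- pmin(dc * exp(stats::rnorm(length(dc),
                                                 sd = noise@dcRelativeSigma)),
                           1)
        })
    }
    new("DelayStack", ac = ac, dc = dc, metadata = metadata)
}
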