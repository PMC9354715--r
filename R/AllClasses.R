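#' @import methods
NULL

# Label codes used in phantom label maps. Stored as an integer matrix so label
# maps can round-trip through 8-bit TIFF without a factor <-> raster dance.
.LABEL_BACKGROUND <- 0L
.LABEL_PARACANCER <- 1L
.LABEL_MELANOMA   <- 2L
.LABEL_NAMES <- c(`0` = "background", `1` = "paracancer", `2` = "melanoma")

#' Pump and probe pulse pair
#'
#' Wavelengths (nm) and temporal FWHM durations (fs) of the pump and probe
#' pulses. The default values describe a 1040 nm pump (~150 fs) with an
#' 860 nm probe (~120 fs), a near-infrared pair for which the probe photon
#' carries more energy than the pump photon, so stimulated emission cannot
#' contribute to the transient-absorption signal.
#'
#' @slot pumpWavelength pump wavelength in nm
#' @slot probeWavelength probe wavelength in nm
#' @slot pumpDuration pump pulse FWHM in fs
#' @slot probeDuration probe pulse FWHM in fs
#' @exportClass PulsePair
setClass("PulsePair", representation(
    pumpWavelength = "numeric", probeWavelength = "numeric",
    pumpDuration = "numeric", probeDuration = "numeric"),
    validity = function(object) {
        v <- c(object@pumpWavelength, object@probeWavelength,
               object@pumpDuration, object@probeDuration)
        if (length(v) != 4L || any(!is.finite(v)) || any(v <= 0))
            return("all pulse-pair fields must be single, finite, positive numbers")
        TRUE
    })

#' Signed exponential transient-absorption component
#'
#' One exponential component of a pigment's transient response. The sign of
#' the amplitude is physical: positive amplitudes are excited-state absorption
#' (ESA), negative amplitudes ground-state bleaching (GSB). The sign is never
#' flipped internally.
#'
#' @slot amplitude signed amplitude in differential-absorption units
#' @slot lifetime decay lifetime in ps (> 0)
#' @exportClass TAComponent
setClass("TAComponent",
    representation(amplitude = "numeric", lifetime = "numeric"),
    validity = function(object) {
        if (length(object@amplitude) != 1L || !is.finite(object@amplitude))
            return("amplitude must be a single finite number")
        if (length(object@lifetime) != 1L || !is.finite(object@lifetime) ||
            object@lifetime <= 0)
            return("lifetime must be a single positive number (ps)")
        TRUE
    })

#' Gaussian instrument response function
#'
#' The temporal cross-correlation of pump and probe pulses, modeled as a
#' Gaussian of standard deviation `sigma` (fs). It smears the ideal
#' exponential decays; [convolvedTrace()] applies it analytically.
#'
#' @slot sigma Gaussian standard deviation of the cross-correlation, in fs
#' @exportClass InstrumentResponse
setClass("InstrumentResponse", representation(sigma = "numeric"),
    validity = function(object) {
        if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
            object@sigma <= 0)
            return("sigma must be a single positive number (fs)")
        TRUE
    })

#' Pigment transient-absorption model
#'
#' A named, ordered collection of [TAComponent-class] objects whose signed
#' sum composes the pigment's transient response.
#'
#' @slot name model identifier (\code{"eumelanin"}, \code{"pheomelanin"}, or
#'   a custom label)
#' @slot components list of [TAComponent-class]
#' @exportClass PigmentModel
setClass("PigmentModel",
    representation(name = "character", components = "list"),
    validity = function(object) {
        if (length(object@name) != 1L || !nzchar(object@name))
            return("name must be a single non-empty string")
        if (length(object@components) < 1L)
            return("a PigmentModel needs at least one component")
        ok <- vapply(object@components, is, logical(1), class2 = "TAComponent")
        if (!all(ok)) return("components must all be TAComponent objects")
        TRUE
    })

#' Acquisition metadata for a delay stack
#'
#' Geometry, delay grid and beam parameters of one pump-probe acquisition.
#' Width/height/FOV define the pixel size; the delay grid defines the third
#' axis of the stack. Powers, dwell time and modulation frequency are carried
#' as informational metadata (they have no computational role here).
#'
#' @slot widthPx,heightPx image size in pixels
#' @slot fovUm field-of-view edge length in micrometres
#' @slot delays strictly increasing interpulse delays in ps
#' @slot pumpWavelength,probeWavelength wavelengths in nm
#' @slot pumpPowerMw,probePowerMw beam powers at sample in mW (informational)
#' @slot pixelDwellUs pixel dwell time in microseconds (informational)
#' @slot modulationFrequencyMhz pump modulation frequency in MHz (informational)
#' @exportClass AcquisitionMetadata
setClass("AcquisitionMetadata", representation(
    widthPx = "integer", heightPx = "integer", fovUm = "numeric",
    delays = "numeric", pumpWavelength = "numeric", probeWavelength = "numeric",
    pumpPowerMw = "numeric", probePowerMw = "numeric",
    pixelDwellUs = "numeric", modulationFrequencyMhz = "numeric"),
    validity = function(object) {
        if (object@widthPx < 1L || object@heightPx < 1L)
            return("widthPx and heightPx must be >= 1")
        if (!is.finite(object@fovUm) || object@fovUm <= 0)
            return("fovUm must be positive")
        d <- object@delays
        if (length(d) < 1L || any(!is.finite(d)))
            return("delays must be non-empty and finite")
        if (is.unsorted(d, strictly = TRUE))
            return("delays must be strictly increasing")
        TRUE
    })

#' Specification of a synthetic tissue phantom
#'
#' Layout identifier plus geometric parameters controlling the phantom
#' generator. A fixed `seed` makes the phantom fully reproducible.
#'
#' @slot layout one of \code{"two_region_interface"}, \code{"choroid_belt"},
#'   \code{"scattered_cells"}, \code{"uniform"}
#' @slot metadata an [AcquisitionMetadata-class]
#' @slot boundaryWaviness dimensionless sinusoidal boundary amplitude as a
#'   fraction of the field of view (two_region_interface)
#' @slot cellDensity cells per 100x100 um tile (scattered_cells)
#' @slot beltWidthUm pheomelanin belt width in um (choroid_belt)
#' @slot concentrationSmoothnessUm correlation length of the concentration
#'   texture in um
#' @slot uniformLabel label filling the field for the uniform layout
#' @slot seed integer seed
#' @exportClass PhantomSpec
setClass("PhantomSpec", representation(
    layout = "character", metadata = "AcquisitionMetadata",
    boundaryWaviness = "numeric", cellDensity = "numeric",
    beltWidthUm = "numeric", concentrationSmoothnessUm = "numeric",
    uniformLabel = "character", seed = "integer"),
    validity = function(object) {
        layouts <- c("two_region_interface", "choroid_belt",
                     "scattered_cells", "uniform")
        if (!(object@layout %in% layouts))
            return(sprintf("unknown layout '%s' (expected one of: %s)",
                           object@layout, paste(layouts, collapse = ", ")))
        geom <- c(object@boundaryWaviness, object@cellDensity,
                  object@beltWidthUm, object@concentrationSmoothnessUm)
        if (any(!is.finite(geom)) || any(geom <= 0))
            return("all geometric parameters must be positive")
        if (!(object@uniformLabel %in% .LABEL_NAMES))
            return("uniformLabel must be background, paracancer or melanoma")
        TRUE
    })

#' Acquisition noise specification
#'
#' Additive Gaussian noise on the AC (lock-in) channel, expressed as a
#' fraction of the stack's peak absolute signal, plus multiplicative relative
#' noise on the DC transmission channel.
#'
#' @slot additiveSigma AC noise s.d. as a fraction of peak |AC|
#' @slot dcRelativeSigma relative DC noise s.d.
#' @slot seed integer seed for the noise draw
#' @exportClass NoiseSpec
setClass("NoiseSpec", representation(
    additiveSigma = "numeric", dcRelativeSigma = "numeric", seed = "integer"),
    validity = function(object) {
        if (object@additiveSigma < 0 || object@dcRelativeSigma < 0)
            return("noise sigmas must be >= 0")
        TRUE
    })

#' Ground-truthed tissue phantom
#'
#' Per-pixel label map and nonnegative pigment concentration maps. Labels are
#' integers (0 background, 1 paracancer, 2 melanoma); the ground-truth tumor
#' mask is the set of melanoma pixels, which by construction coincides with
#' the pixels where eumelanin concentration exceeds pheomelanin concentration.
#'
#' @slot labels integer label matrix
#' @slot concEu,concPh nonnegative concentration matrices (arbitrary units)
#' @slot metadata the [AcquisitionMetadata-class] the phantom was built for
#' @exportClass TissuePhantom
setClass("TissuePhantom", representation(
    labels = "matrix", concEu = "matrix", concPh = "matrix",
    metadata = "AcquisitionMetadata"),
    validity = function(object) {
        d <- dim(object@labels)
        if (!identical(d, dim(object@concEu)) ||
            !identical(d, dim(object@concPh)))
            return("labels, concEu and concPh must share dimensions")
        if (any(object@concEu < 0) || any(object@concPh < 0))
            return("concentration maps must be nonnegative")
        if (!all(object@labels %in% c(.LABEL_BACKGROUND, .LABEL_PARACANCER,
                                      .LABEL_MELANOMA)))
            return("labels must be 0 (background), 1 (paracancer) or 2 (melanoma)")
        TRUE
    })

#' Pump-probe delay stack
#'
#' The three-dimensional transient-absorption dataset S(x, y, tau): an AC
#' signal array indexed (row, column, delay) in differential-absorption units
#' plus the DC transmitted-intensity image used to correct heterogeneous
#' melanin absorption.
#'
#' @slot ac 3-D numeric array (row, col, delay)
#' @slot dc 2-D transmission matrix, values in (0, 1]
#' @slot metadata an [AcquisitionMetadata-class]
#' @exportClass DelayStack
setClass("DelayStack", representation(
    ac = "array", dc = "matrix", metadata = "AcquisitionMetadata"),
    validity = function(object) {
        da <- dim(object@ac)
        if (length(da) != 3L) return("ac must be a 3-D array (row, col, delay)")
        if (da[3L] != length(object@metadata@delays))
            return("ac delay axis length must equal metadata delay count")
        if (!identical(da[1:2], dim(object@dc)))
            return("dc dimensions must match the ac spatial dimensions")
        if (any(object@dc <= 0) || any(object@dc > 1))
            return("dc must lie in (0, 1] everywhere")
        TRUE
    })

#' Decay-fit configuration
#'
#' Controls the multistart nonlinear least-squares fit of IRF-convolved
#' multiexponential models.
#'
#' @slot nComponents 1 or 2 exponential components
#' @slot lifetimeBounds (min, max) lifetime bounds in ps
#' @slot amplitudeBounds signed (min, max) amplitude bounds
#' @slot fitT0 fit the time-zero offset?
#' @slot fitIrfSigma fit the IRF width? (off by default: near-degenerate with
#'   the fast lifetime)
#' @slot multistartGrid list of initial lifetime vectors, tried in order
#' @slot maxIterations Levenberg-Marquardt iteration cap
#' @slot convergenceTolerance relative convergence tolerance
#' @exportClass FitConfig
setClass("FitConfig", representation(
    nComponents = "integer", lifetimeBounds = "numeric",
    amplitudeBounds = "numeric", fitT0 = "logical", fitIrfSigma = "logical",
    multistartGrid = "list", maxIterations = "integer",
    convergenceTolerance = "numeric"),
    validity = function(object) {
        if (!(object@nComponents %in% c(1L, 2L)))
            return("nComponents must be 1 or 2")
        if (length(object@lifetimeBounds) != 2L ||
            object@lifetimeBounds[1] <= 0 ||
            diff(object@lifetimeBounds) <= 0)
            return("lifetimeBounds must be an increasing positive pair (ps)")
        if (length(object@amplitudeBounds) != 2L ||
            diff(object@amplitudeBounds) <= 0)
            return("amplitudeBounds must be an increasing pair")
        if (length(object@multistartGrid) < 1L)
            return("multistartGrid must be non-empty")
        if (!all(vapply(object@multistartGrid, length, 1L) ==
                 object@nComponents))
            return("each multistart entry needs one lifetime per component")
        TRUE
    })

#' Fitted transient-absorption decay
#'
#' Result of fitting an IRF-convolved multiexponential to one trace.
#' Components are reported sorted by ascending lifetime.
#'
#' @slot amplitudes signed amplitudes, one per component
#' @slot lifetimes lifetimes in ps, ascending
#' @slot t0 time-zero offset in ps
#' @slot irfSigma IRF Gaussian s.d. in fs (fitted or fixed)
#' @slot residualRms root-mean-square residual
#' @slot reducedChiSq residual sum of squares / degrees of freedom
#' @slot converged did any multistart converge?
#' @slot nPointsUsed number of delay points fitted
#' @exportClass TADecayFit
setClass("TADecayFit", representation(
    amplitudes = "numeric", lifetimes = "numeric", t0 = "numeric",
    irfSigma = "numeric", residualRms = "numeric", reducedChiSq = "numeric",
    converged = "logical", nPointsUsed = "integer"),
    validity = function(object) {
        if (length(object@amplitudes) != length(object@lifetimes))
            return("amplitudes and lifetimes must have equal length")
        if (is.unsorted(object@lifetimes))
            return("components must be sorted by ascending lifetime")
        TRUE
    })

#' Pigment classification of one fitted trace
#'
#' @slot label \code{"eumelanin"}, \code{"pheomelanin"}, \code{"unpigmented"}
#'   or \code{"ambiguous"}
#' @slot slowNegativeFraction |A_slow| / sum |A_i| when a slow negative
#'   component exists, else 0
#' @slot peakSignal max |trace|
#' @exportClass PigmentCall
setClass("PigmentCall", representation(
    label = "character", slowNegativeFraction = "numeric",
    peakSignal = "numeric"),
    validity = function(object) {
        if (!(object@label %in% c("eumelanin", "pheomelanin", "unpigmented",
                                  "ambiguous")))
            return("label must be eumelanin/pheomelanin/unpigmented/ambiguous")
        TRUE
    })

#' Per-pixel fit map
#'
#' Output of [fitImage()]: one row per binned pixel with fit summaries and a
#' pigment label matrix at the binned resolution.
#'
#' @slot table data.frame with columns row, col, label, A_fast, tau_fast_ps,
#'   A_slow, tau_slow_ps, t0_ps, residual_rms, converged
#' @slot labels character matrix of pigment labels (binned resolution)
#' @slot binning block edge length in original pixels
#' @exportClass PigmentFitMap
setClass("PigmentFitMap", representation(
    table = "data.frame", labels = "matrix", binning = "integer"))

#' Unmixed pigment maps
#'
#' Nonnegative eumelanin and pheomelanin images produced by the two-delay
#' separation, with the delays actually used and the DC-normalization flag.
#'
#' @slot eumelanin,pheomelanin nonnegative matrices
#' @slot sourceDelays the two delays used, in ps
#' @slot dcNormalized were frames DC-normalized before unmixing?
#' @slot invalidMask logical matrix flagging pixels whose DC fell below the
#'   normalization floor (all FALSE when not normalized)
#' @exportClass PigmentMaps
setClass("PigmentMaps", representation(
    eumelanin = "matrix", pheomelanin = "matrix", sourceDelays = "numeric",
    dcNormalized = "logical", invalidMask = "matrix"),
    validity = function(object) {
        if (!identical(dim(object@eumelanin), dim(object@pheomelanin)))
            return("pigment maps must share dimensions")
        if (any(object@eumelanin < 0) || any(object@pheomelanin < 0))
            return("pigment maps must be nonnegative")
        if (length(object@sourceDelays) != 2L)
            return("sourceDelays must hold the two delays used")
        TRUE
    })

#' Tumor-margin delineation configuration
#'
#' @slot fractionEpsilon stabilizer added to the denominator of the
#'   eumelanin fraction
#' @slot smoothSigmaUm Gaussian smoothing scale in um
#' @slot fractionThreshold mask threshold on the smoothed fraction, in (0,1)
#' @slot minObjectAreaUm2 smallest retained connected component, in um^2
#' @slot fillHoles fill holes in the mask?
#' @exportClass DelineationConfig
setClass("DelineationConfig", representation(
    fractionEpsilon = "numeric", smoothSigmaUm = "numeric",
    fractionThreshold = "numeric", minObjectAreaUm2 = "numeric",
    fillHoles = "logical"),
    validity = function(object) {
        v <- c(object@fractionEpsilon, object@smoothSigmaUm,
               object@fractionThreshold, object@minObjectAreaUm2)
        if (any(!is.finite(v)) || any(v <= 0))
            return("all delineation parameters must be positive")
        if (object@fractionThreshold >= 1)
            return("fractionThreshold must lie in (0, 1)")
        TRUE
    })

#' Tumor margin and its evaluation
#'
#' Binary tumor mask, its 8-connected boundary pixels, and (when ground truth
#' was supplied) Dice overlap and boundary-distance scores.
#'
#' @slot tumorMask logical matrix
#' @slot boundary n x 2 integer matrix of (row, col) boundary coordinates
#' @slot dice Dice coefficient vs truth, NA when no truth supplied
#' @slot meanBoundaryDistanceUm,hausdorffDistanceUm boundary distances in um,
#'   NA when no truth supplied
#' @slot nObjects number of connected components retained in the mask
#' @exportClass MarginResult
setClass("MarginResult", representation(
    tumorMask = "matrix", boundary = "matrix", dice = "numeric",
    meanBoundaryDistanceUm = "numeric", hausdorffDistanceUm = "numeric",
    nObjects = "integer"),
    validity = function(object) {
        if (!is.logical(object@tumorMask))
            return("tumorMask must be a logical matrix")
        if (ncol(object@boundary) != 2L && nrow(object@boundary) > 0L)
            return("boundary must be an n x 2 coordinate matrix")
        if (!is.na(object@dice) && (object@dice < 0 || object@dice > 1))
            return("dice must lie in [0, 1]")
        TRUE
    })
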