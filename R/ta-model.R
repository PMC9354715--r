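# Transient-absorption physics: signed exponential components, analytic
# Gaussian IRF convolution, photon-energy bookkeeping, default pigment models.

.HC_EV_NM <- 1239.841984  # CODATA hc, eV * nm
.FS_PER_PS <- 1000

#' Construct a pump/probe pulse pair
#'
#' @param pumpWavelength,probeWavelength wavelengths in nm
#' @param pumpDuration,probeDuration pulse FWHM in fs
#' @return a [PulsePair-class]
#' @examples
#' PulsePair()  # 1040 nm pump / 860 nm probe defaults
#' @export
PulsePair <- function(pumpWavelength = 1040, probeWavelength = 860,
                      pumpDuration = 150, probeDuration = 120) {
    new("PulsePair", pumpWavelength = as.numeric(pumpWavelength),
        probeWavelength = as.numeric(probeWavelength),
        pumpDuration = as.numeric(pumpDuration),
        probeDuration = as.numeric(probeDuration))
}

#' Construct a transient-absorption component
#'
#' @param amplitude signed amplitude (positive = ESA, negative = GSB)
#' @param lifetime lifetime in ps
#' @return a [TAComponent-class]
#' @export
TAComponent <- function(amplitude, lifetime) {
    new("TAComponent", amplitude = as.numeric(amplitude),
        lifetime = as.numeric(lifetime))
}

#' Construct a Gaussian instrument response
#'
#' @param sigma Gaussian standard deviation in fs
#' @return an [InstrumentResponse-class]
#' @seealso [irfFromPulses()] for deriving the width from pulse durations
#' @export
InstrumentResponse <- function(sigma) {
    new("InstrumentResponse", sigma = as.numeric(sigma))
}

#' Construct a pigment model
#'
#' @param name model identifier
#' @param components list of [TAComponent-class], or a single component
#' @return a [PigmentModel-class]
#' @examples
#' PigmentModel("custom", list(TAComponent(1, 0.2), TAComponent(-0.5, 5)))
#' @export
PigmentModel <- function(name, components) {
    if (is(components, "TAComponent")) components <- list(components)
    new("PigmentModel", name = as.character(name), components = components)
}

#' Photon energy of a wavelength
#'
#' Converts wavelength to photon energy, E = hc / lambda, using the CODATA
#' value hc = 1239.841984 eV nm.
#'
#' @param wavelength wavelength(s) in nm, strictly positive
#' @return photon energy in eV
#' @examples
#' photonEnergy(1040)  # pump, ~1.192 eV
#' photonEnergy(860)   # probe, ~1.442 eV
#' @export
photonEnergy <- function(wavelength) {
    if (any(!is.finite(wavelength)) || any(wavelength <= 0))
        stop("wavelength must be positive and finite (nm)")
    .HC_EV_NM / wavelength
}

#' Is stimulated emission absent for a pulse pair?
#'
#' Stimulated emission requires the probe photon to have at most the pump
#' photon's energy; when the probe photon energy exceeds the pump's, the SE
#' pathway is closed and only ESA (positive) and GSB (negative) signals can
#' appear.
#'
#' @param pulses a [PulsePair-class]
#' @return TRUE iff photonEnergy(probe) > photonEnergy(pump)
#' @export
stimulatedEmissionAbsent <- function(pulses) {
    stopifnot(is(pulses, "PulsePair"))
    validObject(pulses)
    photonEnergy(pulses@probeWavelength) > photonEnergy(pulses@pumpWavelength)
}

#' Derive the IRF width from a pulse pair
#'
#' The instrument response of a two-pulse experiment is the pump-probe
#' cross-correlation; for Gaussian pulses its FWHM is the quadrature sum of
#' the two pulse FWHMs. With the default 150 fs pump and 120 fs probe this
#' gives FWHM = sqrt(150^2 + 120^2) ~ 192 fs, sigma ~ 81.6 fs.
#'
#' @param pulses a [PulsePair-class]
#' @return an [InstrumentResponse-class]
#' @export
irfFromPulses <- function(pulses = PulsePair()) {
    stopifnot(is(pulses, "PulsePair"))
    fwhm <- sqrt(pulses@pumpDuration^2 + pulses@probeDuration^2)
    InstrumentResponse(fwhm / (2 * sqrt(2 * log(2))))
}

#' Default instrument response
#'
#' @return the [InstrumentResponse-class] for the default pulse pair
#'   (~81.6 fs sigma, 192 fs FWHM cross-correlation)
#' @export
defaultIRF <- function() irfFromPulses(PulsePair())

#' Ideal multiexponential decay trace
#'
#' Evaluates the pigment model without instrument-response broadening:
#' trace(tau) = sum_i A_i exp(-tau / tau_i) for tau >= 0 and exactly 0 for
#' tau < 0.
#'
#' @param model a [PigmentModel-class]
#' @param delaysPs delay values in ps (finite)
#' @return numeric trace, same length as `delaysPs`
#' @export
decayTrace <- function(model, delaysPs) {
    stopifnot(is(model, "PigmentModel"))
    if (length(delaysPs) == 0L) stop("delay sequence must be non-empty")
    if (any(!is.finite(delaysPs))) stop("delays must be finite")
    a <- amplitudes(model); l <- lifetimes(model)
    out <- numeric(length(delaysPs))
    pos <- delaysPs >= 0
    for (i in seq_along(a))
        out[pos] <- out[pos] + a[i] * exp(-delaysPs[pos] / l[i])
    out
}

# One IRF-convolved exponential component, evaluated stably.
# For a causal exponential decay exp(-u/lambda) convolved with a unit-area
# Gaussian of s.d. sigma:
#   (A/2) exp(sigma^2/(2 lambda^2) - u/lambda) erfc((sigma/lambda - u/sigma)/sqrt(2))
# with u = tau - t0. For b = (sigma/lambda - u/sigma)/sqrt(2) > 0 the exp
# factor can overflow while erfc underflows; using erfcx(b) = exp(b^2) erfc(b)
# the product collapses to (A/2) erfcx(b) exp(-u^2 / (2 sigma^2)), which is
# always finite. For b <= 0 the direct form is already safe (exponent < 0).
.convolvedComponent <- function(amplitude, lifetimePs, sigmaPs, u) {
    b <- (sigmaPs / lifetimePs - u / sigmaPs) / sqrt(2)
    out <- numeric(length(u))
    posb <- b > 0
    if (any(posb))
        out[posb] <- (amplitude / 2) * pracma::erfcx(b[posb]) *
            exp(-u[posb]^2 / (2 * sigmaPs^2))
    if (any(!posb)) {
        a <- sigmaPs^2 / (2 * lifetimePs^2) - u[!posb] / lifetimePs
        out[!posb] <- (amplitude / 2) * exp(a) * pracma::erfc(b[!posb])
    }
    out
}

#' IRF-convolved multiexponential trace
#'
#' Analytic convolution of each model component with a unit-area Gaussian
#' instrument response (the exponentially modified Gaussian), summed over
#' components. Continuous and finite at all delays; evaluated in a
#' log-stabilized form so short lifetimes never overflow.
#'
#' @param model a [PigmentModel-class]
#' @param irf an [InstrumentResponse-class] (sigma in fs)
#' @param delaysPs delay values in ps
#' @param t0 time-zero offset in ps (delay of the cross-correlation maximum)
#' @return numeric trace, same length as `delaysPs`
#' @examples
#' eu <- defaultEumelanin()
#' convolvedTrace(eu, defaultIRF(), c(-0.5, 0, 0.5, 5, 40))
#' @export
convolvedTrace <- function(model, irf, delaysPs, t0 = 0) {
    stopifnot(is(model, "PigmentModel"), is(irf, "InstrumentResponse"))
    validObject(irf)
    if (length(delaysPs) == 0L) stop("delay sequence must be non-empty")
    sigmaPs <- irf@sigma / .FS_PER_PS
    u <- delaysPs - t0
    a <- amplitudes(model); l <- lifetimes(model)
    out <- numeric(length(delaysPs))
    for (i in seq_along(a))
        out <- out + .convolvedComponent(a[i], l[i], sigmaPs, u)
    out
}

#' Default eumelanin transient-absorption model
#'
#' Two signed components: a fast ESA component (A = +1.0, tau = 0.15 ps) and
#' a long-lived GSB component (A = -0.35, tau = 9.4 ps). The model is
#' positive at zero delay (ESA dominates within the IRF) and clearly negative
#' by 0.5 ps, where the fast component has decayed and the bleach remains —
#' the signature that distinguishes eumelanin. Amplitudes are package
#' defaults chosen to reproduce these qualitative signatures; both are
#' overridable through [PigmentModel()].
#'
#' @return a [PigmentModel-class]
#' @export
defaultEumelanin <- function() {
    PigmentModel("eumelanin",
                 list(TAComponent(1.0, 0.15), TAComponent(-0.35, 9.4)))
}

#' Default pheomelanin transient-absorption model
#'
#' A single short-lived ESA component (A = +1.0, tau = 0.15 ps): a positive
#' transient that has decayed to under 5% of its peak by 0.5 ps, with no
#' bleach component.
#'
#' @return a [PigmentModel-class]
#' @export
defaultPheomelanin <- function() {
    PigmentModel("pheomelanin", list(TAComponent(1.0, 0.15)))
}

#' Default pigment model pair
#'
#' @return named list with elements `eumelanin` and `pheomelanin`
#' @export
defaultModels <- function() {
    list(eumelanin = defaultEumelanin(), pheomelanin = defaultPheomelanin())
}

#' Serialize a pigment model to JSON
#'
#' Document shape: `{name, components: [{amplitude, lifetime_ps}]}`.
#'
#' @param model a [PigmentModel-class]
#' @param path optional file path; when NULL the JSON string is returned
#' @return `path` invisibly, or the JSON string
#' @export
pigmentModelToJSON <- function(model, path = NULL) {
    stopifnot(is(model, "PigmentModel"))
    doc <- list(name = model@name,
                components = lapply(pigmentComponents(model), function(k)
                    list(amplitude = k@amplitude, lifetime_ps = k@lifetime)))
    txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (is.null(path)) return(as.character(txt))
    writeLines(txt, path)
    invisible(path)
}

#' Deserialize a pigment model from JSON
#'
#' @param x a file path or a JSON string
#' @return a [PigmentModel-class]
#' @export
pigmentModelFromJSON <- function(x) {
    doc <- jsonlite::fromJSON(x, simplifyVector = FALSE)
    if (is.null(doc$name) || is.null(doc$components))
        stop("pigment model JSON must carry 'name' and 'components'")
    comps <- lapply(doc$components, function(k)
        TAComponent(k$amplitude, k$lifetime_ps))
    PigmentModel(doc$name, comps)
}
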