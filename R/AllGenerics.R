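# Accessor generics. Slot access from user code goes through these.

#' @rdname accessors
#' @param object an object
#' @export
setGeneric("amplitudes", function(object) standardGeneric("amplitudes"))
#' @rdname accessors
#' @export
setGeneric("lifetimes", function(object) standardGeneric("lifetimes"))
#' @rdname accessors
#' @export
setGeneric("pigmentComponents",
           function(object) standardGeneric("pigmentComponents"))
#' @rdname accessors
#' @export
setGeneric("pigmentName", function(object) standardGeneric("pigmentName"))
#' @rdname accessors
#' @export
setGeneric("delays", function(object) standardGeneric("delays"))
#' @rdname accessors
#' @export
setGeneric("acArray", function(object) standardGeneric("acArray"))
#' @rdname accessors
#' @export
setGeneric("dcImage", function(object) standardGeneric("dcImage"))
#' @rdname accessors
#' @export
setGeneric("acqMetadata", function(object) standardGeneric("acqMetadata"))
#' @rdname accessors
#' @export
setGeneric("pixelSizeUm", function(object) standardGeneric("pixelSizeUm"))
#' @rdname accessors
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setGeneric("concEu", function(object) standardGeneric("concEu"))
#' @rdname accessors
#' @export
setGeneric("concPh", function(object) standardGeneric("concPh"))
#' @rdname accessors
#' @export
setGeneric("truthTumorMask",
           function(object) standardGeneric("truthTumorMask"))
#' @rdname accessors
#' @export
setGeneric("eumelaninMap", function(object) standardGeneric("eumelaninMap"))
#' @rdname accessors
#' @export
setGeneric("pheomelaninMap",
           function(object) standardGeneric("pheomelaninMap"))
#' @rdname accessors
#' @export
setGeneric("tumorMask", function(object) standardGeneric("tumorMask"))
#' @rdname accessors
#' @export
setGeneric("diceScore", function(object) standardGeneric("diceScore"))

#' Accessors for melaninTA classes
#'
#' Small read-only accessors for the package's S4 containers.
#'
#' @name accessors
#' @return the corresponding slot value
NULL

#' @rdname accessors
setMethod("amplitudes", "PigmentModel", function(object)
    vapply(object@components, function(k) k@amplitude, numeric(1)))
#' @rdname accessors
setMethod("lifetimes", "PigmentModel", function(object)
    vapply(object@components, function(k) k@lifetime, numeric(1)))
#' @rdname accessors
setMethod("pigmentComponents", "PigmentModel", function(object)
    object@components)
#' @rdname accessors
setMethod("pigmentName", "PigmentModel", function(object) object@name)
#' @rdname accessors
setMethod("amplitudes", "TADecayFit", function(object) object@amplitudes)
#' @rdname accessors
setMethod("lifetimes", "TADecayFit", function(object) object@lifetimes)
#' @rdname accessors
setMethod("delays", "AcquisitionMetadata", function(object) object@delays)
#' @rdname accessors
setMethod("delays", "DelayStack", function(object) object@metadata@delays)
#' @rdname accessors
setMethod("acArray", "DelayStack", function(object) object@ac)
#' @rdname accessors
setMethod("dcImage", "DelayStack", function(object) object@dc)
#' @rdname accessors
setMethod("acqMetadata", "DelayStack", function(object) object@metadata)
#' @rdname accessors
setMethod("acqMetadata", "TissuePhantom", function(object) object@metadata)
#' @rdname accessors
setMethod("pixelSizeUm", "AcquisitionMetadata", function(object)
    object@fovUm / object@widthPx)
#' @rdname accessors
setMethod("pixelSizeUm", "DelayStack", function(object)
    pixelSizeUm(object@metadata))
#' @rdname accessors
setMethod("pixelSizeUm", "TissuePhantom", function(object)
    pixelSizeUm(object@metadata))
#' @rdname accessors
setMethod("labelMap", "TissuePhantom", function(object) object@labels)
#' @rdname accessors
setMethod("concEu", "TissuePhantom", function(object) object@concEu)
#' @rdname accessors
setMethod("concPh", "TissuePhantom", function(object) object@concPh)
#' @rdname accessors
setMethod("truthTumorMask", "TissuePhantom", function(object)
    object@labels == .LABEL_MELANOMA)
#' @rdname accessors
setMethod("eumelaninMap", "PigmentMaps", function(object) object@eumelanin)
#' @rdname accessors
setMethod("pheomelaninMap", "PigmentMaps", function(object)
    object@pheomelanin)
#' @rdname accessors
setMethod("tumorMask", "MarginResult", function(object) object@tumorMask)
#' @rdname accessors
setMethod("diceScore", "MarginResult", function(object) object@dice)

#' Show methods
#' @name show-methods
#' @param object an object
#' @return invisible NULL, called for the side effect of printing
#' @exportMethod show
NULL

#' @rdname show-methods
setMethod("show", "PigmentModel", function(object) {
    cat(sprintf("PigmentModel '%s' with %d component(s)\n", object@name,
                length(object@components)))
    a <- amplitudes(object); l <- lifetimes(object)
    for (i in seq_along(a))
        cat(sprintf("  A = %+.4g (%s), tau = %.4g ps\n", a[i],
                    if (a[i] >= 0) "ESA" else "GSB", l[i]))
})

setMethod("show", "DelayStack", function(object) {
    d <- dim(object@ac)
    cat(sprintf("DelayStack: %d x %d px, %d delays [%.3g .. %.3g ps], FOV %.4g um\n",
                d[1], d[2], d[3], min(delays(object)), max(delays(object)),
                object@metadata@fovUm))
    cat(sprintf("  AC range [%.4g, %.4g], DC range [%.4g, %.4g]\n",
                min(object@ac), max(object@ac), min(object@dc),
                max(object@dc)))
})

setMethod("show", "TissuePhantom", function(object) {
    tab <- table(factor(.LABEL_NAMES[as.character(object@labels)],
                        levels = .LABEL_NAMES))
    cat(sprintf("TissuePhantom: %d x %d px\n", nrow(object@labels),
                ncol(object@labels)))
    cat("  pixels:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                           collapse = ", "), "\n")
})

setMethod("show", "TADecayFit", function(object) {
    cat(sprintf("TADecayFit (%d component(s), %s)\n",
                length(object@amplitudes),
                if (object@converged) "converged" else "NOT converged"))
    for (i in seq_along(object@amplitudes))
        cat(sprintf("  A%d = %+.4g, tau%d = %.4g ps\n", i,
                    object@amplitudes[i], i, object@lifetimes[i]))
    cat(sprintf("  t0 = %.4g ps, IRF sigma = %.4g fs, RMS = %.4g\n",
                object@t0, object@irfSigma, object@residualRms))
})

setMethod("show", "PigmentMaps", function(object) {
    cat(sprintf("PigmentMaps: %d x %d px, delays used: %.3g / %.3g ps, %s\n",
                nrow(object@eumelanin), ncol(object@eumelanin),
                object@sourceDelays[1], object@sourceDelays[2],
                if (object@dcNormalized) "DC-normalized" else "raw"))
})

setMethod("show", "MarginResult", function(object) {
    cat(sprintf("MarginResult: %d tumor px in %d object(s)\n",
                sum(object@tumorMask), object@nObjects))
    if (!is.na(object@dice))
        cat(sprintf("  dice = %.4f, mean boundary dist = %.3g um, Hausdorff = %.3g um\n",
                    object@dice, object@meanBoundaryDistanceUm,
                    object@hausdorffDistanceUm))
})
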