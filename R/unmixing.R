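# Two-delay eumelanin/pheomelanin separation with DC transmission
# normalization. The separation uses exactly two frames of the stack: at
# zero delay both pigments show positive ESA signal, while at 500 fs the
# fast ESA transient has decayed and only eumelanin's ground-state bleach
# survives as a negative signal. Hence
#   S_eu = max(-S(500 fs), 0)
#   S_ph = max(S(0 fs) + S(500 fs), 0)
# with negative values rounded to zero in both channels.

#' Select the two delay frames used for unmixing
#'
#' Finds the frames whose delays lie nearest each target (default 0 and
#' 0.5 ps) and within `tolerance`; the nominal stage positions need not be
#' hit exactly.
#'
#' @param stack a [DelayStack-class]
#' @param targets the two target delays in ps
#' @param tolerance maximum |actual - target| in ps
#' @return list with `S0`, `S500` (matrices) and `actualDelays`
#' @export
selectDelayFrames <- function(stack, targets = c(0, 0.5), tolerance = 0.05) {
    stopifnot(is(stack, "DelayStack"))
    d <- delays(stack)
    pick <- function(target) {
        i <- which.min(abs(d - target))
        if (abs(d[i] - target) > tolerance)
            stop(sprintf(
                "no delay frame within %.3g ps of the %.3g ps target",
                tolerance, target))
        i
    }
    i0 <- pick(targets[1]); i5 <- pick(targets[2])
    taLog("info", "unmixing frames: %.4g ps and %.4g ps", d[i0], d[i5])
    list(S0 = stack@ac[, , i0], S500 = stack@ac[, , i5],
         actualDelays = c(d[i0], d[i5]))
}

#' Two-delay pigment separation
#'
#' Per pixel: `eumelanin = max(-S500, 0)` (the 500 fs image with a sign
#' reversal) and `pheomelanin = max(S0 + S500, 0)`, negative values rounded
#' to zero in both channels. Clamping is applied symmetrically: under noise
#' the sign reversal alone can make the eumelanin channel negative too.
#'
#' @param S0 image at zero delay
#' @param S500 image at 0.5 ps delay, same dimensions
#' @param sourceDelays the actual delays of the two frames, in ps
#' @param dcNormalized bookkeeping flag stored in the result
#' @param invalidMask optional logical matrix of pixels invalidated by the
#'   DC floor
#' @return a [PigmentMaps-class]
#' @examples
#' unmixTwoDelay(matrix(0.5), matrix(-0.3))  # eu = 0.3, ph = 0.2
#' @export
unmixTwoDelay <- function(S0, S500, sourceDelays = c(0, 0.5),
                          dcNormalized = FALSE, invalidMask = NULL) {
    if (!identical(dim(S0), dim(S500)))
        stop("S0 and S500 must share dimensions")
    if (is.null(invalidMask))
        invalidMask <- matrix(FALSE, nrow(S0), ncol(S0))
    new("PigmentMaps", eumelanin = pmax(-S500, 0),
        pheomelanin = pmax(S0 + S500, 0),
        sourceDelays = as.numeric(sourceDelays),
        dcNormalized = isTRUE(dcNormalized), invalidMask = invalidMask)
}

#' Normalize an AC image by the DC transmission
#'
#' Divides pixelwise by `max(dc, dcFloor)` to correct the heterogeneous
#' light absorption by melanin. Pixels whose DC falls below the floor are
#' computed with the floor and flagged in the validity mask.
#'
#' @param acImage AC signal image
#' @param dcImage DC transmission image, same dimensions
#' @param dcFloor small positive fraction guarding the division
#' @return list with `image` and logical `invalid` mask
#' @export
dcNormalize <- function(acImage, dcImage, dcFloor = 0.05) {
    if (!identical(dim(acImage), dim(dcImage)))
        stop("AC and DC images must share dimensions")
    if (!is.finite(dcFloor) || dcFloor <= 0)
        stop("dcFloor must be positive")
    invalid <- dcImage < dcFloor
    nInvalid <- sum(invalid)
    if (nInvalid > 0)
        taLog("info", "dcNormalize: %d pixel(s) below DC floor %.3g",
              nInvalid, dcFloor)
    list(image = acImage / pmax(dcImage, dcFloor), invalid = invalid)
}

#' Unmix a delay stack into pigment maps
#'
#' Selects the 0 and 0.5 ps frames, optionally DC-normalizes each
#' (per-frame, before the delay arithmetic), and applies the two-delay
#' separation.
#'
#' @param stack a [DelayStack-class]
#' @param normalize DC-normalize the frames before unmixing?
#' @param tolerance delay-matching tolerance in ps
#' @param dcFloor DC floor for normalization
#' @return a [PigmentMaps-class]
#' @export
unmixStack <- function(stack, normalize = TRUE, tolerance = 0.05,
                       dcFloor = 0.05) {
    fr <- selectDelayFrames(stack, tolerance = tolerance)
    invalid <- matrix(FALSE, nrow(fr$S0), ncol(fr$S0))
    if (normalize) {
        n0 <- dcNormalize(fr$S0, stack@dc, dcFloor)
        n5 <- dcNormalize(fr$S500, stack@dc, dcFloor)
        fr$S0 <- n0$image; fr$S500 <- n5$image
        invalid <- n0$invalid | n5$invalid
    }
    unmixTwoDelay(fr$S0, fr$S500, sourceDelays = fr$actualDelays,
                  dcNormalized = normalize, invalidMask = invalid)
}
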