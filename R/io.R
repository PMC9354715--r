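# File formats: multi-page 32-bit float TIFF + JSON metadata sidecars for
# stacks, phantoms and pigment maps; 8-bit TIFF for label maps, masks and
# RGB composites.
#
# Reading goes through tiff::readTIFF, which handles IEEE-float sample
# format. Writing float TIFF is done by a minimal built-in writer
# (.writeTiffPages): uncompressed little-endian single-strip pages with
# SampleFormat = IEEE float, byte-stable so seeded pipelines reproduce
# byte-identical files.

.w16 <- function(con, v) writeBin(as.integer(v), con, size = 2,
                                  endian = "little")
.w32 <- function(con, v) writeBin(as.integer(v), con, size = 4,
                                  endian = "little")

# One 12-byte IFD entry. SHORT values sit in the low 2 bytes of the value
# field; LONG values fill it.
.ifdEntry <- function(con, tag, type, count, value) {
    .w16(con, tag); .w16(con, type); .w32(con, count)
    if (type == 3L) { .w16(con, value); .w16(con, 0L) } else .w32(con, value)
}

# Write matrices as a multi-page grayscale TIFF, float32 or uint8.
.writeTiffPages <- function(pages, path, format = c("float32", "uint8")) {
    format <- match.arg(format)
    stopifnot(length(pages) >= 1L)
    bytesPer <- if (format == "float32") 4L else 1L
    sizes <- vapply(pages, function(m) nrow(m) * ncol(m) * bytesPer, 1)
    padded <- sizes + sizes %% 2L          # keep offsets word-aligned
    dataOffsets <- 8L + c(0, cumsum(padded))[seq_along(pages)]
    ifd0 <- 8L + sum(padded)
    ifdSize <- 2L + 10L * 12L + 4L
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw("II"), con); .w16(con, 42L); .w32(con, ifd0)
    for (p in seq_along(pages)) {
        m <- pages[[p]]
        v <- as.vector(t(m))               # row-major scanlines
        if (format == "float32") writeBin(as.numeric(v), con, size = 4,
                                          endian = "little")
        else writeBin(as.raw(pmin(pmax(round(v), 0), 255)), con)
        if (padded[p] > sizes[p]) writeBin(as.raw(0), con)
    }
    for (p in seq_along(pages)) {
        m <- pages[[p]]
        .w16(con, 10L)
        .ifdEntry(con, 256L, 4L, 1L, ncol(m))            # ImageWidth
        .ifdEntry(con, 257L, 4L, 1L, nrow(m))            # ImageLength
        .ifdEntry(con, 258L, 3L, 1L, bytesPer * 8L)      # BitsPerSample
        .ifdEntry(con, 259L, 3L, 1L, 1L)                 # no compression
        .ifdEntry(con, 262L, 3L, 1L, 1L)                 # BlackIsZero
        .ifdEntry(con, 273L, 4L, 1L, dataOffsets[p])     # StripOffsets
        .ifdEntry(con, 277L, 3L, 1L, 1L)                 # SamplesPerPixel
        .ifdEntry(con, 278L, 4L, 1L, nrow(m))            # RowsPerStrip
        .ifdEntry(con, 279L, 4L, 1L, sizes[p])           # StripByteCounts
        .ifdEntry(con, 339L, 3L, 1L,
                  if (format == "float32") 3L else 1L)   # SampleFormat
        .w32(con, if (p < length(pages)) ifd0 + p * ifdSize else 0L)
    }
    invisible(path)
}

.readTiffPages <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages
}

.sidecarPath <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")
.dcPath <- function(path) paste0(sub("\\.tiff?$", "", path), "_dc.tif")

.metadataToList <- function(md) {
    list(width_px = md@widthPx, height_px = md@heightPx, fov_um = md@fovUm,
         delays_ps = md@delays, pump_wavelength_nm = md@pumpWavelength,
         probe_wavelength_nm = md@probeWavelength,
         pump_power_mw = md@pumpPowerMw, probe_power_mw = md@probePowerMw,
         pixel_dwell_us = md@pixelDwellUs,
         modulation_frequency_mhz = md@modulationFrequencyMhz)
}

.metadataFromList <- function(x) {
    AcquisitionMetadata(
        widthPx = x$width_px, heightPx = x$height_px, fovUm = x$fov_um,
        delays = unlist(x$delays_ps),
        pumpWavelength = x$pump_wavelength_nm,
        probeWavelength = x$probe_wavelength_nm,
        pumpPowerMw = x$pump_power_mw, probePowerMw = x$probe_power_mw,
        pixelDwellUs = x$pixel_dwell_us,
        modulationFrequencyMhz = x$modulation_frequency_mhz)
}

.writeSidecar <- function(x, path) {
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), path)
}

#' Write a delay stack to disk
#'
#' The AC array goes to `path` as a multi-page 32-bit float TIFF (one page
#' per delay), the DC image to `<base>_dc.tif`, and the acquisition
#' metadata to a `<base>.json` sidecar. Values are stored at float32
#' precision. Writing is byte-deterministic.
#'
#' @param stack a [DelayStack-class]
#' @param path output TIFF path (`.tif`)
#' @return `path` invisibly
#' @export
writeStack <- function(stack, path) {
    stopifnot(is(stack, "DelayStack"))
    validObject(stack)
    nd <- dim(stack@ac)[3]
    .writeTiffPages(lapply(seq_len(nd), function(k) stack@ac[, , k]), path)
    .writeTiffPages(list(stack@dc), .dcPath(path))
    .writeSidecar(c(.metadataToList(stack@metadata),
                    list(dc_file = basename(.dcPath(path)))),
                  .sidecarPath(path))
    invisible(path)
}

#' Read a delay stack from disk
#'
#' Reads the multi-page float TIFF written by [writeStack()] together with
#' its JSON sidecar and DC companion file, validating that the page count
#' matches the sidecar delay list and that delays are strictly increasing.
#'
#' @param path TIFF path as given to [writeStack()]
#' @return a [DelayStack-class]
#' @export
readStack <- function(path) {
    sidecar <- .sidecarPath(path)
    if (!file.exists(sidecar))
        stop("missing JSON sidecar: ", sidecar)
    meta <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
    d <- unlist(meta$delays_ps)
    if (is.unsorted(d, strictly = TRUE))
        stop("sidecar delays are not strictly increasing")
    pages <- .readTiffPages(path)
    if (length(pages) != length(d))
        stop(sprintf("TIFF has %d page(s) but sidecar lists %d delay(s)",
                     length(pages), length(d)))
    dcFile <- file.path(dirname(path),
                        if (!is.null(meta$dc_file)) meta$dc_file
                        else basename(.dcPath(path)))
    if (!file.exists(dcFile)) stop("missing DC transmission file: ", dcFile)
    dc <- .readTiffPages(dcFile)[[1]]
    ac <- array(unlist(pages), dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                                       length(pages)))
    new("DelayStack", ac = ac, dc = dc, metadata = .metadataFromList(meta))
}

#' Write a tissue phantom to disk
#'
#' Labels go to `<base>_labels.tif` (8-bit: 0 background, 1 paracancer,
#' 2 melanoma), concentrations to `<base>_conc.tif` (two float pages:
#' eumelanin then pheomelanin), metadata to `<base>.json`.
#'
#' @param phantom a [TissuePhantom-class]
#' @param path base TIFF path
#' @return `path` invisibly
#' @export
writePhantom <- function(phantom, path) {
    stopifnot(is(phantom, "TissuePhantom"))
    base <- sub("\\.tiff?$", "", path)
    .writeTiffPages(list(phantom@labels), paste0(base, "_labels.tif"),
                    format = "uint8")
    .writeTiffPages(list(phantom@concEu, phantom@concPh),
                    paste0(base, "_conc.tif"))
    .writeSidecar(.metadataToList(phantom@metadata), paste0(base, ".json"))
    invisible(path)
}

#' Read a tissue phantom from disk
#'
#' @param path base TIFF path as given to [writePhantom()]
#' @return a [TissuePhantom-class]
#' @export
readPhantom <- function(path) {
    base <- sub("\\.tiff?$", "", path)
    meta <- jsonlite::fromJSON(paste0(base, ".json"), simplifyVector = TRUE)
    labels8 <- .readTiffPages(paste0(base, "_labels.tif"))[[1]]
    conc <- .readTiffPages(paste0(base, "_conc.tif"))
    labels <- matrix(as.integer(round(labels8 * 255)), nrow(labels8))
    new("TissuePhantom", labels = labels, concEu = conc[[1]],
        concPh = conc[[2]], metadata = .metadataFromList(meta))
}

#' Write pigment maps to disk
#'
#' Two float pages (eumelanin, then pheomelanin) plus a JSON sidecar with
#' the source delays and the DC-normalization flag.
#'
#' @param maps a [PigmentMaps-class]
#' @param path output TIFF path
#' @return `path` invisibly
#' @export
writePigmentMaps <- function(maps, path) {
    stopifnot(is(maps, "PigmentMaps"))
    .writeTiffPages(list(maps@eumelanin, maps@pheomelanin), path)
    .writeSidecar(list(source_delays_ps = maps@sourceDelays,
                       dc_normalized = maps@dcNormalized,
                       n_invalid_pixels = sum(maps@invalidMask)),
                  .sidecarPath(path))
    invisible(path)
}

#' Read pigment maps from disk
#'
#' @param path TIFF path as given to [writePigmentMaps()]
#' @return a [PigmentMaps-class]
#' @export
readPigmentMaps <- function(path) {
    meta <- jsonlite::fromJSON(.sidecarPath(path), simplifyVector = TRUE)
    pages <- .readTiffPages(path)
    if (length(pages) != 2L)
        stop("pigment-map TIFF must have exactly 2 pages")
    new("PigmentMaps", eumelanin = pages[[1]], pheomelanin = pages[[2]],
        sourceDelays = unlist(meta$source_delays_ps),
        dcNormalized = isTRUE(meta$dc_normalized),
        invalidMask = matrix(FALSE, nrow(pages[[1]]), ncol(pages[[1]])))
}

#' Write a binary mask as 8-bit TIFF
#'
#' @param mask logical matrix
#' @param path output path
#' @return `path` invisibly
#' @export
writeMask <- function(mask, path) {
    .writeTiffPages(list(mask * 255), path, format = "uint8")
    invisible(path)
}

#' RGB composite of pigment maps
#'
#' Display convention: eumelanin in red, pheomelanin in cyan. Each channel
#' is scaled by the joint maximum of the two maps. Returns the H x W x 3
#' array in [0, 1]; optionally writes it as an 8-bit RGB TIFF.
#'
#' @param maps a [PigmentMaps-class]
#' @param path optional output TIFF path
#' @return the RGB array, invisibly when `path` is given
#' @export
compositeRGB <- function(maps, path = NULL) {
    stopifnot(is(maps, "PigmentMaps"))
    top <- max(maps@eumelanin, maps@pheomelanin, 1e-12)
    eu <- maps@eumelanin / top; ph <- maps@pheomelanin / top
    img <- array(0, c(nrow(eu), ncol(eu), 3))
    img[, , 1] <- eu; img[, , 2] <- ph; img[, , 3] <- ph
    img <- pmin(img, 1)
    if (!is.null(path)) {
        tiff::writeTIFF(img, path, bits.per.sample = 8L)
        return(invisible(img))
    }
    img
}
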