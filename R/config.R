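# Pipeline configuration: a versioned nested list serialized as YAML (JSON
# accepted interchangeably), with converters to the typed S4 parameter
# objects.

#' Default pipeline configuration
#'
#' The full-chain configuration consumed by [runPipeline()] and the
#' command-line interface: phantom geometry, noise, fitting, unmixing and
#' delineation parameters plus output directory and log level. Serializes
#' losslessly through YAML or JSON.
#'
#' @return nested configuration list (`config_version` 1)
#' @export
defaultPipelineConfig <- function() {
    list(
        config_version = 1L,
        phantom = list(
            layout = "two_region_interface", width_px = 512L,
            height_px = 512L, fov_um = 212, boundary_waviness = 0.06,
            cell_density = 8, belt_width_um = 12,
            concentration_smoothness_um = 8, uniform_label = "melanoma",
            seed = 0L),
        noise = list(additive_sigma = 0.05, dc_relative_sigma = 0.02,
                     seed = 0L),
        fit = list(n_components = 2L, lifetime_min_ps = 0.02,
                   lifetime_max_ps = 100, fit_t0 = FALSE,
                   fit_irf_sigma = FALSE, binning = 16L),
        unmix = list(normalize = TRUE, tolerance_ps = 0.05, dc_floor = 0.05),
        delineate = list(fraction_epsilon = 1e-6, smooth_sigma_um = 2,
                         fraction_threshold = 0.5, min_object_area_um2 = 20,
                         fill_holes = TRUE),
        output_dir = ".", log_level = "info")
}

# Recursively overlay user values onto the defaults.
.mergeConfig <- function(base, user) {
    for (nm in names(user)) {
        if (is.list(base[[nm]]) && is.list(user[[nm]]))
            base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
        else base[[nm]] <- user[[nm]]
    }
    base
}

#' Read a pipeline configuration
#'
#' YAML (`.yaml`/`.yml`) or JSON, merged over [defaultPipelineConfig()] so
#' partial files are valid.
#'
#' @param path configuration file path
#' @return configuration list
#' @export
readPipelineConfig <- function(path) {
    user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
        yaml::read_yaml(path)
    else jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (!is.null(user$config_version) && user$config_version != 1L)
        stop("unsupported config_version: ", user$config_version)
    .mergeConfig(defaultPipelineConfig(), user)
}

#' Write a pipeline configuration
#'
#' Format chosen from the extension: YAML for `.yaml`/`.yml`, JSON
#' otherwise.
#'
#' @param config configuration list
#' @param path output path
#' @return `path` invisibly
#' @export
writePipelineConfig <- function(config, path) {
    if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
        yaml::write_yaml(config, path)
    else writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                     pretty = TRUE), path)
    invisible(path)
}

# --- config section -> S4 parameter objects ------------------------------

phantomSpecFromConfig <- function(cfg, seed = NULL) {
    p <- cfg$phantom
    PhantomSpec(layout = p$layout,
                metadata = AcquisitionMetadata(
                    widthPx = p$width_px, heightPx = p$height_px,
                    fovUm = p$fov_um),
                boundaryWaviness = p$boundary_waviness,
                cellDensity = p$cell_density, beltWidthUm = p$belt_width_um,
                concentrationSmoothnessUm = p$concentration_smoothness_um,
                uniformLabel = p$uniform_label,
                seed = if (is.null(seed)) p$seed else seed)
}

noiseSpecFromConfig <- function(cfg, seed = NULL) {
    n <- cfg$noise
    NoiseSpec(additiveSigma = n$additive_sigma,
              dcRelativeSigma = n$dc_relative_sigma,
              seed = if (is.null(seed)) n$seed else seed)
}

fitConfigFromConfig <- function(cfg) {
    f <- cfg$fit
    FitConfig(nComponents = f$n_components,
              lifetimeBounds = c(f$lifetime_min_ps, f$lifetime_max_ps),
              fitT0 = f$fit_t0, fitIrfSigma = f$fit_irf_sigma)
}

delineationConfigFromConfig <- function(cfg) {
    d <- cfg$delineate
    DelineationConfig(fractionEpsilon = d$fraction_epsilon,
                      smoothSigmaUm = d$smooth_sigma_um,
                      fractionThreshold = d$fraction_threshold,
                      minObjectAreaUm2 = d$min_object_area_um2,
                      fillHoles = d$fill_holes)
}

#' Run the full pipeline from a configuration
#'
#' Generates the phantom, renders the noisy stack, unmixes the pigment
#' maps, delineates the tumor margin scored against the phantom truth, and
#' (when `fit$binning > 0`) fits per-block decays. When `outputDir` is
#' non-NULL all artifacts are written there: stack, phantom, pigment maps,
#' RGB composite, mask, fit table and a `metrics.json` report with the
#' Dice score, boundary distances and object count.
#'
#' @param config configuration list (see [defaultPipelineConfig()])
#' @param outputDir output directory, NULL for no files
#' @param seed optional seed overriding the phantom and noise seeds
#' @return list with `phantom`, `stack`, `maps`, `margin`, `fitMap`
#'   (NULL when fitting is disabled), and `metrics`
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outputDir = NULL,
                        seed = NULL) {
    oldOpt <- options(melaninTA.log_level = config$log_level)
    on.exit(options(oldOpt))
    spec <- phantomSpecFromConfig(config, seed)
    noise <- noiseSpecFromConfig(config, seed)
    phantom <- generatePhantom(spec)
    stack <- renderStack(phantom, noise = noise)
    maps <- unmixStack(stack, normalize = config$unmix$normalize,
                       tolerance = config$unmix$tolerance_ps,
                       dcFloor = config$unmix$dc_floor)
    margin <- delineate(maps, delineationConfigFromConfig(config),
                        pixelSizeUm(stack), truth = truthTumorMask(phantom))
    fitMap <- NULL
    if (!is.null(config$fit$binning) && config$fit$binning > 0L)
        fitMap <- fitImage(stack, config = fitConfigFromConfig(config),
                           binning = config$fit$binning)
    metrics <- list(dice = margin@dice,
                    mean_boundary_distance_um = margin@meanBoundaryDistanceUm,
                    hausdorff_distance_um = margin@hausdorffDistanceUm,
                    n_components = margin@nObjects)
    if (!is.null(outputDir)) {
        dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
        writeStack(stack, file.path(outputDir, "stack.tif"))
        writePhantom(phantom, file.path(outputDir, "phantom.tif"))
        writePigmentMaps(maps, file.path(outputDir, "pigment_maps.tif"))
        compositeRGB(maps, file.path(outputDir, "composite.tif"))
        writeMask(margin@tumorMask, file.path(outputDir, "tumor_mask.tif"))
        if (!is.null(fitMap))
            writeFitTable(fitMap, file.path(outputDir, "fit_table.csv"))
        .writeSidecar(metrics, file.path(outputDir, "metrics.json"))
    }
    list(phantom = phantom, stack = stack, maps = maps, margin = margin,
         fitMap = fitMap, metrics = metrics)
}
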