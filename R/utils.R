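# Internal helpers: seeded evaluation, Gaussian smoothing, logging.

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
# Every random draw in the package flows through this; nothing consumes the
# global stream.
withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(list = ".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

# Derive a secondary 31-bit seed from a base seed and a stream tag, so that
# phantom texture and acquisition noise use decoupled streams.
deriveSeed <- function(seed, stream) {
    (as.double(seed) * 7919 + stream * 104729) %% 2147483647
}

# Gaussian-smooth a plain matrix (sigma in pixels), replicated borders.
smoothMatrix <- function(m, sigmaPx, boundary = "replicate") {
    if (sigmaPx <= 0) return(m)
    # cap the kernel at the image size (gblur's default 6-sigma support can
    # exceed small images); below a 3-px kernel smoothing is a no-op
    r <- 2 * ceiling(3 * sigmaPx) + 1
    maxR <- min(dim(m))
    if (maxR %% 2 == 0) maxR <- maxR - 1
    r <- min(r, maxR)
    if (r < 3) return(m)
    out <- EBImage::gblur(m, sigma = sigmaPx, radius = r,
                          boundary = boundary)
    matrix(EBImage::imageData(out), nrow = nrow(m))
}

# Unit-mean log-normal texture field with ~`corrPx` correlation length.
# Gaussian-smoothed white noise, renormalized to unit variance, then
# exponentiated with -s^2/2 offset so the mean stays 1 and the field > 0.
# Circular (wraparound) smoothing keeps the field stationary: replicated
# borders would re-count edge noise and inflate edge variance.
textureField <- function(nrow, ncol, corrPx, roughness = 0.4) {
    z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
    z <- smoothMatrix(z, corrPx, boundary = "circular")
    s <- stats::sd(z)
    if (s > 0) z <- z / s
    # winsorize: when the correlation length approaches the image size the
    # smoothed field is near-constant and renormalization would explode
    z <- pmin(pmax(z, -4), 4)
    exp(roughness * z - roughness^2 / 2)
}

.LOG_LEVELS <- c(debug = 10L, info = 20L, warning = 30L, quiet = 40L)

taLogLevel <- function() {
    lv <- getOption("melaninTA.log_level", "info")
    if (!(lv %in% names(.LOG_LEVELS))) lv <- "info"
    lv
}

# Lightweight logger; level filtering via options(melaninTA.log_level=).
taLog <- function(level, fmt, ...) {
    if (.LOG_LEVELS[[level]] >= .LOG_LEVELS[[taLogLevel()]])
        message(sprintf("[melaninTA %s] %s", level, sprintf(fmt, ...)))
    invisible(NULL)
}
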