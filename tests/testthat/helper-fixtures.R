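# Shared fixtures: small acquisition geometries and a brute-force
# convolution oracle kept independent of the analytic implementation.

# Small acquisition keeping the standard pixel pitch (212/512 um).
smallMeta <- function(n = 32L, delays = defaultDelayGrid()) {
    AcquisitionMetadata(widthPx = n, heightPx = n, fovUm = 212 * n / 512,
                        delays = delays)
}

noNoise <- function(seed = 0L) NoiseSpec(0, 0, seed)

# Phantom with hand-set concentration maps (labels from dominance).
manualPhantom <- function(concEu, concPh, metadata) {
    labels <- matrix(1L, nrow(concEu), ncol(concEu))
    labels[concEu > concPh] <- 2L
    labels[concEu + concPh < 1e-12] <- 0L
    new("TissuePhantom", labels = labels, concEu = concEu, concPh = concPh,
        metadata = metadata)
}

# Brute-force discrete convolution of the ideal (causal) decay with a
# sampled Gaussian, midpoint rule at step sigma/20 starting at t = 0 so the
# signal's jump sits on a cell boundary.
bruteConvolvedTrace <- function(model, sigmaFs, delaysPs, t0 = 0) {
    sigmaPs <- sigmaFs / 1000
    dt <- sigmaPs / 20
    tMax <- max(delaysPs) - t0 + 10 * sigmaPs
    tGrid <- seq(dt / 2, max(tMax, dt), by = dt)
    d <- decayTrace(model, tGrid)
    vapply(delaysPs, function(tau) {
        g <- stats::dnorm(tau - t0 - tGrid, sd = sigmaPs)
        sum(d * g) * dt
    }, numeric(1))
}

# Random pigment models for property sweeps (log-uniform lifetimes).
randomModel <- function(nComp = 2L) {
    comps <- lapply(seq_len(nComp), function(i)
        TAComponent(sample(c(-1, 1), 1) * stats::runif(1, 0.2, 1),
                    exp(stats::runif(1, log(0.05), log(20)))))
    PigmentModel("custom", comps)
}
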