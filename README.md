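# melaninTA

Label-free discrimination of **eumelanin** and **pheomelanin** in
femtosecond pump-probe (transient-absorption) microscopy data, and
delineation of the uveal-melanoma margin it implies.

Uveal melanoma tissue is dominated by eumelanin while the surrounding
paracancerous tissue predominantly contains pheomelanin, so a map of
which melanin sits where *is* a map of the tumor margin — without
staining or sectioning chemistry. The package is aimed at groups running
pump-probe microscopes on pigmented tissue, and at method developers who
want a tested, seeded synthetic benchmark for this class of algorithm.

## The model

The measured differential-absorption signal Δα = −ΔT/T at interpulse
delay τ is a signed sum of exponentials convolved with the Gaussian
instrument response (σ ≈ 81.6 fs from the 150 fs pump × 120 fs probe
cross-correlation):

    S(τ) = Σᵢ (Aᵢ/2) · exp(σ²/2τᵢ² − u/τᵢ) · erfc((σ/τᵢ − u/σ)/√2),  u = τ − t₀

with Aᵢ > 0 for excited-state absorption (ESA) and Aᵢ < 0 for
ground-state bleaching (GSB); stimulated emission is energetically
closed (860 nm probe photon > 1040 nm pump photon). Both melanins share
a fast ESA transient (τ < 200 fs); eumelanin adds a long-lived GSB
component (τ ≈ 9.4 ps) whose negative tail survives at 500 fs. That
asymmetry drives both analysis routes:

* **per-pixel decay fitting** — bounded multistart Levenberg–Marquardt
  of 1–2 IRF-convolved components, classified by the sign/lifetime rule;
* **two-delay unmixing** — `S_eu = max(−S(500 fs), 0)`,
  `S_ph = max(S(0) + S(500 fs), 0)`, after per-frame DC-transmission
  normalization;

followed by margin segmentation on the eumelanin fraction
`F = S_eu/(S_eu + S_ph + ε)` (smooth, threshold at 0.5, clean up), scored
against ground truth by Dice overlap and boundary distances. A seeded
phantom generator renders ground-truthed delay stacks (wavy
melanoma/paracancer interfaces, choroidal belts, scattered single cells)
for validation. See the methods vignette
(`vignettes/pump-probe-melanin-methods.Rmd`) for every default and its
rationale.

## Worked example

```r
library(melaninTA)

# 1. fit the default eumelanin transient on the standard delay grid
d     <- defaultDelayGrid()
trace <- convolvedTrace(defaultEumelanin(), defaultIRF(), d)
fitDecay(d, trace, defaultIRF(), FitConfig(2L))
#> TADecayFit (2 component(s), converged)
#>   A1 = +1, tau1 = 0.15 ps
#>   A2 = -0.35, tau2 = 9.4 ps
#>   t0 = 0 ps, IRF sigma = 81.57 fs, RMS = 2.177e-17

# 2. phantom -> noisy stack -> unmix -> delineate, full 512x512 field
ph    <- generatePhantom(PhantomSpec("two_region_interface", seed = 0L))
stack <- renderStack(ph, noise = NoiseSpec(additiveSigma = 0.05, seed = 0L))
stack
#> DelayStack: 512 x 512 px, 13 delays [-0.5 .. 40 ps], FOV 212 um
#>   AC range [-0.2554, 0.3992], DC range [0.09662, 0.9156]
maps  <- unmixStack(stack)
delineate(maps, DelineationConfig(), pixelSizeUm(stack),
          truth = truthTumorMask(ph))
#> MarginResult: 130980 tumor px in 1 object(s)
#>   dice = 0.9996, mean boundary dist = 0.0593 um, Hausdorff = 0.828 um
```

The fit recovers the two lifetimes of the generating model exactly
(0.15 ps ESA, 9.4 ps GSB with negative amplitude); on the noisy phantom
the unmixed margin overlaps the ground-truth tumor region with Dice
0.9996 and a sub-micrometre mean boundary error — the eumelanin/
pheomelanin contrast, not image sharpness, defines the margin.

A command-line wrapper is installed at `inst/cli/melaninta`
(subcommands `simulate`, `unmix`, `fit`, `delineate`, `run-all`; every
subcommand takes `--config` and `--seed`).

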