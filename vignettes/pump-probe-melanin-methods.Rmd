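---
title: "Methods: pump-probe discrimination of eumelanin and pheomelanin"
author: "melaninTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pump-probe discrimination of eumelanin and pheomelanin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melaninTA)
```

## The measurement and its model

Femtosecond pump-probe (transient-absorption, TA) microscopy excites
pigment molecules with a pump pulse and reads out the induced change in
probe absorption, $\Delta\alpha = -\Delta T/T$, as a function of the
interpulse delay $\tau$. Three processes can contribute: excited-state
absorption (ESA, positive signal), ground-state bleaching (GSB, negative
signal) and stimulated emission (SE, negative). With a 1040 nm pump and an
860 nm probe the probe photon (1.442 eV by $hc/\lambda$) carries more
energy than the pump photon (1.192 eV), so SE is energetically closed and
the signal is a pure ESA/GSB mixture — `stimulatedEmissionAbsent()`
encodes exactly this inequality.

The two melanins of pigmented ocular tissue differ sharply in their delay
dependence. Both show a strong, very short-lived ESA transient
(lifetime below 200 fs). Eumelanin — the pigment that dominates uveal
melanoma — additionally shows a long-lived GSB component with a lifetime
of about 9.4 ps, so its signal crosses zero within a few hundred
femtoseconds and stays negative for tens of picoseconds. Pheomelanin,
which dominates the surrounding paracancerous tissue, decays to
essentially nothing by 500 fs. The package models a pigment as a signed
sum of exponentials,

$$ S(\tau) = \sum_i A_i\, e^{-\tau/\tau_i}\,\Theta(\tau), $$

with the amplitude sign carrying the physics ($A_i>0$ ESA, $A_i<0$ GSB).

### Instrument response

The measured trace is this ideal decay convolved with the pump–probe
cross-correlation, modeled as a Gaussian. For Gaussian pulses of 150 fs
(pump) and 120 fs (probe) FWHM the cross-correlation FWHM is the
quadrature sum, $\sqrt{150^2+120^2}\approx 192$ fs, i.e.
$\sigma \approx 81.6$ fs — the package default (`defaultIRF()`). The
convolution has the closed exponentially-modified-Gaussian form

$$ C_i(\tau) = \frac{A_i}{2}
   \exp\!\Big(\frac{\sigma^2}{2\tau_i^2}-\frac{u}{\tau_i}\Big)
   \operatorname{erfc}\!\Big(\frac{\sigma/\tau_i - u/\sigma}{\sqrt 2}\Big),
   \qquad u = \tau - t_0 .$$

Numerically this overflows for $\tau_i \ll \sigma$; `convolvedTrace()`
therefore evaluates the positive-argument branch as
$\tfrac{A_i}{2}\,\mathrm{erfcx}(b)\,e^{-u^2/2\sigma^2}$ (with
$\mathrm{erfcx}(b)=e^{b^2}\mathrm{erfc}(b)$), which is finite for every
parameter combination; the identity
$a - b^2 = -u^2/2\sigma^2$ makes the two branches agree exactly. A
brute-force discrete-convolution oracle (midpoint rule at step
$\sigma/20$) backs this up in the test suite to better than $10^{-3}$
normalized error.

Time zero is defined as the cross-correlation maximum; $t_0$ is an
explicit parameter defaulting to 0. All internal times are in ps; fs
appears only at interfaces (IRF width, reported fast lifetimes).

### Default pigment models

Published measurements constrain the lifetimes (fast component below
200 fs; slow eumelanin bleach ~9.4 ps) but not the amplitudes. The
package defaults are

* pheomelanin: one ESA component, $A=+1$, $\tau=0.15$ ps;
* eumelanin: ESA $A=+1$, $\tau=0.15$ ps plus GSB $A=-0.35$,
  $\tau=9.4$ ps.

The GSB weight $-0.35$ was chosen once so that the eumelanin trace is
clearly positive at $\tau=0$ (ESA dominates within the IRF), crosses zero
near 200–300 fs and is strongly negative at 500 fs, mirroring the
qualitative tissue signatures; both models are plain `PigmentModel`
objects and fully overridable. Note one consequence spelled out because it
matters for interpretation: the *unconvolved* pheomelanin decay retains
only 3.6% of its zero-delay value at 500 fs, but after IRF convolution
the rendered ratio is ~12%, because the convolution halves the
zero-delay peak. The two-delay unmixing is unaffected — the pheomelanin
residual at 500 fs is positive, so it never leaks into the (negative-side)
eumelanin channel.

## Decay fitting

`fitDecay()` minimizes the residual sum of squares between the measured
trace and the IRF-convolved model with bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`). Design choices:

* **Multistart.** Initial lifetimes $\{(0.1),(0.2)\}$ ps for one
  component, $\{(0.1,5),(0.2,10),(0.15,20)\}$ ps for two; amplitudes are
  seeded from the trace values at the frames nearest 0 and 0.5 ps
  (doubling the zero-delay value, since the convolution halves it). The
  lowest residual RMS wins; ties keep the earliest grid entry, so results
  are bit-reproducible.
* **Bounds.** Lifetimes in (0.02, 100) ps by default — the lower bound
  keeps the fast component from collapsing into the IRF, the upper is an
  order of magnitude beyond the slow bleach.
* **Fixed IRF and $t_0$ by default.** Fitting the IRF width is opt-in:
  on coarse delay grids it is nearly degenerate with the fast lifetime.
* **Degenerate input.** An all-zero trace converges immediately with zero
  amplitudes; a fit where every start fails returns `converged = FALSE`
  rather than throwing.
* **Classification floors.** The noise scale is the scaled median absolute
  deviation of pre-time-zero samples (no signal exists before the pulses
  overlap); amplitude floor $3\hat\sigma$, peak floor $5\hat\sigma$, with
  a 1%-of-peak fallback when fewer than four pre-zero samples exist. The
  rule in `classifyPigment()`: below the peak floor → unpigmented; a
  component slower than 1 ps with amplitude below $-3\hat\sigma$ →
  eumelanin; else a dominant positive component faster than 0.5 ps →
  pheomelanin; anything else → ambiguous. The 1 ps / 0.5 ps cutoffs sit
  between the two melanin lifetimes and are configurable.

`fitImage()` bins the stack (block averaging) before fitting, both for
speed and for SNR; with binning equal to the image size it reduces exactly
to a single fit of the mean trace.

## Two-delay unmixing

With the eumelanin bleach the only surviving signal at 500 fs, the
separation needs just two frames:

$$ S_{eu} = \max(-S(500\,\mathrm{fs}),\,0), \qquad
   S_{ph} = \max(S(0) + S(500\,\mathrm{fs}),\,0). $$

The pheomelanin expression adds back the (negative) eumelanin
contribution at zero delay, to first order cancelling eumelanin's ESA;
the clamping to zero is applied to both channels — under noise the sign
reversal alone would otherwise produce negative eumelanin estimates.
Frames are matched to the nominal 0 and 500 fs stage positions within a
0.05 ps tolerance, and the delays actually used are recorded in the
result. DC normalization (dividing by the transmitted-intensity image to
correct heterogeneous melanin absorption) is applied per frame *before*
the delay arithmetic — the acquisition normalizes images frame by frame —
with a floor (default 0.05) guarding the division and a validity mask
flagging floored pixels; a switch disables normalization.

## Margin delineation

The tumor margin is defined by pigment dominance, so the statistic is the
eumelanin fraction $F = S_{eu}/(S_{eu}+S_{ph}+\varepsilon)$, thresholded
at 0.5. A log-ratio statistic was considered and rejected: it needs
special-casing wherever either channel is exactly zero, which clamping
makes common. Before thresholding, $F$ is smoothed with a 2 µm Gaussian
(≈5 px at the default 0.414 µm pitch) — enough to suppress pixel noise,
small enough to keep 10 µm single cells. Connected components below
20 µm² (about a quarter cell) are discarded and holes filled. Dice
overlap and symmetric boundary distances (mean and Hausdorff, from
Euclidean distance transforms of the 8-connected boundary pixel sets)
score the mask against ground truth; two empty masks score Dice 1
(vacuous agreement), one empty mask scores 0.

## The synthetic phantom generator

No image data accompany the published tissue results, so validation runs
on seeded phantoms whose statistics mirror the described tissue scenes:

* `two_region_interface` — eumelanin-dominant melanoma meeting
  pure-pheomelanin paracancer along a wavy sinusoidal boundary;
* `choroid_belt` — melanin-free elliptical cores each ringed by a
  pheomelanin-rich belt inside a paracancer field;
* `scattered_cells` — ~10 µm eumelanin-rich disks (Gaussian-feathered
  edges, ~1 px) over a pheomelanin background;
* `uniform` — single-class fields for calibration.

Concentration maps are the layout indicator times a unit-mean log-normal
texture (Gaussian-smoothed white noise, correlation length 8 µm by
default), which keeps them positive and heterogeneous. Melanoma carries a
0.25 pheomelanin co-fraction (tumor tissue is a mixture); paracancer is
modeled as pheomelanin-only. Labels are *derived* from per-pixel
dominance, so the ground-truth tumor mask equals
$\{c_{eu} > c_{ph}\}$ by construction. The DC channel follows a
Beer–Lambert law $e^{-k_{abs}(c_{eu}+c_{ph})}$ with a single lumped
extinction coefficient ($k_{abs}=0.5$ per unit concentration): the
functional form is a package choice, constrained only by "pigmented
regions transmit less". Noise is additive Gaussian on AC (lock-in
detection noise is approximately Gaussian), scaled to the stack's peak
absolute signal, plus multiplicative log-normal noise on DC; a
signal-dependent (shot-noise-like) term is available but off by default.
The default delay grid (13 frames, −0.5 to 40 ps, denser near zero,
containing 0 and 0.5 exactly) is an emulation — the original scan grid is
not published.

What the phantoms deliberately do **not** model: optical point-spread
blurring, depth sectioning, scattering, motion, and the appearance
differences between frozen, paraffin and fresh sections (the analysis
chain treats them identically). Passing phantom tests therefore
demonstrates the correctness and noise robustness of the *computational
chain* — model, fit, unmixing, segmentation — not the instrument physics
or tissue-preparation effects.

## Problem sizes and reproducibility

The test suite exercises full-resolution 512 × 512 stacks for the
end-to-end delineation check (Dice ≥ 0.90 on the noisy interface phantom)
and 8–128 px grids elsewhere, sizes chosen to probe each property at the
smallest scale that exhibits it. Every random draw flows through an
explicit seed (`withSeed` saves and restores the caller's RNG state);
texture and geometry use independent derived streams so reseeding the
noise never perturbs the noiseless signal. Stacks are stored as
uncompressed little-endian float32 TIFF with JSON sidecars, so repeated
writes of the same object are byte-identical.

## Known limitations

* Amplitude defaults are calibrated to qualitative signatures, not to a
  published amplitude table; quantitative pigment concentrations from
  real tissue would need an instrument-specific calibration.
* The two-delay unmixing assumes exactly two pigments and leaves a small
  model-predicted crosstalk of eumelanin into the pheomelanin channel
  (its residual ESA at 0 fs); `fitImage()` offers the slower,
  full-trace alternative.
* Per-pixel fitting at full 512² resolution is intentionally not the
  default path (binning is); the two-delay separation is the fast
  per-pixel route, exactly as in the underlying method.
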