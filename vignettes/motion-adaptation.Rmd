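---
title: "Motion adaptation in arrays of elementary motion detectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion adaptation in arrays of elementary motion detectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emdadapt)
```

## The model

Flying insects extract the spatial layout of their surroundings from optic
flow.  Only *translational* self-motion carries distance information: a
nearby object sweeps across the retina faster than the background behind it.
Flies exploit this by splitting flight into long translational segments
interrupted by brief saccadic turns.  `emdadapt` simulates the processing
chain that turns retinal luminance into wide-field motion signals, with a
slow, local *motion adaptation* stage whose consequence — the selective
attenuation of sustained background motion relative to transient motion of
nearby objects — is the scientific subject of the package.

The chain is retinotopic: every pixel of the stimulus runs through

1. **Adaptive photoreceptor.**
   `PR = LP_9ms(I) / (LP_250ms(I) + C_PR)` with `C_PR = 10`: a Lipetz-type
   saturation whose operating point follows the ambient light level.  This
   divisive normalisation makes all downstream responses nearly invariant
   over at least eight decades of mean luminance.
2. **LMC (lamina) stage.**  A first-order high-pass (`tau = 10` ms) removes
   the mean, the result is half-wave rectified into an ON and an OFF
   channel (the OFF channel carries the negative lobe as a positive
   signal), and each channel is saturated as `x / (x + 0.03)`.
3. **Correlation-type EMD.**  Per channel, the signal of one column is
   delayed by a 50 ms first-order low-pass and multiplied with the
   undelayed signal of its right-hand neighbour (preferred direction, PD)
   and mirror-symmetrically for the null direction (ND) — four non-negative
   half-detector outputs per detector (ON/OFF x PD/ND).
4. **Divisive motion adaptation.**  Each branch is fast-filtered
   (`tau = 20` ms), raised to an adaptive exponent `a` and divided by
   `LP_4s(EMD_ave)^a + 0.8^a`, where `EMD_ave` is the mean of the four
   branches of that detector.  The shared slow signal is what makes the
   adaptation *direction-independent*.  The exponent obeys
   `da/dt = -(a - 0.5) p1 + (3 - a) p2 LP_4s(EMD_ave)` with
   `p1 = 30`, `p2 = 150` (interpreted as 1/s; the Euler update at
   `dt = 1` ms is stable, `p1 dt = 0.03`), so `a` rests at 0.5 and grows
   towards 3 under sustained motion.
5. **LPTC pooling.**  The tangential-cell model is a plain sum of signed
   detector outputs (`PD - ND`, ON and OFF alike) over the whole array —
   membrane dynamics, after-hyperpolarisation and output-range compression
   are deliberately outside the model's scope.

All temporal filters use the exact exponential update for piecewise-constant
input, so traces change by well under 2% when the step size is halved
(asserted in the test-suite).  Filter memories are initialised at the steady
state of the first frame, and every stimulus protocol starts with a 500 ms
stationary prelude, so onset transients have died out before anything is
measured.

```{r params}
pathway_params()
```

## What the model reproduces

Running the benchmark grating protocols through the chain reproduces, at the
LPTC level, the classic adaptation phenomenology:

* during constant-velocity motion the response declines over seconds, while
  superimposed 50 ms velocity transients keep evoking full-sized (or even
  growing) response excursions (`sim_transients()`, quantified per event by
  the response contrast `C = |R_bg - R_pk| / (R_bg + R_pk)` and the
  enhancement score `C_last - C_first`);
* adaptation is direction-independent: PD, ND and even orthogonal
  adaptation all reduce a subsequent PD test response, although the cell
  hardly responds to orthogonal motion itself
  (`sim_adaptation_direction()`);
* the contrast-gain curve shifts rightward after adaptation
  (`sim_contrast_gain()`);
* steady-state temporal-frequency tuning stays bell-shaped with an
  essentially unshifted peak (`sim_tuning()`).

## The synthetic worlds

The 3D module emulates the spatial-vision experiments: an agent translating
at 1 m/s past a row of eight bars (5 cm x 1 m, 1 m apart, 0.5 m from the
flight line) in front of a wall at 0.55, 2 or 4 m, all textured with random
cloud patterns whose power spectrum falls as 1/f^2 in *physical* spatial
frequency.  For larger wall distances the wall's height, length and texture
element size scale proportionally, so its retinal projection is unchanged
and only its retinal *velocity* differs.  A spherical-eye renderer casts
rays at 2 degree resolution over the left hemisphere; each ommatidium
averages a 2x2 sub-ray box covering its angular cell — with pure point
sampling, texture detail finer than the eye's resolution aliases into
spurious detector input.  Rendering runs at 100 Hz and is linearly
interpolated onto the 1 ms model grid.

The saccadic condition bends each second of flight into a decagon cycle:
ten 80 ms translations (1.25 m/s, conserving path length) alternating with
20 ms, 36 degree saccades whose yaw-velocity profile is a discrete Gaussian
(`tc = 10.5` ms, `sigma = 3.5` ms) normalised to integrate to exactly 36
degrees — ten saccades per second.  The arena is a decagonal wall at the
matched distance with **one** bar 0.5 m outside one path side, so the bar
is passed once per cycle: this keeps the printed 1 bar/s passage rate (ten
bars, one per side, would be passed at 10/s).

Analyses mirror the published ones: the motion-energy series at 90 degree
azimuth (mean |signed response| over all elevations of the lateral detector
column), per-bar response contrasts (peak in a +/-150 ms window around each
crossing against the mean over a +/-150 ms window at the following
inter-bar midpoint; widths are arguments), and windowed-Michelson local
contrast-change maps for profile comparisons.

## Choices made where the sources are open

* **Unprinted texture statistics.**  The cloud textures' rms contrast (0.3)
  and the sky luminance (the mean luminance) are not printed anywhere; 0.3
  is a realistic natural-scene contrast and both are arguments.
* **Transient timing.**  Within the 7420 ms motion block the eight
  transient onsets are spaced 780 ms apart starting 390 ms after motion
  onset, centring the train and leaving >600 ms of background motion after
  the last transient for its background window.
* **Rectification before adaptation.**  Half-detector outputs are clamped
  at zero before the adaptive stage: the Lipetz exponent drops to 0.5, and
  fractional powers of negative products would leave the real line.  With
  non-negative ON/OFF inputs the products are non-negative anyway.
* **Undefined response contrasts.**  `C` requires `R_bg + R_pk > 0`.  In
  the deep low-frequency/low-contrast corner of the screening grid the
  signed LPTC response oscillates around zero and the statistic is
  undefined; such cells are reported as `NA` and count against (never for)
  the enhancement summary.
* **"Before adaptation".**  Evaluated as the early-time response of the
  adapting model (first transient, first bar), not as a separate frozen
  model; `run_pathway(adaptation = FALSE)` exists for explicit
  non-adaptive references and bypasses the divisive stage entirely.
* **Analysis windows at the trace edge.**  The background window of the
  last bar (midpoint extrapolated by half the median crossing interval) is
  clipped to the trace where necessary.

## What a green test does and does not establish

The generator produces Gaussian 1/f^2 textures, rectangular panels, a
point eye at the bar/wall vertical midline and noise-free photon counts.
Green tests therefore establish the *mechanistic* claims — decay of
sustained responses, preserved transient sensitivity, direction
independence, contrast-gain shift, and the qualitative enhancement of
bar/background contrast with adaptation — on this idealised world.  They do
not certify photometric realism, nor performance on natural imagery (the
plain-text stimulus reader accepts external sequences for that), nor any
LPTC-intrinsic adaptation component, which is out of scope by design.

Two quantitative limits of the published parameter set, measured here and
asserted honestly in the acceptance suite, are worth knowing:

* With single-pixel detector spacing on a 19-pixel wavelength, the pooled
  PD-ND signal is only weakly direction-selective, so the *difference*
  decays far less than the individual half-detector branches (which decay
  by 40-70%); the background LPTC decay between the first and last
  inter-transient window is 12-29% across the benchmark conditions.
* At 0.3 texture contrast, the wall at 0.55 m drives detectors at a
  substantial fraction of the bar response, so single-seed bar-passage
  peaks can drown in texture noise; the enhancement of bar/background
  contrast is recovered in seed medians, as in the published
  50-texture averages.

## A short worked example

```{r example, eval = FALSE}
r <- sim_transients() # 2 Hz background, 4 Hz transients, c = 0.88
r$contrasts           # per-transient response contrasts
r$enhancement         # C_8 - C_1 > 0: sensitisation by adaptation
plot(r$run)           # the adapting LPTC trace
```
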