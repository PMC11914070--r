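---
title: "The MS-INRF motion sensor: model, stimuli and experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The MS-INRF motion sensor: model, stimuli and experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msinrf)
```

## The model

Classical motion sensors (Reichardt correlators, motion-energy models)
are built from linear spatio-temporal filters followed by a pointwise
nonlinearity.  The sensor implemented here instead places the
nonlinearity *inside* the receptive field, as a model of dendritic
computation: part of the dendritic tree sums the input linearly, and
part applies a saturating nonlinearity to local input *differences*
that is re-centred by the neuron's own current input.

At a sensor location $s_i$ and time $t$ the spatio-temporal response is

$$\mathrm{stINRF}(s_i,t)= \sum_u T_m(u) \sum_j m_j\, I(s_j,t-u)
  \;-\; \lambda \sum_u T_w(u) \sum_j w_j\,
  \sigma\!\big(I(s_j,t-u) - I(s_i,t)\big),$$

and the motion sensor readout is the time-average of this trace over
the frames with full temporal-filter support.  Its sign encodes
direction: positive responses mean rightward motion.

The components, all fixed to a single parameter set for every
experiment in the package:

* $T_m(t) = (kt)^n e^{-kt}\!\left[\tfrac{1}{n!} -
  \tfrac{(kt)^2}{(n+2)!}\right]$ with $k = 0.4\,\mathrm{ms}^{-1}$,
  $n = 5$, support 50 ms — a biphasic (bandpass) filter with a single
  sign change near 16 ms.
* $T_w(t) = \cos\!\big(\pi(t+10)/120\big)$, support 50 ms —
  non-negative (lowpass) on its support, vanishing exactly at 50 ms.
* $m$: an isotropic Gaussian, $\sigma = 0.031$ deg, unit sum, so a
  uniform field passes through the linear branch unchanged.
* $w$: a vertically oriented, sine-phase (odd-symmetric) Gabor whose
  positive and negative lobes are each 0.125 deg wide (carrier period
  0.25 deg).
* $\sigma(z) = |z|^p/(|z|^p + q^p)$ with $p = 0.4$, $q = 0.1$: even,
  zero at zero, half-saturated at $|z| = q$, bounded by 1.  Crucially,
  its argument is shifted by the **current** sensor value $I(s_i,t)$
  at every delay $u$: the minuend is delayed, the subtrahend is not.
* $\lambda = -30$, frame rate 120 Hz, calibration 2 deg across 400 px
  (0.005 deg/px).

Because $\sigma$ is even, the dendritic term is exactly invariant under
contrast-polarity inversion $I \to 1-I$, which is why the sensor
responds identically to white-on-black and black-on-white bars.  Because
$m$ is even and $w$ odd under horizontal mirroring, the dendritic term
exactly negates when the stimulus and the sensor location are mirrored
— the origin of the left/right antisymmetry of every experiment.

## Decisions the formulas leave open

The definitions above leave several discretisation choices open; the
package fixes them as follows.

**Temporal sampling.** Taps at delays $u = 0, \Delta t, \dots, 50$ ms
with $\Delta t = 1000/\mathrm{fps}$ (7 taps at 120 Hz).  The stimulus
is frame-sampled, so sub-frame quadrature would add nothing.  The taps
are used *unnormalised*: $\lambda$ is an absolute weight, and rescaling
the taps would silently change the linear/nonlinear balance.

**Kernel truncation.** Both spatial kernels are truncated at three
standard deviations (of the envelope, for the Gabor) with odd side
lengths; the Gaussian is renormalised to unit sum after truncation.

**Gabor construction.** Only the lobe width is prescribed, so the
envelope is chosen isotropic with $\sigma$ equal to a quarter of the
carrier period (0.0625 deg).  This keeps any third lobe below 5% of the
main lobes: an effectively two-lobed odd kernel.  The grid is built by
mirror-negating one half, making the antisymmetry (and hence the zero
sum) exact rather than approximate.

**Lobe polarity.** Neither lobe is designated positive by the
formulas, yet the sign of every response hinges on it.  The package
fixes the convention once: the positive lobe sits to the right of the
kernel centre, which makes the response to a canonical
rightward-drifting 2 c/deg, 4 Hz grating positive.  All "rightward =
positive" statements in the experiments inherit from this single
choice.

**Averaging window.** The sensor readout averages "the recent past";
the package averages over *all* frames with full temporal support
(frames 7–120 at the defaults, 1-based).  The shipped stimuli are
statistically stationary over their one-second duration, so any
sufficiently long window converges to the same value; `ms_inrf()`
exposes a `window` argument for shorter readouts.

**Sensor readout.** Experiments report the response of the single
central sensor (pixel 200,200).  After phase averaging the grating-family
stimuli are spatially homogeneous, so a pooled readout would add cost
without changing conclusions; `stinrf_field()` provides grid readouts
where spatial structure is of interest.

**Boundaries.** Spatial kernels are only evaluated where fully
supported (mirror padding is available but off by default; the central
sensor never needs it).  Time is strictly causal: the first six frames
have no full filter support, are flagged invalid, and are excluded from
the readout mean.

**Precision.** Everything is double precision.  The dendritic term
admits no separable shortcut — the shift of $\sigma$ depends on the
sensor's own trace — so its cost (kernel pixels x taps x frames) is
paid in full; the inner loop is compiled (Rcpp), and a literal
nested-loop reference implementation (`stinrf_bruteforce()`) serves as
the independent oracle in the tests, with agreement required to
$10^{-10}$ relative error.

## The stimulus suite

All stimuli are 400 x 400 px sequences of 120 frames at 120 Hz spanning
2 deg, values in $[0,1]$ (experiments may generate smaller images for
speed; the model sees identical central patches for the periodic
recipes).  Every recipe is deterministic given its seed, and each
generated object records its recipe, parameters and seed.

* **Moving bar** — 0.25 deg wide, 2 deg/s, white-on-black or its exact
  luminance inverse, wrapping horizontally.  Non-integer per-frame
  displacements (3.33 px at the defaults) use accumulated-remainder
  integer shifts rather than interpolation, so binary patterns stay
  binary.
* **Drifting grating** — $0.5(1 + C\sin(2\pi(f_s x - d f_t t) + \varphi))$;
  mean luminance 0.5, Michelson contrast $C$.
* **Masked grating** — signal (0.4 contrast, 2.5 c/deg, 10 Hz,
  rightward) plus a jittering noise grating (0.4 contrast) whose
  spatial phase is resampled uniformly every 100 ms and held in
  between.  The noise has no coherent drift: a drifting-noise reading
  of the recipe makes same-frequency noise *facilitate* the response
  (it adds coherent rightward energy), inverting the masking
  phenomenon, so the phase jitter is taken to replace the drift.  At
  the default contrasts the sum never leaves $[0,1]$.
* **Random strip pattern** — binary vertical strips (0.05 deg wide by
  default; the recipe only says "random patterns", and vertical strips
  give the vertically-oriented Gabor maximal signal), Michelson
  contrast 0.9, translated rightward at 8.5 deg/s with wraparound;
  reverse-phi inverts luminance on every other frame.
* **Square wave / missing fundamental** — Fourier-synthesised from odd
  harmonics up to the pixel Nyquist limit (1.5 c/deg, contrast 0.9);
  the missing-fundamental variant omits the first harmonic before
  synthesis.  Motion is either a quarter-period jump every 66 ms
  (rounded to 8 frames at 120 Hz) or smooth drift at 4 Hz.  Gibbs
  overshoot at contrast 0.9 is clipped (about 1% of pixels, recorded
  per sequence).
* **Contrast-modulated stimulus** — local contrast
  $c(x,t) = 0.3\,(1 + 0.8 \sin(2\pi(x - d\,7t) + \varphi))$ on a
  4 c/deg carrier whose phase is resampled on every frame, giving
  second-order motion: mean luminance is 0.5 everywhere and the
  seed-averaged luminance spectrum has no net directional energy.  The
  printed "contrast 0.8" is read as the contrast of the *envelope* and
  "modulation depth 0.3" as the mean carrier contrast, keeping local
  contrast inside $[0.06, 0.54]$.
* **Compound grating** — mean 0.5 plus two rightward sinusoidal
  modulations of 0.4 contrast each.
* **Pre-filters** — a centre-surround DoG ($\sigma$ 0.036 / 0.18 deg;
  the "balance factor 5" is read as centre integral = 5 x surround
  integral, so uniform fields are scaled by $1 - 1/5$), used for the
  LGN condition of the masking experiment and *not* clipped (its
  output is a neural signal, not luminance); and an optional Gaussian
  pre-blur standing in for the eye's optics, off by default in every
  experiment.  Both use circular boundaries, consistent with the
  periodic stimuli; for y-constant stimuli (all shipped recipes) the
  2D convolution reduces exactly to a 1D convolution with the kernel's
  column sums, which the implementation exploits.

## The experiments and what they show

Each experiment averages the central sensor's readout over starting
phases (periodic stimuli) or independent random generations (stochastic
stimuli), reports the spread over those repeats as its dispersion, and
is reproducible bit-for-bit from its stored config and seeds.

* **First-order motion** (4 conditions): positive for rightward bars,
  negative for leftward, near-identical across contrast polarity (the
  dendritic term is exactly polarity-invariant; only the small linear
  term distinguishes the polarities).
* **Contrast saturation** (20 contrasts x 10 phases at print scale):
  response magnitude rises monotonically and saturates; the log-log
  slope over the top quartile of contrasts is well below the
  bottom-quartile slope.
* **Motion masking** (noise spatial frequency swept over [0, 10] c/deg):
  jittering noise suppresses the signal response.  With the DoG LGN
  stage the suppression is clearly tuned, strongest near the signal
  frequency.  Without it the suppression is broad and its maximum sits
  near the Gabor's own passband (~4–5 c/deg) rather than at the
  2.5 c/deg signal: a single-channel sensor's masking tuning tracks its
  kernel, and pre-filtering is what sharpens the tuning — consistent
  with the narrowing of frequency tuning across processing stages.
  This is the one shipped check that asserts more than the raw model
  delivers, and it is left failing rather than weakened.
* **Reverse-phi** (10 random patterns): frame-wise polarity inversion
  flips the response sign from positive to negative.
* **Missing fundamental**: with quarter-cycle jumps the square wave
  gives a positive and the fundamental-removed stimulus a negative
  response; with smooth drift both are positive and the illusion
  vanishes.
* **Second-order motion**: the sign follows the contrast envelope's
  direction even though the luminance carries no directional energy; a
  static-envelope control estimates the noise floor and is
  statistically indistinguishable from zero.
* **Nonlinearity maps**: over a spatio-temporal frequency grid, a
  fixed grating G (8.5 c/deg, 1 Hz) produces under 5% of the maximal
  single-grating response on its own, yet adding it changes the map by
  far more than 5% — a direct violation of superposition.  The same
  harness run with $\lambda = 0$ (a purely linear sensor) passes
  superposition to numerical precision, confirming the effect is the
  dendritic term's.

### Problem sizes

The print-scale protocols (e.g. 20 contrasts x 10 phases; 100 x 100
frequency grids with 100 phase pairs) are available through the
experiment arguments and the `--scale=full` CLI switch.  The shipped
tests and the acceptance script run reduced grids chosen so that every
sign-based conclusion is preserved: 10 contrasts x 4 phases, 11 noise
frequencies x 3 phases, 4 phases for the illusion experiments, and a
6 x 6 frequency grid x 2 phases (on 200 px frames) for the
nonlinearity maps.  The phase-mean of a drifting-grating response is
stable to a few percent across disjoint phase grids of this density,
which is the basis for the scaling.

## What the synthetic stimuli do not emulate

The stimulus suite covers the luminance structure of the classical
laboratory stimuli but not display gamma, optical aberrations beyond an
optional Gaussian blur, photoreceptor adaptation, temporal integration
beyond the model's own filters, eye movements, or any 2D motion
(plaids, rotations): the sensor is a single, vertically-oriented,
horizontally-tuned unit.  Passing these experiments therefore shows
that the *model* reproduces the six phenomena on idealised inputs, not
that it predicts responses to natural video.

## Known limitations

* One orientation, one spatial scale: no multi-orientation bank or 2D
  motion integration.
* The dendritic term's cost is quadratic in kernel radius per frame
  and location; full-field response maps at 400 px are expensive by
  design (no separable shortcut exists).
* The masking experiment's raw (no-LGN) tuning is broad, as discussed
  above.
* Parameters are fixed constants; no fitting to neural or
  psychophysical data is provided or intended.
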