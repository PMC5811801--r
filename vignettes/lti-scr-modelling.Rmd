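---
title: "Modelling the sudomotor-nerve to skin-conductance mapping as an LTI system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the sudomotor-nerve to skin-conductance mapping as an LTI system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Skin conductance responses (SCR) are driven by bursts of sudomotor nerve
(SN) firing. Model-based SCR analysis assumes that the peripheral mapping
from SN activity to measured conductance is linear and time-invariant
(LTI), so that the whole mapping is captured by one impulse response — the
skin conductance response function (SCRF). `scrlti` implements both halves
of that model and everything needed to test it:

* **SN bursts** are modelled as Gaussians,
  $u(t) = \frac{A}{\sqrt{2\pi}\,\sigma} e^{-(t-\mu)^2 / 2\sigma^2} + c$,
  with area $A$, latency $\mu$ relative to the eliciting stimulus,
  dispersion $\sigma$ (about 0.3 s for real bursts) and baseline firing
  $c$ (`burst_params()`, `gaussian_burst()`).
* **The SCRF** is defined implicitly by a third-order constant-coefficient
  linear ODE,
  $\dddot x + \vartheta_1 \ddot x + \vartheta_2 \dot x + \vartheta_3 x
  + g\, u(t - \vartheta_4) = 0$,
  with shape coefficients $\vartheta_{1..3}$, a pure input delay
  $\vartheta_4$ (conduction distance between recording sites; may be
  negative) and a free gain $g$ (`scrf_params()`, `scrf_simulate()`).
  As written, a positive input drives $x$ negative; the gain absorbs
  polarity, so gains fitted against positive-going conductance data come
  out negative and are reported as-is.

Stability of a coefficient set is the Routh–Hurwitz condition for the
characteristic cubic ($\vartheta_1 > 0$, $\vartheta_3 > 0$,
$\vartheta_1\vartheta_2 > \vartheta_3$; `scrf_stable()`). All four
canonical sets shipped in `canonical_params()` satisfy it, and two useful
closed forms follow directly from the ODE: the steady state under constant
input is $x_{ss} = -g u_0/\vartheta_3$, and the time-integral of the Dirac
impulse response is $-1/\vartheta_3$. Both are used as analytic oracles in
the test suite.

## Numerical choices

* **Integration** is fixed-step fourth-order Runge–Kutta on the data grid
  with 10 internal substeps per sample and linear interpolation of the
  input (C++ inner loop). Halving the step changes canonical responses by
  less than $10^{-4}$ relative L2; the `substeps` argument exposes the
  knob. An independent stiff solver (`deSolve::lsoda`) is used in the test
  suite as a cross-check, never in the implementation.
* **The Dirac impulse response** is computed from the jump condition
  ($x = \dot x = 0$, $\ddot x = -g$ at $0^+$) rather than from a discrete
  spike: a one-sample spike under linear input interpolation would carry
  only half its nominal area.
* **The delay line** $\vartheta_4$ acts on the input by linear
  interpolation, with the input held at its boundary values outside the
  recorded span. A negative $\vartheta_4$ makes the system non-causal with
  respect to the input, which a causal convolution with a shifted kernel
  cannot represent; `scrf_predict()` therefore shifts the *input* (with
  the solver's exact semantics) and convolves with the zero-delay kernel.
  The two pathways then agree within $10^{-3}$ relative L2 on random
  stable systems — the package's core LTI self-consistency check.
* **Degenerate inputs**: a zero-variance observation makes the gain and
  $R^2$ undefined; fitters return gain 0 and $R^2 = 1$ by convention with
  a `degenerate` flag rather than failing inside batch runs.

## Estimation

`fit_gaussian_burst()` is plain least squares under Nelder–Mead with three
jittered starts (fixed seed), initialized from the epoch argmax, a 0.3 s
dispersion, the 5th percentile as baseline and the peak height.
`fit_scrf()` minimizes the squared error of the simulated response under
bounded multi-start L-BFGS-B (five jittered starts; bounds
$\vartheta_{1,2} \in (0, 20]$, $\vartheta_3 \in (0, 5]$,
$\vartheta_4 \in [-5, 5]$), with the gain profiled out analytically at
every step. Optional Gaussian priors on $\vartheta$ add a quadratic
penalty. When several segments are passed, one coefficient set is fitted
jointly with one profiled gain per segment — the "common response
function, variable gain" model. Because quite different coefficient
vectors can generate near-identical impulse responses, recovery is always
judged on impulse-response shape ($R^2$ against a reference or the
generating truth, `compare_scrf_to_reference()`), not on raw coefficients.

Two estimation choices deserve emphasis, because both were forced by
measurement rather than taste:

* **Observation-model fitting.** Recorded conductance passes through
  causal filters (and, in the stimulation experiment, a derivative
  recording device) before analysis. Comparing a raw ODE solution with
  such data is structurally misspecified: in our experiments the fitted
  coefficients then absorbed the measurement chain and the recovered
  impulse response bore almost no resemblance to the generating one
  (shape $R^2 \approx 0.12$). The pipelines therefore pass the model
  prediction through the same, fully known measurement chain before
  computing residuals (`obs_transform` of `fit_scrf()`). This is forward
  modelling of the observation process with documented hardware
  constants, not an inversion of the device. With it, the stimulation
  pipeline recovers impulse-response shape with $R^2 > 0.99$ and reaches
  the additive-noise ceiling of explained variance.
* **Affine gain regression.** z-scoring and minimum correction of
  causally filtered signals introduce per-epoch additive constants that a
  through-origin slope cannot absorb; with slope-only gains the same fits
  scored large negative explained variance. The pipelines therefore
  profile a slope *and* intercept per epoch (`gain_intercept = TRUE` in
  `pipeline_config()`); `estimate_gain()` keeps the through-origin slope
  $g = \langle p, o\rangle / \langle p, p\rangle$ as its default, with
  the intercept available as a switch.

## Preprocessing

The standard chains mirror common electrodermal practice: skin
conductance is band-passed (first-order Butterworth, 0.0159 Hz — a 10 s
time constant — to 5 Hz), z-scored and decimated to 10 Hz; raw nerve
recordings are band-passed with an order-398 equiripple FIR (300–4000 Hz,
delay-compensated by the 199-sample group delay), z-scored, full-wave
rectified and leaky-integrated ($\tau$ = 100 ms, with a $(1-\alpha)$ input
weight so a constant envelope is reproduced at unit gain), then decimated.
Rectification precedes integration because a zero-mean band-passed signal
would otherwise integrate to nothing. All filtering is causal single-pass:
the model's latency parameters ($\mu$, $\vartheta_4$) absorb constant
delays, and zero-phase filtering would make the observation model
(forward-filtering of predictions) inconsistent with the data.

Piecewise linear detrending of the nerve envelope (`piecewise_detrend()`,
independent OLS lines on 5 s windows) is implemented and tested, but the
pipeline default leaves it off (`detrend_window = NULL`). The reason is
quantitative: per-window OLS forces every window of the input to integrate
to zero, and the SCRF is slow (dominant time constant ~10–17 s for the
canonical sets), so the convolution of the detrended envelope loses
precisely the content the model must predict. On an exactly-LTI synthetic
dataset, enabling the 5 s detrend drops canonical explained variance from
~94% to ~23% and corrupts the fitted response shape. Baseline drift — the
step's purpose — is already removed by the 0.0159 Hz high-pass inside the
observation model. Users wanting the fully traditional chain can set
`detrend_window = 5`.

Epochs are half-open windows from 5 s before to 25 s after each onset
(300 samples at 10 Hz), minimum-corrected so the modelled response sits on
a zero baseline (conductance level maintained without SN firing carries no
event information). Averages over all epochs of an event type (pooled, or
per subject) provide the canonical and subject-level estimation targets.

## The derivative-recording device

The stimulation experiment's conductance was recorded by an AC-coupled
amplifier with a 0.3 s rise time constant, a 3 s decay constant, and a
0.7 Hz acquisition high-pass. `emulate_derivative_recorder()` models this
as three first-order causal sections — low-pass at $1/(2\pi \cdot 0.3)$ Hz,
high-pass with $\tau = 3$ s, high-pass at 0.7 Hz — with *no* explicit
differencing: in the conductance band ($f \ll 0.7$ Hz) the AC coupling
itself acts as the differentiator, $|H(f)| \approx f/0.7$, which is what
the mean-subtract-and-cumulative-sum reconstruction
(`reconstruct_scr_from_derivative()`) subsequently inverts. Two
consequences are worth knowing:

* Reconstruction recovers the *shape* of responses well enough for
  model fitting (the stimulation pipeline reaches the noise ceiling), but
  an AC-coupled device is blind below its slowest high-pass corner
  (~0.05 Hz): the slowly accumulating conductance level under sustained
  stimulation is not recoverable, so the raw correlation between a
  reconstructed trace and the true conductance is modest (~0.3–0.8
  depending on how much sub-corner content the signal carries). This is
  an information-theoretic property of the hardware, not an
  implementation artifact.
* In the stimulation pipeline, each constant-rate epoch is sliced from
  the device channel and reconstructed independently, so the data chain
  and the prediction-side observation transform share identical boundary
  handling; slices are scaled by a subject-level (not per-epoch) standard
  deviation so gains stay comparable across a subject's epochs.

## The synthetic-data generator

`generate_dataset()` builds two study designs with full ground truth:

* **Recording style (`exp1`)**: 6 subjects, 20 aversive and 10 oddball
  events each, onsets at least 30 s apart (plus up to 10 s uniform
  jitter) so response tails are unambiguous. Each subject carries an SN
  envelope channel and a conductance channel. Spontaneous sudomotor
  activity (white, 10% of the burst peak) appears in the nerve channel
  *and* drives the conductance — the world is LTI end-to-end — while a
  separate non-sudomotor interference term (5% of the burst peak)
  contaminates the nerve channel only, emulating neighbouring vasomotor
  or piloerector fibers that fire without sweating. That interference,
  not measurement noise, is what keeps recording-style explained variance
  below 100%, mirroring the interpretation of lower explained variance in
  intraneural recording than in stimulation.
* **Stimulation style (`exp2`)**: 4 subjects sharing 15 constant-rate
  epochs (six at ~0.1 Hz, three at ~0.2 Hz, one each at ~0.5 and ~1 Hz,
  two at ~1.5 Hz, two at ~10 Hz), with ~39 / ~77 / ~180 stimulations per
  epoch in the low / medium / high ranges and inter-stimulus jitter of up
  to 5%. Each subject carries the derivative-device output; the pre-device
  conductance is kept in the truth record.

Shared structure: response-function truth defaults to the canonical
coefficients (recording style: aversive set; stimulation style: low-rate
set), with log-scale between-subject spread 0.1 on $\vartheta_{1..3}$ and
0.1 s on $\vartheta_4$ — enough to make subject-specific response
functions genuinely better than the canonical one, as observed. Gains are
log-normal between epochs (SD 0.3) so they keep their sign, with an
optional additive repetition trend. Measurement noise is white Gaussian at
5% of the clean signal SD; baseline drift is a 0.005 Hz sinusoid at 10%
of signal SD (below the 0.0159 Hz high-pass, so preprocessing removes
it). Noise levels are calibration choices for a plausible laboratory
recording, not claims about any particular dataset.

The **gain-depletion nonlinearity** (`apply_depletion()`) emulates the
high-rate breakdown: each burst multiplies an availability state by
$1-\delta$ ($\delta = 0.3$) and the state relaxes back to 1 with
$\tau_{rec} = 20$ s. These defaults make the nonlinearity negligible at
0.1–0.2 Hz (inter-stimulus intervals long relative to $\tau_{rec}$ leave
gains within a few percent of nominal) and strong above 1 Hz, so fitted
response functions at high stimulation rates diverge from the truth — the
direction the analysis must detect. It is enabled by default for the
stimulation style.

What the generator does **not** emulate: realistic residual noise spectra
(real electrodermal noise is not white), motion and electrode artifacts
beyond simple clipping, nonstationary baseline dynamics, true multi-unit
spike statistics (the optional 10 kHz raw-nerve channel is band-limited
noise under a Gaussian envelope, sufficient only to exercise the FIR and
integrator), or physiological between-day variability. Passing tests
therefore show that the estimation machinery is correct and
well-calibrated under the stated statistical structure — not that real
recordings satisfy it.

## Problem sizes

Tests and the acceptance script run the stimulation pipeline with 12
stimulations per epoch and 2–6 epochs (well within the 10–58 per-epoch
range the design allows), the recording pipeline with 3–4 subjects and
6–13 events each, 50 random systems for the pathway-equivalence check,
and 400 s horizons for steady-state and impulse-integral limits. The
analysis scripts under `analysis/` run the full-size designs.

## Known limitations

* Gain-trend inference uses OLS with fixed subject intercepts, a
  deliberate simplification of a mixed-effects analysis; its standard
  errors ignore within-subject correlation beyond the intercept.
* Under the negative-gain sign convention, a declining physical gain
  appears as a positive slope of the (negative) fitted gains over
  repetitions; interpret trends with the sign convention in mind, or on
  gain magnitudes.
* Explained variance is measured in the analyzed (filtered, possibly
  device-recorded) signal domain — the only domain available for real
  data. Chains that reweight the signal-to-noise spectrum move the
  attainable ceiling accordingly.
* `compare_scrf_to_reference()` reports the best integer-sample alignment
  within ±5 s; for response functions differing mainly by conduction
  delay this is intended, but it can flatter genuinely different shapes
  by up to one sample of residual misalignment.
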