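---
title: "Methods: pupillometry and microsaccade analysis in oculodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pupillometry and microsaccade analysis in oculodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oculodyn)
```

# Overview

`oculodyn` analyses concurrently recorded pupil dilation (PD) and
microsaccades (MS) from speech-in-noise listening experiments with a
high-load (HL) and a low-load (LL) condition. This vignette documents the
models and procedures, the parameters that matter and their defaults, what
the synthetic-data generator does and does not emulate, the numerical
conventions, and the package's known limitations. Everything stated here
about behaviour is computed by the test suite or by `scripts/acceptance.R`;
nothing is asserted from memory.

# The microsaccade detector

Detection follows the Engbert–Kliegl velocity-threshold family of
algorithms. Gaze velocity is estimated with the 5-sample moving window

$$v_n = \frac{x_{n+2} + x_{n+1} - x_{n-1} - x_{n-2}}{6\,\Delta t},$$

which is exact on linear signals and suppresses sample-to-sample jitter.
Any velocity sample whose window overlaps missing data (blinks, series
boundaries) is masked, and candidate runs touching masked samples are
discarded rather than truncated — a run of unknown extent cannot be
duration-tested fairly.

The threshold is relative: per axis, per eye, per *subject block*,
$\sigma = \sqrt{\mathrm{median}(v^2) - \mathrm{median}(v)^2}$, and a
sample is above threshold when
$(v_x/\lambda\sigma_x)^2 + (v_y/\lambda\sigma_y)^2 > 1$ with
$\lambda = 6$. Because the threshold scales with the data, the detector is
invariant to a global rescaling of gaze units (a property the test suite
asserts), which is why the package never needs a pixel-to-degree
conversion.

Admission criteria: above-threshold duration in [5, 100] ms; binocular
onset disparity strictly below 10 ms (greedy chronological pairing,
earliest unpaired partner first); successive onsets strictly more than
50 ms apart (chronological scan, earlier event wins). A paired binocular
event spans the union interval of its monocular parts, with amplitude and
peak velocity averaged over eyes. Amplitude is the integrated-velocity
displacement over the run, which equals the endpoint displacement of the
position trace for the estimator above.

Boundary conventions are exactly as printed in the definitions: strict
`<` for disparity, strict `>` for the inter-event interval; comparisons
carry a 1-ns guard so that floating-point representation of, e.g., an
exactly-50-ms gap does not flip the decision.

# Rate estimation

Event onsets become unit pulses on the epoch grid. Per condition and
participant, pulses are summed across trials and normalized by trial
count and sampling rate, giving an events-per-second density, then
convolved with the causal kernel

$$\omega(\tau) = \alpha^2 \tau e^{-\alpha\tau},$$

discretized on the sample grid and renormalized to unit mass
($\sum\omega\,\Delta t = 1$). The package parameterizes the kernel by its
characteristic time $1/\alpha$, 150 ms by default: $\omega$'s argument
$\alpha\tau$ must be dimensionless, so a "150 ms" decay constant can only
be the kernel's peak/decay *time*, not $\alpha$ itself. The kernel peaks
at $\tau = 1/\alpha$ with height $\alpha e^{-1} \approx 2.4525$ per
second, and the rate's time axis is shifted earlier by $1/\alpha$ so the
smoothed response to a pulse at $t_0$ peaks at $t_0$ — both facts are
asserted in closed form by the tests.

Numerical choices: the default kernel support is $20/\alpha$ (truncated
tail mass $\approx 4\times10^{-8}$); supports shorter than $10/\alpha$ or
with tail mass above $10^{-6}$ are rejected. Convolution treats the epoch
start as silence (zero-padding), not as missing data, so the early epoch
is a genuine warm-up from zero rather than `NA`.

## Edge bias of the causal kernel

One consequence of causal smoothing deserves emphasis, because the test
suite measures it. About 74% of $\omega$'s mass lies *after* its peak, so
even after the peak-shift correction, a step change in the underlying
rate at time $t_0$ is spread forward: at $t_0 + 0.2$ s roughly a third of
the pre-change rate still leaks into the estimate, decaying with the
150-ms time constant. In the end-to-end recovery experiment (a programmed
50% HL rate dip over [1.5, 2.8] s at full study scale), the bootstrap
significance interval therefore starts on time (unbiased onset edge,
observed within ±0.1 s of 1.5 s) but ends late, roughly 0.3 s after the
true dip offset. The corresponding acceptance expectation (offset edge
within ±0.2 s) is left failing deliberately: the bias is a property of
the smoothing method itself, with the magnitude predicted by the kernel
mass calculation above, and is the honest outcome at this power. Users
comparing recovery-interval edges against programmed changes should
expect offset edges to trail by 1–3 kernel time constants, more so at
higher statistical power.

# Pupil preprocessing

The chain runs in a fixed order: fixation-break/blink masking → epoching
→ sparse-epoch rejection → interpolation → outlier-trial rejection →
per-participant z-scoring → (optional) baseline correction → averaging.
The test suite compares the composed chain against an independently coded
straight-line implementation on random fixtures.

* **Masking.** Only the analysed eye (left by default) feeds the pupil
  chain. Samples farther than 100 pixels (strict `>`) from the fixation
  center, or already invalid, are missing. Participants with more than
  50% missing data overall (strict `>`) are excluded.
* **Epoching.** Half-open windows $[-2, 5.5)$ s around noise onset: 7500
  samples at 1000 Hz. Onsets falling between samples align to the
  nearest sample. Epochs with more than 50% missing data are discarded.
* **Interpolation.** Linear between nearest valid neighbours; edge gaps
  hold the nearest valid value (no extrapolation).
* **Outlier trials.** Per time point, mean and SD over the surviving
  trials of the trial's own condition, computed after interpolation and
  before z-scoring (the only reading computable trial-by-trial); a trial
  is dropped when at least 10% of its samples deviate by more than 3 SD.
  Whether the original procedure applied this rule to raw or
  baseline-corrected data is not stated anywhere; this package's choice
  is documented, not attributed.
* **z-scoring.** One mean and SD per participant over all retained
  samples of both conditions pooled — not per time point. Pooled
  transformed data has mean 0, SD 1 (asserted to 1e-9). A consequence
  worth knowing: absolute programmed effects (e.g. a 0.3-unit tonic
  offset) are rescaled by the participant's pooled SD, so recovery
  checks against absolute ground truth use the non-z-scored condition
  means that `run_pipeline()` also returns (`pd_traces_raw`).
* **Baseline correction.** Per-trial subtraction of the $[-0.2, 0)$ s
  window mean; the post-hoc baseline mean is zero to 1e-12.

Summary measures: `pd_peak()` is a plain argmax in a search window (ties
to the earliest sample); `pd_load_effect()` is the mean HL−LL difference
over the closed [2, 5] s window; `blink_rate()` is the fraction of trials
missing at each time point, from the pre-interpolation masks.

# Bootstrap inference

For each participant the HL−LL difference trace is computed; iterations
resample participants with replacement and store the across-participant
mean trace. A time point is significant when the fraction of iteration
means strictly above (or strictly below) zero exceeds the criterion,
0.99 by default. Read literally this is two one-sided 1% tests — a
nominal two-sided level near 2% — and the `criterion` argument accepts
0.995 for a strict two-sided 1%. Iteration means exactly at zero count in
neither tail (conservative). No correction across time points is applied,
matching the procedure the package reproduces; with ~2% pointwise
false-positive rate over a 7500-sample epoch, isolated spurious runs at
the smoothing correlation scale are expected, which is why
`significant_intervals()` exposes a minimum-run-length filter. The null
calibration (31 participants, 200 independent standard-normal time
points, 1000 iterations, 50 replicates) lands near the nominal 2% and is
checked to lie in [0.005, 0.05] on average.

# The staircase

One-up-one-down, starting at 20 dB SNR; steps 12, 8, 5 dB, then a 2 dB
floor. Conventions that the printed procedure leaves open, fixed here and
verified by a hand-simulated alternating-observer track
(20, 8, 16, 11, 13, 11, 13, 11 with reversal SNRs 8, 16, 11, 13, 11, 13,
11 and threshold 12 dB):

* a reversal is attributed to the trial at which the induced direction
  changes, and that trial's SNR is the reversal SNR;
* the step size drops immediately after a reversal is logged, so the
  move *away* from a reversal trial already uses the reduced step;
* the first trial establishes no direction, so the earliest possible
  reversal is at trial 2;
* no SNR clamping by default (a configurable clamp exists, off).

Termination after 7 reversals or 25 trials, whichever first; threshold =
mean of the final 4 reversal SNRs, `NA` (an explicit sentinel, not an
error) when fewer than 4 reversals occurred — the printed procedure does
not say what was done in that case. The simulated observer is logistic
with guess rate 1/48 (the color-by-number chance level of the 48-item
response set); its analytic 50% point is
$\theta + s\ln(1 - 2\gamma)$, slightly *below* the latent threshold
because guessing helps, and staircase recovery is validated against the
root of $p(\mathrm{snr}) = 0.5$ found numerically.

# The synthetic-data generator

Defaults are the study conditions the analysis chain targets: 1000 Hz
binocular sampling; trials with noise onset at 0 s, sentence 0.5–2.6 s,
silence to 5.5 s, recorded from −2 s (pre-roll) to 6 s; 31 participants,
30 trials per condition in counterbalanced blocks; epoch window
$[-2, 5.5)$ s.

* **Drift**: mean-reverting random walk (AR(1), innovation SD $10^{-3}$
  gaze-units/sample, coefficient 0.998), common to both eyes plus 30%
  independent per-eye noise.
* **Microsaccades**: inhomogeneous Poisson onsets (base 1.5 events/s —
  the physiological 1–2 Hz band — times an optional
  `ms_rate_profile(t, condition)` modulation) with a 100-ms refractory
  dead time; raised-cosine velocity pulses (smooth, zero endpoint
  velocity; peak velocity $2A/D$), uniform direction, amplitude
  0.2–1.0 gaze-units, duration 10–40 ms, binocular disparity uniform in
  [0, 5] ms. Every injected event satisfies the detector's admission
  rules by construction, so detector recall on strong injections is a
  fair test. The injection process is validated against an independent
  per-sample thinning simulation.
* **Blinks**: Poisson at 4/min, 100–300 ms, invalidating both eyes and
  the pupil. **Gaze excursions**: smooth out-and-back displacements of
  150–300 units at 0.5/min — large enough to trip the 100-pixel fixation
  rule, too slow (0.4–1 s) to pass the 100-ms duration criterion.
* **Pupil**: participant baseline (SD 0.2) + condition tonic offset
  (HL 0.3, LL 0) + gamma-shaped phasic bump
  $h(t) \propto (t/t_p)^{10} e^{10(1 - t/t_p)}$ rising from sentence
  onset with peak latencies HL 3.09 s, LL 2.78 s and amplitudes HL 0.6,
  LL 0.4 — reproducing the monotonic-rise, post-offset-peak morphology —
  plus slow AR(1) noise (stationary SD 0.3, coefficient 0.998,
  correlation time ≈ 0.5 s, the vasomotor/respiratory scale that
  dominates pupil noise). The bump shape 10 follows the canonical
  Hoeks–Levelt pupil impulse-response shape ($n \approx 10.1$).
* **Per-participant variability**: pupil baseline, lognormal MS-rate
  multiplier (CV 0.2), and speech-reception threshold (mean 5, SD 3 dB)
  for staircase observers.

A design note on peak-latency recovery: with a realistically broad bump
and realistic noise, the group-average argmax at 31-participants × 30-trials
scale has an intrinsic jitter of roughly 0.1–0.15 s (95th percentile,
measured by direct simulation of the group trace for shapes 4–12 and a
range of noise settings). The ±100 ms recovery check in the acceptance
suite therefore sits near the edge of what the study design can deliver;
it passes at the frozen seed, but users should not expect group argmax
latencies to be much more precise than ±0.1 s at this scale — a caveat
that applies equally to real data of this size.

What the generator does **not** emulate: saccadic main-sequence
amplitude–velocity–duration coupling beyond the $2A/D$ relation; MS
direction statistics (directions are uniform; the analyses pool over
direction); pupil foreshortening or luminance responses; tracker
measurement noise models beyond drift; overshoots ("dynamic overshoot")
in the saccade waveform. Passing tests on synthetic data therefore show
that the chain is correct and recovers programmed effects under
plausible statistics — not that real recordings meet those statistics.

# Problem sizes used by the tests

The unit suites run on small fixtures (tens of trials, reduced sampling
rates where the arithmetic allows). The end-to-end recovery experiment
runs at the full default scale (31 participants × 60 trials, 1000
bootstrap iterations, ≈ 1 minute), the detector round-trip and
recall/precision suites on 90–100 five-second fixation trials (≈ 500+
injected events), and the bootstrap calibration on 50 replicates of a
31 × 200 null. These sizes are the package's validation design; the
acceptance script re-runs the two headline computations (staircase trial
cap; fixation-rate round trip on 100 trials) from scratch under a
caller-supplied seed.

# Known limitations

* EDF binary parsing is out of scope; the ASC-style dialect (integer-ms
  timestamps, left-then-right sample columns, `.` for invalid fields,
  `MSG` events) and a canonical CSV are the supported formats.
* The pointwise bootstrap applies no multiple-comparison correction, by
  design fidelity; interval-level interpretation should use
  `significant_intervals()` with a minimum length.
* Detection assumes stationary velocity noise within a subject block
  (one σ per block); slow drifts in noise level would dilute the
  threshold.
* The causal-kernel offset-edge bias discussed above applies to any
  step-like rate change.
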