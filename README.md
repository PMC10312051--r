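# oculodyn

Concurrent pupillometry and microsaccade analysis for effortful-listening
experiments.

When people listen to speech in noise, the effort they deploy shows up in
their eyes in two complementary ways: **pupil dilation** (PD) tracks
arousal — a tonic (baseline) component plus a phasic, sentence-evoked bump
that rises from sentence onset and peaks after sentence offset — while the
rate of **microsaccades** (MS, the small involuntary fixational saccades
that occur at roughly 1–2 per second) drops transiently exactly when the
demand on instantaneous auditory attention is highest. `oculodyn`
implements the full analysis chain that turns raw binocular eye-tracker
samples into condition-level PD curves, smoothed MS-rate curves, and
bootstrap significance masks for the contrast between high-load (HL) and
low-load (LL) listening conditions, together with a synthetic-data
generator with known ground truth and a simulator of the adaptive
speech-reception-threshold procedure used to set the load conditions.

It is intended for researchers analysing such experiments, for method
validation on simulated recordings, and as a tested reference
implementation of the individual processing steps.

## What is implemented

**Microsaccade detection** (`detect_microsaccades()`) follows the
Engbert–Kliegl velocity-threshold approach with four admission criteria:

1. gaze velocity, estimated by the 5-sample moving window
   `v_n = (x_{n+2} + x_{n+1} − x_{n−1} − x_{n−2}) / (6Δt)`, exceeds
   λ = 6 times the median-based standard deviation
   `σ = sqrt(median(v²) − median(v)²)` per axis, per eye, per subject
   (elliptical criterion `(v_x/λσ_x)² + (v_y/λσ_y)² > 1`);
2. the above-threshold run lasts between 5 and 100 ms;
3. the event appears in both eyes with onset disparity < 10 ms;
4. successive events are separated by more than 50 ms.

**Rate estimation** (`rate_estimate()`): detected events become unit
pulses, are summed across trials and normalized by trial count and
sampling rate, then convolved with the causal kernel

    ω(τ) = α² τ e^(−ατ),   1/α = 150 ms,

normalized to unit mass; the time axis is shifted earlier by the kernel
peak time 1/α so the response to a pulse at t₀ peaks at t₀.

**Pupil preprocessing** (`mask_fixation_breaks()`, `clean_epochs()`,
`zscore_participant()`, `baseline_correct()`, `condition_mean()`): left-eye
samples outside a 100-pixel fixation radius or inside blinks are treated
as missing; epochs (−2 to 5.5 s around noise onset) with > 50% missing
data are discarded; remaining gaps are linearly interpolated; trials with
≥ 10% of samples deviating > 3 SD from the per-time-point condition mean
are removed; data are z-scored per participant across both conditions
pooled, optionally baseline-corrected to the [−0.2, 0) s window, and
averaged per condition. Summary measures: peak latency/amplitude
(`pd_peak()`), the 2–5 s load effect (`pd_load_effect()`), and
missing-data incidence (`blink_rate()`).

**Inference** (`bootstrap_mask()`): the HL−LL difference time series, one
per participant, is resampled over participants with replacement (1000
iterations); a time point is significant when more than 99% of iteration
means fall above (or below) zero. `significant_intervals()` extracts the
contiguous significant runs.

**Threshold procedure** (`run_staircase()`): one-up-one-down staircase
starting at 20 dB SNR with steps 12, 8, 5 dB (shrinking after each
reversal) to a 2 dB floor, ending after 7 reversals or 25 trials; the
threshold is the mean SNR of the final four reversals. A logistic
`observer_model()` (guess rate 1/48, the CRM color-by-number chance
level) supplies simulated responses.

**Synthesis** (`sim_config()`, `simulate_experiment()`,
`simulate_fixation_block()`): binocular fixational drift with
raised-cosine-velocity microsaccades injected from a refractory Poisson
process, blinks, gaze excursions, and per-trial pupil traces with
condition-dependent tonic offsets and gamma-shaped phasic bumps — all with
exported ground truth, so every downstream stage can be validated.

`run_pipeline()` chains all stages over a simulated multi-participant
experiment and writes traces, rates, masks and a manifest as CSV/JSON.

## Worked example

```r
library(oculodyn)
set.seed(20)

cfg <- sim_config(n_participants = 4, n_trials_per_condition = 8)
sim <- simulate_participant(cfg, "P01")
sim$recording
#> <gaze_recording> 128000 samples @ 1000 Hz [0.000, 127.999] s, 16 events
#>   invalid: left 1.3%, right 1.3%

events <- detect_microsaccades(mask_fixation_breaks(sim$recording))
head(events, 3)
#>   onset offset duration_ms peak_velocity amplitude       eye
#> 1 0.463  0.497          34      32.98672 0.6287042 binocular
#> 2 0.967  1.000          33      32.95354 0.6366251 binocular
#> 3 1.317  1.329          12      66.52975 0.4564922 binocular

rate_estimate(ms_pulse_epochs(events, sim$trials$onset_s))
#> <rate_series> 7500 samples, axis [-2.150, 5.349] s, alpha = 6.667 /s (peak 150 ms), 16 trials
#>   mean rate 1.172 events/s

run_staircase(observer_model(threshold_db = 5, slope_db = 2))
#> <staircase_result> 10 trials, 7 reversals, terminated by reversals
#>   threshold: 5.50 dB
```

The 16 trial-onset events mark the participant's two 8-trial blocks; the
157 detected events over 128 s of recording give the expected fixation
rate of roughly 1.2 events/s, and the staircase estimate (5.50 dB) sits
next to the simulated observer's 5 dB threshold.

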