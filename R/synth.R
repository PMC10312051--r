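#' Simulation configuration
#'
#' Parameters of the synthetic binocular eye-tracking experiment: trial
#' timing, fixational drift, microsaccade injection, blinks, gaze excursions,
#' pupil dynamics, and per-participant variability. Defaults reproduce the
#' study conditions the analysis chain is designed for: 1000 Hz binocular
#' sampling, trials with noise onset at 0 s, sentence from 0.5 to 2.6 s and a
#' silent period to 5.5 s, analysis epochs from -2 to 5.5 s, 31 participants
#' with 30 trials in each of a high-load (HL) and low-load (LL) condition,
#' and a physiological microsaccade incidence of 1-2 events/s.
#'
#' Gaze is in abstract "gaze-units" scaled so that 1 unit is roughly 1 pixel;
#' the velocity-threshold detector is relative (lambda times a robust SD), so
#' units cancel. `ms_rate_profile`, if given, is a
#' `function(time_s, condition)` returning a nonnegative multiplicative
#' modulation of the base microsaccade rate over trial time.
#'
#' @param sampling_rate Hz.
#' @param pre_roll,noise_onset,sentence_onset,sentence_offset,trial_end
#'   Trial layout in seconds relative to noise onset; samples are generated
#'   out to `trial_end + post_pad` so the analysis epoch is fully covered.
#' @param post_pad Seconds of extra recording after `trial_end`.
#' @param n_trials_per_condition,n_participants Design size.
#' @param conditions Condition labels; the first is the high-load condition.
#' @param drift_sd Random-walk drift innovation SD, gaze-units per sample.
#' @param drift_rho Mean-reversion coefficient of the drift (AR(1)).
#' @param ms_base_rate Baseline microsaccade rate, events/s (physiological
#'   range 1-2).
#' @param ms_rate_profile Optional `function(time_s, condition)` rate
#'   modulation; `NULL` means constant 1.
#' @param ms_amplitude_range Injected amplitude range, gaze-units.
#' @param ms_duration_range Injected duration range, ms; must lie in
#'   \[5, 100\].
#' @param refractory Minimum separation between injected onsets, ms; must
#'   exceed 50 ms so ground truth survives the inter-event rule.
#' @param max_disparity_ms Upper bound of the uniform injected binocular
#'   onset disparity, ms.
#' @param blink_rate Blinks per minute.
#' @param blink_duration_range Blink duration range, ms.
#' @param excursion_rate Gaze excursions (looks away from fixation) per
#'   minute.
#' @param excursion_amplitude_range,excursion_duration_range Excursion size
#'   (gaze-units) and total out-and-back duration (s).
#' @param pupil_tonic Named per-condition tonic pupil offset (z-units).
#' @param pupil_phasic_amp Named per-condition phasic bump amplitude
#'   (z-units).
#' @param pupil_phasic_peak_latency Named per-condition peak latency of the
#'   phasic bump, seconds post noise onset.
#' @param pupil_phasic_shape Shape parameter of the gamma-shaped bump.
#' @param noise_sd Stationary SD of the AR(1) pupil noise (z-units).
#' @param noise_rho AR(1) coefficient of the pupil noise.
#' @param participant_tonic_sd SD of the per-participant pupil baseline.
#' @param participant_ms_rate_cv Lognormal CV of per-participant MS base
#'   rate.
#' @param participant_threshold_mean,participant_threshold_sd Distribution of
#'   per-participant speech-reception thresholds (dB SNR), used by the
#'   staircase observers.
#' @param seed Integer seed; required by [simulate_experiment()].
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(sampling_rate = 1000,
                       pre_roll = -2, noise_onset = 0, sentence_onset = 0.5,
                       sentence_offset = 2.6, trial_end = 5.5,
                       post_pad = 0.5,
                       n_trials_per_condition = 30, n_participants = 31,
                       conditions = c("HL", "LL"),
                       drift_sd = 1e-3, drift_rho = 0.998,
                       ms_base_rate = 1.5, ms_rate_profile = NULL,
                       ms_amplitude_range = c(0.2, 1.0),
                       ms_duration_range = c(10, 40),
                       refractory = 100, max_disparity_ms = 5,
                       blink_rate = 4, blink_duration_range = c(100, 300),
                       excursion_rate = 0.5,
                       excursion_amplitude_range = c(150, 300),
                       excursion_duration_range = c(0.4, 1.0),
                       pupil_tonic = c(HL = 0.3, LL = 0),
                       pupil_phasic_amp = c(HL = 0.6, LL = 0.4),
                       pupil_phasic_peak_latency = c(HL = 3.09, LL = 2.78),
                       pupil_phasic_shape = 10,
                       noise_sd = 0.3, noise_rho = 0.998,
                       participant_tonic_sd = 0.2,
                       participant_ms_rate_cv = 0.2,
                       participant_threshold_mean = 5,
                       participant_threshold_sd = 3,
                       seed = NULL) {
  cfg <- as.list(environment())
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (pre_roll > -2 || trial_end < 5.5) {
    stop("trial layout must cover the [-2, 5.5] s analysis epoch")
  }
  if (ms_duration_range[1] < 5 || ms_duration_range[2] > 100 ||
      diff(ms_duration_range) < 0) {
    stop("ms_duration_range must lie within [5, 100] ms")
  }
  if (refractory <= 50) stop("refractory must exceed 50 ms")
  nonneg <- c(drift_sd, ms_base_rate, blink_rate, excursion_rate, noise_sd,
              participant_tonic_sd, participant_ms_rate_cv,
              n_trials_per_condition, n_participants)
  if (any(nonneg < 0)) stop("rates, SDs and counts must be nonnegative")
  if (!is.null(ms_rate_profile) && !is.function(ms_rate_profile)) {
    stop("ms_rate_profile must be NULL or a function(time_s, condition)")
  }
  for (f in c("pupil_tonic", "pupil_phasic_amp",
              "pupil_phasic_peak_latency")) {
    if (!all(conditions %in% names(cfg[[f]]))) {
      stop(f, " must be named for every condition")
    }
  }
  if (any(pupil_phasic_peak_latency <= sentence_onset |
          pupil_phasic_peak_latency >= trial_end)) {
    stop("pupil_phasic_peak_latency must lie inside the trial window")
  }
  structure(cfg, class = "sim_config")
}

#' Psychometric observer
#'
#' A logistic observer for the speech-in-noise task:
#' `p(correct) = guess + (1 - guess - lapse) * logistic((snr - threshold)/slope)`.
#' The default guess rate is 1/48, the chance level of a
#' color-by-number response set with 48 combinations.
#'
#' @param threshold_db Midpoint of the latent logistic, dB SNR.
#' @param slope_db Logistic scale parameter, dB.
#' @param guess_rate,lapse_rate Asymptote parameters, probabilities.
#' @return A list of class `observer_model`.
#' @export
observer_model <- function(threshold_db, slope_db = 2,
                           guess_rate = 1 / 48, lapse_rate = 0) {
  if (slope_db <= 0) stop("slope_db must be positive")
  if (guess_rate < 0 || guess_rate >= 1) stop("guess_rate must be in [0, 1)")
  if (lapse_rate < 0 || lapse_rate >= 1 - guess_rate) {
    stop("lapse_rate must be in [0, 1 - guess_rate)")
  }
  structure(list(threshold_db = threshold_db, slope_db = slope_db,
                 guess_rate = guess_rate, lapse_rate = lapse_rate),
            class = "observer_model")
}

#' Probability of a correct response at a given SNR
#'
#' @param observer An [observer_model()].
#' @param snr_db SNR in dB (vectorized).
#' @return Probability of a correct response; nondecreasing in `snr_db`.
#' @export
psychometric_p <- function(observer, snr_db) {
  o <- observer
  o$guess_rate + (1 - o$guess_rate - o$lapse_rate) *
    stats::plogis((snr_db - o$threshold_db) / o$slope_db)
}

#' Draw a Bernoulli response from a psychometric observer
#'
#' @inheritParams psychometric_p
#' @return Logical: correct or not. Uses the current RNG state.
#' @export
psychometric_response <- function(observer, snr_db) {
  stats::runif(length(snr_db)) < psychometric_p(observer, snr_db)
}

# trial sample grid in seconds relative to noise onset
trial_time_axis <- function(config) {
  fs <- config$sampling_rate
  n <- round((config$trial_end + config$post_pad - config$pre_roll) * fs)
  config$pre_roll + (seq_len(n) - 1) / fs
}

# AR(1) drift track of length n
ar1_track <- function(n, sd, rho) {
  as.numeric(stats::filter(stats::rnorm(n, 0, sd), rho,
                           method = "recursive"))
}

# draw injected microsaccade onsets: inhomogeneous Poisson (thinning) with a
# dead time of `refractory` ms after each accepted event
draw_ms_onsets <- function(config, condition, t_start, t_end) {
  base <- config$ms_base_rate
  if (base <= 0) return(numeric())
  prof <- config$ms_rate_profile
  grid <- seq(t_start, t_end, by = 0.01)
  pmax_val <- if (is.null(prof)) 1 else max(prof(grid, condition), 0)
  if (pmax_val <= 0) return(numeric())
  lambda_max <- base * pmax_val
  refr <- config$refractory / 1000
  onsets <- numeric()
  t <- t_start
  last <- -Inf
  repeat {
    t <- t + stats::rexp(1, lambda_max)
    if (t > t_end) break
    p_keep <- if (is.null(prof)) 1 else max(prof(t, condition), 0) / pmax_val
    if (stats::runif(1) < p_keep && t - last >= refr) {
      onsets <- c(onsets, t)
      last <- t
    }
  }
  onsets
}

# raised-cosine velocity pulse sampled at fs; returns per-sample velocity
rc_velocity <- function(n_samp, amplitude, dur_s) {
  tt <- (seq_len(n_samp) - 0.5) / n_samp * dur_s
  v_pk <- 2 * amplitude / dur_s
  v_pk * (1 - cos(2 * pi * tt / dur_s)) / 2
}

#' Simulate one trial of binocular gaze during fixation
#'
#' Gaze is a mean-reverting random-walk drift (common to both eyes plus small
#' per-eye noise) with ballistic microsaccades injected from an inhomogeneous
#' Poisson process with a refractory dead time. Each microsaccade has a
#' raised-cosine velocity profile (smooth, zero endpoint velocity), a uniform
#' random direction, and is near-simultaneous in the two eyes (right-eye
#' onset delayed by a uniform 0-`max_disparity_ms` ms). Blinks and gaze
#' excursions are inserted per the configured rates; blink samples are
#' invalid in both eyes.
#'
#' @param config A [sim_config()].
#' @param condition Condition label (selects the rate profile).
#' @param ms_rate_mult Multiplier on the base microsaccade rate (used for
#'   per-participant variability).
#' @return A list with `recording` (a [gaze_recording()] on the trial-relative
#'   time axis), `ms` (data.frame of injected events: onset s, duration_ms,
#'   amplitude, disparity_ms), and `blinks` (data.frame of start/end s).
#'   Uses the current RNG state.
#' @export
simulate_trial_gaze <- function(config, condition = config$conditions[1],
                                ms_rate_mult = 1, time = NULL) {
  fs <- config$sampling_rate
  dt <- 1 / fs
  if (is.null(time)) time <- trial_time_axis(config)
  n <- length(time)
  t0 <- time[1]; t1 <- time[n]

  drift_x <- ar1_track(n, config$drift_sd, config$drift_rho)
  drift_y <- ar1_track(n, config$drift_sd, config$drift_rho)
  eye_noise <- function() ar1_track(n, 0.3 * config$drift_sd,
                                    config$drift_rho)

  cfg_ms <- config
  cfg_ms$ms_base_rate <- config$ms_base_rate * ms_rate_mult
  max_dur_s <- config$ms_duration_range[2] / 1000
  onsets <- draw_ms_onsets(cfg_ms, condition,
                           t0 + 0.01, t1 - max_dur_s - 0.02)
  n_ms <- length(onsets)
  vinj_xl <- vinj_yl <- vinj_xr <- vinj_yr <- numeric(n)
  ms <- data.frame(onset = numeric(), duration_ms = numeric(),
                   amplitude = numeric(), disparity_ms = numeric())
  if (n_ms > 0) {
    dur_ms <- stats::runif(n_ms, config$ms_duration_range[1],
                           config$ms_duration_range[2])
    amp <- stats::runif(n_ms, config$ms_amplitude_range[1],
                        config$ms_amplitude_range[2])
    theta <- stats::runif(n_ms, 0, 2 * pi)
    disp_ms <- stats::runif(n_ms, 0, config$max_disparity_ms)
    for (k in seq_len(n_ms)) {
      dur_s <- dur_ms[k] / 1000
      n_samp <- max(2L, round(dur_s * fs))
      v <- rc_velocity(n_samp, amp[k], dur_s)
      i_l <- round((onsets[k] - t0) * fs) + 1
      i_r <- i_l + round(disp_ms[k] / 1000 * fs)
      idx_l <- i_l:(i_l + n_samp - 1)
      idx_r <- i_r:(i_r + n_samp - 1)
      vinj_xl[idx_l] <- vinj_xl[idx_l] + v * cos(theta[k])
      vinj_yl[idx_l] <- vinj_yl[idx_l] + v * sin(theta[k])
      vinj_xr[idx_r] <- vinj_xr[idx_r] + v * cos(theta[k])
      vinj_yr[idx_r] <- vinj_yr[idx_r] + v * sin(theta[k])
    }
    ms <- data.frame(onset = onsets, duration_ms = dur_ms,
                     amplitude = amp, disparity_ms = disp_ms)
  }

  # gaze excursions: smooth out-and-back displacement away from fixation
  exc_x <- exc_y <- numeric(n)
  n_exc <- stats::rpois(1, config$excursion_rate / 60 * (t1 - t0))
  if (n_exc > 0) {
    for (k in seq_len(n_exc)) {
      dur <- stats::runif(1, config$excursion_duration_range[1],
                          config$excursion_duration_range[2])
      start <- stats::runif(1, t0, t1 - dur)
      a <- stats::runif(1, config$excursion_amplitude_range[1],
                        config$excursion_amplitude_range[2])
      th <- stats::runif(1, 0, 2 * pi)
      idx <- which(time >= start & time < start + dur)
      bump <- a * (1 - cos(2 * pi * (time[idx] - start) / dur)) / 2
      exc_x[idx] <- exc_x[idx] + bump * cos(th)
      exc_y[idx] <- exc_y[idx] + bump * sin(th)
    }
  }

  xl <- drift_x + eye_noise() + cumsum(vinj_xl) * dt + exc_x
  yl <- drift_y + eye_noise() + cumsum(vinj_yl) * dt + exc_y
  xr <- drift_x + eye_noise() + cumsum(vinj_xr) * dt + exc_x
  yr <- drift_y + eye_noise() + cumsum(vinj_yr) * dt + exc_y

  valid <- rep(TRUE, n)
  blinks <- data.frame(start = numeric(), end = numeric())
  n_bl <- stats::rpois(1, config$blink_rate / 60 * (t1 - t0))
  if (n_bl > 0) {
    bl_dur <- stats::runif(n_bl, config$blink_duration_range[1],
                           config$blink_duration_range[2]) / 1000
    bl_start <- stats::runif(n_bl, t0, t1 - bl_dur)
    blinks <- data.frame(start = bl_start, end = bl_start + bl_dur)
    for (k in seq_len(n_bl)) {
      valid[time >= blinks$start[k] & time < blinks$end[k]] <- FALSE
    }
  }
  xl[!valid] <- NA; yl[!valid] <- NA
  xr[!valid] <- NA; yr[!valid] <- NA

  rec <- gaze_recording(xl, yl, pl = rep(NA_real_, n), xr, yr,
                        pr = rep(NA_real_, n),
                        valid_l = valid, valid_r = valid,
                        sampling_rate = fs, time = time)
  list(recording = rec, ms = ms, blinks = blinks)
}

# noiseless phasic pupil template: gamma-shaped bump rising from sentence
# onset, unit peak at `peak_latency`
phasic_template <- function(time, sentence_onset, peak_latency, shape) {
  tp <- peak_latency - sentence_onset
  tt <- pmax(time - sentence_onset, 0)
  (tt / tp)^shape * exp(shape * (1 - tt / tp))
}

#' Simulate one trial's pupil trace
#'
#' Trace = participant baseline + condition tonic offset + gamma-shaped
#' phasic bump (parameterized peak amplitude and latency) + AR(1) noise.
#' Samples inside supplied blink intervals are set to `NA`.
#'
#' @param config A [sim_config()].
#' @param condition Condition label.
#' @param baseline Participant baseline (z-units).
#' @param blinks Optional data.frame of blink intervals (`start`, `end`, s).
#' @return List with `pupil` (numeric trace) and `valid` (logical mask), on
#'   the trial time axis. Uses the current RNG state.
#' @export
simulate_trial_pupil <- function(config, condition = config$conditions[1],
                                 baseline = 0, blinks = NULL) {
  time <- trial_time_axis(config)
  n <- length(time)
  tp <- config$pupil_phasic_peak_latency[[condition]]
  if (tp <= config$sentence_onset || tp >= config$trial_end) {
    stop("phasic peak latency outside the trial window")
  }
  tmpl <- phasic_template(time, config$sentence_onset, tp,
                          config$pupil_phasic_shape)
  trace <- baseline + config$pupil_tonic[[condition]] +
    config$pupil_phasic_amp[[condition]] * tmpl
  if (config$noise_sd > 0) {
    innov_sd <- config$noise_sd * sqrt(1 - config$noise_rho^2)
    trace <- trace + ar1_track(n, innov_sd, config$noise_rho)
  }
  valid <- rep(TRUE, n)
  if (!is.null(blinks) && nrow(blinks) > 0) {
    for (k in seq_len(nrow(blinks))) {
      valid[time >= blinks$start[k] & time < blinks$end[k]] <- FALSE
    }
  }
  trace[!valid] <- NA
  list(pupil = trace, valid = valid)
}

#' Simulate a block of steady-fixation trials
#'
#' Convenience wrapper around [simulate_trial_gaze()] for plain fixation
#' recordings with no task structure: `n_trials` independent segments of
#' `duration_s` seconds each, generated with the configured drift and
#' microsaccade statistics. Blinks default to off (steady-fixation
#' validation blocks exclude them by design).
#'
#' @param config A [sim_config()].
#' @param n_trials Number of fixation segments.
#' @param duration_s Segment duration in seconds.
#' @param blink_rate Blinks per minute for these segments (default 0).
#' @return List with `recordings` (list of [gaze_recording()]) and `ms`
#'   (ground-truth data.frame with a `trial` column). Uses the current RNG
#'   state.
#' @export
simulate_fixation_block <- function(config, n_trials = 100,
                                    duration_s = 5, blink_rate = 0) {
  cfg <- config
  cfg$blink_rate <- blink_rate
  fs <- cfg$sampling_rate
  time <- (seq_len(round(duration_s * fs)) - 1) / fs
  recs <- vector("list", n_trials)
  gt <- list()
  for (i in seq_len(n_trials)) {
    g <- simulate_trial_gaze(cfg, cfg$conditions[1], time = time)
    recs[[i]] <- g$recording
    if (nrow(g$ms) > 0) {
      gt[[length(gt) + 1]] <- cbind(trial = i, g$ms)
    }
  }
  list(recordings = recs, ms = do.call(rbind, c(gt, list(data.frame()))))
}

#' Noiseless programmed pupil curves per condition
#'
#' The generator's ground-truth pupil template (tonic offset + phasic bump,
#' no participant baseline, no noise) evaluated on the trial time axis.
#'
#' @param config A [sim_config()].
#' @return Matrix conditions x time with the trial axis as a `"time"`
#'   attribute.
#' @export
programmed_pd_curves <- function(config) {
  time <- trial_time_axis(config)
  out <- t(vapply(config$conditions, function(cond) {
    config$pupil_tonic[[cond]] + config$pupil_phasic_amp[[cond]] *
      phasic_template(time, config$sentence_onset,
                      config$pupil_phasic_peak_latency[[cond]],
                      config$pupil_phasic_shape)
  }, numeric(length(time))))
  attr(out, "time") <- time
  out
}

# draw per-participant latent parameters (one row per participant)
draw_participants <- function(config) {
  np <- config$n_participants
  data.frame(
    participant = sprintf("P%02d", seq_len(np)),
    baseline = stats::rnorm(np, 0, config$participant_tonic_sd),
    ms_rate_mult = exp(stats::rnorm(np, 0, config$participant_ms_rate_cv)),
    threshold_db = stats::rnorm(np, config$participant_threshold_mean,
                                config$participant_threshold_sd),
    stringsAsFactors = FALSE)
}

#' Simulate one participant's full recording
#'
#' Trials of the two conditions are presented in blocks (condition order
#' alternating with `block_order`), concatenated into one continuous
#' recording with trial-onset event markers.
#'
#' @param config A [sim_config()].
#' @param participant Participant identifier.
#' @param baseline,ms_rate_mult Latent participant parameters.
#' @param block_order Permutation of `config$conditions`.
#' @return List with `recording`, `trials` (data.frame: participant, trial,
#'   condition, onset_s), and ground truth `ms` / `blinks` data.frames (onset
#'   times absolute). Uses the current RNG state.
#' @export
simulate_participant <- function(config, participant = "P01",
                                 baseline = 0, ms_rate_mult = 1,
                                 block_order = config$conditions) {
  fs <- config$sampling_rate
  trial_axis <- trial_time_axis(config)
  block_len <- length(trial_axis) / fs
  conds <- rep(block_order, each = config$n_trials_per_condition)
  nt <- length(conds)
  chans <- c("xl", "yl", "pl", "xr", "yr", "pr")
  acc <- stats::setNames(vector("list", length(chans)), chans)
  valid_l <- valid_r <- vector("list", nt)
  gt_ms <- list(); gt_bl <- list()
  onsets <- numeric(nt)
  for (i in seq_len(nt)) {
    offset <- (i - 1) * block_len - trial_axis[1]  # absolute time of onset
    onsets[i] <- offset
    g <- simulate_trial_gaze(config, conds[i], ms_rate_mult)
    p <- simulate_trial_pupil(config, conds[i], baseline, g$blinks)
    rec <- g$recording
    rec$pl <- p$pupil; rec$pr <- p$pupil
    for (ch in chans) acc[[ch]][[i]] <- rec[[ch]]
    valid_l[[i]] <- rec$valid_l; valid_r[[i]] <- rec$valid_r
    if (nrow(g$ms) > 0) {
      gt_ms[[length(gt_ms) + 1]] <- data.frame(
        participant = participant, trial = i, condition = conds[i],
        onset = g$ms$onset + offset, rel_onset = g$ms$onset,
        duration_ms = g$ms$duration_ms, amplitude = g$ms$amplitude,
        disparity_ms = g$ms$disparity_ms)
    }
    if (nrow(g$blinks) > 0) {
      gt_bl[[length(gt_bl) + 1]] <- data.frame(
        participant = participant, trial = i,
        start = g$blinks$start + offset, end = g$blinks$end + offset)
    }
  }
  events <- data.frame(label = sprintf("TRIAL %d %s", seq_len(nt), conds),
                       time = onsets)
  recording <- gaze_recording(
    unlist(acc$xl), unlist(acc$yl), unlist(acc$pl),
    unlist(acc$xr), unlist(acc$yr), unlist(acc$pr),
    unlist(valid_l), unlist(valid_r),
    events = events, sampling_rate = fs, start_time = 0)
  list(recording = recording,
       trials = data.frame(participant = participant, trial = seq_len(nt),
                           condition = conds, onset_s = onsets,
                           stringsAsFactors = FALSE),
       ms = do.call(rbind, c(gt_ms, list(data.frame()))),
       blinks = do.call(rbind, c(gt_bl, list(data.frame()))))
}

#' Simulate a full multi-participant experiment
#'
#' Draws per-participant latent parameters (pupil baseline, microsaccade
#' rate multiplier, speech-reception threshold), then simulates each
#' participant's continuous recording. Fully reproducible given
#' `config$seed`.
#'
#' @param config A [sim_config()] with `seed` set.
#' @return List with `recordings` (named list of [gaze_recording()]),
#'   `trials` (data.frame across participants), `participants` (latent
#'   parameter table), `ground_truth` (list: `injected_ms`,
#'   `blink_intervals`, `programmed_pd_curves`), and `config`.
#' @export
simulate_experiment <- function(config) {
  if (is.null(config$seed)) stop("config$seed must be set")
  set.seed(config$seed)
  parts <- draw_participants(config)
  recordings <- list()
  trials <- list(); ms <- list(); blinks <- list()
  for (i in seq_len(nrow(parts))) {
    ord <- if (i %% 2 == 1) config$conditions else rev(config$conditions)
    sim <- simulate_participant(config, parts$participant[i],
                                parts$baseline[i], parts$ms_rate_mult[i],
                                block_order = ord)
    recordings[[parts$participant[i]]] <- sim$recording
    trials[[i]] <- sim$trials
    ms[[i]] <- sim$ms
    blinks[[i]] <- sim$blinks
  }
  list(recordings = recordings,
       trials = do.call(rbind, c(trials, list(data.frame()))),
       participants = parts,
       ground_truth = list(
         injected_ms = do.call(rbind, c(ms, list(data.frame()))),
         blink_intervals = do.call(rbind, c(blinks, list(data.frame()))),
         programmed_pd_curves = programmed_pd_curves(config)),
       config = config)
}
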