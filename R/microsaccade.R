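#' Microsaccade detection parameters
#'
#' The four admission criteria of the binocular velocity-threshold detector:
#' (1) velocity above `lambda_threshold` times a median-based SD, (2)
#' above-threshold duration within `[min_duration, max_duration]` ms, (3)
#' detected in both eyes with onset disparity strictly below
#' `max_binocular_disparity` ms, (4) successive events separated by more than
#' `min_inter_event_interval` ms.
#'
#' @param lambda_threshold Velocity threshold in multiples of the
#'   median-based SD (default 6).
#' @param min_duration,max_duration Event duration bounds, ms (5 and 100).
#' @param max_binocular_disparity Pairing window, ms (10, strict `<`).
#' @param min_inter_event_interval Inter-event interval, ms (50, strict `>`).
#' @param velocity_window Samples in the moving-window velocity estimator.
#' @return A validated list of class `detection_params`.
#' @export
detection_params <- function(lambda_threshold = 6, min_duration = 5,
                             max_duration = 100,
                             max_binocular_disparity = 10,
                             min_inter_event_interval = 50,
                             velocity_window = 5) {
  if (lambda_threshold <= 0) stop("lambda_threshold must be positive")
  if (!(min_duration > 0 && min_duration < max_duration)) {
    stop("need 0 < min_duration < max_duration")
  }
  if (max_binocular_disparity <= 0 || min_inter_event_interval <= 0) {
    stop("disparity and inter-event interval must be positive")
  }
  structure(list(lambda_threshold = lambda_threshold,
                 min_duration = min_duration, max_duration = max_duration,
                 max_binocular_disparity = max_binocular_disparity,
                 min_inter_event_interval = min_inter_event_interval,
                 velocity_window = velocity_window),
            class = "detection_params")
}

#' Moving-window gaze velocity
#'
#' The 5-sample weighted velocity estimator
#' `v_n = (x_{n+2} + x_{n+1} - x_{n-1} - x_{n-2}) / (6 dt)`, exact on linear
#' signals and attenuating sample noise. Samples whose 5-sample window
#' overlaps a missing sample (or the series boundary) are velocity-masked.
#'
#' @param recording A [gaze_recording()].
#' @return List with per-eye components `left` and `right`, each holding
#'   `vx`, `vy` (gaze-units/s) and a logical `mask` of unusable samples.
#' @export
compute_velocity <- function(recording) {
  r <- recording
  n <- length(r$time)
  if (n < 5) stop("recording shorter than the velocity window")
  dt <- 1 / r$sampling_rate
  one_axis <- function(x) {
    v <- rep(NA_real_, n)
    idx <- 3:(n - 2)
    v[idx] <- (x[idx + 2] + x[idx + 1] - x[idx - 1] - x[idx - 2]) / (6 * dt)
    v
  }
  one_eye <- function(x, y, valid) {
    bad <- !valid | is.na(x) | is.na(y)
    # window overlap: any missing sample within +/- 2 samples
    mask <- rep(TRUE, n)
    idx <- 3:(n - 2)
    mask[idx] <- bad[idx - 2] | bad[idx - 1] | bad[idx] |
      bad[idx + 1] | bad[idx + 2]
    x0 <- x; y0 <- y
    x0[bad] <- 0; y0[bad] <- 0  # keep arithmetic finite; masked anyway
    list(vx = one_axis(x0), vy = one_axis(y0), mask = mask)
  }
  list(left = one_eye(r$xl, r$yl, r$valid_l),
       right = one_eye(r$xr, r$yr, r$valid_r),
       sampling_rate = r$sampling_rate)
}

#' Median-based standard deviation of a velocity series
#'
#' The robust scale estimate `sigma = sqrt(median(v^2) - median(v)^2)`,
#' computed over all valid samples of a subject's block, per axis.
#'
#' @param v Numeric velocity samples (NAs and masked samples excluded by the
#'   caller or tolerated here).
#' @return The scalar sigma (gaze-units/s).
#' @export
median_sd <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) < 5) stop("need at least 5 valid velocity samples")
  s2 <- stats::median(v^2) - stats::median(v)^2
  if (s2 <= 1e-12^2) stop("degenerate velocity distribution (sigma ~ 0)")
  sqrt(s2)
}

# run-length scan: maximal runs of TRUE; returns data.frame(start, end)
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Monocular microsaccade candidates
#'
#' Applies the elliptical velocity criterion
#' `(vx/(lambda sx))^2 + (vy/(lambda sy))^2 > 1` and keeps maximal
#' above-threshold runs whose duration lies in
#' `[min_duration, max_duration]` ms. Runs touching velocity-masked samples
#' are discarded. Amplitude is the integrated-velocity displacement over the
#' run; peak velocity is the maximal speed.
#'
#' @param vel One eye's component from [compute_velocity()] (`vx`, `vy`,
#'   `mask`).
#' @param sigma Length-2 vector `(sigma_x, sigma_y)` from [median_sd()].
#' @param params A [detection_params()].
#' @param time Sample time axis in seconds.
#' @return data.frame of candidates: `onset`, `offset` (s), `duration_ms`,
#'   `peak_velocity`, `amplitude`.
#' @export
detect_monocular <- function(vel, sigma, params, time) {
  dt <- diff(time[1:2])
  lam <- params$lambda_threshold
  crit <- (vel$vx / (lam * sigma[1]))^2 + (vel$vy / (lam * sigma[2]))^2
  above <- !is.na(crit) & crit > 1 & !vel$mask
  runs <- true_runs(above)
  empty <- data.frame(onset = numeric(), offset = numeric(),
                      duration_ms = numeric(), peak_velocity = numeric(),
                      amplitude = numeric())
  if (nrow(runs) == 0) return(empty)
  n <- length(above)
  # discard runs adjacent to masked samples or the series boundary
  touch <- vapply(seq_len(nrow(runs)), function(i) {
    s <- runs$start[i]; e <- runs$end[i]
    (s == 1 || vel$mask[s - 1]) || (e == n || vel$mask[e + 1])
  }, logical(1))
  runs <- runs[!touch, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)
  dur_ms <- (runs$end - runs$start + 1) * dt * 1000
  keep <- dur_ms >= params$min_duration & dur_ms <= params$max_duration
  runs <- runs[keep, , drop = FALSE]
  dur_ms <- dur_ms[keep]
  if (nrow(runs) == 0) return(empty)
  pk <- amp <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start[i]:runs$end[i]
    pk[i] <- max(sqrt(vel$vx[idx]^2 + vel$vy[idx]^2))
    amp[i] <- sqrt(sum(vel$vx[idx] * dt)^2 + sum(vel$vy[idx] * dt)^2)
  }
  data.frame(onset = time[runs$start], offset = time[runs$end],
             duration_ms = dur_ms, peak_velocity = pk, amplitude = amp)
}

#' Pair monocular candidates into binocular events
#'
#' Greedy chronological pairing: each left-eye candidate pairs with the
#' earliest unpaired right-eye candidate whose onset differs by strictly
#' less than the disparity window. A paired event spans the union interval
#' (onset = earlier onset, offset = later offset) with amplitude and peak
#' velocity averaged over eyes; unpaired candidates are dropped.
#'
#' @param left,right Candidate data.frames from [detect_monocular()],
#'   sorted by onset.
#' @param params A [detection_params()].
#' @return data.frame of binocular events with an `eye = "binocular"`
#'   column.
#' @export
binocular_pair <- function(left, right, params) {
  win <- params$max_binocular_disparity / 1000
  out <- list()
  used <- rep(FALSE, nrow(right))
  for (i in seq_len(nrow(left))) {
    # strict < with a 1-ns guard against floating-point ties
    j <- which(!used & abs(right$onset - left$onset[i]) - win < -1e-9)
    if (length(j) == 0) next
    j <- j[1]
    used[j] <- TRUE
    onset <- min(left$onset[i], right$onset[j])
    offset <- max(left$offset[i], right$offset[j])
    out[[length(out) + 1]] <- data.frame(
      onset = onset, offset = offset,
      duration_ms = (offset - onset) * 1000,
      peak_velocity = mean(c(left$peak_velocity[i],
                             right$peak_velocity[j])),
      amplitude = mean(c(left$amplitude[i], right$amplitude[j])),
      eye = "binocular")
  }
  if (length(out) == 0) {
    return(data.frame(onset = numeric(), offset = numeric(),
                      duration_ms = numeric(), peak_velocity = numeric(),
                      amplitude = numeric(), eye = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$onset), , drop = FALSE]
}

#' Enforce the minimum inter-event interval
#'
#' Chronological scan keeping the earlier event: an event whose onset is at
#' most `min_inter_event_interval` ms after the previous retained event's
#' onset is removed.
#'
#' @param events Event data.frame sorted by onset.
#' @param params A [detection_params()].
#' @return Filtered event data.frame.
#' @export
enforce_imi <- function(events, params) {
  if (nrow(events) <= 1) return(events)
  imi <- params$min_inter_event_interval / 1000
  keep <- logical(nrow(events))
  last <- -Inf
  for (i in seq_len(nrow(events))) {
    # strict > with a 1-ns guard against floating-point ties
    if (events$onset[i] - last - imi > 1e-9) {
      keep[i] <- TRUE
      last <- events$onset[i]
    }
  }
  events[keep, , drop = FALSE]
}

#' Detect binocular microsaccades in a recording
#'
#' Full criteria chain: moving-window velocity, per-axis median-based SD
#' over the whole block (per subject), elliptical monocular threshold with
#' duration bounds, binocular pairing, and the inter-event-interval rule.
#'
#' @param recording A [gaze_recording()].
#' @param params A [detection_params()].
#' @param sigma Optional precomputed list with `left` and `right` length-2
#'   sigma vectors (e.g. from a subject's full block when detecting on
#'   epochs); computed from this recording when `NULL`.
#' @return data.frame of `MicrosaccadeEvent`s: onset, offset (s),
#'   duration_ms, peak_velocity, amplitude, eye.
#' @export
detect_microsaccades <- function(recording, params = detection_params(),
                                 sigma = NULL) {
  empty <- data.frame(onset = numeric(), offset = numeric(),
                      duration_ms = numeric(), peak_velocity = numeric(),
                      amplitude = numeric(), eye = character())
  vel <- compute_velocity(recording)
  if (is.null(sigma)) {
    # an all-masked or motionless block has no velocity distribution to
    # threshold against: nothing can be detected
    sigma <- tryCatch(block_sigma(vel), error = function(e) NULL)
    if (is.null(sigma)) return(empty)
  }
  left <- detect_monocular(vel$left, sigma$left, params, recording$time)
  right <- detect_monocular(vel$right, sigma$right, params, recording$time)
  enforce_imi(binocular_pair(left, right, params), params)
}

#' Per-axis median-based sigma for both eyes of a velocity block
#'
#' @param vel Output of [compute_velocity()] on a subject's block.
#' @return List with `left` and `right` length-2 `(sigma_x, sigma_y)`
#'   vectors.
#' @export
block_sigma <- function(vel) {
  sig <- function(e) c(median_sd(e$vx[!e$mask]), median_sd(e$vy[!e$mask]))
  list(left = sig(vel$left), right = sig(vel$right))
}

#' Pooled median-based sigma across several velocity blocks
#'
#' Computes the per-eye, per-axis median-based SD over the concatenated
#' valid velocity samples of several segments, for the "one sigma per
#' subject" convention when a subject's data comes in separate trials or
#' blocks.
#'
#' @param vels List of [compute_velocity()] outputs.
#' @return List with `left` and `right` length-2 `(sigma_x, sigma_y)`
#'   vectors.
#' @export
pooled_sigma <- function(vels) {
  gather <- function(eye, axis) {
    unlist(lapply(vels, function(v) {
      e <- v[[eye]]
      e[[axis]][!e$mask]
    }))
  }
  list(left = c(median_sd(gather("left", "vx")),
                median_sd(gather("left", "vy"))),
       right = c(median_sd(gather("right", "vx")),
                 median_sd(gather("right", "vy"))))
}

#' Causal rate-smoothing kernel
#'
#' The alpha kernel `w(tau) = alpha^2 tau exp(-alpha tau)` sampled on
#' `tau = 0, dt, 2 dt, ...` and renormalized so that `sum(w) * dt = 1`. The
#' kernel peaks at `tau = 1/alpha`; the package parameterizes by the
#' characteristic (peak) time `1/alpha`, 150 ms by default, which is the
#' only dimensionally consistent reading of an "alpha of 150 ms".
#'
#' @param alpha Decay rate in 1/s (default `1/0.150`).
#' @param dt Sample interval in s.
#' @param support Kernel support length in s; must be at least `10/alpha`
#'   and long enough that the truncated continuous tail mass is below 1e-6
#'   (the default `20/alpha` satisfies both).
#' @return Numeric kernel with attributes `peak_index` (1-based discrete
#'   argmax) and `peak_time` (`1/alpha`).
#' @export
make_kernel <- function(alpha = 1 / 0.150, dt = 0.001,
                        support = 20 / alpha) {
  if (alpha <= 0 || dt <= 0) stop("alpha and dt must be positive")
  if (support < 10 / alpha) stop("support too short: need >= 10/alpha")
  # Gamma(shape 2) upper tail of the continuous kernel beyond `support`
  tail_mass <- exp(-alpha * support) * (1 + alpha * support)
  if (tail_mass > 1e-6) {
    stop("support too short: truncated tail mass exceeds 1e-6")
  }
  tau <- seq(0, support, by = dt)
  w <- alpha^2 * tau * exp(-alpha * tau)
  w <- w / (sum(w) * dt)
  structure(w, peak_index = as.integer(round((1 / alpha) / dt)) + 1L,
            peak_time = 1 / alpha)
}

#' Build unit-pulse epochs from detected microsaccades
#'
#' Places each event onset as a unit pulse (Dirac delta on the sample grid)
#' into fixed peristimulus epochs around the given trial onsets. Events
#' whose onset falls outside every epoch window are ignored.
#'
#' @param events Detected event data.frame (absolute `onset` s).
#' @param onsets Trial-onset times, s.
#' @param window Epoch window, s (default `c(-2, 5.5)`, half-open).
#' @param sampling_rate Hz.
#' @param condition,participant Labels forwarded to the [epoch_set()].
#' @return An [epoch_set()] of 0/1 pulses.
#' @export
ms_pulse_epochs <- function(events, onsets, window = c(-2, 5.5),
                            sampling_rate = 1000, condition = NULL,
                            participant = NA_character_) {
  n_per <- round((window[2] - window[1]) * sampling_rate)
  nt <- length(onsets)
  data <- matrix(0, nt, n_per)
  for (i in seq_len(nt)) {
    rel <- events$onset - onsets[i]
    rel <- rel[rel >= window[1] & rel < window[2]]
    if (length(rel) > 0) {
      idx <- floor((rel - window[1]) * sampling_rate) + 1
      data[i, idx] <- data[i, idx] + 1
    }
  }
  axis <- window[1] + (seq_len(n_per) - 1) / sampling_rate
  epoch_set(pmin(data, 1), axis, condition = condition,
            participant = participant)
}

#' Smoothed microsaccade rate from pulse epochs
#'
#' Pulses are summed across trials and normalized by the number of trials
#' and the sampling rate to give an events-per-second density, then
#' convolved with the causal alpha kernel. To undo the delay introduced by
#' the causal kernel, the time axis is shifted earlier by the kernel peak
#' time `1/alpha`, so the smoothed response to a pulse at `t0` peaks at
#' `t0`.
#'
#' @param pulses An [epoch_set()] of 0/1 pulses.
#' @param alpha Kernel decay rate, 1/s.
#' @param support Kernel support, s (see [make_kernel()]).
#' @return A `rate_series`: list with `time` (shifted axis), `rate`
#'   (events/s), `raw` (unsmoothed density), `alpha`, `shift_applied`,
#'   `n_trials`.
#' @export
rate_estimate <- function(pulses, alpha = 1 / 0.150, support = 20 / alpha) {
  if (nrow(pulses$data) < 1) stop("need at least one trial")
  if (any(!pulses$data %in% c(0, 1))) stop("pulse epochs must be 0/1")
  dt <- diff(pulses$time[1:2])
  fs <- 1 / dt
  n_trials <- nrow(pulses$data)
  raw <- colSums(pulses$data) / n_trials * fs
  kern <- make_kernel(alpha, dt, support)
  # causal convolution with zero initial condition: pad with leading zeros
  # so the epoch start is treated as silence, not as missing data
  L <- length(kern)
  padded <- c(numeric(L - 1), raw)
  rate <- as.numeric(stats::filter(padded, kern * dt,
                                   method = "convolution", sides = 1))
  rate <- rate[L:length(padded)]
  shift <- attr(kern, "peak_time")
  structure(list(time = pulses$time - shift, rate = rate, raw = raw,
                 alpha = alpha, shift_applied = shift,
                 n_trials = n_trials),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf(
    "<rate_series> %d samples, axis [%.3f, %.3f] s, alpha = %.3f /s (peak %g ms), %d trials\n",
    length(x$rate), min(x$time), max(x$time), x$alpha,
    1000 * x$shift_applied, x$n_trials))
  cat(sprintf("  mean rate %.3f events/s\n", mean(x$rate)))
  invisible(x)
}

#' Repair a consistent pre-onset recording gap in pulse epochs
#'
#' For recordings where the tracker briefly interrupted before each trial
#' (leaving an artefactual absence of events in a fixed pre-onset window),
#' the gap window of each trial is overwritten by the donor window of a
#' uniformly chosen *other* trial of the same participant.
#'
#' @param pulses An [epoch_set()] of pulses.
#' @param gap Gap window, s (default `c(-0.3, 0)`, half-open).
#' @param donor Donor window of equal length (default `c(-0.6, -0.3)`).
#' @param seed Optional integer seed for reproducible donor choice.
#' @return The repaired [epoch_set()].
#' @export
patch_preonset_gap <- function(pulses, gap = c(-0.3, 0),
                               donor = c(-0.6, -0.3), seed = NULL) {
  nt <- nrow(pulses$data)
  if (nt < 2) stop("need at least 2 trials to draw a donor")
  tol <- diff(pulses$time[1:2]) / 2
  gi <- which(pulses$time >= gap[1] - tol & pulses$time < gap[2] - tol)
  di <- which(pulses$time >= donor[1] - tol & pulses$time < donor[2] - tol)
  if (length(gi) == 0 || length(di) == 0) {
    stop("gap and donor windows must lie within the epoch axis")
  }
  if (length(gi) != length(di)) stop("gap and donor windows must match")
  if (!is.null(seed)) set.seed(seed)
  out <- pulses
  for (i in seq_len(nt)) {
    j <- sample(setdiff(seq_len(nt), i), 1)
    out$data[i, gi] <- pulses$data[j, di]
  }
  out
}
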