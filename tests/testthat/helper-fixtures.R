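# Small shared fixtures, built in code.

# a desk-scale config for fast tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_participants = 2, n_trials_per_condition = 3,
         blink_rate = 2, excursion_rate = 0, seed = 99),
    list(...))
  do.call(sim_config, args)
}

# epoch_set on the standard [-2, 5.5) axis at a reduced rate for speed
make_epochs <- function(data, fs = 100, condition = NULL, missing = NULL) {
  n <- ncol(data)
  epoch_set(data, -2 + (seq_len(n) - 1) / fs, missing = missing,
            condition = condition)
}

# a quiet drift recording with optional injected raised-cosine events;
# returns the recording and the injection table
drift_with_events <- function(n_s = 10, fs = 1000, drift_sd = 1e-3,
                              onsets = numeric(), amplitude = 0.6,
                              duration_ms = 20, disparity_ms = 0) {
  n <- n_s * fs
  dt <- 1 / fs
  ar <- function() as.numeric(stats::filter(rnorm(n, 0, drift_sd), 0.998,
                                            method = "recursive"))
  dx <- ar(); dy <- ar()
  vx <- numeric(n)
  for (on in onsets) {
    ns <- round(duration_ms / 1000 * fs)
    tt <- (seq_len(ns) - 0.5) / ns * (duration_ms / 1000)
    v <- 2 * amplitude / (duration_ms / 1000) *
      (1 - cos(2 * pi * tt / (duration_ms / 1000))) / 2
    i0 <- round(on * fs) + 1
    vx[i0:(i0 + ns - 1)] <- vx[i0:(i0 + ns - 1)] + v
  }
  shift <- round(disparity_ms / 1000 * fs)
  vxr <- c(numeric(shift), vx)[seq_len(n)]
  xl <- dx + cumsum(vx) * dt
  xr <- dx + cumsum(vxr) * dt
  gaze_recording(xl, dy, pl = rep(500, n), xr, dy, pr = rep(500, n),
                 sampling_rate = fs)
}
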