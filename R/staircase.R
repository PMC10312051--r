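#' Adaptive staircase configuration
#'
#' The one-up-one-down speech-reception-threshold procedure: SNR starts at
#' `initial_snr`, decreases by the current step after a correct response and
#' increases after an incorrect one. The step size drops to the next
#' schedule entry immediately after each of the first reversals and stays at
#' the floor thereafter. The run ends after `max_reversals` reversals or
#' `max_trials` trials, whichever comes first; the threshold is the mean SNR
#' of the final `reversals_for_threshold` reversals.
#'
#' @param initial_snr Starting SNR, dB (default 20).
#' @param step_schedule Step sizes in dB applied before the first, second,
#'   ... reversal (default `c(12, 8, 5)`).
#' @param step_floor Minimum step size, dB (default 2).
#' @param max_reversals Reversal cap (default 7).
#' @param max_trials Trial cap (default 25).
#' @param reversals_for_threshold Reversals averaged for the threshold
#'   (default 4).
#' @param snr_limits Optional length-2 clamp on the presented SNR; default
#'   unbounded.
#' @return A validated list of class `staircase_config`.
#' @export
staircase_config <- function(initial_snr = 20, step_schedule = c(12, 8, 5),
                             step_floor = 2, max_reversals = 7,
                             max_trials = 25, reversals_for_threshold = 4,
                             snr_limits = c(-Inf, Inf)) {
  steps <- c(step_schedule, step_floor)
  if (any(steps <= 0)) stop("all steps must be positive")
  if (any(diff(steps) >= 0)) {
    stop("step_schedule must decrease strictly to the floor")
  }
  if (max_trials < max_reversals) stop("max_trials must be >= max_reversals")
  if (reversals_for_threshold <= 0) {
    stop("reversals_for_threshold must be positive")
  }
  structure(list(initial_snr = initial_snr, step_schedule = step_schedule,
                 step_floor = step_floor, max_reversals = max_reversals,
                 max_trials = max_trials,
                 reversals_for_threshold = reversals_for_threshold,
                 snr_limits = snr_limits),
            class = "staircase_config")
}

#' Run a one-up-one-down adaptive staircase
#'
#' `observer` is either an [observer_model()] (responses drawn with
#' [psychometric_response()] from the current RNG state) or a
#' `function(snr_db)` returning a logical correct/incorrect. A reversal is
#' logged at the trial whose induced direction (down after correct, up
#' after incorrect) differs from the previously established direction; the
#' step size is updated immediately after the reversal is logged, so the
#' move away from a reversal trial already uses the reduced step.
#'
#' @param observer Response source (see above).
#' @param config A [staircase_config()].
#' @return A `staircase_result`: list with `trial_snrs`, `responses`,
#'   `reversal_trials`, `reversal_snrs`, `threshold` (`NA` when fewer than
#'   `reversals_for_threshold` reversals occurred), and `termination`
#'   (`"reversals"` or `"trial_cap"`).
#' @export
run_staircase <- function(observer, config = staircase_config()) {
  respond <- if (inherits(observer, "observer_model")) {
    function(snr) psychometric_response(observer, snr)
  } else if (is.function(observer)) {
    observer
  } else {
    stop("observer must be an observer_model or a function(snr_db)")
  }
  steps <- c(config$step_schedule, config$step_floor)
  snr <- config$initial_snr
  trial_snrs <- numeric(0)
  responses <- logical(0)
  reversal_trials <- integer(0)
  reversal_snrs <- numeric(0)
  prev_dir <- 0L  # no established direction before the first trial
  n_rev <- 0L
  termination <- "trial_cap"
  for (t in seq_len(config$max_trials)) {
    correct <- tryCatch(isTRUE(respond(snr)), error = function(e) {
      stop(sprintf("observer failed at trial %d: %s", t,
                   conditionMessage(e)))
    })
    trial_snrs[t] <- snr
    responses[t] <- correct
    dir <- if (correct) -1L else 1L
    if (prev_dir != 0L && dir != prev_dir) {
      n_rev <- n_rev + 1L
      reversal_trials <- c(reversal_trials, t)
      reversal_snrs <- c(reversal_snrs, snr)
    }
    prev_dir <- dir
    step <- steps[min(n_rev + 1L, length(steps))]
    snr <- snr + dir * step
    snr <- min(max(snr, config$snr_limits[1]), config$snr_limits[2])
    if (n_rev >= config$max_reversals) {
      termination <- "reversals"
      break
    }
  }
  res <- structure(
    list(trial_snrs = trial_snrs, responses = responses,
         reversal_trials = reversal_trials, reversal_snrs = reversal_snrs,
         threshold = NA_real_, termination = termination,
         config = config),
    class = "staircase_result")
  res$threshold <- threshold_from_reversals(
    res, config$reversals_for_threshold)
  res
}

#' @export
print.staircase_result <- function(x, ...) {
  cat(sprintf(
    "<staircase_result> %d trials, %d reversals, terminated by %s\n",
    length(x$trial_snrs), length(x$reversal_snrs), x$termination))
  cat(sprintf("  threshold: %s dB\n",
              if (is.na(x$threshold)) "undefined"
              else sprintf("%.2f", x$threshold)))
  invisible(x)
}

#' Threshold from the final reversals
#'
#' Mean SNR of the last `k` reversals; `NA` (an explicit sentinel, not an
#' error) when fewer than `k` reversals occurred.
#'
#' @param result A [run_staircase()] result.
#' @param k Number of final reversals to average (default 4).
#' @return Threshold in dB SNR, or `NA_real_`.
#' @export
threshold_from_reversals <- function(result, k = 4) {
  if (k <= 0) stop("k must be positive")
  rs <- result$reversal_snrs
  if (length(rs) < k) return(NA_real_)
  mean(utils::tail(rs, k))
}

#' Low-load SNR from an estimated threshold
#'
#' The low-load condition is presented at the speech-reception threshold
#' plus 10 dB.
#'
#' @param threshold_db Estimated threshold, dB SNR.
#' @return `threshold_db + 10`.
#' @export
ll_snr <- function(threshold_db) threshold_db + 10
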