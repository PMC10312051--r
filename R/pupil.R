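#' Pupillometry preprocessing parameters
#'
#' Thresholds of the pupil cleaning chain. Boundary conventions follow the
#' printed rules exactly: samples farther than `fixation_radius` (strict
#' `>`) are missing; participants and epochs with missing fraction strictly
#' above 0.5 are excluded; a trial is removed when 10% *or more* of its
#' samples deviate by strictly more than 3 SD from the per-time-point
#' condition mean.
#'
#' @param fixation_center Fixation-cross center `(x, y)`, gaze-units.
#' @param fixation_radius Allowed gaze radius (100 pixels).
#' @param participant_missing_max Participant exclusion fraction (0.5).
#' @param epoch_missing_max Epoch rejection fraction (0.5).
#' @param outlier_z Outlier deviation threshold in SD units (3).
#' @param outlier_fraction Fraction of outlying samples that removes a trial
#'   (0.10, inclusive).
#' @param baseline_window Baseline window, s (`[-0.2, 0)`).
#' @param load_window Load-effect window, s (`[2, 5]`).
#' @param eye Analyzed eye, `"left"` (default) or `"right"`.
#' @return A validated list of class `pupil_params`.
#' @export
pupil_params <- function(fixation_center = c(0, 0), fixation_radius = 100,
                         participant_missing_max = 0.5,
                         epoch_missing_max = 0.5,
                         outlier_z = 3, outlier_fraction = 0.10,
                         baseline_window = c(-0.2, 0),
                         load_window = c(2, 5), eye = c("left", "right")) {
  eye <- match.arg(eye)
  fr <- c(participant_missing_max, epoch_missing_max, outlier_fraction)
  if (any(fr <= 0 | fr > 1)) stop("fractions must lie in (0, 1]")
  if (fixation_radius <= 0 || outlier_z <= 0) {
    stop("fixation_radius and outlier_z must be positive")
  }
  structure(list(fixation_center = fixation_center,
                 fixation_radius = fixation_radius,
                 participant_missing_max = participant_missing_max,
                 epoch_missing_max = epoch_missing_max,
                 outlier_z = outlier_z, outlier_fraction = outlier_fraction,
                 baseline_window = baseline_window,
                 load_window = load_window, eye = eye),
            class = "pupil_params")
}

#' Mask fixation breaks as missing data
#'
#' Samples whose gaze lies strictly outside `fixation_radius` of the
#' fixation center (per eye, using that eye's own gaze), or that are already
#' invalid (blinks, eye closure), are marked missing. A sample at exactly
#' the radius is retained.
#'
#' @param recording A [gaze_recording()].
#' @param params A [pupil_params()].
#' @return The recording with updated validity masks.
#' @export
mask_fixation_breaks <- function(recording, params = pupil_params()) {
  cx <- params$fixation_center[1]; cy <- params$fixation_center[2]
  dist_l <- sqrt((recording$xl - cx)^2 + (recording$yl - cy)^2)
  dist_r <- sqrt((recording$xr - cx)^2 + (recording$yr - cy)^2)
  recording$valid_l <- recording$valid_l & !is.na(dist_l) &
    dist_l <= params$fixation_radius
  recording$valid_r <- recording$valid_r & !is.na(dist_r) &
    dist_r <= params$fixation_radius
  recording
}

#' Participant-level missing-data exclusion
#'
#' @param recording A masked [gaze_recording()] (or list of recordings for a
#'   participant's blocks).
#' @param params A [pupil_params()].
#' @return List with `excluded` (TRUE iff the overall missing fraction is
#'   strictly above the threshold) and `missing_fraction`.
#' @export
participant_excluded <- function(recording, params = pupil_params()) {
  recs <- if (inherits(recording, "gaze_recording")) list(recording)
          else recording
  valid <- unlist(lapply(recs, function(r) {
    if (params$eye == "left") r$valid_l else r$valid_r
  }))
  if (length(valid) == 0) stop("empty recording")
  frac <- mean(!valid)
  list(excluded = frac > params$participant_missing_max,
       missing_fraction = frac)
}

# linear interpolation across missing samples of one epoch row;
# edge gaps are held at the nearest valid value
interp_row <- function(x, miss) {
  ok <- !miss & !is.na(x)
  if (!any(ok)) return(x)
  if (all(ok)) return(x)
  stats::approx(which(ok), x[ok], xout = seq_along(x), method = "linear",
                rule = 2)$y
}

#' Clean pupil epochs: sparse-epoch rejection, interpolation, outlier trials
#'
#' Applies, in order: (a) epochs with a missing fraction strictly above
#' `epoch_missing_max` are discarded; (b) remaining gaps are filled by
#' linear interpolation between nearest valid neighbours, holding the
#' nearest valid value at epoch edges; (c) per time point, the mean and SD
#' over surviving trials of each condition are computed, and a trial is
#' dropped when at least `outlier_fraction` of its samples deviate by more
#' than `outlier_z` SD from its condition's per-time-point mean.
#'
#' @param epochs An [epoch_set()].
#' @param params A [pupil_params()].
#' @return List with `epochs` (cleaned, interpolated [epoch_set()]; the
#'   missing mask is retained as pre-interpolation information) and
#'   `report` (counts dropped per rule).
#' @export
clean_epochs <- function(epochs, params = pupil_params()) {
  miss_frac <- rowMeans(epochs$missing)
  keep_a <- miss_frac <= params$epoch_missing_max
  n_sparse <- sum(!keep_a)
  ep <- subset_epochs(epochs, keep_a)
  if (nrow(ep$data) == 0) stop("all epochs discarded by the missing rule")
  for (i in seq_len(nrow(ep$data))) {
    ep$data[i, ] <- interp_row(ep$data[i, ], ep$missing[i, ])
  }
  # rule (c): per-time-point condition mean/SD over surviving trials
  out_frac <- numeric(nrow(ep$data))
  for (cond in unique(ep$condition)) {
    rows <- which(ep$condition == cond)
    if (length(rows) == 0) next
    m <- ep$data[rows, , drop = FALSE]
    mu <- colMeans(m)
    sd_t <- apply(m, 2, stats::sd)
    if (length(rows) == 1) sd_t <- rep(0, ncol(m))
    dev <- abs(sweep(m, 2, mu))
    thr <- params$outlier_z * sd_t
    out_frac[rows] <- rowMeans(sweep(dev, 2, thr) > 0)
  }
  keep_c <- out_frac < params$outlier_fraction
  n_outlier <- sum(!keep_c)
  ep <- subset_epochs(ep, keep_c)
  if (nrow(ep$data) == 0) stop("all epochs discarded by the outlier rule")
  for (cond in unique(epochs$condition)) {
    if (!cond %in% ep$condition) {
      stop("condition with zero surviving trials: ", cond)
    }
  }
  list(epochs = ep,
       report = list(n_in = nrow(epochs$data),
                     n_dropped_sparse = n_sparse,
                     n_dropped_outlier = n_outlier,
                     n_out = nrow(ep$data)))
}

#' Per-participant z-scoring across pooled conditions
#'
#' One mean and SD are computed over all retained samples of all conditions
#' for the participant, and every sample is transformed as `(x - mean)/SD`,
#' so the pooled transformed data has mean 0 and SD 1.
#'
#' @param epochsets A single [epoch_set()] containing both conditions, or a
#'   list of epoch sets for one participant.
#' @return The same structure with transformed data; the pooled `mean` and
#'   `sd` are attached as attributes.
#' @export
zscore_participant <- function(epochsets) {
  single <- inherits(epochsets, "epoch_set")
  sets <- if (single) list(epochsets) else epochsets
  pooled <- unlist(lapply(sets, function(e) e$data))
  pooled <- pooled[!is.na(pooled)]
  if (length(unique(pooled)) < 2) {
    stop("need at least 2 distinct pooled values to z-score")
  }
  mu <- mean(pooled)
  s <- stats::sd(pooled)
  if (s <= 0) stop("zero pooled SD")
  sets <- lapply(sets, function(e) {
    e$data <- (e$data - mu) / s
    e
  })
  out <- if (single) sets[[1]] else sets
  attr(out, "mean") <- mu
  attr(out, "sd") <- s
  out
}

#' Baseline-correct epochs
#'
#' Subtracts from each trial the mean of its samples in the baseline window
#' (half-open, default `[-0.2, 0)` s).
#'
#' @param epochs An [epoch_set()] (interpolated: no NAs).
#' @param window Baseline window, s.
#' @return The corrected [epoch_set()].
#' @export
baseline_correct <- function(epochs, window = c(-0.2, 0)) {
  idx <- which(epochs$time >= window[1] & epochs$time < window[2])
  if (length(idx) == 0) stop("baseline window outside the epoch axis")
  base <- rowMeans(epochs$data[, idx, drop = FALSE])
  epochs$data <- epochs$data - base
  epochs
}

#' Condition-mean traces for one participant
#'
#' Time-domain average across all epochs of each condition.
#'
#' @param epochs An [epoch_set()].
#' @return Matrix conditions x time (rownames = condition labels), with the
#'   epoch axis as attribute `"time"` and trial counts as `"n"`.
#' @export
condition_mean <- function(epochs) {
  conds <- unique(epochs$condition)
  out <- matrix(NA_real_, length(conds), ncol(epochs$data),
                dimnames = list(conds, NULL))
  n <- stats::setNames(integer(length(conds)), conds)
  for (cond in conds) {
    rows <- which(epochs$condition == cond)
    if (length(rows) == 0) stop("empty condition: ", cond)
    out[cond, ] <- colMeans(epochs$data[rows, , drop = FALSE])
    n[cond] <- length(rows)
  }
  attr(out, "time") <- epochs$time
  attr(out, "n") <- n
  out
}

#' Group-mean traces across participants
#'
#' Unweighted mean of per-participant condition traces.
#'
#' @param traces List of [condition_mean()] matrices (one per participant),
#'   sharing conditions and time axis.
#' @return Matrix conditions x time with attribute `"time"`.
#' @export
group_mean <- function(traces) {
  stopifnot(length(traces) >= 1)
  conds <- rownames(traces[[1]])
  # align by condition label: row order may differ across participants
  # (e.g. counterbalanced block order)
  aligned <- lapply(traces, function(m) {
    if (!all(conds %in% rownames(m))) {
      stop("participants disagree on condition labels")
    }
    m[conds, , drop = FALSE]
  })
  out <- Reduce(`+`, aligned) / length(traces)
  attr(out, "time") <- attr(traces[[1]], "time")
  out
}

#' Peak latency and amplitude of a trace
#'
#' Argmax and max within a search window; ties resolve to the earliest time
#' point.
#'
#' @param trace Numeric time series.
#' @param time Time axis, s.
#' @param window Search window, s (closed).
#' @return List with `latency` (s) and `amplitude`.
#' @export
pd_peak <- function(trace, time, window = range(time)) {
  idx <- which(time >= window[1] & time <= window[2])
  if (length(idx) == 0) stop("search window outside the axis")
  vals <- trace[idx]
  if (all(is.na(vals))) stop("all-missing search window")
  k <- idx[which.max(vals)]  # which.max returns the first maximum
  list(latency = time[k], amplitude = trace[k])
}

#' Pupil load effect between two condition traces
#'
#' Mean over the load window (closed, default `[2, 5]` s) of the difference
#' `hl - ll`.
#'
#' @param hl,ll Condition traces on a shared axis.
#' @param time Time axis, s.
#' @param window Load window, s.
#' @return Scalar mean difference (z-units).
#' @export
pd_load_effect <- function(hl, ll, time, window = c(2, 5)) {
  idx <- which(time >= window[1] & time <= window[2])
  if (length(idx) == 0) stop("load window outside the axis")
  mean(hl[idx] - ll[idx])
}

#' Missing-data incidence over the epoch
#'
#' Fraction of trials missing at each time point, computed from the raw
#' (pre-interpolation) missing masks; a proxy for the blink rate when the
#' mask is blink-dominated. Multiple epoch sets (participants) are pooled
#' over trials.
#'
#' @param epochs An [epoch_set()] or a list of epoch sets sharing a time
#'   axis.
#' @param condition Optional condition label to restrict to.
#' @return Numeric incidence series in `[0, 1]` with attribute `"time"`.
#' @export
blink_rate <- function(epochs, condition = NULL) {
  sets <- if (inherits(epochs, "epoch_set")) list(epochs) else epochs
  masks <- lapply(sets, function(e) {
    keep <- if (is.null(condition)) seq_len(nrow(e$missing))
            else which(e$condition == condition)
    e$missing[keep, , drop = FALSE]
  })
  m <- do.call(rbind, masks)
  out <- colMeans(m)
  attr(out, "time") <- sets[[1]]$time
  out
}
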