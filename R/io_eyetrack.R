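#' Binocular gaze recording
#'
#' Container for a continuous binocular eye-tracker sample stream: horizontal
#' and vertical gaze position and pupil size for each eye on a uniform time
#' base, per-eye validity masks, and a log of event markers (e.g. trial
#' onsets). Values at invalid samples are ignored by all consumers and are
#' conventionally `NA`.
#'
#' @param xl,yl Left-eye gaze coordinates (gaze-units).
#' @param pl Left-eye pupil size (arbitrary units).
#' @param xr,yr,pr Right-eye channels.
#' @param valid_l,valid_r Logical validity masks, one element per sample.
#' @param events `data.frame` with columns `label` and `time` (seconds).
#' @param sampling_rate Sampling rate in Hz.
#' @param start_time Time of the first sample in seconds.
#' @param time Optional explicit time vector (seconds); must be uniform at
#'   `1/sampling_rate` within 1e-9 s.
#'
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(xl = numeric(), yl = numeric(), pl = numeric(),
                           xr = numeric(), yr = numeric(), pr = numeric(),
                           valid_l = NULL, valid_r = NULL,
                           events = NULL, sampling_rate = 1000,
                           start_time = 0, time = NULL) {
  n <- length(xl)
  chans <- list(xl = xl, yl = yl, pl = pl, xr = xr, yr = yr, pr = pr)
  if (any(vapply(chans, length, 1L) != n)) {
    stop("all channels must have equal length")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be positive")
  }
  if (is.null(time)) {
    time <- start_time + (seq_len(n) - 1) / sampling_rate
  }
  if (length(time) != n) stop("time must match channel length")
  if (n > 1) {
    dt <- diff(time)
    if (any(abs(dt - 1 / sampling_rate) > 1e-9)) {
      stop("time base is not uniform at 1/sampling_rate")
    }
  }
  if (is.null(valid_l)) valid_l <- rep(TRUE, n)
  if (is.null(valid_r)) valid_r <- rep(TRUE, n)
  stopifnot(length(valid_l) == n, length(valid_r) == n)
  if (is.null(events)) {
    events <- data.frame(label = character(), time = numeric())
  }
  structure(
    list(time = as.numeric(time),
         xl = as.numeric(xl), yl = as.numeric(yl), pl = as.numeric(pl),
         xr = as.numeric(xr), yr = as.numeric(yr), pr = as.numeric(pr),
         valid_l = as.logical(valid_l), valid_r = as.logical(valid_r),
         events = events, sampling_rate = sampling_rate),
    class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  n <- length(x$time)
  cat(sprintf("<gaze_recording> %d samples @ %g Hz", n, x$sampling_rate))
  if (n > 0) cat(sprintf(" [%.3f, %.3f] s", x$time[1], x$time[n]))
  cat(sprintf(", %d events\n", nrow(x$events)))
  cat(sprintf("  invalid: left %.1f%%, right %.1f%%\n",
              100 * mean(!x$valid_l), 100 * mean(!x$valid_r)))
  invisible(x)
}

#' Set of peristimulus epochs
#'
#' Trials-by-time matrix of one channel cut around trial onsets, on a fixed
#' half-open peristimulus axis, with per-sample missing-data masks and
#' condition/participant labels.
#'
#' @param data Numeric matrix, trials in rows, time in columns.
#' @param time Peristimulus time axis in seconds (length `ncol(data)`).
#' @param missing Logical matrix of the same shape marking missing samples.
#' @param condition Condition label per trial.
#' @param participant Participant identifier (scalar or per trial).
#' @param trial Trial identifiers.
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, time, missing = NULL, condition = NULL,
                      participant = NA_character_, trial = NULL) {
  data <- as.matrix(data)
  if (length(time) != ncol(data)) stop("time axis must match ncol(data)")
  if (is.null(missing)) {
    missing <- matrix(FALSE, nrow(data), ncol(data))
  }
  missing <- as.matrix(missing)
  stopifnot(all(dim(missing) == dim(data)))
  if (is.null(condition)) condition <- rep(NA_character_, nrow(data))
  if (length(condition) == 1) condition <- rep(condition, nrow(data))
  stopifnot(length(condition) == nrow(data))
  if (length(participant) == 1) participant <- rep(participant, nrow(data))
  if (is.null(trial)) trial <- seq_len(nrow(data))
  structure(
    list(data = data, time = as.numeric(time), missing = missing,
         condition = as.character(condition),
         participant = as.character(participant), trial = trial),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d samples, axis [%.3f, %.3f] s\n",
              nrow(x$data), ncol(x$data), min(x$time), max(x$time)))
  tb <- table(x$condition, useNA = "ifany")
  cat("  conditions:",
      paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

# subset an epoch_set by trial index, keeping labels in step
subset_epochs <- function(ep, keep) {
  epoch_set(ep$data[keep, , drop = FALSE], ep$time,
            ep$missing[keep, , drop = FALSE], ep$condition[keep],
            ep$participant[keep], ep$trial[keep])
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "."
  out
}

#' Write a recording in the ASC text dialect
#'
#' One sample per line: integer-millisecond timestamp, then left-eye x, y,
#' pupil, then right-eye x, y, pupil, tab-separated. Invalid samples are
#' serialized as `.` in all three fields of the affected eye. Event markers
#' become `MSG <ms> <label>` lines placed chronologically. Lines beginning
#' with `**` are header comments. The dialect requires sample times on an
#' integer-millisecond grid (sampling rates that divide 1000 Hz).
#'
#' @param recording A [gaze_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_asc <- function(recording, path) {
  r <- recording
  n <- length(r$time)
  header <- c("** ASC-dialect export (oculodyn)",
              sprintf("** RATE %g", r$sampling_rate))
  ms <- round(r$time * 1000)
  if (n > 0 && any(abs(r$time * 1000 - ms) > 1e-6)) {
    stop("sample times are not on an integer-millisecond grid")
  }
  eye_fields <- function(x, y, p, valid) {
    fx <- fmt_num(x); fy <- fmt_num(y); fp <- fmt_num(p)
    fx[!valid] <- "."; fy[!valid] <- "."; fp[!valid] <- "."
    cbind(fx, fy, fp)
  }
  if (n > 0) {
    m <- cbind(sprintf("%d", as.integer(ms)),
               eye_fields(r$xl, r$yl, r$pl, r$valid_l),
               eye_fields(r$xr, r$yr, r$pr, r$valid_r))
    sample_lines <- apply(m, 1, paste, collapse = "\t")
  } else {
    sample_lines <- character()
  }
  msg_lines <- character()
  msg_t <- numeric()
  if (nrow(r$events) > 0) {
    msg_lines <- sprintf("MSG\t%d %s", as.integer(round(r$events$time * 1000)),
                         r$events$label)
    msg_t <- r$events$time
  }
  # interleave chronologically; MSG precedes samples at the same timestamp
  all_lines <- c(msg_lines, sample_lines)
  key <- c(msg_t - 1e-9, r$time)
  body <- all_lines[order(key)]
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a recording from the ASC text dialect
#'
#' Parses the dialect written by [write_asc()]: sample lines are
#' `(ms, xl, yl, pl, xr, yr, pr)`, `.` or absent fields mark the eye invalid,
#' `MSG <ms> <label>` lines become events, `**` lines and unrecognized line
#' types are skipped (their count is reported with a message).
#'
#' @param path Input file path.
#' @param sampling_rate Declared sampling rate in Hz (the dialect does not
#'   carry it authoritatively; must be positive).
#' @param quiet Suppress the skipped-line message.
#' @return A [gaze_recording()].
#' @export
read_asc <- function(path, sampling_rate = 1000, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  lines <- readLines(path, warn = FALSE)
  is_msg <- grepl("^MSG\\b", lines)
  is_sample <- grepl("^[0-9]", lines)
  is_header <- grepl("^\\*\\*", lines) | !nzchar(trimws(lines))
  skipped <- sum(!is_msg & !is_sample & !is_header)
  if (skipped > 0 && !quiet) {
    message("read_asc: skipped ", skipped, " unrecognized line(s)")
  }
  events <- data.frame(label = character(), time = numeric())
  if (any(is_msg)) {
    m <- regmatches(lines[is_msg],
                    regexec("^MSG\\s+(-?[0-9]+)\\s+(.*)$", lines[is_msg]))
    ok <- vapply(m, length, 1L) == 3
    events <- data.frame(
      label = vapply(m[ok], `[`, "", 3),
      time = as.numeric(vapply(m[ok], `[`, "", 2)) / 1000)
  }
  if (!any(is_sample)) {
    return(gaze_recording(events = events, sampling_rate = sampling_rate))
  }
  toks <- strsplit(trimws(lines[is_sample]), "[ \t]+")
  nf <- vapply(toks, length, 1L)
  fields <- matrix(".", nrow = length(toks), ncol = 7)
  for (i in seq_along(toks)) {
    k <- min(nf[i], 7L)
    fields[i, seq_len(k)] <- toks[[i]][seq_len(k)]
  }
  t_ms <- suppressWarnings(as.numeric(fields[, 1]))
  if (anyNA(t_ms)) stop("unparseable sample timestamp")
  if (any(diff(t_ms) <= 0)) {
    bad <- which(diff(t_ms) <= 0)[1] + 1
    stop(sprintf("nonmonotonic timestamps at sample line %d (t=%g ms)",
                 bad, t_ms[bad]))
  }
  num <- function(j) suppressWarnings(as.numeric(fields[, j]))
  xl <- num(2); yl <- num(3); pl <- num(4)
  xr <- num(5); yr <- num(6); pr <- num(7)
  valid_l <- !(is.na(xl) | is.na(yl) | is.na(pl))
  valid_r <- !(is.na(xr) | is.na(yr) | is.na(pr))
  gaze_recording(xl, yl, pl, xr, yr, pr, valid_l, valid_r,
                 events = events, sampling_rate = sampling_rate,
                 time = t_ms / 1000)
}

#' Cut a continuous recording into fixed peristimulus epochs
#'
#' Extracts a half-open window `[onset + window[1], onset + window[2])` of one
#' channel around each trial onset; at 1000 Hz the default window yields
#' exactly 7500 samples per epoch. Onsets falling between samples are aligned
#' to the nearest sample. The channel's per-eye validity mask is carried
#' through as the epoch missing mask.
#'
#' @param recording A [gaze_recording()].
#' @param onsets Trial-onset times in seconds.
#' @param window Length-2 window in seconds relative to onset
#'   (default `c(-2, 5.5)`).
#' @param channel One of `"xl","yl","pl","xr","yr","pr"`.
#' @param condition Optional condition label per trial.
#' @param participant Optional participant identifier.
#' @return An [epoch_set()].
#' @export
epoch_by_events <- function(recording, onsets, window = c(-2, 5.5),
                            channel = "pl", condition = NULL,
                            participant = NA_character_) {
  r <- recording
  if (!channel %in% c("xl", "yl", "pl", "xr", "yr", "pr")) {
    stop("unknown channel: ", channel)
  }
  fs <- r$sampling_rate
  n_per <- round((window[2] - window[1]) * fs)
  if (n_per < 1) stop("window must have positive length")
  valid <- if (grepl("l$", channel)) r$valid_l else r$valid_r
  vals <- r[[channel]]
  nt <- length(onsets)
  data <- matrix(NA_real_, nt, n_per)
  missing <- matrix(TRUE, nt, n_per)
  tol <- 0.5 / fs + 1e-9
  for (i in seq_len(nt)) {
    t0 <- onsets[i] + window[1]
    i0 <- round((t0 - r$time[1]) * fs) + 1
    if (i0 < 1 || abs(r$time[pmin(pmax(i0, 1), length(r$time))] - t0) > tol ||
        i0 + n_per - 1 > length(r$time)) {
      stop(sprintf(
        "trial %d: window [%.3f, %.3f] s not covered by the recording",
        i, t0, onsets[i] + window[2]))
    }
    idx <- i0:(i0 + n_per - 1)
    data[i, ] <- vals[idx]
    missing[i, ] <- !valid[idx]
  }
  axis <- window[1] + (seq_len(n_per) - 1) / fs
  epoch_set(data, axis, missing, condition, participant)
}
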