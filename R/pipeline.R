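#' Run the full synthetic-experiment analysis pipeline
#'
#' Orchestrates simulate, mask, epoch, clean, z-score, average (pupil
#' chain) and detect, pulse-epoch, rate-smooth (microsaccade chain), then
#' computes participant-level bootstrap significance masks for the
#' condition difference of each measure. Participants are simulated and
#' processed one at a time so memory stays bounded; everything is
#' deterministic given `seed`.
#'
#' @param config A [sim_config()]; its `seed` is overridden by `seed` when
#'   given.
#' @param seed Integer seed for the whole run.
#' @param detection A [detection_params()].
#' @param pupil A [pupil_params()].
#' @param n_iterations,criterion Bootstrap settings (see
#'   [bootstrap_mask()]).
#' @param patch_gap If `TRUE`, apply [patch_preonset_gap()] to the pulse
#'   epochs (for recordings with a consistent pre-onset dropout).
#' @param window Epoch window, s.
#' @param out_dir Optional directory; when given, traces, rates, masks and
#'   a JSON manifest are written as CSV/JSON files.
#' @return List with `pd` (group traces, non-baseline-corrected), `pd_bc`
#'   (baseline-corrected), `ms_rate` (group rate traces), the three
#'   corresponding `significance_mask`s (`mask_pd`, `mask_pd_bc`,
#'   `mask_ms`), per-participant matrices, cleaning `reports`, and the
#'   latent `participants` table.
#' @export
run_pipeline <- function(config = sim_config(), seed = config$seed,
                         detection = detection_params(),
                         pupil = pupil_params(),
                         n_iterations = 1000, criterion = 0.99,
                         patch_gap = FALSE, window = c(-2, 5.5),
                         out_dir = NULL) {
  if (is.null(seed)) stop("seed must be set")
  set.seed(seed)
  parts <- draw_participants(config)
  np <- nrow(parts)
  if (np < 2) stop("pipeline needs at least 2 participants")
  sub_seeds <- sample.int(2^31 - 2, np + 1)
  pd_traces <- pd_bc_traces <- pd_raw_traces <- ms_traces <- list()
  reports <- list()
  excluded <- character(0)
  rate_time <- NULL
  for (i in seq_len(np)) {
    set.seed(sub_seeds[i])
    ord <- if (i %% 2 == 1) config$conditions else rev(config$conditions)
    sim <- simulate_participant(config, parts$participant[i],
                                parts$baseline[i], parts$ms_rate_mult[i],
                                block_order = ord)
    rec <- mask_fixation_breaks(sim$recording, pupil)
    pe <- participant_excluded(rec, pupil)
    if (pe$excluded) {
      excluded <- c(excluded, parts$participant[i])
      next
    }
    chan <- if (pupil$eye == "left") "pl" else "pr"
    ep <- epoch_by_events(rec, sim$trials$onset_s, window, chan,
                          condition = sim$trials$condition,
                          participant = parts$participant[i])
    cl <- clean_epochs(ep, pupil)
    reports[[parts$participant[i]]] <- cl$report
    z <- zscore_participant(cl$epochs)
    pd_traces[[parts$participant[i]]] <- condition_mean(z)
    pd_bc_traces[[parts$participant[i]]] <-
      condition_mean(baseline_correct(z, pupil$baseline_window))
    # condition means in the generator's own units (before z-scoring), for
    # recovery checks against programmed absolute effects
    pd_raw_traces[[parts$participant[i]]] <- condition_mean(cl$epochs)
    # microsaccade chain: block-level sigma, detection on the continuous
    # recording, pulses epoched per condition
    events <- detect_microsaccades(rec, detection)
    rates <- NULL
    for (cond in config$conditions) {
      tr <- sim$trials[sim$trials$condition == cond, ]
      pulses <- ms_pulse_epochs(events, tr$onset_s, window,
                                config$sampling_rate, condition = cond,
                                participant = parts$participant[i])
      if (patch_gap) {
        pulses <- patch_preonset_gap(pulses, seed = sub_seeds[np + 1] + i)
      }
      rs <- rate_estimate(pulses)
      rate_time <- rs$time
      rates <- rbind(rates, rs$rate)
    }
    rownames(rates) <- config$conditions
    attr(rates, "time") <- rate_time
    ms_traces[[parts$participant[i]]] <- rates
  }
  if (length(pd_traces) < 2) stop("fewer than 2 participants survived")
  res <- list(
    pd = group_mean(pd_traces), pd_bc = group_mean(pd_bc_traces),
    ms_rate = group_mean(ms_traces),
    mask_pd = bootstrap_mask(
      condition_difference(pd_traces, config$conditions),
      n_iterations, criterion, seed = sub_seeds[np + 1]),
    mask_pd_bc = bootstrap_mask(
      condition_difference(pd_bc_traces, config$conditions),
      n_iterations, criterion, seed = sub_seeds[np + 1] + 1L),
    mask_ms = bootstrap_mask(
      condition_difference(ms_traces, config$conditions),
      n_iterations, criterion, seed = sub_seeds[np + 1] + 2L),
    pd_traces = pd_traces, pd_bc_traces = pd_bc_traces,
    pd_raw_traces = pd_raw_traces,
    ms_traces = ms_traces, reports = reports, excluded = excluded,
    participants = parts, seed = seed)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

trace_to_long <- function(m) {
  tm <- attr(m, "time")
  do.call(rbind, lapply(rownames(m), function(cond) {
    data.frame(time_s = tm, condition = cond, mean = m[cond, ])
  }))
}

mask_to_df <- function(mask) {
  data.frame(time_s = mask$time, prop_above = mask$prop_above,
             prop_below = mask$prop_below,
             significant = mask$significant, sign = mask$sign)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trace_to_long(res$pd),
                   file.path(out_dir, "pd_traces.csv"), row.names = FALSE)
  utils::write.csv(trace_to_long(res$pd_bc),
                   file.path(out_dir, "pd_traces_bc.csv"),
                   row.names = FALSE)
  utils::write.csv(trace_to_long(res$ms_rate),
                   file.path(out_dir, "ms_rates.csv"), row.names = FALSE)
  for (nm in c("mask_pd", "mask_pd_bc", "mask_ms")) {
    utils::write.csv(mask_to_df(res[[nm]]),
                     file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  manifest <- list(
    seed = res$seed,
    n_participants = length(res$pd_traces),
    excluded = res$excluded,
    reports = res$reports,
    n_significant = lapply(res[c("mask_pd", "mask_pd_bc", "mask_ms")],
                           function(m) sum(m$significant)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
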