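#' Standard 37-channel scalp montage
#'
#' Channel labels of the 10-20 montage used throughout the package: 37 scalp
#' positions (ground AFz and reference CPz are not recorded).
#'
#' @return Character vector of 37 scalp channel labels.
#' @export
default_scalp_labels <- function() {
  c("Fpz", "Fp1", "Fp2", "AF3", "AF4",
    "Fz", "F1", "F2", "F3", "F4", "F5", "F6",
    "FCz", "FC1", "FC2", "FC3", "FC4",
    "Cz", "C1", "C2", "C3", "C4",
    "T7", "T8",
    "CP1", "CP2", "TP7", "TP8",
    "Pz", "P3", "P4", "P7", "P8",
    "POz", "Oz", "O1", "O2")
}

# Approximate 2-D electrode coordinates (x: left-right in [-1, 1],
# y: posterior-anterior in [-1, 1]) used to build smooth spatial noise maps.
electrode_positions <- function(labels = default_scalp_labels()) {
  rows <- c(Fp = 1, AF = 0.8, F = 0.55, FC = 0.3, C = 0, T = 0,
            CP = -0.3, TP = -0.3, P = -0.55, PO = -0.8, O = -1)
  pos <- t(vapply(labels, function(lab) {
    prefix <- sub("^([A-Za-z]+).*$", "\\1", lab)
    prefix <- sub("z$", "", prefix)
    suffix <- sub("^[A-Za-z]+", "", lab)
    y <- rows[[prefix]]
    if (suffix == "" || suffix == "z") {
      x <- 0
    } else {
      k <- as.numeric(suffix)
      side <- if (k %% 2 == 1) -1 else 1   # odd = left
      x <- side * min(1, ceiling(k / 2) * 0.28)
    }
    c(x = x, y = y)
  }, numeric(2)))
  rownames(pos) <- labels
  pos
}

#' Experimental paradigm configuration
#'
#' Describes the session layout: runs of trials, each trial being one
#' non-emergency video immediately followed by one emergency video.  Event
#' onsets are derived from the cumulative video durations plus inter-run gaps.
#'
#' @param n_runs Number of runs per session (default 20).
#' @param trials_per_run Trials per run (default 12).
#' @param fs Sampling rate in Hz (default 1000).
#' @param non_emergency_duration Non-emergency video length in seconds
#'   (default 6; must exceed 3 s so that the pre-onset normal training window
#'   predates the emergency cleanly).
#' @param emergency_duration Emergency video length in seconds (default 5;
#'   videos are cut 5 s before impact).
#' @param inter_run_gap Gap between runs in seconds (default 5).
#' @param lead_in,lead_out Quiet padding at session start/end in seconds.
#' @param channel_labels Scalp channel labels (default the 37-channel montage).
#' @param eog_labels Two EOG channel labels.
#' @return An object of class `paradigm_config`.
#' @export
paradigm_config <- function(n_runs = 20, trials_per_run = 12, fs = 1000,
                            non_emergency_duration = 6.0,
                            emergency_duration = 5.0,
                            inter_run_gap = 5.0,
                            lead_in = 5.0, lead_out = 5.0,
                            channel_labels = default_scalp_labels(),
                            eog_labels = c("EOG1", "EOG2")) {
  if (n_runs < 1 || trials_per_run < 1)
    stopf("n_runs and trials_per_run must be >= 1")
  if (non_emergency_duration <= 0 || emergency_duration <= 0)
    stopf("video durations must be positive")
  if (fs <= 0) stopf("fs must be positive")
  if (length(channel_labels) == 0 || length(eog_labels) == 0)
    stopf("channel label lists must be non-empty")
  if (any(eog_labels %in% channel_labels))
    stopf("scalp and EOG channel labels must be disjoint")
  structure(list(
    n_runs = as.integer(n_runs), trials_per_run = as.integer(trials_per_run),
    fs = fs, non_emergency_duration = non_emergency_duration,
    emergency_duration = emergency_duration, inter_run_gap = inter_run_gap,
    lead_in = lead_in, lead_out = lead_out,
    channel_labels = channel_labels, eog_labels = eog_labels),
    class = "paradigm_config")
}

#' Build the session event schedule
#'
#' Lays out `n_runs * trials_per_run` trials; each trial contributes one
#' `non_emergency` event and, `non_emergency_duration` seconds later, one
#' `emergency` event.  Onset samples are 0-based; the event onset is the first
#' sample of the stimulus.
#'
#' @param config A [paradigm_config()].
#' @return An object of class `event_schedule`: a list with an `events`
#'   data frame (`onset_sample`, `type`, `run`, `trial`) and the config.
#' @export
build_schedule <- function(config) {
  stopifnot(inherits(config, "paradigm_config"))
  fs <- config$fs
  trial_dur <- config$non_emergency_duration + config$emergency_duration
  rows <- vector("list", config$n_runs * config$trials_per_run)
  t0 <- config$lead_in
  idx <- 1L
  for (r in seq_len(config$n_runs)) {
    for (tr in seq_len(config$trials_per_run)) {
      ne_onset <- t0
      em_onset <- t0 + config$non_emergency_duration
      rows[[idx]] <- data.frame(
        onset_sample = round(c(ne_onset, em_onset) * fs),
        type = c("non_emergency", "emergency"),
        run = r, trial = tr)
      idx <- idx + 1L
      t0 <- t0 + trial_dur
    }
    t0 <- t0 + config$inter_run_gap
  }
  events <- do.call(rbind, rows)
  duration <- t0 - config$inter_run_gap + config$lead_out
  sched <- structure(list(events = events, config = config,
                          n_samples = round(duration * fs)),
                     class = "event_schedule")
  validate_schedule(sched)
  sched
}

validate_schedule <- function(schedule) {
  ev <- schedule$events
  stim <- ev[ev$type %in% c("non_emergency", "emergency"), ]
  if (any(diff(stim$onset_sample) <= 0))
    stopf("event onsets must be strictly increasing")
  n_em <- sum(ev$type == "emergency")
  n_ne <- sum(ev$type == "non_emergency")
  if (n_em != n_ne) stopf("emergency / non-emergency counts differ")
  invisible(schedule)
}

#' @export
print.event_schedule <- function(x, ...) {
  ev <- x$events
  cat(sprintf("<event_schedule> %d runs x %d trials, %d events, %.1f s at %g Hz\n",
              x$config$n_runs, x$config$trials_per_run, nrow(ev),
              x$n_samples / x$config$fs, x$config$fs))
  for (ty in unique(ev$type))
    cat(sprintf("  %-14s %d\n", ty, sum(ev$type == ty)))
  invisible(x)
}

# Event onsets (seconds) of one type.
event_onsets <- function(schedule, type) {
  ev <- schedule$events
  ev$onset_sample[ev$type == type] / schedule$config$fs
}
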