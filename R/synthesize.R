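new_recording <- function(data, fs, channel_labels, eog_indices, schedule) {
  stopifnot(nrow(data) == length(channel_labels))
  if (!is.null(schedule) &&
      any(schedule$events$onset_sample >= ncol(data)))
    stopf("schedule onsets exceed recording length")
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 eog_indices = eog_indices, schedule = schedule),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels (%d EOG) x %d samples at %g Hz (%.1f s)\n",
              nrow(x$data), length(x$eog_indices), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  if (!is.null(x$schedule))
    cat(sprintf("  events: %d\n", nrow(x$schedule$events)))
  invisible(x)
}

scalp_indices <- function(rec) setdiff(seq_len(nrow(rec$data)), rec$eog_indices)

#' Synthesize a session recording
#'
#' Renders background noise, adds the per-condition ERP template at each
#' scheduled event onset, superimposes blink and burst artifacts, and inserts
#' a keypress event after each emergency onset at a log-normally distributed
#' reaction delay.  The result is bit-identical for a given `noise$seed`.
#'
#' @param schedule An [build_schedule()] event schedule.
#' @param templates Named list with `non_emergency` and `emergency` component
#'   lists (default [default_templates()]).
#' @param noise A [noise_spec()].
#' @param config Paradigm config (defaults to the schedule's).
#' @return An `eeg_recording`: `data` (channels x samples, uV; scalp channels
#'   first, then EOG), `fs`, labels, EOG indices and the schedule (with
#'   keypress events added).
#' @export
synthesize <- function(schedule, templates = default_templates(),
                       noise = noise_spec(), config = schedule$config) {
  stopifnot(inherits(schedule, "event_schedule"), inherits(noise, "noise_spec"))
  with_seed(noise$seed, synthesize_impl(schedule, templates, noise, config))
}

synthesize_impl <- function(schedule, templates, noise, config) {
  fs <- config$fs
  n <- schedule$n_samples
  labels <- config$channel_labels
  n_scalp <- length(labels)
  all_labels <- c(labels, config$eog_labels)
  n_ch <- length(all_labels)
  data <- matrix(0, n_ch, n, dimnames = list(all_labels, NULL))

  ## --- background -----------------------------------------------------
  sd_tot <- noise$background_sd
  sd_rhythm <- sd_tot * sqrt(noise$rhythm_fraction)
  sd_pink <- sd_tot * sqrt(noise$pink_fraction)
  sd_white <- sd_tot * sqrt(max(0, 1 - noise$rhythm_fraction - noise$pink_fraction))
  if (sd_tot > 0) {
    maps <- shared_noise_maps(labels)
    k <- ncol(maps)
    rhythm <- if (sd_rhythm > 0)
      vapply(seq_len(k), function(i) rhythm_source(n, fs, noise$rhythm_band),
             numeric(n)) else matrix(0, n, k)
    pink <- if (sd_pink > 0)
      vapply(seq_len(k), function(i) pink_source(n, fs, noise$pink_flatten_hz),
             numeric(n)) else matrix(0, n, k)
    # unit row norms of `maps` make each channel's shared variance exact
    for (i in seq_len(n_scalp)) {
      row <- if (sd_white > 0) sd_white * stats::rnorm(n) else numeric(n)
      if (sd_rhythm > 0) row <- row + sd_rhythm * drop(rhythm %*% maps[i, ])
      if (sd_pink > 0) row <- row + sd_pink * drop(pink %*% maps[i, ])
      data[i, ] <- row
    }
  }
  if (noise$eog_sd > 0)
    for (i in seq_len(n_ch - n_scalp))
      data[n_scalp + i, ] <- noise$eog_sd * stats::rnorm(n)

  ## --- ERP templates ---------------------------------------------------
  tmpl <- lapply(templates, render_erp_template, fs = fs,
                 channel_labels = labels)
  ev <- schedule$events
  for (j in seq_len(nrow(ev))) {
    ty <- ev$type[j]
    if (!ty %in% names(tmpl)) next
    tm <- tmpl[[ty]]
    off <- round(attr(tm, "times")[1] * fs)
    i0 <- ev$onset_sample[j] + off + 1L     # onsets are 0-based
    skip <- max(0L, 1L - i0)
    i0 <- i0 + skip
    len <- min(ncol(tm) - skip, n - i0 + 1L)
    if (len < ncol(tm) - skip)
      warnf("template truncated at recording end for event %d", j)
    data[seq_len(n_scalp), i0:(i0 + len - 1L)] <-
      data[seq_len(n_scalp), i0:(i0 + len - 1L)] + tm[, skip + seq_len(len)]
  }

  ## --- artifacts -------------------------------------------------------
  dur_min <- n / fs / 60
  if (noise$blink_rate > 0 && noise$blink_amplitude > 0) {
    gains <- blink_gains(labels, config$eog_labels)
    nb <- stats::rpois(1, noise$blink_rate * dur_min)
    blen <- round(noise$blink_duration * fs)
    bump <- noise$blink_amplitude * hann_bump(blen)
    if (nb > 0) {
      onsets <- sort(round(stats::runif(nb, 0, n - blen - 1)))
      for (o in onsets)
        data[, (o + 1):(o + blen)] <-
          data[, (o + 1):(o + blen)] + outer(unname(gains), bump)
    }
  }
  if (noise$burst_rate > 0 && noise$burst_amplitude > 0) {
    nb <- stats::rpois(1, noise$burst_rate * dur_min)
    blen <- round(noise$burst_duration * fs)
    env <- hann_bump(blen)
    tgrid <- (seq_len(blen) - 1) / fs
    for (b in seq_len(nb)) {
      o <- round(stats::runif(1, 0, n - blen - 1))
      chs <- sample(n_scalp, sample(1:3, 1))
      f0 <- stats::runif(1, 20, 60)
      wave <- noise$burst_amplitude * env * sin(2 * pi * f0 * tgrid +
                                                stats::runif(1, 0, 2 * pi))
      for (ch in chs)
        data[ch, (o + 1):(o + blen)] <- data[ch, (o + 1):(o + blen)] + wave
    }
  }

  ## --- keypress events -------------------------------------------------
  em <- ev[ev$type == "emergency", ]
  if (nrow(em) > 0) {
    delays <- stats::rlnorm(nrow(em), log(noise$keypress_delay_median),
                            noise$keypress_delay_sdlog)
    kp <- data.frame(onset_sample = pmin(em$onset_sample + round(delays * fs),
                                         n - 1L),
                     type = "keypress", run = em$run, trial = em$trial)
    ev <- rbind(ev, kp)
    ev <- ev[order(ev$onset_sample), ]
    rownames(ev) <- NULL
  }
  sched <- schedule
  sched$events <- ev

  new_recording(data, fs, all_labels,
                eog_indices = n_scalp + seq_along(config$eog_labels), sched)
}
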