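#' Preprocessing configuration
#'
#' Parameters of the shared offline/online preprocessing chain.  The chain
#' order is fixed: downsample, trailing-window baseline correction, ICA
#' cleaning, artifact subspace reconstruction, band-pass filtering.  All
#' stages are causal or fit-on-train-only so that the online path never uses
#' future samples.
#'
#' @param target_fs Target sampling rate in Hz (default 200).
#' @param baseline_window Trailing baseline window in samples at `target_fs`
#'   (default 100, i.e. 0.5 s).
#' @param filter_order Total band-pass order (default 4: a fourth-order
#'   Butterworth band-pass).
#' @param band Pass band in Hz (default `c(0.1, 5)`).
#' @param reject_threshold Epoch rejection threshold in uV (default 100).
#' @param ica_reject_corr Absolute Pearson correlation with an EOG channel
#'   above which an independent component is rejected (default 0.7).
#' @param asr_cutoff ASR clamp threshold in calibration SD units (default 20).
#' @param asr_block ASR reconstruction block length in seconds (default 0.5).
#' @param antialias_order Order of the anti-alias low-pass used when
#'   downsampling (default 8).
#' @return An object of class `preproc_config`.
#' @export
preproc_config <- function(target_fs = 200, baseline_window = 100,
                           filter_order = 4, band = c(0.1, 5),
                           reject_threshold = 100, ica_reject_corr = 0.7,
                           asr_cutoff = 20, asr_block = 0.5,
                           antialias_order = 8) {
  if (band[1] <= 0 || band[1] >= band[2] || band[2] >= target_fs / 2)
    stopf("band must satisfy 0 < low < high < target_fs/2")
  if (reject_threshold <= 0 || ica_reject_corr <= 0 || asr_cutoff <= 0)
    stopf("thresholds must be positive")
  structure(list(target_fs = target_fs, baseline_window = baseline_window,
                 filter_order = filter_order, band = band,
                 reject_threshold = reject_threshold,
                 ica_reject_corr = ica_reject_corr,
                 asr_cutoff = asr_cutoff, asr_block = asr_block,
                 antialias_order = antialias_order),
            class = "preproc_config")
}

#' Downsample a recording
#'
#' Causal anti-alias low-pass (Butterworth at 0.8 x the target Nyquist)
#' followed by decimation.  Event onsets are rescaled by the sampling ratio.
#'
#' @param rec An `eeg_recording`.
#' @param target_fs Target rate; must divide `rec$fs`.
#' @param order Anti-alias filter order.
#' @return The downsampled recording.
#' @export
downsample_recording <- function(rec, target_fs, order = 8) {
  r <- rec$fs / target_fs
  if (abs(r - round(r)) > 1e-9)
    stopf("target_fs (%g) must divide fs (%g)", target_fs, rec$fs)
  r <- as.integer(round(r))
  if (r == 1L) return(rec)
  coef <- butter_design(order, 0.8 * target_fs / 2, "low", rec$fs)
  data <- filter_rows(rec$data, coef)
  keep <- seq(1, ncol(data), by = r)
  data <- data[, keep, drop = FALSE]
  sched <- rec$schedule
  if (!is.null(sched)) {
    sched$events$onset_sample <- sched$events$onset_sample %/% r
    sched$n_samples <- ncol(data)
    sched$config$fs <- target_fs
  }
  new_recording(data, target_fs, rec$channel_labels, rec$eog_indices, sched)
}

#' Trailing-mean baseline correction
#'
#' Subtracts from each sample the mean of the preceding `window` samples
#' (a causal trailing mean; the first samples use the available prefix, and
#' the very first sample is left unchanged).  This is the streaming-safe
#' reading of a sliding baseline correction.
#'
#' @param x Numeric vector (single channel).
#' @param window Window length in samples (>= 1).
#' @return Numeric vector of the same length.
#' @export
sliding_baseline <- function(x, window) {
  if (window < 1) stopf("window must be >= 1")
  n <- length(x)
  if (n == 0) return(numeric(0))
  s <- cumsum(x)
  out <- numeric(n)
  out[1] <- x[1]
  if (n >= 2) {
    t2 <- 2:n
    k <- pmin(window, t2 - 1)
    lo <- t2 - 1 - k           # prefix sum index below the window
    slo <- ifelse(lo >= 1, s[pmax(lo, 1)], 0)
    out[t2] <- x[t2] - (s[t2 - 1] - slo) / k
  }
  out
}

sliding_baseline_recording <- function(rec, window) {
  idx <- scalp_indices(rec)
  for (i in idx) rec$data[i, ] <- sliding_baseline(rec$data[i, ], window)
  rec
}

#' Band-pass filter a recording
#'
#' Causal Butterworth band-pass applied per scalp channel (causal so the
#' online path never uses future samples).  `order` is the total filter
#' order; the default fourth-order band-pass has two pole pairs.
#'
#' @param rec An `eeg_recording`.
#' @param config A [preproc_config()] (uses `band` and `filter_order`).
#' @return Filtered recording.
#' @export
bandpass_recording <- function(rec, config = preproc_config()) {
  if (config$band[2] >= rec$fs / 2) stopf("band edge >= Nyquist")
  coef <- bandpass_coef(config, rec$fs)
  filter_rows_recording(rec, coef)
}

bandpass_coef <- function(config, fs)
  butter_design(max(1L, config$filter_order %/% 2L), config$band, "pass", fs)

filter_rows_recording <- function(rec, coef) {
  rec$data <- filter_rows(rec$data, coef, rows = scalp_indices(rec))
  rec
}

#' Extract epochs around events
#'
#' Cuts `[window[1], window[2])` second segments relative to each qualifying
#' event onset.  Events whose window falls outside the recording are skipped
#' with a warning.
#'
#' @param rec An `eeg_recording` with a schedule.
#' @param window Length-2 seconds relative to onset (default `c(-2, 2)`).
#' @param types Event types to epoch (default both stimulus types).
#' @return An `epoch_set`: `data` (trials x channels x samples), `labels`
#'   (condition per trial), `times`, `fs`, channel labels and EOG indices.
#' @export
extract_epochs <- function(rec, window = c(-2, 2),
                           types = c("non_emergency", "emergency")) {
  stopifnot(!is.null(rec$schedule))
  ev <- rec$schedule$events
  ev <- ev[ev$type %in% types, , drop = FALSE]
  span <- round((window[2] - window[1]) * rec$fs)
  n <- ncol(rec$data)
  start <- ev$onset_sample + round(window[1] * rec$fs)   # 0-based
  ok <- start >= 0 & (start + span) <= n
  if (any(!ok))
    warnf("%d event(s) skipped: epoch window outside recording", sum(!ok))
  ev <- ev[ok, , drop = FALSE]
  start <- start[ok]
  arr <- array(0, dim = c(nrow(ev), nrow(rec$data), span),
               dimnames = list(NULL, rec$channel_labels, NULL))
  for (j in seq_len(nrow(ev)))
    arr[j, , ] <- rec$data[, (start[j] + 1):(start[j] + span), drop = FALSE]
  new_epoch_set(arr, labels = ev$type,
                times = window[1] + (seq_len(span) - 1) / rec$fs,
                fs = rec$fs, channel_labels = rec$channel_labels,
                eog_indices = rec$eog_indices, events = ev,
                n_skipped = sum(!ok))
}

new_epoch_set <- function(data, labels, times, fs, channel_labels,
                          eog_indices, events = NULL, n_skipped = 0) {
  stopifnot(dim(data)[1] == length(labels),
            dim(data)[3] == length(times))
  structure(list(data = data, labels = as.character(labels), times = times,
                 fs = fs, channel_labels = channel_labels,
                 eog_indices = eog_indices, events = events,
                 n_skipped = n_skipped),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples at %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs))
  print(table(x$labels))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param epochs An `epoch_set`.
#' @return Integer count.
#' @export
n_epochs <- function(epochs) dim(epochs$data)[1]

subset_epochs <- function(epochs, idx) {
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$labels <- epochs$labels[idx]
  if (!is.null(epochs$events)) epochs$events <- epochs$events[idx, , drop = FALSE]
  epochs
}

#' Reject epochs on peak amplitude
#'
#' Drops epochs whose maximum absolute scalp-channel amplitude exceeds the
#' threshold.
#'
#' @param epochs An `epoch_set`.
#' @param threshold Rejection threshold in uV (default 100).
#' @return The retained `epoch_set`, with a `rejection` attribute listing
#'   retained/dropped counts.
#' @export
reject_amplitude <- function(epochs, threshold = 100) {
  scalp <- setdiff(seq_len(dim(epochs$data)[2]), epochs$eog_indices)
  peak <- apply(abs(epochs$data[, scalp, , drop = FALSE]), 1, max)
  keep <- peak <= threshold
  out <- subset_epochs(epochs, keep)
  attr(out, "rejection") <- list(retained = sum(keep), dropped = sum(!keep),
                                 threshold = threshold)
  out
}

#' Extract classifier training samples
#'
#' Relative to each emergency onset, cuts a `normal` epoch from
#' `[-3, -2.5]` s (quiet pre-event activity) and an `emergency` epoch from
#' `[-0.25, 0.25]` s, yielding two balanced classes of 0.5-s epochs.
#' Emergency events without 3 s of preceding data are skipped with a warning.
#'
#' @param rec A preprocessed `eeg_recording` with schedule.
#' @param normal_window,emergency_window Seconds relative to emergency onset.
#' @return A labelled `epoch_set` (times are within-epoch seconds).
#' @export
extract_training_samples <- function(rec, normal_window = c(-3, -2.5),
                                     emergency_window = c(-0.25, 0.25)) {
  ev <- rec$schedule$events
  em <- ev[ev$type == "emergency", , drop = FALSE]
  span <- round((normal_window[2] - normal_window[1]) * rec$fs)
  span_e <- round((emergency_window[2] - emergency_window[1]) * rec$fs)
  stopifnot(span == span_e)
  n <- ncol(rec$data)
  s_norm <- em$onset_sample + round(normal_window[1] * rec$fs)
  s_emrg <- em$onset_sample + round(emergency_window[1] * rec$fs)
  ok <- s_norm >= 0 & (s_emrg + span) <= n
  if (any(!ok)) warnf("%d emergency event(s) skipped: insufficient context",
                      sum(!ok))
  em <- em[ok, , drop = FALSE]
  s_norm <- s_norm[ok]; s_emrg <- s_emrg[ok]
  m <- nrow(em)
  arr <- array(0, dim = c(2 * m, nrow(rec$data), span),
               dimnames = list(NULL, rec$channel_labels, NULL))
  for (j in seq_len(m)) {
    arr[j, , ] <- rec$data[, (s_norm[j] + 1):(s_norm[j] + span)]
    arr[m + j, , ] <- rec$data[, (s_emrg[j] + 1):(s_emrg[j] + span)]
  }
  new_epoch_set(arr, labels = rep(c("normal", "emergency"), each = m),
                times = (seq_len(span) - 1) / rec$fs, fs = rec$fs,
                channel_labels = rec$channel_labels,
                eog_indices = rec$eog_indices,
                events = rbind(em, em), n_skipped = sum(!ok))
}

#' Fit the full preprocessing chain on a training recording
#'
#' Runs downsample, trailing baseline, ICA (fit + clean), ASR (calibrate +
#' clean) and band-pass in the fixed chain order, returning both the
#' processed recording and the fitted state (ICA unmixing matrix, rejected
#' components, ASR calibration, config).  The state is reused verbatim on
#' test data and in the online path.
#'
#' @param rec Raw `eeg_recording`.
#' @param config A [preproc_config()].
#' @param seed Seed for the ICA initialisation.
#' @return List with `recording` (processed) and `state` (`preproc_state`).
#' @export
fit_preproc <- function(rec, config = preproc_config(), seed = 1) {
  ds <- downsample_recording(rec, config$target_fs, config$antialias_order)
  bl <- sliding_baseline_recording(ds, config$baseline_window)
  ica <- fit_ica(bl, config, seed = seed)
  cl <- apply_ica(bl, ica)
  asr <- asr_calibrate(cl, config)
  cl <- asr_clean(cl, asr, block = config$asr_block)
  bp <- bandpass_recording(cl, config)
  state <- structure(list(ica = ica, asr = asr, config = config),
                     class = "preproc_state")
  list(recording = bp, state = state)
}

#' Apply a fitted preprocessing chain to new data
#'
#' Same chain as [fit_preproc()], but the ICA unmixing matrix and the ASR
#' calibration fitted on the training data are applied directly.
#'
#' @param rec Raw `eeg_recording`.
#' @param state A `preproc_state` from [fit_preproc()].
#' @return Processed `eeg_recording`.
#' @export
apply_preproc <- function(rec, state) {
  config <- state$config
  ds <- downsample_recording(rec, config$target_fs, config$antialias_order)
  bl <- sliding_baseline_recording(ds, config$baseline_window)
  cl <- apply_ica(bl, state$ica)
  cl <- asr_clean(cl, state$asr, block = config$asr_block)
  bandpass_recording(cl, config)
}
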