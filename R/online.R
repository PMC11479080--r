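#' Online streaming protocol configuration
#'
#' @param command_period Command cadence in seconds (default 0.2: one
#'   command every 200 ms).
#' @param buffer_extract Length of the buffer segment consulted per command,
#'   seconds (default 1).
#' @param classify_span Portion of the extracted segment actually classified
#'   (the most recent part), seconds; must match the trained epoch length
#'   (default 0.5).
#' @param consecutive_required Number of consecutive emergency commands that
#'   constitute a detection (default 2).
#' @param hit_window Seconds after an emergency onset within which a
#'   detection counts as a hit (default 1).
#' @param refractory Suppression period after a detection, seconds (default 1).
#' @return An object of class `stream_config`.
#' @export
stream_config <- function(command_period = 0.2, buffer_extract = 1.0,
                          classify_span = 0.5, consecutive_required = 2,
                          hit_window = 1.0, refractory = 1.0) {
  if (classify_span > buffer_extract)
    stopf("classify_span must not exceed buffer_extract")
  if (consecutive_required < 1) stopf("consecutive_required must be >= 1")
  structure(list(command_period = command_period,
                 buffer_extract = buffer_extract,
                 classify_span = classify_span,
                 consecutive_required = consecutive_required,
                 hit_window = hit_window, refractory = refractory),
            class = "stream_config")
}

#' Replay a recording as a stream and emit classifier commands
#'
#' Simulates the online loop on a virtual clock: every `command_period`
#' seconds the newly arrived raw samples are pushed through the causal
#' preprocessing chain (anti-alias + decimation, trailing baseline, the
#' train-fit ICA projection, per-chunk ASR clamp, causal band-pass, all with
#' carried filter state), and once the buffer holds `buffer_extract` seconds
#' the most recent `classify_span` seconds are classified, appending one
#' command.  No sample later than the current clock is ever read.
#'
#' @param rec Raw `eeg_recording` at the acquisition rate.
#' @param model A fitted `hdca_model`.
#' @param state A `preproc_state` fit on the offline (training) data.
#' @param config A [stream_config()].
#' @return A `command_log` data frame: `time` (s), `label`, `score`.
#' @export
stream_decode <- function(rec, model, state, config = stream_config()) {
  pc <- state$config
  fs <- rec$fs
  r <- as.integer(round(fs / pc$target_fs))
  if (abs(fs / pc$target_fs - r) > 1e-9) stopf("target_fs must divide fs")
  scalp <- scalp_indices(rec)
  p <- length(scalp)
  aa_coef <- butter_design(pc$antialias_order, 0.8 * pc$target_fs / 2, "low", fs)
  bp_coef <- bandpass_coef(pc, pc$target_fs)
  aa_state <- vector("list", p)
  bp_state <- vector("list", p)
  base_prev <- matrix(numeric(0), p, 0)   # trailing raw samples per channel
  n_seen <- 0L                            # downsampled samples seen so far
  chunk_raw <- round(config$command_period * fs)
  n <- ncol(rec$data)
  n_ds_total <- length(seq(1, n, by = r))
  proc <- matrix(0, p, n_ds_total)        # processed buffer (grows virtually)
  filled <- 0L
  span <- round(config$classify_span * pc$target_fs)
  spw <- model$samples_per_window
  nw <- model$n_windows
  if (span != spw * nw)
    stopf("classify_span does not match the trained epoch geometry")
  out_t <- numeric(0); out_s <- numeric(0)
  raw_pos <- 0L
  while (raw_pos < n) {
    upto <- min(n, raw_pos + chunk_raw)
    idx <- (raw_pos + 1):upto
    chunk <- rec$data[scalp, idx, drop = FALSE]
    ds_rows <- vector("list", p)
    for (i in seq_len(p)) {
      fl <- iir_filter(aa_coef, chunk[i, ], aa_state[[i]])
      aa_state[[i]] <- fl$state
      # keep raw-grid samples with (global index - 1) %% r == 0
      keep <- which((idx - 1) %% r == 0)
      ds_rows[[i]] <- fl$y[keep]
    }
    m <- length(ds_rows[[1]])
    if (m > 0) {
      ds <- do.call(rbind, ds_rows)
      # trailing baseline with carried prefix
      w <- pc$baseline_window
      ext <- cbind(base_prev, ds)
      k0 <- ncol(base_prev)
      bl <- matrix(0, p, m)
      cums <- t(apply(ext, 1, cumsum))
      if (n_seen == 0 && m >= 1) bl[, 1] <- ds[, 1]
      for (j in seq_len(m)) {
        tglob <- n_seen + j
        if (tglob == 1) next
        kk <- min(w, tglob - 1)
        hi <- k0 + j - 1
        lo <- hi - kk
        slo <- if (lo >= 1) cums[, lo] else 0
        bl[, j] <- ds[, j] - (cums[, hi] - slo) / kk
      }
      base_prev <- ext[, max(1, ncol(ext) - w + 1):ncol(ext), drop = FALSE]
      n_seen <- n_seen + m
      # ICA projection (memoryless), per-chunk ASR clamp, causal band-pass
      bl <- ica_clean_matrix(bl, state$ica)
      bl <- asr_clean_block(bl, state$asr)
      for (i in seq_len(p)) {
        fl <- iir_filter(bp_coef, bl[i, ], bp_state[[i]])
        bp_state[[i]] <- fl$state
        bl[i, ] <- fl$y
      }
      proc[, (filled + 1):(filled + m)] <- bl
      filled <- filled + m
    }
    raw_pos <- upto
    clock <- raw_pos / fs
    if (clock + 1e-9 >= config$buffer_extract && filled >= span) {
      seg <- proc[, (filled - span + 1):filled, drop = FALSE]
      x <- array(0, dim = c(1, p, span))
      x[1, , ] <- seg
      vals <- array(0, dim = c(1, nw, p))
      for (wdx in seq_len(nw))
        vals[1, wdx, ] <- rowMeans(seg[, ((wdx - 1) * spw + 1):(wdx * spw),
                                       drop = FALSE])
      y <- numeric(nw)
      for (wdx in seq_len(nw))
        y[wdx] <- sum(vals[1, wdx, ] * model$window_weights[, wdx])
      sc <- sum(y * model$second_stage$weights) + model$second_stage$bias
      out_t <- c(out_t, clock)
      out_s <- c(out_s, sc)
    }
  }
  structure(data.frame(time = out_t,
                       label = ifelse(out_s > 0, model$positive_class,
                                      model$negative_class),
                       score = out_s),
            class = c("command_log", "data.frame"))
}

#' Turn a command log into detections
#'
#' A detection is declared at the time of the Nth consecutive emergency
#' command (`consecutive_required`); after a detection, further detections
#' are suppressed for `refractory` seconds and the consecutive counter
#' restarts.
#'
#' @param commands A `command_log` (or data frame with `time` and `label`).
#' @param config A [stream_config()].
#' @return Numeric vector of detection times (s).
#' @export
detect_events <- function(commands, config = stream_config()) {
  need <- config$consecutive_required
  det <- numeric(0)
  streak <- 0L
  last_det <- -Inf
  for (j in seq_len(nrow(commands))) {
    if (commands$time[j] <= last_det + config$refractory) { streak <- 0L; next }
    if (commands$label[j] == "emergency") {
      streak <- streak + 1L
      if (streak >= need) {
        det <- c(det, commands$time[j])
        last_det <- commands$time[j]
        streak <- 0L
      }
    } else streak <- 0L
  }
  det
}

#' Score detections against the event schedule
#'
#' Recall is the percentage of emergency events with a detection within
#' `hit_window` seconds of onset; FAR is the percentage of emergency-labelled
#' commands among all commands issued during normal stages (clock times
#' outside `[onset, onset + hit_window]` of every emergency event); accuracy
#' is `(recall + (100 - FAR)) / 2`; the response time of a hit is the first
#' in-window detection time minus the onset.
#'
#' @param detections Detection times from [detect_events()].
#' @param commands The `command_log`.
#' @param schedule The session `event_schedule`.
#' @param config A [stream_config()].
#' @return A `detection_report`.
#' @export
score_detections <- function(detections, commands, schedule,
                             config = stream_config()) {
  if (nrow(commands) == 0) stopf("empty command log")
  onsets <- event_onsets(schedule, "emergency")
  if (length(onsets) == 0) stopf("schedule contains no emergency events")
  hits <- logical(length(onsets))
  rt <- rep(NA_real_, length(onsets))
  for (j in seq_along(onsets)) {
    inwin <- detections[detections >= onsets[j] &
                        detections <= onsets[j] + config$hit_window]
    if (length(inwin) > 0) { hits[j] <- TRUE; rt[j] <- inwin[1] - onsets[j] }
  }
  in_any_hit_window <- vapply(commands$time, function(tt)
    any(tt >= onsets & tt <= onsets + config$hit_window), logical(1))
  normal_cmd <- commands[!in_any_hit_window, , drop = FALSE]
  far <- if (nrow(normal_cmd) == 0) 0 else
    100 * mean(normal_cmd$label == "emergency")
  recall <- 100 * mean(hits)
  new_detection_report(
    detections = detections,
    per_event = data.frame(onset = onsets, hit = hits, response_time = rt),
    recall = recall, far = far,
    mean_response_time = if (any(hits)) 1000 * mean(rt[hits]) else NA_real_,
    n_commands = nrow(commands), n_normal_commands = nrow(normal_cmd))
}

new_detection_report <- function(detections, per_event, recall, far,
                                 mean_response_time, n_commands,
                                 n_normal_commands) {
  stopifnot(recall >= 0, recall <= 100, far >= 0, far <= 100)
  structure(list(detections = detections, per_event = per_event,
                 recall = recall, far = far,
                 accuracy = eq2_accuracy(recall, far),
                 mean_response_time = mean_response_time,
                 n_commands = n_commands,
                 n_normal_commands = n_normal_commands),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat("<detection_report>\n")
  cat(sprintf("  accuracy  %6.2f%%\n  recall    %6.2f%%\n  FAR       %6.2f%%\n",
              x$accuracy, x$recall, x$far))
  if (!is.na(x$mean_response_time))
    cat(sprintf("  response  %6.2f ms\n", x$mean_response_time))
  cat(sprintf("  commands  %d (%d in normal stages), detections %d\n",
              x$n_commands, x$n_normal_commands, length(x$detections)))
  invisible(x)
}

#' Run a full offline-training / online-testing experiment
#'
#' Generates an offline session (model training) and an online session
#' (streamed detection) for one synthetic subject, mirroring the
#' 10-offline-runs / 10-online-runs protocol: the preprocessing state and the
#' HDCA model are fit on the offline portion only, the online portion is
#' replayed through [stream_decode()], and the command log is scored.
#'
#' @param n_offline_runs,n_online_runs Runs per portion (defaults 10 and 10).
#' @param templates Per-condition ERP component lists.
#' @param noise A [noise_spec()]; its seed is ignored in favour of `seed`.
#' @param paradigm Base [paradigm_config()] (run counts overridden).
#' @param preproc A [preproc_config()].
#' @param stream A [stream_config()].
#' @param seed Master seed (offline session uses `seed`, online `seed + 1`).
#' @return List: `report` (overall `detection_report`), `per_run` recall /
#'   response-time breakdown, `model`, `state`, `cv` (NULL unless
#'   `offline_cv = TRUE`).
#' @param offline_cv Also cross-validate the offline training samples.
#' @export
run_online_experiment <- function(n_offline_runs = 10, n_online_runs = 10,
                                  templates = default_templates(),
                                  noise = noise_spec(),
                                  paradigm = paradigm_config(),
                                  preproc = preproc_config(),
                                  stream = stream_config(),
                                  seed = 1, offline_cv = FALSE) {
  make_session <- function(n_runs, sd) {
    cfg <- paradigm
    cfg$n_runs <- as.integer(n_runs)
    ns <- noise; ns$seed <- sd
    synthesize(build_schedule(cfg), templates, ns, cfg)
  }
  off <- make_session(n_offline_runs, seed)
  fitted <- fit_preproc(off, preproc, seed = seed)
  train <- extract_training_samples(fitted$recording)
  model <- fit_hdca(train,
                    noise_cov = background_covariance(fitted$recording))
  cv <- if (offline_cv)
    crossvalidate_hdca(train, seed = seed) else NULL
  on <- make_session(n_online_runs, seed + 1L)
  commands <- stream_decode(on, model, fitted$state, stream)
  detections <- detect_events(commands, stream)
  report <- score_detections(detections, commands, on$schedule, stream)
  ev <- on$schedule$events
  em <- ev[ev$type == "emergency", ]
  per_event <- report$per_event
  per_event$run <- em$run
  per_run <- do.call(rbind, lapply(split(per_event, per_event$run), function(d)
    data.frame(run = d$run[1], recall = 100 * mean(d$hit),
               mean_response_time = if (any(d$hit))
                 1000 * mean(d$response_time[d$hit]) else NA_real_)))
  list(report = report, per_run = per_run, model = model,
       state = fitted$state, commands = commands, cv = cv)
}
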