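mk_commands <- function(labels, period = 0.2, start = 0) {
  structure(data.frame(time = start + period * (seq_along(labels) - 1),
                       label = labels, score = ifelse(labels == "emergency", 1, -1)),
            class = c("command_log", "data.frame"))
}

test_that("two-consecutive detection rule on hand-simulated command logs", {
  cfg <- stream_config()
  det <- detect_events(mk_commands(c("normal", "normal", "emergency",
                                     "emergency", "normal")), cfg)
  expect_equal(det, 0.6)
  expect_length(detect_events(mk_commands(rep("normal", 10)), cfg), 0)
  expect_length(detect_events(
    mk_commands(c("emergency", "normal", "emergency", "normal", "emergency")),
    cfg), 0)
  # refractory suppresses immediate re-detection
  det2 <- detect_events(mk_commands(rep("emergency", 12)), cfg)
  expect_equal(det2[1], 0.2)
  expect_true(all(diff(det2) > cfg$refractory))
})

test_that("scoring arithmetic reproduces the accuracy identity", {
  expect_equal(eq2_accuracy(91.67, 8.85), 91.41)
  expect_equal(eq2_accuracy(100, 0), 100)
  expect_equal(eq2_accuracy(0, 0), 50)
  expect_equal(eq2_accuracy(82.11, 20.63), 80.74)
})

test_that("score_detections: hits, FAR partition and the all-normal case", {
  cfg <- small_config(n_runs = 1, trials_per_run = 2, fs = 100)
  sch <- build_schedule(cfg)
  onsets <- emergeeg:::event_onsets(sch, "emergency")
  sc <- stream_config()
  # commands covering the session, all normal
  n_cmd <- floor(sch$n_samples / 100 / 0.2)
  cmd <- mk_commands(rep("normal", n_cmd), start = 1)
  rep0 <- score_detections(numeric(0), cmd, sch, sc)
  expect_equal(rep0$recall, 0)
  expect_equal(rep0$far, 0)
  expect_equal(rep0$accuracy, 50)
  # one hit inside the window, one miss; some false emergency commands
  labels <- rep("normal", n_cmd)
  times <- 1 + 0.2 * (seq_len(n_cmd) - 1)
  hit_slot <- which(times >= onsets[1] & times <= onsets[1] + 1)[1:2]
  labels[hit_slot] <- "emergency"
  far_slots <- which(times < onsets[1] - 2)[1:5]
  labels[far_slots] <- "emergency"
  cmd <- mk_commands(labels, start = 1)
  det <- detect_events(cmd, sc)
  rep1 <- score_detections(det, cmd, sch, sc)
  expect_equal(rep1$recall, 50)
  n_normal <- rep1$n_normal_commands
  expect_equal(rep1$far, 100 * 5 / n_normal)
  expect_equal(rep1$accuracy, (rep1$recall + 100 - rep1$far) / 2)
  # response time: second command of the pair minus the onset
  expect_equal(rep1$per_event$response_time[1],
               times[hit_slot[2]] - onsets[1])
})

test_that("minimum response time equals the confirmation lag", {
  # detection cannot precede the Nth consecutive command after onset
  sc <- stream_config()
  onset <- 2.0
  labels <- rep("normal", 40)
  times0 <- 1 + 0.2 * (0:39)
  first_post <- which(times0 >= onset)[1]
  labels[first_post:(first_post + 1)] <- "emergency"
  cmd <- mk_commands(labels, start = 1)
  det <- detect_events(cmd, sc)
  expect_gte(det[1] - onset,
             (sc$consecutive_required - 1) * sc$command_period)
})

test_that("stream_decode emits the right command cadence", {
  cfg <- small_config(n_runs = 1, trials_per_run = 3, fs = 400)
  rec <- small_session(seed = 31, config = cfg)
  fitted <- fit_preproc(rec, preproc_config(), seed = 1)
  tr <- extract_training_samples(fitted$recording)
  model <- fit_hdca(tr)
  cmd <- stream_decode(rec, model, fitted$state)
  dur <- ncol(rec$data) / rec$fs
  expect_equal(nrow(cmd), floor((dur - 1) / 0.2) + 1)
  expect_equal(cmd$time[1], 1.0)
  expect_equal(unique(round(diff(cmd$time), 10)), 0.2)
})

test_that("streaming is causal: corrupting future samples changes nothing", {
  cfg <- small_config(n_runs = 1, trials_per_run = 3, fs = 400)
  rec <- small_session(seed = 32, config = cfg)
  fitted <- fit_preproc(rec, preproc_config(), seed = 1)
  tr <- extract_training_samples(fitted$recording)
  model <- fit_hdca(tr)
  cmd <- stream_decode(rec, model, fitted$state)
  # corrupt everything after the time of command k; commands up to k must
  # be bit-identical
  k <- 25
  cut <- round(cmd$time[k] * rec$fs)
  rec2 <- rec
  rec2$data[, (cut + 1):ncol(rec2$data)] <- 9999
  cmd2 <- stream_decode(rec2, model, fitted$state)
  expect_identical(cmd$score[1:k], cmd2$score[1:k])
})

test_that("streamed preprocessing matches the batch chain sample-exactly", {
  # same causal chain, chunked with carried state vs applied in one pass
  cfg <- small_config(n_runs = 1, trials_per_run = 3, fs = 400)
  rec <- small_session(seed = 33, config = cfg)
  pc <- preproc_config()
  fitted <- fit_preproc(rec, pc, seed = 2)
  batch <- apply_preproc(rec, fitted$state)
  tr <- extract_training_samples(fitted$recording)
  model <- fit_hdca(tr)
  cmd <- stream_decode(rec, model, fitted$state)
  # recompute the last command's features from the batch recording
  sc <- stream_config()
  span <- round(sc$classify_span * pc$target_fs)
  last_t <- tail(cmd$time, 1)
  upto <- length(seq(1, round(last_t * rec$fs), by = 2))
  seg <- batch$data[seq_len(37), (upto - span + 1):upto]
  spw <- model$samples_per_window
  y <- vapply(seq_len(model$n_windows), function(w)
    sum(rowMeans(seg[, ((w - 1) * spw + 1):(w * spw)]) *
          model$window_weights[, w]), numeric(1))
  sc_batch <- sum(y * model$second_stage$weights) + model$second_stage$bias
  # ASR blocking differs between paths only when a block is clamped; on this
  # quiet recording no clamping occurs and the paths agree to rounding
  expect_equal(tail(cmd$score, 1), sc_batch, tolerance = 1e-6)
})

test_that("a noise-free stream fires only around emergencies", {
  cfg <- small_config(n_runs = 1, trials_per_run = 3, fs = 400)
  rec0 <- small_session(noise = quiet_noise(seed = 41), config = cfg)
  # train on a separate noisy session so the model is non-degenerate
  rec_tr <- small_session(seed = 42, config = small_config(n_runs = 2,
                                                           trials_per_run = 6,
                                                           fs = 400))
  fitted <- fit_preproc(rec_tr, preproc_config(), seed = 1)
  tr <- extract_training_samples(fitted$recording)
  model <- fit_hdca(tr)
  cmd <- stream_decode(rec0, model, fitted$state)
  em <- cmd[cmd$label == "emergency", ]
  ev <- rec0$schedule$events
  stim <- ev$onset_sample[ev$type != "keypress"] / rec0$fs
  # emergency-labelled commands may only occur where some stimulus template
  # is in play: the template span plus the slow rebound tail of the 0.1-Hz
  # high-pass pole (time constant ~1.6 s)
  near_any_event <- vapply(em$time, function(tt)
    any(tt >= stim - 0.4 & tt <= stim + 4), logical(1))
  expect_true(all(near_any_event))
  expect_gt(nrow(em), 0)
})

test_that("detection reports respect the accuracy identity and ranges", {
  cfg <- small_config(n_runs = 1, trials_per_run = 3, fs = 400)
  rec <- small_session(seed = 51, config = cfg)
  fitted <- fit_preproc(rec, preproc_config(), seed = 1)
  tr <- extract_training_samples(fitted$recording)
  model <- fit_hdca(tr)
  sc <- stream_config()
  cmd <- stream_decode(rec, model, fitted$state, sc)
  repx <- score_detections(detect_events(cmd, sc), cmd, rec$schedule, sc)
  expect_equal(repx$accuracy, (repx$recall + (100 - repx$far)) / 2)
  expect_true(repx$recall >= 0 && repx$recall <= 100)
  expect_true(repx$far >= 0 && repx$far <= 100)
  expect_true(all(repx$per_event$response_time >= 0, na.rm = TRUE))
})
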