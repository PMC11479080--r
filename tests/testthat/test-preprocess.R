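make_rec <- function(data, fs, eog = integer(0), schedule = NULL) {
  emergeeg:::new_recording(data, fs,
                           c(paste0("ch", seq_len(nrow(data) - length(eog))),
                             rep("EOG1", length(eog))),
                           eog_indices = eog, schedule = schedule)
}

test_that("downsampling: sample counts, DC preservation, alias rejection", {
  fs <- 1000
  n <- 10 * fs
  t <- (seq_len(n) - 1) / fs
  data <- rbind(rep(2.5, n), sin(2 * pi * 400 * t))
  rec <- make_rec(data, fs)
  ds <- downsample_recording(rec, 200)
  expect_equal(ncol(ds$data), 2000)
  expect_equal(ds$fs, 200)
  # DC unchanged
  expect_equal(unname(ds$data[1, ]), rep(2.5, 2000), tolerance = 1e-6)
  # 400 Hz content attenuated below 1 % after the anti-alias filter
  expect_lt(max(abs(ds$data[2, 100:2000])), 0.01)
  # non-integer ratio rejected
  expect_error(downsample_recording(rec, 300), "divide")
})

test_that("downsampling rescales event onsets by the sampling ratio", {
  cfg <- small_config(fs = 1000)
  rec <- small_session(noise = quiet_noise(), config = cfg)
  ds <- downsample_recording(rec, 200)
  expect_equal(ds$schedule$events$onset_sample,
               rec$schedule$events$onset_sample %/% 5)
})

test_that("sliding baseline: constant, ramp and brute-force oracle", {
  expect_equal(sliding_baseline(numeric(0), 10), numeric(0))
  y <- sliding_baseline(rep(3.7, 200), 100)
  expect_equal(y[1], 3.7)
  expect_equal(y[-1], rep(0, 199), tolerance = 1e-12)
  # trailing mean of a ramp converges to m*(w+1)/2
  m <- 0.25; w <- 100
  y <- sliding_baseline(m * seq_len(1000), w)
  expect_equal(tail(y, 1), m * (w + 1) / 2, tolerance = 1e-9)
  # naive O(n*w) oracle on random input
  set.seed(11)
  x <- rnorm(400)
  brute <- vapply(seq_along(x), function(t)
    if (t == 1) x[1] else x[t] - mean(x[max(1, t - 30):(t - 1)]), numeric(1))
  expect_equal(sliding_baseline(x, 30), brute, tolerance = 1e-12)
})

test_that("band-pass: DC removal and magnitude response at 2 and 20 Hz", {
  fs <- 200
  n <- 40 * fs
  t <- (seq_len(n) - 1) / fs
  rec <- make_rec(rbind(rep(5, n), sin(2 * pi * 20 * t), sin(2 * pi * 2 * t)), fs)
  bp <- bandpass_recording(rec, preproc_config())
  tailidx <- (n / 2):n
  expect_lt(max(abs(bp$data[1, tailidx])), 1e-6)            # DC -> 0
  a20 <- max(abs(bp$data[2, tailidx]))
  expect_lt(20 * log10(a20), -20)                            # > 20 dB down
  a2 <- max(abs(bp$data[3, tailidx]))
  expect_gt(20 * log10(a2), -3)                              # within 3 dB
  expect_error(bandpass_recording(make_rec(matrix(0, 1, 100), 8),
                                  preproc_config()), "Nyquist|band")
})

test_that("ICA isolates a known ocular source and cleaning is conservative", {
  set.seed(21)
  fs <- 200; n <- 60 * fs
  blink <- rep(0, n)
  for (o in seq(400, n - 200, by = 1500))
    blink[o:(o + 59)] <- 120 * sin(pi * (1:60) / 60)^2
  p <- 8
  S <- rbind(matrix(rnorm((p - 1) * n), p - 1, n), blink)
  A <- diag(p); A[1, p] <- 0.8; A[2, p] <- 0.6      # blink mixed frontally
  X <- A %*% S
  eogn <- blink + rnorm(n, 0, 1)
  rec <- make_rec(rbind(X, eogn), fs, eog = p + 1)
  st <- fit_ica(rec, preproc_config(), seed = 2)
  expect_gte(length(st$rejected), 1)
  cleaned <- apply_ica(rec, st)
  expect_lt(abs(cor(cleaned$data[1, ], blink)), 0.2)
  expect_lt(var(cleaned$data[1, ]), var(rec$data[1, ]))
  # EOG channel untouched
  expect_identical(cleaned$data[p + 1, ], rec$data[p + 1, ])
  # cleaning is strictly linear
  rec2 <- rec; rec2$data <- 2 * rec$data
  expect_equal(apply_ica(rec2, st)$data, 2 * cleaned$data, tolerance = 1e-9)
})

test_that("ICA with no EOG activity rejects nothing and is then an identity", {
  set.seed(22)
  fs <- 200; n <- 40 * fs
  X <- matrix(rnorm(6 * n), 6, n)
  rec <- make_rec(rbind(X, rnorm(n)), fs, eog = 7)
  st <- fit_ica(rec, preproc_config(), seed = 3)
  expect_length(st$rejected, 0)
  expect_identical(apply_ica(rec, st)$data, rec$data)
  # determinism given seed
  st2 <- fit_ica(rec, preproc_config(), seed = 3)
  expect_equal(st$unmixing, st2$unmixing)
})

test_that("ASR clamps bursts, leaves clean data alone, and is idempotent", {
  set.seed(23)
  fs <- 200; n <- 80 * fs
  X <- matrix(rnorm(6 * n, 0, 5), 6, n)
  burst_at <- 70 * fs
  Xb <- X
  Xb[3, burst_at:(burst_at + 39)] <- Xb[3, burst_at:(burst_at + 39)] +
    500 * sin(pi * (1:40) / 40)^2
  rec <- make_rec(Xb, fs)
  st <- asr_calibrate(rec, preproc_config())
  cleaned <- asr_clean(rec, st)
  expect_lt(max(abs(cleaned$data[3, burst_at:(burst_at + 39)])), 100)
  # burst-free portions barely change
  pre <- 1:(60 * fs)
  expect_lt(mean(abs(cleaned$data[, pre] - Xb[, pre])), 0.05 * sd(X))
  twice <- asr_clean(cleaned, st)
  expect_equal(twice$data, cleaned$data, tolerance = 0.05 * sd(X))
  expect_error(asr_clean(rec, list(V = NULL)), "calibration")
})

test_that("epoch extraction: counts, geometry and boundary handling", {
  cfg <- small_config(fs = 500)
  rec <- small_session(noise = quiet_noise(), config = cfg)
  ds <- downsample_recording(rec, 250)
  ep <- extract_epochs(ds, c(-2, 2))
  expect_equal(dim(ep$data)[3], 1000)
  expect_equal(sum(ep$labels == "emergency"), 6)
  expect_equal(sum(ep$labels == "non_emergency"), 6)
  # an event too close to the recording start is skipped with a warning
  rec2 <- rec
  rec2$schedule$events$onset_sample[1] <- 10
  expect_warning(ep2 <- extract_epochs(rec2, c(-2, 2)), "skipped")
  expect_equal(n_epochs(ep2), 11)
  expect_equal(ep2$n_skipped, 1)
})

test_that("amplitude rejection drops exactly the exceeding epochs", {
  ep <- epoch_fixture(n_per_class = 5, sd = 1)          # 10 epochs
  ep$data[c(2, 5, 9), 3, 50] <- 150
  kept <- reject_amplitude(ep, 100)
  expect_equal(n_epochs(kept), 7)
  expect_equal(attr(kept, "rejection")$dropped, 3)
  # all-clean input is an identity
  ep2 <- epoch_fixture(n_per_class = 4, sd = 1)
  kept2 <- reject_amplitude(ep2, 100)
  expect_equal(kept2$data, ep2$data)
})

test_that("training-sample extraction yields balanced 0.5-s classes", {
  cfg <- small_config(fs = 1000)
  rec <- small_session(noise = quiet_noise(), config = cfg)
  ds <- downsample_recording(rec, 200)
  tr <- extract_training_samples(ds)
  expect_equal(dim(tr$data)[3], 100)              # 0.5 s at 200 Hz
  expect_equal(sum(tr$labels == "normal"), 6)
  expect_equal(sum(tr$labels == "emergency"), 6)
  # noise-free: emergency class carries signal at POz, normal class none
  poz <- match("POz", tr$channel_labels)
  em_mean <- mean(abs(tr$data[tr$labels == "emergency", poz, ]))
  no_mean <- mean(abs(tr$data[tr$labels == "normal", poz, ]))
  expect_gt(em_mean, 0.05)
  expect_lt(no_mean, 1e-9)
})

test_that("the full chain is approximately idempotent on clean data", {
  cfg <- small_config(n_runs = 2, trials_per_run = 4, fs = 1000)
  rec <- small_session(seed = 6, config = cfg,
                       noise = noise_spec(seed = 6, blink_rate = 4,
                                          burst_rate = 0.5))
  pc <- preproc_config()
  one <- fit_preproc(rec, pc, seed = 1)$recording
  # re-apply the data-driven stages to the already-clean recording
  ica2 <- fit_ica(one, pc, seed = 1)
  two <- apply_ica(one, ica2)
  asr2 <- asr_calibrate(two, pc)
  two <- asr_clean(two, asr2)
  scalp <- seq_len(37)
  rel <- mean(abs(two$data[scalp, ] - one$data[scalp, ])) /
    sd(one$data[scalp, ])
  expect_lt(rel, 0.05)
})
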