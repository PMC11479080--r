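# Shared fixtures: everything is generated in code at test time.

# A small paradigm: short videos, few trials, moderate rate to keep the
# suite fast while exercising every stage.
small_config <- function(n_runs = 2, trials_per_run = 3, fs = 500,
                         non_emergency_duration = 5,
                         emergency_duration = 4, ...) {
  paradigm_config(n_runs = n_runs, trials_per_run = trials_per_run, fs = fs,
                  non_emergency_duration = non_emergency_duration,
                  emergency_duration = emergency_duration,
                  inter_run_gap = 2, lead_in = 4, lead_out = 4, ...)
}

quiet_noise <- function(seed = 1, ...)
  noise_spec(background_sd = 0, eog_sd = 0, blink_rate = 0, burst_rate = 0,
             seed = seed, ...)

small_session <- function(seed = 1, noise = noise_spec(seed = seed),
                          config = small_config(),
                          templates = default_templates()) {
  synthesize(build_schedule(config), templates, noise, config)
}

# Feature-level fixture: two classes separated by `sep` on channel 1,
# spatially independent unit noise elsewhere.
feature_fixture <- function(n_per_class = 40, n_windows = 4, n_channels = 6,
                            sep = 0, seed = 1, sd = 1) {
  with_seed <- emergeeg:::with_seed
  vals <- with_seed(seed, {
    v <- array(stats::rnorm(2 * n_per_class * n_windows * n_channels, 0, sd),
               c(2 * n_per_class, n_windows, n_channels))
    v[(n_per_class + 1):(2 * n_per_class), , 1] <-
      v[(n_per_class + 1):(2 * n_per_class), , 1] + sep
    v
  })
  structure(list(values = vals, window_ms = 125, n_windows = n_windows,
                 samples_per_window = 25,
                 channels = paste0("ch", seq_len(n_channels)), fs = 200,
                 labels = rep(c("normal", "emergency"), each = n_per_class)),
            class = "windowed_features")
}

# Epoch-level fixture built directly (trials x channels x samples).
epoch_fixture <- function(n_per_class = 30, n_channels = 6, n_samples = 100,
                          fs = 200, signal = NULL, seed = 1, sd = 1) {
  emergeeg:::with_seed(seed, {
    n <- 2 * n_per_class
    arr <- array(stats::rnorm(n * n_channels * n_samples, 0, sd),
                 c(n, n_channels, n_samples))
    if (!is.null(signal))
      for (j in (n_per_class + 1):n) arr[j, , ] <- arr[j, , ] + signal
    emergeeg:::new_epoch_set(
      arr, labels = rep(c("normal", "emergency"), each = n_per_class),
      times = (seq_len(n_samples) - 1) / fs, fs = fs,
      channel_labels = paste0("ch", seq_len(n_channels)),
      eog_indices = integer(0))
  })
}
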