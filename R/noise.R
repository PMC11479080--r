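#' Background noise and artifact specification
#'
#' The synthetic background at each scalp channel has total RMS
#' `background_sd` and is composed of three parts (variance fractions sum to
#' one):
#' \itemize{
#'   \item a spatially coherent rhythmic component (alpha-band oscillatory
#'     activity, the dominant ongoing EEG signal), carried by three smooth
#'     spatial patterns (`rhythm_fraction`);
#'   \item a spatially coherent 1/f ("pink") slow component carried by the
#'     same low-rank patterns (`pink_fraction`);
#'   \item channel-independent broadband white noise (sensor/EMG floor,
#'     the remaining fraction).
#' }
#' Ocular (blink) and high-frequency burst artifacts are generated as Poisson
#' event trains; their amplitudes default to values that trip the 100 uV
#' epoch rejection when left uncleaned.  See the vignette for the rationale
#' behind this composition and what it does and does not emulate.
#'
#' @param background_sd Total background RMS per scalp channel, uV (default 10).
#' @param rhythm_fraction,pink_fraction Variance fractions of the rhythmic and
#'   1/f components (defaults 0.98 and 0.001; the remainder is white).
#' @param rhythm_band Rhythm centre band in Hz (default 8-12).
#' @param pink_flatten_hz 1/f spectrum is flattened below this frequency
#'   (default 1 Hz) to keep the variance finite.
#' @param eog_sd White-noise RMS on the EOG channels, uV.
#' @param blink_rate Blinks per minute on EOG + frontal-pole channels.
#' @param blink_amplitude Blink peak amplitude at the EOG channels, uV.
#' @param blink_duration Blink duration, seconds.
#' @param burst_rate High-frequency burst artifacts per minute.
#' @param burst_amplitude Burst peak amplitude, uV.
#' @param burst_duration Burst duration, seconds.
#' @param keypress_delay_median Median operator reaction delay, seconds
#'   (log-normal).
#' @param keypress_delay_sdlog Log-normal sdlog of the reaction delay.
#' @param seed Integer seed; the whole synthesis is deterministic given it.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(background_sd = 10,
                       rhythm_fraction = 0.98, pink_fraction = 0.001,
                       rhythm_band = c(8, 12), pink_flatten_hz = 1,
                       eog_sd = 5,
                       blink_rate = 12, blink_amplitude = 150,
                       blink_duration = 0.3,
                       burst_rate = 1, burst_amplitude = 300,
                       burst_duration = 0.2,
                       keypress_delay_median = 0.6,
                       keypress_delay_sdlog = 0.25,
                       seed = NULL) {
  if (background_sd < 0 || eog_sd < 0) stopf("noise SDs must be >= 0")
  if (blink_rate < 0 || burst_rate < 0) stopf("artifact rates must be >= 0")
  if (rhythm_fraction < 0 || pink_fraction < 0 ||
      rhythm_fraction + pink_fraction > 1)
    stopf("variance fractions must be >= 0 and sum to <= 1")
  structure(list(
    background_sd = background_sd, rhythm_fraction = rhythm_fraction,
    pink_fraction = pink_fraction, rhythm_band = rhythm_band,
    pink_flatten_hz = pink_flatten_hz, eog_sd = eog_sd,
    blink_rate = blink_rate, blink_amplitude = blink_amplitude,
    blink_duration = blink_duration,
    burst_rate = burst_rate, burst_amplitude = burst_amplitude,
    burst_duration = burst_duration,
    keypress_delay_median = keypress_delay_median,
    keypress_delay_sdlog = keypress_delay_sdlog,
    seed = seed), class = "noise_spec")
}

# Gaussian noise with amplitude spectrum shape(f), normalised to unit RMS.
shaped_noise <- function(n, fs, shape) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * fs / n
  g <- shape(f)
  g[1] <- 0  # remove DC
  X <- X * g
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) rep(0, n) else y / s
}

pink_source <- function(n, fs, flatten_hz = 1)
  shaped_noise(n, fs, function(f) 1 / sqrt(pmax(f, flatten_hz)))

rhythm_source <- function(n, fs, band = c(8, 12)) {
  centre <- mean(band)
  bw <- (band[2] - band[1]) / 2
  shaped_noise(n, fs, function(f) exp(-(f - centre)^2 / (2 * bw^2)))
}

# Low-rank smooth spatial maps with exact unit row norms: every channel
# receives unit variance from K independent unit-variance sources.
shared_noise_maps <- function(labels) {
  pos <- electrode_positions(labels)
  m <- cbind(1, pos[, "y"], pos[, "x"])
  m / sqrt(rowSums(m^2))
}

hann_bump <- function(n) sin(pi * (seq_len(n) - 0.5) / n)^2

# Frontal-pole projection of the ocular source (gain 1 at the EOG channels).
blink_gains <- function(labels, eog_labels) {
  g <- setNames(numeric(length(labels) + length(eog_labels)),
                c(labels, eog_labels))
  for (lab in eog_labels) g[lab] <- 1
  for (lab in intersect(c("Fpz", "Fp1", "Fp2"), labels)) g[lab] <- 0.9
  for (lab in intersect(c("AF3", "AF4"), labels)) g[lab] <- 0.5
  g
}
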