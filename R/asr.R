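# Artifact subspace reconstruction, simplified: calibration on the cleanest
# stretch of the training data defines a principal subspace and per-component
# block-RMS thresholds; at run time each block's principal-component
# amplitudes are clamped to the calibration thresholds.  Blocks are processed
# independently given the calibration, which keeps the operation causal and
# streaming-safe.

#' Calibrate ASR statistics on clean training data
#'
#' Ranks 1-s windows by total RMS, keeps the cleanest ones (up to
#' `max_calib` seconds), and computes the principal axes of their scalp
#' covariance together with per-component block-RMS mean/SD.  The clamp
#' threshold per component is `mean + cutoff * SD` of the calibration
#' block RMS.
#'
#' @param rec An `eeg_recording` (post-ICA).
#' @param config A [preproc_config()] (uses `asr_cutoff`, `asr_block`).
#' @param calib_window Ranking window length in seconds (default 1).
#' @param max_calib Maximum calibration data in seconds (default 60).
#' @return ASR state: principal axes `V`, clamp `thresholds`, config echo.
#' @export
asr_calibrate <- function(rec, config = preproc_config(),
                          calib_window = 1, max_calib = 60) {
  scalp <- scalp_indices(rec)
  X <- rec$data[scalp, , drop = FALSE]
  win <- round(calib_window * rec$fs)
  n_win <- floor(ncol(X) / win)
  if (n_win < 5) stopf("ASR calibration needs at least %d s of data", 5 * win / rec$fs)
  rms <- vapply(seq_len(n_win), function(w)
    sqrt(mean(X[, ((w - 1) * win + 1):(w * win)]^2)), numeric(1))
  keep <- order(rms)[seq_len(min(n_win, max(5, round(max_calib / calib_window))))]
  calib <- X[, as.vector(vapply(sort(keep), function(w)
    ((w - 1) * win + 1):(w * win), integer(win))), drop = FALSE]
  C <- tcrossprod(calib) / ncol(calib)
  eg <- eigen(C, symmetric = TRUE)
  V <- eg$vectors
  block <- round(config$asr_block * rec$fs)
  n_blk <- floor(ncol(calib) / block)
  Y <- t(V) %*% calib
  brms <- vapply(seq_len(n_blk), function(b)
    sqrt(rowMeans(Y[, ((b - 1) * block + 1):(b * block), drop = FALSE]^2)),
    numeric(nrow(Y)))
  mu <- rowMeans(brms)
  sdv <- apply(brms, 1, stats::sd)
  list(V = V, thresholds = mu + config$asr_cutoff * sdv,
       mu = mu, sd = sdv, cutoff = config$asr_cutoff,
       fs = rec$fs, scalp = scalp)
}

#' Reconstruct burst segments using the calibration subspace
#'
#' Processes the scalp data in non-overlapping blocks: principal-component
#' amplitudes whose block RMS exceeds the calibration threshold are scaled
#' down to the threshold and the block is back-projected.  Clean blocks pass
#' through unchanged.
#'
#' @param rec An `eeg_recording`.
#' @param state ASR state from [asr_calibrate()].
#' @param block Block length in seconds (default the calibrated block).
#' @return Cleaned recording.
#' @export
asr_clean <- function(rec, state, block = 0.5) {
  if (is.null(state$V)) stopf("missing ASR calibration")
  scalp <- scalp_indices(rec)
  blk <- round(block * rec$fs)
  n <- ncol(rec$data)
  starts <- seq(1, n, by = blk)
  for (s in starts) {
    e <- min(n, s + blk - 1)
    rec$data[scalp, s:e] <- asr_clean_block(rec$data[scalp, s:e, drop = FALSE],
                                            state)
  }
  rec
}

asr_clean_block <- function(X, state) {
  Y <- t(state$V) %*% X
  r <- sqrt(rowMeans(Y^2))
  sc <- pmin(1, state$thresholds / pmax(r, .Machine$double.eps))
  if (all(sc >= 1)) return(X)
  state$V %*% (Y * sc)
}
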