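#' Grand-average waveform
#'
#' Pointwise mean across epochs, for one channel or all channels.
#'
#' @param epochs An `epoch_set` (>= 1 epoch).
#' @param channel Channel label or index; when `NULL`, a channels x samples
#'   matrix is returned.
#' @return For a single channel, an `erp_waveform` (list with `times`,
#'   `amplitude`, `fs`, `channel`); otherwise a matrix.
#' @export
grand_average <- function(epochs, channel = NULL) {
  if (n_epochs(epochs) == 0) stopf("empty epoch set")
  if (is.null(channel)) {
    out <- apply(epochs$data, c(2, 3), mean)
    rownames(out) <- epochs$channel_labels
    return(out)
  }
  if (is.character(channel)) channel <- match(channel, epochs$channel_labels)
  if (is.na(channel)) stopf("unknown channel")
  amp <- if (n_epochs(epochs) == 1) epochs$data[1, channel, ]
         else colMeans(epochs$data[, channel, , drop = TRUE])
  structure(list(times = epochs$times, amplitude = as.numeric(amp),
                 fs = epochs$fs, channel = epochs$channel_labels[channel]),
            class = "erp_waveform")
}

#' Low-pass smooth a waveform for peak measurement
#'
#' Zero-phase Butterworth low-pass (reflection-padded), the standard
#' amplitude-preserving smoothing applied to grand averages before peak
#' quantification.  Offline use only; the detection path is causal.
#'
#' @param waveform An `erp_waveform`.
#' @param cutoff Cut-off in Hz (default 5).
#' @param order Filter order (default 4).
#' @return Smoothed `erp_waveform`.
#' @export
lowpass_waveform <- function(waveform, cutoff = 5, order = 4) {
  coef <- butter_design(order, cutoff, "low", waveform$fs)
  waveform$amplitude <- zerophase_filter(coef, waveform$amplitude)
  waveform
}

#' Find an extremum of a waveform within a search window
#'
#' Returns the most negative (or most positive) amplitude within the window
#' and its latency; ties resolve to the earliest latency.
#'
#' @param waveform An `erp_waveform` (or list with `times` and `amplitude`).
#' @param search_window Length-2 seconds.
#' @param polarity `"negative"` or `"positive"`.
#' @return List with `amplitude` (uV) and `latency` (s).
#' @export
find_peak <- function(waveform, search_window,
                      polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  sel <- waveform$times >= search_window[1] - 1e-9 &
         waveform$times <= search_window[2] + 1e-9
  if (!any(sel)) stopf("search window contains no samples")
  amp <- waveform$amplitude[sel]
  tt <- waveform$times[sel]
  idx <- if (polarity == "negative") which.min(amp) else which.max(amp)
  list(amplitude = amp[idx], latency = tt[idx])
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two independent groups: exact
#' enumeration when both groups have at most 10 observations and no ties,
#' normal approximation with tie correction otherwise (mid-ranks).
#'
#' @param group_a,group_b Numeric vectors (each n >= 2).
#' @return List with `statistic` (Mann-Whitney U of `group_a`), `p.value`
#'   and `method`.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stopf("each group needs at least 2 observations")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- !ties && length(group_a) <= 10 && length(group_b) <= 10
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = !exact))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Sign-flip permutation paired t-test
#'
#' Two-sided permutation test of the paired t statistic under the sign-flip
#' null.  With n <= 12 pairs all `2^n` sign patterns are enumerated
#' (p = #\{|t*| >= |t|\} / 2^n); otherwise `n_perm` random sign draws are
#' used with p = (1 + #\{|t*| >= |t|\}) / (1 + n_perm).
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2).
#' @param n_perm Monte-Carlo draws for n > 12 (default 10000).
#' @param seed Seed for the Monte-Carlo branch.
#' @return List with `statistic` (observed t), `p.value`, `exact` flag.
#' @export
permutation_paired_ttest <- function(x, y, n_perm = 10000, seed = 1) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 2) stopf("need at least 2 pairs")
  d <- x - y
  if (all(d == 0))
    return(list(statistic = 0, p.value = 1, exact = TRUE))
  tstat <- function(m, ssq) {
    v <- (ssq - n * m^2) / (n - 1)
    ifelse(v <= 0, sign(m) * Inf, m / sqrt(v / n))
  }
  ssq <- sum(d^2)
  t_obs <- tstat(mean(d), ssq)
  if (n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    m_star <- as.numeric(signs %*% d) / n
    t_star <- tstat(m_star, ssq)   # sum d^2 is sign-invariant
    p <- mean(abs(t_star) >= abs(t_obs) - 1e-12)
    list(statistic = t_obs, p.value = p, exact = TRUE)
  } else {
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        m_star <- mean(d * sample(c(-1, 1), n, replace = TRUE))
        abs(tstat(m_star, ssq)) >= abs(t_obs) - 1e-12
      }, logical(1)))
    })
    list(statistic = t_obs, p.value = (1 + hits) / (1 + n_perm), exact = FALSE)
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted p-values (monotone).
#' @export
fdr_bh <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-subject peak table
#'
#' Measures one peak per subject x condition on the (optionally smoothed)
#' grand average of a channel, for downstream group statistics.
#'
#' @param epoch_sets Named list of `epoch_set`s, one per subject, each
#'   containing both conditions in its labels.
#' @param channel Channel label.
#' @param search_window Seconds.
#' @param polarity `"negative"` or `"positive"`.
#' @param smooth_cutoff Low-pass cut-off in Hz applied before peak picking
#'   (NULL to skip).
#' @return Data frame: subject, condition, amplitude, latency.
#' @export
peak_table <- function(epoch_sets, channel, search_window,
                       polarity = "negative", smooth_cutoff = 5) {
  rows <- list()
  for (s in seq_along(epoch_sets)) {
    ep <- epoch_sets[[s]]
    for (cond in unique(ep$labels)) {
      sub <- subset_epochs(ep, ep$labels == cond)
      wf <- grand_average(sub, channel)
      if (!is.null(smooth_cutoff)) wf <- lowpass_waveform(wf, smooth_cutoff)
      pk <- find_peak(wf, search_window, polarity)
      rows[[length(rows) + 1]] <- data.frame(
        subject = names(epoch_sets)[s] %||% s, condition = cond,
        amplitude = pk$amplitude, latency = pk$latency)
    }
  }
  do.call(rbind, rows)
}
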