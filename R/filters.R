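# Causal IIR filtering with explicit carried state, so that chunked
# (streaming) application is sample-exact equal to batch application.
# Coefficients come from signal::butter; application is done with
# stats::filter (vectorised C code) in an MA + recursive decomposition.

butter_design <- function(order, cutoff, type, fs) {
  bt <- signal::butter(order, cutoff / (fs / 2), type = type)
  list(b = as.numeric(bt$b), a = as.numeric(bt$a))
}

# Steady-state filter state for a constant input level x0.
iir_steady_state <- function(coef, x0) {
  nb <- length(coef$b); na <- length(coef$a)
  dc_gain <- sum(coef$b) / sum(coef$a)
  list(x = rep(x0, nb - 1), y = rep(x0 * dc_gain, na - 1))
}

# One causal filtering pass.  `state` carries the last nb-1 inputs and na-1
# outputs (chronological order); when NULL it is initialised to the steady
# state for x[1], which suppresses the onset step transient.
iir_filter <- function(coef, x, state = NULL) {
  b <- coef$b; a <- coef$a
  if (abs(a[1] - 1) > 1e-12) { b <- b / a[1]; a <- a / a[1] }
  nb <- length(b); na <- length(a)
  n <- length(x)
  if (is.null(state)) state <- iir_steady_state(coef, x[1])
  xx <- c(state$x, x)
  u <- stats::filter(xx, b, method = "convolution", sides = 1)
  u <- as.numeric(u[(nb - 1) + seq_len(n)])
  if (na > 1) {
    y <- stats::filter(u, -a[-1], method = "recursive", init = rev(state$y))
    y <- as.numeric(y)
  } else y <- u
  list(y = y,
       state = list(x = tail(c(state$x, x), nb - 1),
                    y = tail(c(state$y, y), na - 1)))
}

# Zero-phase filtering with reflection padding (offline ERP use only; the
# detection path is strictly causal).
zerophase_filter <- function(coef, x, pad = NULL) {
  n <- length(x)
  pad <- min(n - 1, pad %||% 512)
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- signal::filtfilt(coef$b, coef$a, xp)
  y[pad + seq_len(n)]
}

filter_rows <- function(data, coef, rows = seq_len(nrow(data))) {
  for (i in rows) data[i, ] <- iir_filter(coef, data[i, ])$y
  data
}
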