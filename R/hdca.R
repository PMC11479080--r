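#' Within-window mean-amplitude features
#'
#' Divides each epoch evenly into consecutive time windows (default 125 ms)
#' and takes the mean amplitude of each scalp channel within each window:
#' `x[trial, window, channel]`.  These are the features the hierarchical
#' discriminant operates on.
#'
#' @param epochs An `epoch_set`.
#' @param window_ms Window length in milliseconds (default 125); must divide
#'   the epoch duration evenly.
#' @return A `windowed_features` object: `values` (trials x windows x
#'   channels), window geometry, channel labels and the epoch labels.
#' @export
window_average <- function(epochs, window_ms = 125) {
  spw <- window_ms / 1000 * epochs$fs
  if (abs(spw - round(spw)) > 1e-9)
    stopf("window of %g ms is not a whole number of samples at %g Hz",
          window_ms, epochs$fs)
  spw <- as.integer(round(spw))
  S <- dim(epochs$data)[3]
  n_windows <- S %/% spw
  rem <- S %% spw
  if (rem != 0)
    stopf("epoch length (%d samples) is not divisible into %g ms windows (remainder %d samples)",
          S, window_ms, rem)
  scalp <- setdiff(seq_len(dim(epochs$data)[2]), epochs$eog_indices)
  n_tr <- dim(epochs$data)[1]
  vals <- array(0, dim = c(n_tr, n_windows, length(scalp)),
                dimnames = list(NULL, NULL, epochs$channel_labels[scalp]))
  for (w in seq_len(n_windows)) {
    cols <- ((w - 1) * spw + 1):(w * spw)
    # mean over samples for every trial x channel
    vals[, w, ] <- apply(epochs$data[, scalp, cols, drop = FALSE], c(1, 2), mean)
  }
  structure(list(values = vals, window_ms = window_ms, n_windows = n_windows,
                 samples_per_window = spw, channels = epochs$channel_labels[scalp],
                 fs = epochs$fs, labels = epochs$labels),
            class = "windowed_features")
}

#' Background covariance of window-mean features
#'
#' Estimates the channels x channels covariance of window-mean amplitudes
#' from the quiet stretches of a preprocessed continuous recording:
#' non-overlapping windows of `window_ms` are taken over the whole session,
#' windows within `[-0.5, +1.5]` s of any stimulus onset are excluded, and
#' the covariance of the remaining window means is returned.  Used as the
#' `noise_cov` argument of [fit_hdca()].
#'
#' @param rec A preprocessed `eeg_recording` with a schedule.
#' @param window_ms Window length in milliseconds (must match the HDCA
#'   windowing; default 125).
#' @return Covariance matrix over scalp channels.
#' @export
background_covariance <- function(rec, window_ms = 125) {
  scalp <- scalp_indices(rec)
  spw <- as.integer(round(window_ms / 1000 * rec$fs))
  n <- ncol(rec$data)
  starts <- seq(1, n - spw + 1, by = spw)
  centres <- (starts + spw / 2) / rec$fs
  if (!is.null(rec$schedule)) {
    ev <- rec$schedule$events
    onsets <- ev$onset_sample[ev$type != "keypress"] / rec$fs
    keep <- vapply(centres, function(tt)
      !any(tt >= onsets - 0.5 & tt <= onsets + 1.5), logical(1))
    starts <- starts[keep]
  }
  M <- vapply(starts, function(s)
    rowMeans(rec$data[scalp, s:(s + spw - 1), drop = FALSE]),
    numeric(length(scalp)))
  stats::cov(t(M))
}

# Ledoit-Wolf shrinkage covariance toward a scaled identity, on a matrix of
# observations (rows) that have already been class-centred.
shrinkage_cov <- function(Xc) {
  n <- nrow(Xc); p <- ncol(Xc)
  S <- crossprod(Xc) / n
  mu <- mean(diag(S))
  d2 <- sum((S - diag(mu, p))^2) / p
  if (d2 < .Machine$double.eps)
    return(list(sigma = diag(mu + 1e-12, p), lambda = 1))
  b2bar <- 0
  for (i in seq_len(n)) {
    xi <- Xc[i, ]
    b2bar <- b2bar + sum((tcrossprod(xi) - S)^2)
  }
  b2bar <- b2bar / (n^2 * p)
  b2 <- min(b2bar, d2)
  lambda <- b2 / d2
  list(sigma = lambda * diag(mu, p) + (1 - lambda) * S, lambda = lambda)
}

fisher_direction <- function(X, y, positive, noise_cov = NULL) {
  m1 <- colMeans(X[y == positive, , drop = FALSE])
  m0 <- colMeans(X[y != positive, , drop = FALSE])
  if (is.null(noise_cov)) {
    Xc <- X
    Xc[y == positive, ] <- sweep(X[y == positive, , drop = FALSE], 2, m1)
    Xc[y != positive, ] <- sweep(X[y != positive, , drop = FALSE], 2, m0)
    sc <- shrinkage_cov(Xc)
    sigma <- sc$sigma
    lambda <- sc$lambda
  } else {
    # externally estimated background covariance; a small diagonal ridge
    # keeps directions emptied by the ICA projection invertible
    lambda <- 0.05
    mu <- mean(diag(noise_cov))
    sigma <- (1 - lambda) * noise_cov + lambda * diag(mu, ncol(X))
  }
  w <- solve(sigma, m1 - m0)
  list(w = w, m0 = m0, m1 = m1, lambda = lambda)
}

#' Fit a hierarchical discriminant component analysis model
#'
#' Stage one learns, per time window, a Fisher discriminant weight vector
#' over channels (shrinkage-regularised within-class covariance), compressing
#' the multichannel window into a single score
#' \eqn{y_n = \sum_i w_{i,n} x_{i,n}}.  Stage two fits a second Fisher
#' discriminant on the window-score vectors.  The decision threshold is the
#' midpoint of the two class score means; ties go to the normal class.
#' Training weights are reused verbatim at test time.
#'
#' @param features A `windowed_features` object (or an `epoch_set`, which is
#'   windowed at `window_ms`).
#' @param labels Trial labels (two classes); defaults to the labels carried
#'   by `features`.  The positive class is `"emergency"` when present,
#'   otherwise the second factor level.
#' @param window_ms Window length when `features` is an `epoch_set`.
#' @param crossfit Internal folds used to form unbiased window scores for
#'   the second stage (default 5): stage-one weights are refit with each
#'   fold held out and the held-out projections train the second-stage
#'   discriminant and its midpoint threshold, so the decision threshold is
#'   calibrated for out-of-sample scores rather than for the (optimistic)
#'   resubstitution scores.  Set to 0 to fit both stages on the same data.
#' @param crossfit_seed Seed for the internal fold assignment.
#' @param noise_cov Optional channels x channels background covariance of
#'   window-mean features, e.g. from [background_covariance()]: when the
#'   continuous training recording is available, its quiet stretches estimate
#'   the within-class covariance far more precisely than the training epochs
#'   alone (thousands of windows instead of a few hundred trials), which
#'   sharpens the spatial weights considerably.
#' @return An object of class `hdca_model`.
#' @export
fit_hdca <- function(features, labels = NULL, window_ms = 125, crossfit = 5,
                     crossfit_seed = 1, noise_cov = NULL) {
  if (inherits(features, "epoch_set"))
    features <- window_average(features, window_ms)
  labels <- labels %||% features$labels
  labels <- as.character(labels)
  if (anyNA(features$values)) stopf("features contain NaN/NA")
  cls <- sort(unique(labels))
  if (length(cls) != 2) stopf("exactly two classes required, got %d", length(cls))
  positive <- if ("emergency" %in% cls) "emergency" else cls[2]
  negative <- setdiff(cls, positive)
  nw <- features$n_windows
  p <- dim(features$values)[3]
  W <- matrix(0, p, nw, dimnames = list(features$channels, NULL))
  for (n in seq_len(nw)) {
    fd <- fisher_direction(features$values[, n, ], labels, positive, noise_cov)
    W[, n] <- fd$w
  }
  crossfit <- min(crossfit, min(table(labels)))
  if (crossfit >= 2) {
    Y <- matrix(0, length(labels), nw)
    folds <- with_seed(crossfit_seed, stratified_folds(labels, crossfit))
    for (f in seq_len(crossfit)) {
      te <- folds == f
      for (n in seq_len(nw)) {
        fd <- fisher_direction(features$values[!te, n, , drop = FALSE][, 1, ],
                               labels[!te], positive, noise_cov)
        Y[te, n] <- features$values[te, n, , drop = FALSE][, 1, ] %*% fd$w
      }
    }
  } else {
    Y <- project_features(features$values, W)
  }
  fd2 <- fisher_direction(Y, labels, positive)
  v <- fd2$w
  bias <- -sum(v * (fd2$m0 + fd2$m1) / 2)
  # orient so that positive-class scores are positive
  if (sum(v * fd2$m1) + bias < 0) { v <- -v; bias <- -bias }
  structure(list(window_weights = W,
                 second_stage = list(weights = v, bias = bias),
                 positive_class = positive, negative_class = negative,
                 window_ms = features$window_ms, n_windows = nw,
                 samples_per_window = features$samples_per_window,
                 channels = features$channels, fs = features$fs),
            class = "hdca_model")
}

project_features <- function(values, W) {
  nw <- ncol(W)
  Y <- matrix(0, dim(values)[1], nw)
  for (n in seq_len(nw)) Y[, n] <- values[, n, ] %*% W[, n]
  Y
}

#' Project windowed features through the first-stage weights
#'
#' Computes the Eq.-style linear contraction over channels,
#' `y[trial, n] = sum_i w[i, n] * x[trial, n, i]`.
#'
#' @param model An `hdca_model`.
#' @param features A `windowed_features` object.
#' @return Trials x windows score matrix.
#' @export
project_windows <- function(model, features) {
  if (dim(features$values)[3] != nrow(model$window_weights))
    stopf("channel dimension (%d) does not match model (%d)",
          dim(features$values)[3], nrow(model$window_weights))
  if (dim(features$values)[2] != model$n_windows)
    stopf("window count (%d) does not match model (%d)",
          dim(features$values)[2], model$n_windows)
  project_features(features$values, model$window_weights)
}

#' Predict labels and scores for epochs
#'
#' @param object An `hdca_model`.
#' @param newdata An `epoch_set` or `windowed_features` with the training
#'   geometry.
#' @param ... Unused.
#' @return Data frame with `score` (second-stage discriminant value) and
#'   `label`; scores above 0 are labelled as the positive (emergency) class,
#'   ties go to the normal class.
#' @export
predict.hdca_model <- function(object, newdata, ...) {
  if (inherits(newdata, "epoch_set"))
    newdata <- window_average(newdata, object$window_ms)
  Y <- project_windows(object, newdata)
  score <- drop(Y %*% object$second_stage$weights) + object$second_stage$bias
  data.frame(score = score,
             label = ifelse(score > 0, object$positive_class,
                            object$negative_class))
}

#' Single-split linear comparators
#'
#' Comparator classifiers evaluated on the same window-mean features as
#' HDCA, flattened to one vector per trial: `flat_lda` is a single linear
#' discriminant (MASS), `linear_svm` a linear-kernel support vector machine
#' (e1071).
#'
#' @param kind `"flat_lda"` or `"linear_svm"`.
#' @param train_features,test_features `windowed_features`.
#' @param train_labels Labels for the training trials.
#' @return Data frame with predicted `label` (and `score` where available).
#' @export
baseline_fit_predict <- function(kind = c("flat_lda", "linear_svm"),
                                 train_features, train_labels, test_features) {
  kind <- match.arg(kind)
  flat <- function(f) {
    d <- dim(f$values)
    matrix(f$values, d[1], d[2] * d[3])
  }
  Xtr <- flat(train_features); Xte <- flat(test_features)
  ytr <- factor(train_labels)
  if (kind == "flat_lda") {
    # collinearity warnings are expected when windows x channels exceeds the
    # trial count; lda still returns a usable least-squares discriminant
    fit <- suppressWarnings(MASS::lda(Xtr, grouping = ytr))
    pr <- stats::predict(fit, Xte)
    data.frame(score = pr$x[, 1], label = as.character(pr$class))
  } else {
    fit <- e1071::svm(Xtr, ytr, kernel = "linear", scale = FALSE)
    data.frame(label = as.character(stats::predict(fit, Xte)))
  }
}

#' Stratified k-fold cross-validation with repeated cycles
#'
#' Evaluates HDCA (or a comparator) with stratified k-fold cross-validation
#' repeated over cycles (fold assignment reseeded per cycle as
#' `seed + cycle`).  Optionally refits the data-driven preprocessing stages
#' (ICA rejection, ASR calibration, band-pass) inside each training fold and
#' applies them to the held-out fold, so no test information leaks into the
#' fitted state.  Recall is the emergency-class true positive rate, FAR the
#' normal-class false positive rate, and accuracy the mean of recall and
#' (100 - FAR).
#'
#' @param epochs An `epoch_set` (for `fold_preproc` it must still contain the
#'   EOG channels and be unfiltered, i.e. taken after downsampling/baseline
#'   only).
#' @param labels Trial labels; default the epoch labels.
#' @param k Folds (default 5).
#' @param cycles Repetitions (default 10).
#' @param seed Base seed.
#' @param method `"hdca"`, `"flat_lda"` or `"linear_svm"`.
#' @param window_ms First-stage window length.
#' @param fold_preproc Optional [preproc_config()]; when supplied, ICA + ASR +
#'   band-pass are fit on each training fold and applied to its test fold.
#' @return A `cv_result`: per-cycle metrics and a mean +/- SD summary.
#' @export
crossvalidate_hdca <- function(epochs, labels = NULL, k = 5, cycles = 10,
                               seed = 1, method = "hdca", window_ms = 125,
                               fold_preproc = NULL) {
  labels <- as.character(labels %||% epochs$labels)
  stopifnot(length(labels) == n_epochs(epochs))
  cls <- sort(unique(labels))
  if (length(cls) != 2) stopf("two classes required")
  positive <- if ("emergency" %in% cls) "emergency" else cls[2]
  if (k > min(table(labels))) stopf("k exceeds the smallest class size")
  rows <- vector("list", cycles)
  for (cy in seq_len(cycles)) {
    folds <- with_seed(seed + cy, stratified_folds(labels, k))
    pred <- character(length(labels))
    for (f in seq_len(k)) {
      te <- folds == f
      tr_ep <- subset_epochs(epochs, !te)
      te_ep <- subset_epochs(epochs, te)
      if (!is.null(fold_preproc)) {
        pp <- fold_preprocess(tr_ep, te_ep, fold_preproc, seed = seed + cy)
        tr_ep <- pp$train; te_ep <- pp$test
      }
      ftr <- window_average(tr_ep, window_ms)
      fte <- window_average(te_ep, window_ms)
      if (method == "hdca") {
        model <- fit_hdca(ftr, labels[!te])
        pred[te] <- predict(model, fte)$label
      } else {
        pred[te] <- baseline_fit_predict(method, ftr, labels[!te], fte)$label
      }
    }
    tp <- sum(pred == positive & labels == positive)
    fp <- sum(pred == positive & labels != positive)
    recall <- 100 * tp / sum(labels == positive)
    far <- 100 * fp / sum(labels != positive)
    rows[[cy]] <- data.frame(cycle = cy, recall = recall, far = far,
                             accuracy = eq2_accuracy(recall, far))
  }
  res <- do.call(rbind, rows)
  structure(list(cycles = res,
                 summary = data.frame(
                   metric = c("accuracy", "recall", "far"),
                   mean = c(mean(res$accuracy), mean(res$recall), mean(res$far)),
                   sd = c(stats::sd(res$accuracy), stats::sd(res$recall),
                          stats::sd(res$far))),
                 method = method, k = k, n_cycles = cycles),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold x %d cycles\n", x$method, x$k, x$n_cycles))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %6.2f%% +/- %.2f%%\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

# Fold-internal refit of the data-driven stages: ICA and ASR are fit on the
# concatenated training epochs and applied to both folds; the band-pass is
# causal per epoch with steady-state initialisation.
fold_preprocess <- function(train_ep, test_ep, config, seed = 1) {
  tr_rec <- epochs_as_recording(train_ep)
  ica <- fit_ica(tr_rec, config, seed = seed, max_samples = 5e4)
  tr_rec <- apply_ica(tr_rec, ica)
  asr <- asr_calibrate(tr_rec, config,
                       calib_window = min(1, dim(train_ep$data)[3] / train_ep$fs),
                       max_calib = 60)
  clean <- function(ep) {
    scalp <- setdiff(seq_len(dim(ep$data)[2]), ep$eog_indices)
    coef <- bandpass_coef(config, ep$fs)
    for (j in seq_len(n_epochs(ep))) {
      X <- ep$data[j, scalp, ]
      X <- ica_clean_matrix(X, ica)
      X <- asr_clean_block(X, asr)
      for (i in seq_len(nrow(X))) X[i, ] <- iir_filter(coef, X[i, ])$y
      ep$data[j, scalp, ] <- X
    }
    ep
  }
  list(train = clean(train_ep), test = clean(test_ep))
}

# Concatenate epochs back into a pseudo-continuous recording (for
# fold-internal ICA/ASR fitting).
epochs_as_recording <- function(ep) {
  d <- dim(ep$data)
  data <- matrix(0, d[2], d[1] * d[3])
  for (j in seq_len(d[1]))
    data[, ((j - 1) * d[3] + 1):(j * d[3])] <- ep$data[j, , ]
  new_recording(data, ep$fs, ep$channel_labels, ep$eog_indices, NULL)
}
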