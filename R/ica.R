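# Seeded FastICA (symmetric fixed-point, tanh contrast) with EOG-guided
# component rejection.  Written in-package: compact whitening + fixed-point
# iteration on (optionally subsampled) scalp data; determinism comes from the
# seeded random orthonormal initialisation.

#' Fit ICA on the scalp channels and mark ocular components
#'
#' Estimates a square unmixing matrix on the scalp channels (FastICA,
#' symmetric tanh fixed point, seeded initialisation) and marks components
#' whose absolute Pearson correlation with either EOG channel exceeds
#' `config$ica_reject_corr` as rejected.
#'
#' @param rec An `eeg_recording` containing EOG channels.
#' @param config A [preproc_config()].
#' @param seed Seed for the random orthonormal initialisation.
#' @param max_samples Maximum number of time points used for fitting
#'   (evenly subsampled; default 1e5).
#' @param max_iter,tol Fixed-point iteration controls.
#' @return List (ICA state): `unmixing` (components x channels), `mixing`
#'   (its inverse), `rejected` (component indices), `eog_cor` (components x
#'   EOG correlation matrix).
#' @export
fit_ica <- function(rec, config = preproc_config(), seed = 1,
                    max_samples = 1e5, max_iter = 200, tol = 1e-6) {
  scalp <- scalp_indices(rec)
  n <- ncol(rec$data)
  if (n < 30 * rec$fs)
    stopf("ICA requires at least 30 s of data (got %.1f s)", n / rec$fs)
  idx <- unique(round(seq(1, n, length.out = min(n, max_samples))))
  X <- rec$data[scalp, idx, drop = FALSE]
  ctr <- rowMeans(X)
  X <- X - ctr
  m <- ncol(X)
  C <- tcrossprod(X) / m
  dead <- which(diag(C) < max(diag(C)) * 1e-12)
  if (length(dead) > 0)
    stopf("rank-deficient data: channel(s) %s carry (near) zero variance",
          paste(rec$channel_labels[scalp][dead], collapse = ", "))
  eg <- eigen(C, symmetric = TRUE)
  # dimensions emptied by earlier linear cleaning (e.g. a previous ICA pass)
  # are dropped; ICA runs in the remaining full-rank subspace
  keep <- eg$values > max(eg$values) * 1e-9
  if (sum(keep) < 2)
    stopf("rank-deficient data: fewer than two independent dimensions")
  eg$values <- eg$values[keep]
  eg$vectors <- eg$vectors[, keep, drop = FALSE]
  K <- diag(1 / sqrt(eg$values), nrow = sum(keep)) %*% t(eg$vectors)
  Z <- K %*% X
  p <- sum(keep)
  W <- with_seed(seed, {
    qr.Q(qr(matrix(stats::rnorm(p * p), p, p)))
  })
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W1 <- tcrossprod(G, Z) / m - diag(rowMeans(1 - G^2)) %*% W
    W1 <- sym_decorrelate(W1)
    conv <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (conv < tol) break
  }
  unmixing <- W %*% K                      # components x channels
  # pseudo-inverse back-projection (exact inverse when no dimension dropped)
  mixing <- eg$vectors %*% diag(sqrt(eg$values), nrow = p) %*% t(W)
  S <- unmixing %*% X
  eog <- rec$data[rec$eog_indices, idx, drop = FALSE]
  eog_cor <- abs(stats::cor(t(S), t(eog)))
  rejected <- which(apply(eog_cor, 1, max) > config$ica_reject_corr)
  list(unmixing = unmixing, mixing = mixing, rejected = rejected,
       eog_cor = eog_cor, scalp = scalp, iterations = it)
}

sym_decorrelate <- function(W) {
  sv <- eigen(tcrossprod(W), symmetric = TRUE)
  sv$vectors %*% diag(1 / sqrt(sv$values)) %*% t(sv$vectors) %*% W
}

#' Remove rejected ICA components
#'
#' Back-projects the data with the rejected components zeroed; the transform
#' is strictly linear and memoryless, so it is shared verbatim by the online
#' path.  EOG channels pass through untouched.
#'
#' @param rec An `eeg_recording`.
#' @param state ICA state from [fit_ica()].
#' @return Cleaned recording.
#' @export
apply_ica <- function(rec, state) {
  scalp <- scalp_indices(rec)
  if (length(scalp) != ncol(state$unmixing))
    stopf("channel count (%d) does not match ICA state (%d)",
          length(scalp), ncol(state$unmixing))
  if (length(state$rejected) == 0) return(rec)
  rec$data[scalp, ] <- ica_clean_matrix(rec$data[scalp, , drop = FALSE], state)
  rec
}

ica_clean_matrix <- function(X, state) {
  rej <- state$rejected
  if (length(rej) == 0) return(X)
  X - state$mixing[, rej, drop = FALSE] %*%
    (state$unmixing[rej, , drop = FALSE] %*% X)
}
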