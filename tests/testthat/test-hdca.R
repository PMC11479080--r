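test_that("window averaging: arithmetic, constants and brute-force oracle", {
  ep <- epoch_fixture(n_per_class = 4, n_channels = 3, n_samples = 100,
                      fs = 200, seed = 2)
  fe <- window_average(ep, 125)
  expect_equal(fe$n_windows, 4)
  expect_equal(fe$samples_per_window, 25)
  # brute-force per-window loop mean
  for (tr in c(1, 5)) for (w in 1:4) for (ch in 1:3)
    expect_equal(unname(fe$values[tr, w, ch]),
                 mean(ep$data[tr, ch, ((w - 1) * 25 + 1):(w * 25)]))
  # constant epoch value propagates
  ep$data[1, , ] <- 7.5
  expect_equal(unname(window_average(ep, 125)$values[1, , ]),
               matrix(7.5, 4, 3))
  # indivisible window length errors with the remainder named
  expect_error(window_average(ep, 130), "remainder")
})

test_that("a widely separated fixture is classified perfectly", {
  fe <- feature_fixture(sep = 10, seed = 3)
  m <- fit_hdca(fe)
  pred <- predict(m, fe)
  expect_equal(mean(pred$label == fe$labels), 1)
  # the separating channel dominates every window's weights
  expect_true(all(abs(m$window_weights[1, ]) >
                  apply(abs(m$window_weights[-1, , drop = FALSE]), 2, max)))
})

test_that("projection equals the explicit double-loop summation", {
  fe <- feature_fixture(sep = 2, seed = 4)
  m <- fit_hdca(fe)
  Y <- project_windows(m, fe)
  Yb <- matrix(0, dim(fe$values)[1], fe$n_windows)
  for (t in seq_len(nrow(Yb))) for (n in seq_len(ncol(Yb)))
    Yb[t, n] <- sum(m$window_weights[, n] * fe$values[t, n, ])
  expect_equal(Y, Yb, tolerance = 1e-12)
  # zero features give zero scores; scaling is linear
  fz <- fe; fz$values[] <- 0
  expect_true(all(project_windows(m, fz) == 0))
  fs2 <- fe; fs2$values <- 3 * fe$values
  expect_equal(project_windows(m, fs2), 3 * Y, tolerance = 1e-12)
})

test_that("a perfectly collinear duplicated channel is handled by shrinkage", {
  fe <- feature_fixture(sep = 3, n_channels = 5, seed = 5)
  dup <- fe
  dup$values <- array(0, dim = dim(fe$values) + c(0, 0, 1))
  dup$values[, , 1:5] <- fe$values
  dup$values[, , 6] <- fe$values[, , 5]
  dup$channels <- c(fe$channels, "dup")
  m1 <- fit_hdca(fe)
  m2 <- fit_hdca(dup)
  expect_false(anyNA(m2$window_weights))
  p1 <- predict(m1, fe)$label
  p2 <- predict(m2, dup)$label
  expect_gt(mean(p1 == p2), 0.97)
})

test_that("prediction ignores channels with zero training weight", {
  fe <- feature_fixture(sep = 6, seed = 6)
  m <- fit_hdca(fe)
  m_aug <- m
  m_aug$window_weights <- rbind(m$window_weights, extra = 0)
  fe2 <- fe
  fe2$values <- array(0, dim = dim(fe$values) + c(0, 0, 1))
  fe2$values[, , seq_len(dim(fe$values)[3])] <- fe$values
  fe2$values[, , dim(fe2$values)[3]] <- 999     # arbitrary junk channel
  fe2$channels <- c(fe$channels, "extra")
  expect_equal(predict(m_aug, fe2)$score, predict(m, fe)$score,
               tolerance = 1e-9)
})

test_that("noise-free template epochs and flat epochs get the right labels", {
  tmpl <- render_erp_template(emergency_components(), 200,
                              window = c(-0.4, 1.2))
  tt <- attr(tmpl, "times")
  sig <- tmpl[c("POz", "Oz", "Fz"), ]
  # build trainable epochs: signal = first 100 samples around onset
  on <- which.min(abs(tt))
  win <- sig[, (on - 50):(on + 49)]
  ep <- epoch_fixture(n_per_class = 40, n_channels = 3, n_samples = 100,
                      fs = 200, signal = win, sd = 0.05, seed = 7)
  m <- fit_hdca(ep)
  noisefree <- epoch_fixture(n_per_class = 1, n_channels = 3, n_samples = 100,
                             fs = 200, signal = win, sd = 1e-9, seed = 8)
  pred <- predict(m, noisefree)
  expect_equal(pred$label, c("normal", "emergency"))
  expect_gt(pred$score[2], 0)
  expect_lt(pred$score[1], 0)
})

test_that("permuted labels stay at chance under cross-validation", {
  ep <- epoch_fixture(n_per_class = 120, n_channels = 8, n_samples = 100,
                      fs = 200, seed = 9)
  cv <- crossvalidate_hdca(ep, k = 5, cycles = 10, seed = 1)
  acc <- cv$summary$mean[cv$summary$metric == "accuracy"]
  expect_gt(acc, 45)
  expect_lt(acc, 55)
})

test_that("corrupting test-fold labels cannot change the trained model", {
  fe <- feature_fixture(sep = 2, n_per_class = 30, seed = 10)
  tr <- seq_len(40)
  te <- 41:60
  sub <- function(f, idx) {
    f$values <- f$values[idx, , , drop = FALSE]
    f$labels <- f$labels[idx]; f
  }
  m1 <- fit_hdca(sub(fe, tr))
  corrupted <- fe
  corrupted$labels[te] <- sample(corrupted$labels[te])
  m2 <- fit_hdca(sub(corrupted, tr))
  expect_identical(m1$window_weights, m2$window_weights)
  expect_identical(m1$second_stage, m2$second_stage)
})

test_that("comparators: separable fixtures solved, chance under permutation", {
  fe_tr <- feature_fixture(sep = 8, n_per_class = 40, seed = 11)
  fe_te <- feature_fixture(sep = 8, n_per_class = 40, seed = 12)
  for (kind in c("flat_lda", "linear_svm")) {
    pr <- baseline_fit_predict(kind, fe_tr, fe_tr$labels, fe_te)
    expect_gte(mean(pr$label == fe_te$labels), 0.99)
  }
  ep <- epoch_fixture(n_per_class = 60, n_channels = 6, seed = 13)
  cv <- crossvalidate_hdca(ep, k = 5, cycles = 4, seed = 2,
                           method = "flat_lda")
  expect_lt(abs(cv$summary$mean[1] - 50), 8)
})

test_that("HDCA beats a flat LDA when the topography flips between windows", {
  # discriminative pattern: +ch1 in windows 1-2, -ch1 +ch2 in windows 3-4;
  # with many nuisance channels the hierarchical (per-window, shrunken)
  # discriminant is better conditioned than one flat discriminant over the
  # full window-by-channel feature vector
  set.seed(14)
  n <- 50; p <- 30
  mk <- function(lab) {
    v <- array(rnorm(n * 4 * p, 0, 2), c(n, 4, p))
    if (lab == "emergency") {
      v[, 1:2, 1] <- v[, 1:2, 1] + 1.8
      v[, 3:4, 1] <- v[, 3:4, 1] - 1.8
      v[, 3:4, 2] <- v[, 3:4, 2] + 1.8
    }
    v
  }
  vals <- array(0, c(2 * n, 4, p))
  vals[seq_len(n), , ] <- mk("normal")
  vals[n + seq_len(n), , ] <- mk("emergency")
  # epochs whose 25-sample windows are constant, so window_average is exact
  arr <- array(0, c(2 * n, p, 100))
  for (w in 1:4) for (s in ((w - 1) * 25 + 1):(w * 25))
    arr[, , s] <- vals[, w, ]
  eps <- emergeeg:::new_epoch_set(
    arr, rep(c("normal", "emergency"), each = n), (0:99) / 200, 200,
    paste0("ch", seq_len(p)), integer(0))
  acc_h <- crossvalidate_hdca(eps, k = 5, cycles = 3, seed = 3)$summary$mean[1]
  acc_f <- crossvalidate_hdca(eps, k = 5, cycles = 3, seed = 3,
                              method = "flat_lda")$summary$mean[1]
  expect_gte(acc_h, acc_f)
  expect_gt(acc_h, 70)
})
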