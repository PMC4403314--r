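make_white_stim <- function(bands, bins, seed = 1) {
  set.seed(seed)
  spectrogram(matrix(rnorm(bands * bins), bands, bins), bin_ms = 1)
}

test_that("PSTH counts, averages, and integrates correctly", {
  one <- trial_set(list(spike_train(25, T = 100)))
  p <- compute_psth(one, bin_ms = 10)
  expect_equal(length(p$values), 10)
  expect_equal(p$values[3], 0.1)
  expect_equal(sum(p$values[-3]), 0)

  u <- rand_train(12, 200)
  same <- compute_psth(trial_set(lapply(1:4, function(i) u)), 1)
  expect_equal(same$values, compute_psth(trial_set(list(u)), 1)$values)

  # integral of the PSTH equals the mean spike count
  set.seed(41)
  trials <- trial_set(lapply(1:6, function(i) rand_train(sample(5:30, 1), 500)))
  p <- compute_psth(trials, 2)
  expect_equal(sum(p$values) * 2,
               mean(vapply(trials$trains, n_spikes, numeric(1))))
  # edge-corrected smoothing approximately preserves the integral
  ps <- compute_psth(trials, 2, smooth_ms = 4)
  expect_equal(sum(ps$values), sum(p$values), tolerance = 0.05)
  expect_error(compute_psth(trials, bin_ms = 0), "bin_ms")
})

test_that("the design matrix realizes the lagged convolution", {
  s <- make_white_stim(4, 50, seed = 42)
  # one lag: the design is the stimulus itself
  expect_equal(build_design_matrix(s, 1), t(s$values))

  # impulse stimulus: exactly n_lag nonzero rows
  imp <- spectrogram(matrix(c(rep(0, 11), 1, rep(0, 4 * 30 - 12)), 4, 30), 1)
  X <- build_design_matrix(imp, 7)
  expect_equal(sum(rowSums(abs(X)) > 0), 7)

  # two-path equivalence with predict_rate for random kernels
  h <- strf_kernel(matrix(rnorm(4 * 6), 4, 6), lag_ms = 1)
  X <- build_design_matrix(s, 6)
  expect_equal(as.numeric(X %*% as.vector(h$values)),
               predict_rate(h, s)$values, tolerance = 1e-12)
})

test_that("the regularized pseudo-inverse keeps singular values under the tolerance", {
  expect_equal(regularized_pseudoinverse(diag(3), 1), diag(3),
               ignore_attr = TRUE)

  # hand-evaluated 2x2 case: keeps only the dominant dimension
  out <- regularized_pseudoinverse(diag(c(3, 1)), 0.76)
  expect_equal(attr(out, "m"), 1)
  expect_equal(out, diag(c(1 / 3, 0)), ignore_attr = TRUE)

  # full-rank well-conditioned matrix at lambda = 1 inverts exactly
  set.seed(43)
  B <- crossprod(matrix(rnorm(64), 8) + diag(8) * 3)
  expect_lt(max(abs(regularized_pseudoinverse(B, 1) %*% B - diag(8))), 1e-8)

  # the keep count is monotone non-decreasing in lambda
  d <- c(5, 3, 1.5, 0.4, 0.1)
  A <- diag(d)
  ms <- vapply(c(0.2, 0.5, 0.7, 0.9, 0.999, 1), function(l)
    attr(regularized_pseudoinverse(A, l), "m"), integer(1))
  expect_true(all(diff(ms) >= 0))
  expect_equal(ms[[1]], 1) # at least one dimension always kept
  expect_error(regularized_pseudoinverse(matrix(1, 2, 3), 1), "square")
  expect_error(regularized_pseudoinverse(diag(2), 0), "lambda")
})

test_that("reverse correlation recovers a known kernel from noiseless data", {
  s <- make_white_stim(6, 400, seed = 44)
  h_true <- strf_kernel(matrix(rnorm(6 * 8), 6, 8), lag_ms = 1)
  r <- predict_rate(h_true, s)
  h <- estimate_strf(s, r, n_lag = 8, lambda = 1)
  expect_lt(max(abs(h$values - h_true$values)) / max(abs(h_true$values)), 1e-6)

  # zero response -> zero kernel
  h0 <- estimate_strf(s, rep(0, 400), n_lag = 8, lambda = 1)
  expect_equal(max(abs(h0$values)), 0, tolerance = 1e-10)

  # pooling stimuli sharpens the estimate and stays exact when noiseless
  s2 <- make_white_stim(6, 400, seed = 45)
  hp <- estimate_strf(list(s, s2), list(r, predict_rate(h_true, s2)),
                      n_lag = 8, lambda = 1)
  expect_lt(max(abs(hp$values - h_true$values)) / max(abs(h_true$values)), 1e-6)
  expect_error(estimate_strf(s, rep(0, 399), 8), "length")
})

test_that("cross-validation selects sensible tolerances", {
  s <- make_white_stim(5, 300, seed = 46)
  h_true <- strf_kernel(matrix(rnorm(5 * 6), 5, 6), lag_ms = 1)
  r <- predict_rate(h_true, s)

  grid <- c(0.6, 0.8, 0.95, 1)
  expect_equal(cross_validate_lambda(s, r, 6, 0.7), 0.7) # single candidate
  lam <- cross_validate_lambda(s, r, 6, grid, folds = 3)
  expect_true(as.numeric(lam) %in% grid)
  expect_equal(as.numeric(lam), 1) # noiseless white noise needs no truncation

  # correlated stimulus + noisy response: cross-validated lambda does not
  # predict worse than lambda = 1 on held-out data
  set.seed(47)
  raw <- matrix(rnorm(5 * 600), 5, 600)
  for (k in 2:600) raw[, k] <- 0.95 * raw[, k - 1] + 0.3 * raw[, k]
  sc <- spectrogram(raw, 1)
  rv <- predict_rate(h_true, sc)$values + rnorm(600, 0, 3 * sd(predict_rate(h_true, sc)$values))
  tr <- 1:400; te <- 401:600
  s_tr <- spectrogram(raw[, tr], 1); s_te <- spectrogram(raw[, te], 1)
  lam <- as.numeric(cross_validate_lambda(s_tr, rv[tr], 6,
                                          c(0.5, 0.7, 0.85, 0.95, 1), folds = 4))
  mse <- function(l) {
    h <- estimate_strf(s_tr, rv[tr], 6, lambda = l)
    mean((predict_rate(h, s_te)$values - rv[te])^2)
  }
  expect_lte(mse(lam), mse(1) * (1 + 1e-9))
})

test_that("rate prediction is linear and respects the kernel layout", {
  s <- make_white_stim(3, 60, seed = 48)
  # single-entry kernel at lag 0 scales one stimulus band
  h <- strf_kernel(matrix(c(0, 2, 0), 3, 1), lag_ms = 1)
  expect_equal(predict_rate(h, s)$values, 2 * s$values[2, ])

  h0 <- strf_kernel(matrix(0, 3, 5), lag_ms = 1)
  expect_equal(predict_rate(h0, s)$values, rep(0, 60))

  # linear in the kernel and in the stimulus
  h1 <- strf_kernel(matrix(rnorm(15), 3, 5)); h2 <- strf_kernel(matrix(rnorm(15), 3, 5))
  hsum <- strf_kernel(h1$values + h2$values)
  expect_equal(predict_rate(hsum, s)$values,
               predict_rate(h1, s)$values + predict_rate(h2, s)$values,
               tolerance = 1e-12)
  expect_error(predict_rate(strf_kernel(matrix(1, 4, 2)), s), "band count")
})

test_that("L1 normalization splits shape from scale", {
  h <- strf_kernel(matrix(c(1, -3, 0.5, 1.5), 2, 2))
  n <- normalize_l1(h)
  expect_equal(sum(abs(n$strf$values)), 1)
  expect_equal(n$scale, 6)
  # idempotent on a normalized kernel
  n2 <- normalize_l1(n$strf)
  expect_equal(n2$scale, 1)
  expect_equal(n2$strf$values, n$strf$values)
  # scaling the kernel scales only the returned scale
  n7 <- normalize_l1(strf_kernel(7 * h$values))
  expect_equal(n7$strf$values, n$strf$values)
  expect_equal(n7$scale, 42)
  # prediction factorizes
  s <- make_white_stim(2, 40, seed = 49)
  expect_equal(predict_rate(h, s)$values,
               n$scale * predict_rate(n$strf, s)$values, tolerance = 1e-12)
  expect_error(normalize_l1(strf_kernel(matrix(0, 2, 2))), "zero")
})

test_that("spectrogram and STRF files round-trip", {
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  s <- make_white_stim(4, 25, seed = 50)
  write_spectrogram(s, path)
  back <- read_spectrogram(path)
  expect_equal(back$values, s$values, tolerance = 1e-9)
  expect_equal(back$bin_ms, s$bin_ms)
  expect_equal(back$band_edges, s$band_edges, tolerance = 1e-9)

  h <- strf_kernel(matrix(rnorm(8), 2, 4), lag_ms = 1)
  write_strf(h, path)
  hb <- read_strf(path)
  expect_equal(hb$values, h$values, tolerance = 1e-9)
})
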