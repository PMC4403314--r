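#' Spectrogram-like stimulus matrix
#'
#' @param values matrix, rows = frequency bands (low to high), columns =
#'   time bins.
#' @param bin_ms time-bin width in ms (default 1).
#' @param band_edges frequency band edges in Hz (length `nrow + 1`; default
#'   evenly spaced on 0-8 kHz).
#' @return an object of class `spectrogram`.
#' @export
spectrogram <- function(values, bin_ms = 1,
                        band_edges = seq(0, 8000, length.out = nrow(values) + 1)) {
  values <- as.matrix(values)
  if (nrow(values) < 1) stopf("spectrogram needs at least one band")
  if (any(!is.finite(values))) stopf("spectrogram values must be finite")
  if (bin_ms <= 0) stopf("bin_ms must be > 0")
  structure(list(values = values, bin_ms = bin_ms, band_edges = band_edges),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d bands x %d bins (%g ms), %g-%g Hz\n",
              nrow(x$values), ncol(x$values), x$bin_ms,
              min(x$band_edges), max(x$band_edges)))
  invisible(x)
}

#' Spectro-temporal receptive field kernel
#'
#' @param values matrix `h(tau, omega)`: rows = frequency bands, columns =
#'   time lags (lag 0 first).
#' @param lag_ms lag-bin width in ms (default 1).
#' @param band_edges frequency band edges in Hz.
#' @return an object of class `strf`.
#' @export
strf_kernel <- function(values, lag_ms = 1,
                        band_edges = seq(0, 8000, length.out = nrow(values) + 1)) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stopf("STRF values must be finite")
  structure(list(values = values, lag_ms = lag_ms, band_edges = band_edges),
            class = "strf")
}

#' @export
print.strf <- function(x, ...) {
  cat(sprintf("<strf> %d bands x %d lags (%g ms bins), |h|_1 = %.4g\n",
              nrow(x$values), ncol(x$values), x$lag_ms, sum(abs(x$values))))
  invisible(x)
}

#' Peri-stimulus time histogram
#'
#' Spike counts per bin averaged over trials and divided by the bin width,
#' giving the trial-averaged rate in spikes/ms.
#'
#' @param trials a [trial_set()].
#' @param bin_ms bin width in ms (default 1).
#' @param smooth_ms optional Gaussian smoothing standard deviation in ms
#'   (0 = raw histogram).  Smoothing preserves the integral of the rate.
#' @return a [sampled_trace()] of rate values, one per bin.
#' @export
compute_psth <- function(trials, bin_ms = 1, smooth_ms = 0) {
  stopifnot(inherits(trials, "trial_set"))
  if (bin_ms <= 0) stopf("bin_ms must be > 0")
  nb <- max(2L, as.integer(ceiling(trials$T / bin_ms - 1e-9)))
  counts <- rowSums(vapply(trials$trains, function(tr) {
    idx <- pmin(floor(tr$times / bin_ms) + 1L, nb)
    tabulate(idx, nbins = nb)
  }, numeric(nb)))
  r <- counts / n_trials(trials) / bin_ms
  if (smooth_ms > 0) {
    half <- ceiling(3 * smooth_ms / bin_ms)
    k <- stats::dnorm(seq(-half, half) * bin_ms, 0, smooth_ms)
    k <- k / sum(k)
    num <- stats::filter(c(rep(0, half), r, rep(0, half)), k, sides = 2)
    den <- stats::filter(c(rep(0, half), rep(1, nb), rep(0, half)), k, sides = 2)
    idx <- (half + 1):(half + nb)
    r <- as.numeric(num[idx] / den[idx]) # edge-corrected Gaussian smoothing
  }
  sampled_trace(r, dt = bin_ms, t0 = 0, unit = "spikes/ms")
}

#' Lagged-stimulus design matrix
#'
#' Row `t` contains the stimulus values `s(t - i, k)` for lags
#' `i = 0..n_lag-1` and bands `k = 1..M`, vectorized lag-major (all bands of
#' lag 0, then all bands of lag 1, ...), so that
#' `design %*% as.vector(h$values)` equals the discrete convolution
#' [predict_rate()].  History before the first bin is zero-padded.
#'
#' @param s a [spectrogram()].
#' @param n_lag number of lag bins (>= 1).
#' @return numeric matrix, `ncol(s) x (n_lag * nrow(s))`.
#' @export
build_design_matrix <- function(s, n_lag) {
  stopifnot(inherits(s, "spectrogram"))
  if (n_lag < 1) stopf("n_lag must be >= 1")
  M <- nrow(s$values); Tt <- ncol(s$values)
  X <- matrix(0, Tt, n_lag * M)
  for (i in 0:(n_lag - 1))
    X[(i + 1):Tt, (i * M + 1):(i * M + M)] <- t(s$values[, 1:(Tt - i), drop = FALSE])
  X
}

#' SVD-regularized pseudo-inverse
#'
#' Singular value decomposition of the (symmetric positive semidefinite)
#' stimulus autocorrelation matrix, keeping the largest `m` singular values
#' whose cumulative fraction of the total stays below `lambda` (at least one
#' dimension is always kept; `lambda >= 1` keeps all), and inverting only
#' those.
#'
#' @param A square symmetric matrix (typically `t(S) %*% S`).
#' @param lambda cumulative singular-value fraction tolerance in (0, 1].
#' @return the regularized pseudo-inverse matrix, with attribute `m` (number
#'   of dimensions kept).
#' @export
regularized_pseudoinverse <- function(A, lambda) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stopf("A must be square")
  if (lambda <= 0) stopf("lambda must be in (0, 1]")
  sv <- svd(A)
  m <- svd_keep_count(sv$d, lambda)
  dinv <- c(1 / sv$d[seq_len(m)], rep(0, length(sv$d) - m))
  out <- sv$v %*% (dinv * t(sv$u))
  attr(out, "m") <- m
  out
}

svd_keep_count <- function(d, lambda) {
  total <- sum(d)
  if (total <= 0) return(1L)
  if (lambda >= 1) return(length(d))
  max(1L, sum(cumsum(d) / total < lambda))
}

#' Estimate an STRF by normalized reverse correlation
#'
#' Solves the least-squares normal equations
#' `h = pinv_lambda(t(S) S) %*% t(S) r` with the SVD-regularized
#' pseudo-inverse, and reshapes the solution to a bands x lags kernel.
#'
#' @param s a [spectrogram()], or a list of spectrograms whose normal
#'   equations are pooled (summed) before inversion.
#' @param r response rate aligned with `s`'s time grid (a [sampled_trace()]
#'   from [compute_psth()], or a numeric vector of length `ncol(s)`); a list
#'   aligned with `s` when pooling.
#' @param n_lag number of lag bins.
#' @param lambda regularization tolerance (see
#'   [regularized_pseudoinverse()]); default 1 (no regularization).
#' @return a [strf_kernel()].
#' @export
estimate_strf <- function(s, r, n_lag, lambda = 1) {
  if (inherits(s, "spectrogram")) { s <- list(s); r <- list(r) }
  stopifnot(is.list(s), length(s) == length(r))
  A <- 0; csr <- 0
  for (i in seq_along(s)) {
    si <- s[[i]]
    stopifnot(inherits(si, "spectrogram"))
    rv <- if (inherits(r[[i]], "sampled_trace")) {
      if (abs(r[[i]]$dt - si$bin_ms) > 1e-9)
        stopf("response grid does not match the spectrogram")
      r[[i]]$values
    } else as.numeric(r[[i]])
    if (length(rv) != ncol(si$values))
      stopf("response length does not match the spectrogram")
    X <- build_design_matrix(si, n_lag)
    A <- A + crossprod(X)
    csr <- csr + crossprod(X, rv)
  }
  h <- regularized_pseudoinverse(A, lambda) %*% csr
  strf_kernel(matrix(h, nrow = nrow(s[[1]]$values)), lag_ms = s[[1]]$bin_ms,
              band_edges = s[[1]]$band_edges)
}

#' Cross-validate the regularization tolerance
#'
#' Splits the time axis into `folds` contiguous blocks; for each fold the
#' STRF is estimated on the remaining blocks at every candidate `lambda` and
#' the held-out block's predicted rate is correlated with the PSTH.  The
#' returned `lambda` maximizes the mean held-out correlation (largest
#' candidate on ties).
#'
#' @param s a [spectrogram()].
#' @param trials a [trial_set()] (or a rate [sampled_trace()]).
#' @param n_lag number of lag bins.
#' @param lambda_grid numeric vector of candidate tolerances.
#' @param folds number of cross-validation folds (>= 2).
#' @return the selected `lambda` (an element of `lambda_grid`), with
#'   attribute `score` (mean held-out correlation per candidate).
#' @export
cross_validate_lambda <- function(s, trials, n_lag, lambda_grid, folds = 4) {
  stopifnot(inherits(s, "spectrogram"))
  if (length(lambda_grid) == 1) return(lambda_grid)
  if (folds < 2) stopf("need at least 2 folds")
  r <- if (inherits(trials, "trial_set")) compute_psth(trials, s$bin_ms)$values
       else if (inherits(trials, "sampled_trace")) trials$values
       else as.numeric(trials)
  Tt <- ncol(s$values)
  if (Tt < folds * 2) stopf("degenerate folds: too few time bins")
  X <- build_design_matrix(s, n_lag)
  fold_id <- cut(seq_len(Tt), folds, labels = FALSE)
  scores <- matrix(NA_real_, folds, length(lambda_grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    A <- crossprod(X[tr, , drop = FALSE])
    ctr <- crossprod(X[tr, , drop = FALSE], r[tr])
    sv <- svd(A)
    for (li in seq_along(lambda_grid)) {
      m <- svd_keep_count(sv$d, lambda_grid[li])
      dinv <- c(1 / sv$d[seq_len(m)], rep(0, length(sv$d) - m))
      h <- sv$v %*% (dinv * crossprod(sv$u, ctr))
      pred <- X[te, , drop = FALSE] %*% h
      scores[f, li] <- if (sd(pred) > 0 && sd(r[te]) > 0) cor(pred, r[te]) else -Inf
    }
  }
  msc <- colMeans(scores)
  best <- max(msc)
  out <- max(lambda_grid[msc >= best - 1e-12])
  attr(out, "score") <- setNames(msc, lambda_grid)
  out
}

#' Predict a firing rate (or drive) from an STRF
#'
#' Discrete convolution of the kernel with the stimulus,
#' `r(t) = sum_{i,k} h(i, k) s(t - i, k)`, zero-padding the stimulus before
#' its first bin.
#'
#' @param h a [strf_kernel()].
#' @param s a [spectrogram()] with the same number of bands.
#' @return a [sampled_trace()] on the stimulus grid.
#' @export
predict_rate <- function(h, s) {
  stopifnot(inherits(h, "strf"), inherits(s, "spectrogram"))
  if (nrow(h$values) != nrow(s$values))
    stopf("band count mismatch between STRF and spectrogram")
  Tt <- ncol(s$values); L <- ncol(h$values)
  r <- numeric(Tt)
  for (i in 0:(L - 1)) {
    contrib <- colSums(s$values[, 1:(Tt - i), drop = FALSE] * h$values[, i + 1])
    r[(i + 1):Tt] <- r[(i + 1):Tt] + contrib
  }
  sampled_trace(r, dt = s$bin_ms, t0 = 0, unit = "rate")
}

#' L1-normalize an STRF
#'
#' Rescales the kernel to unit L1 norm and returns the scale separately, so
#' `predict_rate(h, s) == scale * predict_rate(h_normalized, s)`.
#'
#' @param h a [strf_kernel()], not identically zero.
#' @return list with `strf` (unit L1 norm) and `scale` (the removed L1
#'   norm).
#' @export
normalize_l1 <- function(h) {
  stopifnot(inherits(h, "strf"))
  s <- sum(abs(h$values))
  if (s == 0) stopf("cannot normalize an identically zero kernel")
  list(strf = strf_kernel(h$values / s, lag_ms = h$lag_ms, band_edges = h$band_edges),
       scale = s)
}
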