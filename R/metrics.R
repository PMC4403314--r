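# exponential cross sum S(u, v) = sum_ij wu_i wv_j exp(-|u_i - v_j|/tau)
cross_sum <- function(tu, wu, tv, wv, tau, method = "efficient") {
  if (length(tu) == 0 || length(tv) == 0) return(0)
  if (method == "efficient") {
    exp_cross_sum_cpp(tu, wu, tv, wv, tau)
  } else {
    sum(outer(wu, wv) * exp(-abs(outer(tu, tv, "-")) / tau))
  }
}

#' van Rossum distance between two spike trains
#'
#' The L2 distance between the exponentially filtered trains.  With the
#' default kernel normalization `sqrt(2/tau)`,
#' `d^2(u, v) = S(u,u) + S(v,v) - 2 S(u,v)` where
#' `S(u,v) = sum_ij exp(-|u_i - v_j|/tau)`, so the distance between a
#' one-spike train and the empty train is exactly 1.  Both a brute-force
#' double-sum and an efficient O(m+n) sorted-merge implementation are
#' available and agree to floating-point accuracy.
#'
#' @param u,v [spike_train()] objects.
#' @param tau kernel timescale in ms (> 0).
#' @param method `"efficient"` (sorted-merge recursion) or `"brute"`
#'   (double sum).
#' @param normalization kernel height `kappa` (default `sqrt(2/tau)`).
#' @return non-negative distance.
#' @export
van_rossum_distance <- function(u, v, tau, method = c("efficient", "brute"),
                                normalization = sqrt(2 / tau)) {
  method <- match.arg(method)
  if (!is.finite(tau) || tau <= 0) stopf("tau must be > 0")
  stopifnot(is_spike_train(u), is_spike_train(v))
  wu <- rep(1, n_spikes(u)); wv <- rep(1, n_spikes(v))
  base <- cross_sum(u$times, wu, u$times, wu, tau, method) +
    cross_sum(v$times, wv, v$times, wv, tau, method) -
    2 * cross_sum(u$times, wu, v$times, wv, tau, method)
  sqrt(max(0, normalization^2 * tau / 2 * base))
}

#' van Rossum distance between a spike train and a filtered function
#'
#' L2 distance between `filter_train(u, tau)` and a target function `g`.  For
#' an exponential-sum `g` (the output of [filter_train()] or
#' [average_function()]) the distance is computed analytically; for a plain R
#' function it is computed by adaptive quadrature (relative tolerance 1e-8).
#'
#' @param u a [spike_train()].
#' @param g a `filtered_function`, or a plain function of time (ms).
#' @param tau required when `g` is a plain function; must equal `g$tau`
#'   otherwise.
#' @param upper integration upper limit for the numeric branch.
#' @return non-negative distance.
#' @export
van_rossum_to_function <- function(u, g, tau = NULL, upper = NULL) {
  stopifnot(is_spike_train(u))
  if (inherits(g, "filtered_function")) {
    if (!is.null(tau) && abs(tau - g$tau) > 1e-9)
      stopf("tau mismatch between train kernel and target function")
    tau <- g$tau
    wu <- rep(1, n_spikes(u))
    base <- cross_sum(u$times, wu, u$times, wu, tau) +
      cross_sum(g$times, g$weights, g$times, g$weights, tau) -
      2 * cross_sum(u$times, wu, g$times, g$weights, tau)
    return(sqrt(max(0, g$kappa^2 * tau / 2 * base)))
  }
  if (!is.function(g)) stopf("g must be a filtered_function or a function")
  if (is.null(tau) || tau <= 0) stopf("numeric branch needs tau > 0")
  fu <- filter_train(u, tau)
  if (is.null(upper)) upper <- max(c(u$times, u$T, 0)) + 40 * tau
  ig <- stats::integrate(function(t) (evaluate_filtered(fu, t) - g(t))^2,
                         lower = 0, upper = upper, rel.tol = 1e-8,
                         subdivisions = 2000L)
  sqrt(max(0, ig$value))
}

#' Coincidence factor between a model and a target spike train
#'
#' `Gamma = 2 / (1 - 2 delta f) * (N_c - 2 delta f N_e) / (N_e + N_m)` where
#' `N_c` is the number of coincident spike pairs within `|dt| <= delta`
#' (greedy earliest-first one-to-one matching), `N_e`, `N_m` are the target
#' and model spike counts, and `f` is the target's firing rate.  `Gamma <= 1`
#' with 1 a perfect match at resolution `delta` and 0 chance level.
#'
#' @param model,target [spike_train()] objects (the target supplies `f` and
#'   `N_e`).
#' @param delta coincidence window in ms; requires `2 * f * delta < 1`.
#' @return an object of class `coincidence_result` with fields `gamma`,
#'   `n_c`, `n_e`, `n_m`, `delta`, `f`.
#' @export
coincidence_factor <- function(model, target, delta) {
  stopifnot(is_spike_train(model), is_spike_train(target))
  if (!is.finite(delta) || delta <= 0) stopf("delta must be > 0")
  n_e <- n_spikes(target); n_m <- n_spikes(model)
  if (n_e == 0 && n_m == 0) {
    res <- list(gamma = 1, n_c = 0L, n_e = 0L, n_m = 0L, delta = delta, f = 0)
    return(structure(res, class = "coincidence_result", degenerate = TRUE))
  }
  if (n_e == 0) stopf("coincidence factor undefined: empty target train (N_e = 0)")
  f <- n_e / target$T
  if (2 * f * delta >= 1)
    stopf("coincidence factor undefined: 2*f*delta = %.3f >= 1", 2 * f * delta)
  n_c <- coincidence_count_cpp(model$times, target$times, delta)
  gamma <- 2 / (1 - 2 * delta * f) * (n_c - 2 * delta * f * n_e) / (n_e + n_m)
  structure(list(gamma = gamma, n_c = n_c, n_e = n_e, n_m = n_m,
                 delta = delta, f = f), class = "coincidence_result")
}

#' @export
print.coincidence_result <- function(x, ...) {
  cat(sprintf("<coincidence_result> Gamma = %.4f (N_c = %d, N_e = %d, N_m = %d, delta = %g ms)\n",
              x$gamma, x$n_c, x$n_e, x$n_m, x$delta))
  invisible(x)
}

#' Intrinsic reliability of a trial set
#'
#' The mean inter-trial coincidence factor over all unordered trial pairs.
#' Because the coincidence factor is asymmetric in which train supplies the
#' rate `f`, each pair is symmetrized by averaging the two directed values.
#' The cluster size is the mean pairwise van Rossum distance at `tau`.
#'
#' @param trials a [trial_set()] with at least 2 trials.
#' @param delta coincidence window in ms.
#' @param tau van Rossum timescale in ms used for the cluster size.
#' @param model optional model [spike_train()]; when given, the performance
#'   factor `Gamma_A = Gamma(model)/Gamma_i` is also reported (with
#'   `Gamma(model)` the mean coincidence factor of the model against the
#'   trials).
#' @return an object of class `reliability_result` with fields `gamma_i`,
#'   `cluster_size`, and (when `model` is given) `gamma_model`, `gamma_a`.
#' @export
intrinsic_reliability <- function(trials, delta, tau = 10, model = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  n <- n_trials(trials)
  if (n < 2) stopf("intrinsic reliability needs at least 2 trials")
  gs <- c(); ds <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- trials$trains[[i]]; b <- trials$trains[[j]]
    gs <- c(gs, mean(c(coincidence_factor(a, b, delta)$gamma,
                       coincidence_factor(b, a, delta)$gamma)))
    ds <- c(ds, van_rossum_distance(a, b, tau))
  }
  out <- list(gamma_i = mean(gs), cluster_size = mean(ds), delta = delta, tau = tau)
  if (!is.null(model)) {
    gm <- mean(vapply(trials$trains, function(tr)
      coincidence_factor(model, tr, delta)$gamma, numeric(1)))
    out$gamma_model <- gm
    out$gamma_a <- gm / out$gamma_i
  }
  structure(out, class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability_result> Gamma_i = %.4f, cluster size = %.4f (delta = %g ms, tau = %g ms)\n",
              x$gamma_i, x$cluster_size, x$delta, x$tau))
  if (!is.null(x$gamma_a))
    cat(sprintf("  model Gamma = %.4f, Gamma_A = Gamma/Gamma_i = %.4f\n",
                x$gamma_model, x$gamma_a))
  invisible(x)
}

#' Expected coincidence factor of an inhomogeneous Poisson process
#'
#' The expected coincidence factor between Poisson spike trains with rate
#' `r(t)` and a target train: the expected model spike count is the integral
#' of the rate, and the expected coincidence count is estimated by Monte
#' Carlo over `n_mc` thinning-sampled Poisson trains.
#'
#' @param rate a non-negative [sampled_trace()] in spikes/ms.
#' @param target a [spike_train()].
#' @param delta coincidence window in ms.
#' @param n_mc number of Monte Carlo draws (default 100).
#' @param seed RNG seed for the draws.
#' @return the expected coincidence factor, with attributes `se` (Monte Carlo
#'   standard error propagated through the formula), `n_c_mean` and
#'   `n_m_expected`.
#' @export
expected_coincidence_poisson <- function(rate, target, delta, n_mc = 100,
                                         seed = NULL) {
  stopifnot(inherits(rate, "sampled_trace"), is_spike_train(target))
  if (any(rate$values < 0)) stopf("rate must be non-negative")
  n_e <- n_spikes(target)
  if (n_e == 0) stopf("empty target train")
  f <- n_e / target$T
  if (2 * f * delta >= 1) stopf("2*f*delta >= 1")
  tt <- trace_times(rate)
  n_m_exp <- trapz(tt, rate$values)
  counts <- with_seed(seed, {
    vapply(seq_len(n_mc), function(k) {
      tr <- generate_poisson_train(rate, seed = NULL)
      coincidence_count_cpp(tr$times, target$times, delta)
    }, numeric(1))
  })
  n_c_mean <- mean(counts)
  denom <- 0.5 * (n_e + n_m_exp) * (1 - 2 * f * delta)
  gamma <- (n_c_mean - 2 * f * delta * n_e) / denom
  se <- (sd(counts) / sqrt(n_mc)) / denom
  structure(gamma, se = se, n_c_mean = n_c_mean, n_m_expected = n_m_exp)
}

#' Expected van Rossum distance of an inhomogeneous Poisson process
#'
#' The distance between the filtered target train and the kernel-filtered
#' rate (the expected filtered function of a large Poisson ensemble),
#' computed on the rate's grid with trapezoidal integration.  The filtered
#' train is evaluated by exact exponential recursion at the grid points; the
#' rate convolution uses a zero-order-hold exponential recursion.  Note this
#' is the distance between expected functions, a lower bound on the true
#' expected distance (which carries an additional Poisson variance term).
#'
#' @param rate a non-negative [sampled_trace()] in spikes/ms.
#' @param u a [spike_train()].
#' @param tau kernel timescale in ms.
#' @param normalization kernel height (default `sqrt(2/tau)`).
#' @return non-negative expected distance.
#' @export
expected_van_rossum_poisson <- function(rate, u, tau,
                                        normalization = sqrt(2 / tau)) {
  stopifnot(inherits(rate, "sampled_trace"), is_spike_train(u))
  if (any(rate$values < 0)) stopf("rate must be non-negative")
  if (!is.finite(tau) || tau <= 0) stopf("tau must be > 0")
  dt <- rate$dt
  tt <- trace_times(rate)
  n <- length(tt)
  dec <- exp(-dt / tau)
  # exact filtered train at grid points
  fu <- numeric(n)
  st <- u$times
  si <- 1
  acc <- 0
  for (k in seq_len(n)) {
    if (k > 1) acc <- acc * dec
    while (si <= length(st) && st[si] <= tt[k]) {
      acc <- acc + exp(-(tt[k] - st[si]) / tau)
      si <- si + 1
    }
    fu[k] <- acc
  }
  fu <- fu * normalization
  # zero-order-hold convolution of the rate with the kernel
  fr <- numeric(n)
  gain <- normalization * tau * (1 - dec)
  for (k in 2:n) fr[k] <- fr[k - 1] * dec + rate$values[k - 1] * gain
  sqrt(max(0, trapz(tt, (fu - fr)^2)))
}
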