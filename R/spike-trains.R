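#' Spike train on a finite recording window
#'
#' A spike train is an ordered set of spike times (ms) on the window
#' `[0, T]`.  Times must be strictly increasing; spikes closer than 1e-9 ms
#' are treated as duplicates and rejected.
#'
#' @param times numeric vector of spike times in ms, sorted ascending.
#' @param T duration of the recording window in ms.
#' @return an object of class `spike_train` with fields `times` and `T`.
#' @examples
#' u <- spike_train(c(10, 20, 30), T = 100)
#' n_spikes(u)
#' @export
spike_train <- function(times = numeric(0), T) {
  times <- as.numeric(times)
  if (!is.numeric(T) || length(T) != 1 || !is.finite(T) || T < 0)
    stopf("T must be a single non-negative number")
  if (anyNA(times) || any(!is.finite(times)))
    stopf("spike times must be finite")
  if (any(times < -1e-9) || any(times > T + 1e-9))
    stopf("spike times must lie in [0, T]")
  if (is.unsorted(times, strictly = FALSE))
    stopf("spike times must be sorted ascending")
  if (length(times) > 1 && any(diff(times) <= 1e-9))
    stopf("duplicate spike times (closer than 1e-9 ms)")
  structure(list(times = times, T = as.numeric(T)), class = "spike_train")
}

#' @rdname spike_train
#' @param u a `spike_train`.
#' @export
n_spikes <- function(u) length(u$times)

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes on [0, %g] ms\n", n_spikes(x), x$T))
  invisible(x)
}

is_spike_train <- function(x) inherits(x, "spike_train")

#' Regularly sampled trace
#'
#' Holds sampled signals: injected current, membrane voltage, firing rates.
#'
#' @param values numeric vector of samples (length >= 2).
#' @param dt sampling step in ms (> 0).
#' @param t0 time of the first sample in ms.
#' @param unit free-text unit label ("mV" for voltage, model units otherwise).
#' @return an object of class `sampled_trace`.
#' @export
sampled_trace <- function(values, dt, t0 = 0, unit = "") {
  values <- as.numeric(values)
  if (length(values) < 2) stopf("a sampled_trace needs at least 2 samples")
  if (!is.finite(dt) || dt <= 0) stopf("dt must be > 0")
  structure(list(values = values, dt = as.numeric(dt), t0 = as.numeric(t0),
                 unit = unit), class = "sampled_trace")
}

#' @rdname sampled_trace
#' @param x a `sampled_trace`.
#' @export
trace_times <- function(x) x$t0 + (seq_along(x$values) - 1) * x$dt

#' @rdname sampled_trace
#' @export
trace_duration <- function(x) (length(x$values) - 1) * x$dt

#' @export
print.sampled_trace <- function(x, ...) {
  cat(sprintf("<sampled_trace> %d samples, dt = %g ms, t0 = %g ms%s\n",
              length(x$values), x$dt, x$t0,
              if (nzchar(x$unit)) paste0(" [", x$unit, "]") else ""))
  invisible(x)
}

#' Set of spike-train trials sharing one stimulus
#'
#' @param trains list of [spike_train()] objects sharing a common duration, or
#'   a list of numeric vectors (then `T` must be given).
#' @param T common duration in ms (taken from the trains when omitted).
#' @param stimulus_id optional identifier of the stimulus.
#' @return an object of class `trial_set`.
#' @export
trial_set <- function(trains, T = NULL, stimulus_id = NULL) {
  if (is_spike_train(trains)) trains <- list(trains)
  trains <- lapply(trains, function(tr) {
    if (is_spike_train(tr)) tr else spike_train(tr, T = T)
  })
  if (length(trains) == 0) stopf("a trial_set needs at least one trial")
  Ts <- vapply(trains, function(tr) tr$T, numeric(1))
  if (diff(range(Ts)) > 1e-6) stopf("all trials must share one duration T")
  structure(list(trains = trains, T = Ts[1], stimulus_id = stimulus_id),
            class = "trial_set")
}

#' @rdname trial_set
#' @param x a `trial_set`.
#' @export
n_trials <- function(x) length(x$trains)

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials on [0, %g] ms%s\n", n_trials(x), x$T,
              if (!is.null(x$stimulus_id)) paste0(" (", x$stimulus_id, ")") else ""))
  invisible(x)
}

#' Extract spike times from a voltage trace
#'
#' Finds upward threshold crossings and places each spike at the linearly
#' interpolated crossing time between the bracketing samples.  Crossings
#' closer together than `refractory_ms` are merged into a single spike (one
#' spike per action potential).
#'
#' @param v a [sampled_trace()] of membrane voltage (mV).
#' @param threshold crossing threshold in mV (default 0).
#' @param refractory_ms merge window in ms (default 1).
#' @return a [spike_train()] on `[0, duration(v)]`, times relative to the
#'   start of the trace.
#' @export
extract_spikes_from_voltage <- function(v, threshold = 0, refractory_ms = 1) {
  stopifnot(inherits(v, "sampled_trace"))
  val <- v$values
  n <- length(val)
  idx <- which(val[-n] < threshold & val[-1] >= threshold)
  times <- numeric(0)
  if (length(idx)) {
    frac <- (threshold - val[idx]) / (val[idx + 1] - val[idx])
    times <- (idx - 1 + frac) * v$dt
    keep <- c(TRUE, diff(times) >= refractory_ms)
    # sequential merge: keep a crossing only if >= refractory after last kept
    if (!all(keep)) {
      kept <- times[1]; out <- times[1]
      for (t in times[-1]) if (t - kept >= refractory_ms) { out <- c(out, t); kept <- t }
      times <- out
    }
  }
  spike_train(times, T = (n - 1) * v$dt)
}

#' Filter a spike train with the causal exponential kernel
#'
#' Maps a spike train `u` to the function `f(t; u) = sum_i h(t - u_i)` with
#' `h(t) = kappa * exp(-t/tau)` for `t >= 0` and 0 otherwise.  The default
#' normalization `kappa = sqrt(2/tau)` makes the van Rossum distance between
#' a one-spike train and the empty train exactly 1 at every `tau`.
#'
#' @param u a [spike_train()].
#' @param tau kernel timescale in ms (> 0).
#' @param normalization kernel height `kappa` (default `sqrt(2/tau)`).
#' @return an object of class `filtered_function`: an exponential sum that can
#'   be evaluated exactly at arbitrary times with [evaluate_filtered()].
#' @export
filter_train <- function(u, tau, normalization = sqrt(2 / tau)) {
  if (!is.finite(tau) || tau <= 0) stopf("tau must be > 0")
  stopifnot(is_spike_train(u))
  filtered_function(u$times, rep(1, n_spikes(u)), tau, normalization)
}

filtered_function <- function(times, weights, tau, kappa) {
  structure(list(times = as.numeric(times), weights = as.numeric(weights),
                 tau = tau, kappa = kappa), class = "filtered_function")
}

#' @rdname filter_train
#' @param f a `filtered_function`.
#' @param t numeric vector of evaluation times in ms.
#' @export
evaluate_filtered <- function(f, t) {
  stopifnot(inherits(f, "filtered_function"))
  if (length(f$times) == 0) return(rep(0, length(t)))
  vapply(t, function(tt) {
    d <- tt - f$times
    live <- d >= 0
    sum(f$weights[live] * f$kappa * exp(-d[live] / f$tau))
  }, numeric(1))
}

#' @export
print.filtered_function <- function(x, ...) {
  cat(sprintf("<filtered_function> %d kernels, tau = %g ms, kappa = %g\n",
              length(x$times), x$tau, x$kappa))
  invisible(x)
}

#' Average filtered function of a trial set
#'
#' The average function is the pointwise mean of the per-trial filtered
#' functions (set `aggregate = "sum"` for the plain sum).
#'
#' @param trials a [trial_set()].
#' @param tau kernel timescale in ms.
#' @param normalization kernel height (default `sqrt(2/tau)`).
#' @param aggregate `"mean"` (default) or `"sum"`.
#' @return a `filtered_function`.
#' @export
average_function <- function(trials, tau, normalization = sqrt(2 / tau),
                             aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(trials, "trial_set"))
  if (!is.finite(tau) || tau <= 0) stopf("tau must be > 0")
  n <- n_trials(trials)
  times <- unlist(lapply(trials$trains, function(tr) tr$times))
  w <- if (aggregate == "mean") rep(1 / n, length(times)) else rep(1, length(times))
  o <- order(times)
  filtered_function(times[o], w[o], tau, normalization)
}

#' Mean inter-spike interval and firing rate
#'
#' @param u a [spike_train()].
#' @return list with `mean_isi` (ms; `NA` for fewer than 2 spikes) and `rate`
#'   (spikes/ms, count divided by the window duration `T`).
#' @export
mean_isi_and_rate <- function(u) {
  stopifnot(is_spike_train(u))
  if (u$T <= 0) stopf("rate requires T > 0")
  list(mean_isi = if (n_spikes(u) >= 2) mean(diff(u$times)) else NA_real_,
       rate = n_spikes(u) / u$T)
}
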