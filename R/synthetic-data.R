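#' Random injected-current specification
#'
#' Describes an Ornstein-Uhlenbeck current waveform emulating in-vivo-like
#' somatic current injection: mean `mu`, stationary standard deviation
#' `sigma`, correlation time `tau_c`.  The defaults are chosen so that the
#' reference aEIF target neuron ([table2_parameters()]) fires in the 5-15 Hz
#' band.
#'
#' @param duration total duration in ms (default 4000).
#' @param dt sampling step in ms (default 0.1).
#' @param mu mean current (model units).
#' @param sigma stationary standard deviation.
#' @param tau_c correlation time in ms.
#' @param seed RNG seed.
#' @return a list of class `current_spec`.
#' @export
current_spec <- function(duration = 4000, dt = 0.1, mu = 1.0, sigma = 2.5,
                         tau_c = 5, seed = 1) {
  if (sigma < 0) stopf("sigma must be >= 0")
  if (tau_c <= 0) stopf("tau_c must be > 0")
  structure(list(duration = duration, dt = dt, mu = mu, sigma = sigma,
                 tau_c = tau_c, seed = seed), class = "current_spec")
}

#' Generate an Ornstein-Uhlenbeck current trace
#'
#' Euler recursion `I(t+dt) = I + (mu - I) dt/tau_c + sigma sqrt(2 dt/tau_c) z`
#' with standard normal `z`, started at `I(0) = mu`.  Deterministic given
#' the spec's seed.
#'
#' @param spec a [current_spec()].
#' @return a [sampled_trace()].
#' @export
generate_current <- function(spec) {
  stopifnot(inherits(spec, "current_spec"))
  n <- as.integer(round(spec$duration / spec$dt))
  with_seed(spec$seed, {
    z <- rnorm(n - 1)
    I <- numeric(n)
    I[1] <- spec$mu
    a <- spec$dt / spec$tau_c
    s <- spec$sigma * sqrt(2 * spec$dt / spec$tau_c)
    for (k in 2:n) I[k] <- I[k - 1] + (spec$mu - I[k - 1]) * a + s * z[k - 1]
    sampled_trace(I, dt = spec$dt, t0 = 0, unit = "current")
  })
}

#' Reference aEIF target parameters
#'
#' The target parameter set of the synthetic parameter-recovery experiment:
#' `tau_m` = 10 ms, `tau_w` = 144 ms, `b` = 0.001, `V_T` = -50 mV,
#' `V_r = E_L` = -70 mV, `alpha` = 1 mV, `Delta_T` = 2 mV, with the input
#' scale `R` = 1 and cutoff `V_c` = 0 mV held fixed.
#'
#' @return an aEIF [parameter_set()].
#' @export
table2_parameters <- function() {
  parameter_set("aEIF", tau_m = 10, tau_w = 144, b = 0.001, V_T = -50,
                E_L = -70, V_r = -70, alpha = 1, Delta_T = 2, R = 1, V_c = 0)
}

#' Initialization ranges of the recovery experiment
#'
#' The feasible region used to initialize the genetic algorithm in the
#' recovery experiment: per parameter roughly `[0.3x, 1.7x]` the target
#' value (voltages spanning the physiological range).  The reset is tied to
#' the resting potential (`V_r = E_L`), so the gene has 7 coordinates.
#'
#' @return named list of `c(low, high)` intervals.
#' @export
table2_ranges <- function() {
  list(tau_m = c(3, 17), tau_w = c(36, 204), b = c(0.0003, 0.0017),
       V_T = c(-70, -20), E_L = c(-120, -50), alpha = c(0.3, 1.7),
       Delta_T = c(0.5, 3))
}

#' Synthetic aEIF recovery dataset
#'
#' Simulates the reference aEIF neuron ([table2_parameters()]) for 4 s in
#' response to an Ornstein-Uhlenbeck current, splitting the result into a
#' 2 s training half and a 2 s validation half.  Regeneration from the same
#' seed is bit-exact.
#'
#' @param seed RNG seed for the current waveform.
#' @param duration total duration in ms (default 4000, split in half).
#' @param dt integration and sampling step in ms.
#' @param spec optional [current_spec()] overriding the defaults (its seed
#'   is replaced by `seed`).
#' @return an object of class `synthetic_dataset`: list with `params`,
#'   `current` (full trace), `spikes` (full train), and `train` /
#'   `validation` halves, each a list with `current` and `spikes` (times
#'   re-based to the half's own window).
#' @export
make_table2_dataset <- function(seed = 1, duration = 4000, dt = 0.1,
                                spec = NULL) {
  spec <- spec %||% current_spec(duration = duration, dt = dt, seed = seed)
  spec$seed <- seed
  current <- generate_current(spec)
  params <- table2_parameters()
  sim <- simulate_neuron(params, current, dt = dt)
  T_half <- spec$duration / 2
  n_half <- as.integer(round(T_half / spec$dt))
  split_half <- function(first) {
    idx <- if (first) 1:n_half else (n_half + 1):length(current$values)
    off <- if (first) 0 else T_half
    times <- sim$spikes$times[sim$spikes$times >= off & sim$spikes$times < off + T_half] - off
    list(current = sampled_trace(current$values[idx], dt = spec$dt, t0 = 0,
                                 unit = "current"),
         spikes = spike_train(times, T = T_half))
  }
  structure(list(params = params, current = current, spikes = sim$spikes,
                 train = split_half(TRUE), validation = split_half(FALSE),
                 seed = seed, spec = spec),
            class = "synthetic_dataset")
}

#' Sample an inhomogeneous Poisson spike train by thinning
#'
#' Candidate spikes are drawn from a homogeneous Poisson process at the
#' rate's maximum and accepted with probability `r(t)/r_max` (rate linearly
#' interpolated between samples).  Deterministic given the seed.
#'
#' @param rate a non-negative bounded [sampled_trace()] in spikes/ms.
#' @param seed RNG seed (`NULL` uses the current RNG stream).
#' @return a [spike_train()] on the rate's duration.
#' @export
generate_poisson_train <- function(rate, seed = NULL) {
  stopifnot(inherits(rate, "sampled_trace"))
  if (any(rate$values < 0)) stopf("rate must be non-negative")
  T <- trace_duration(rate)
  rmax <- max(rate$values)
  body <- function() {
    if (rmax == 0) return(spike_train(numeric(0), T = T))
    tt <- trace_times(rate) - rate$t0
    cand <- numeric(0)
    t_last <- 0
    repeat {
      n_draw <- max(16L, as.integer(ceiling((T - t_last) * rmax * 1.5)))
      gaps <- rexp(n_draw, rate = rmax)
      new <- t_last + cumsum(gaps)
      cand <- c(cand, new[new < T])
      if (length(new) == 0 || max(new) >= T) break
      t_last <- max(new)
    }
    if (length(cand) == 0) return(spike_train(numeric(0), T = T))
    rt <- approx(tt, rate$values, xout = cand, rule = 2)$y
    keep <- runif(length(cand)) < rt / rmax
    times <- cand[keep]
    if (length(times) > 1) times <- times[c(TRUE, diff(times) > 1e-9)]
    spike_train(times, T = T)
  }
  if (is.null(seed)) body() else with_seed(seed, body())
}

# Gabor-shaped ground-truth kernel used by the auditory generator
gabor_strf <- function(n_bands = 20, n_lags = 40, lag_ms = 1) {
  lag <- seq(0, by = lag_ms, length.out = n_lags)
  band <- seq_len(n_bands)
  env <- outer(exp(-(band - 10)^2 / (2 * 3^2)), exp(-(lag - 10)^2 / (2 * 5^2)))
  carrier <- matrix(cos(2 * pi * (lag - 10) / 25), n_bands, n_lags, byrow = TRUE)
  normalize_l1(strf_kernel(env * carrier, lag_ms = lag_ms))$strf
}

#' Synthetic auditory cascade dataset
#'
#' Emulates the structure of extracellular auditory experiments: random
#' band-limited spectrogram stimuli (~2 s, 20 bands) drive a known
#' ground-truth cascade (Gabor-shaped L1-normalized STRF, scale `C`, aEIF
#' neuron); each stimulus's deterministic cascade spike train is replicated
#' into trials with Gaussian spike-time jitter and a small deletion
#' probability emulating trial-to-trial variability.  Stimuli are split in
#' half into training and validation sets.
#'
#' @param n_stimuli number of stimuli (>= 2; default 10).
#' @param n_trials trials per stimulus (default 10).
#' @param noise_jitter_ms spike-time jitter standard deviation in ms (0 for
#'   noiseless trials).
#' @param p_delete per-spike deletion probability (default 0.03; forced to
#'   0 when `noise_jitter_ms` is 0).
#' @param seed master RNG seed; regeneration is bit-exact.
#' @param duration_ms stimulus duration (default 2000).
#' @param n_bands,n_lags STRF geometry (defaults 20 bands, 40 lags).
#' @param bin_ms spectrogram bin width in ms (default 1).
#' @param C drive scale of the ground-truth genome.
#' @return an object of class `synthetic_dataset`: list with `stimuli`,
#'   `responses` (trial sets), `truth` (the generating [cascade_genome()]),
#'   `train_idx`, `validation_idx`, `seed`.
#' @export
make_auditory_dataset <- function(n_stimuli = 10, n_trials = 10,
                                  noise_jitter_ms = 1, p_delete = 0.03,
                                  seed = 1, duration_ms = 2000, n_bands = 20,
                                  n_lags = 40, bin_ms = 1, C = 55) {
  if (n_stimuli < 2) stopf("need at least 2 stimuli for a train/validation split")
  if (noise_jitter_ms == 0) p_delete <- 0
  truth <- cascade_genome(gabor_strf(n_bands, n_lags, bin_ms), C,
                          parameter_set("aEIF", tau_m = 10, tau_w = 144,
                                        b = 0.001, V_T = -50, E_L = -70,
                                        V_r = -70, alpha = 1, Delta_T = 2,
                                        R = 1, V_c = 0))
  nt <- as.integer(round(duration_ms / bin_ms))
  with_seed(seed, {
    stimuli <- lapply(seq_len(n_stimuli), function(i) {
      # white noise per band, lightly smoothed in time (3-bin moving average)
      m <- matrix(rnorm(n_bands * nt), n_bands, nt)
      sm <- t(apply(m, 1, function(r) stats::filter(r, rep(1 / 3, 3), sides = 1)))
      sm[is.na(sm)] <- m[is.na(sm)]
      spectrogram(sm * sqrt(3), bin_ms = bin_ms)
    })
    responses <- lapply(stimuli, function(s) {
      u <- simulate_cascade(truth, s)
      trains <- lapply(seq_len(n_trials), function(k) {
        times <- u$times
        if (p_delete > 0) times <- times[runif(length(times)) >= p_delete]
        if (noise_jitter_ms > 0) times <- times + rnorm(length(times), 0, noise_jitter_ms)
        times <- sort(clip_range(times, 0, u$T))
        if (length(times) > 1) times <- times[c(TRUE, diff(times) > 1e-9)]
        spike_train(times, T = u$T)
      })
      trial_set(trains)
    })
    half <- floor(n_stimuli / 2)
    structure(list(stimuli = stimuli, responses = responses, truth = truth,
                   train_idx = seq_len(half),
                   validation_idx = (half + 1):n_stimuli, seed = seed),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  if (!is.null(x$stimuli))
    cat(sprintf("<synthetic_dataset> auditory: %d stimuli x %d trials\n",
                length(x$stimuli), n_trials(x$responses[[1]])))
  else
    cat(sprintf("<synthetic_dataset> current injection: %d spikes over %g ms\n",
                n_spikes(x$spikes), x$spikes$T))
  invisible(x)
}
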