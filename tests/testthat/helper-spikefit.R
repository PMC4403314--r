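# shared fixtures and independent oracles, built in code

rand_train <- function(n, T, min_gap = 1e-6) {
  times <- sort(stats::runif(n, 0, T))
  if (n > 1) {
    keep <- c(TRUE, diff(times) > min_gap)
    times <- times[keep]
  }
  spike_train(times, T = T)
}

# independent numeric-integration oracle for the van Rossum distance:
# evaluate both filtered functions on a dense grid (augmented with the spike
# times, where the functions jump) and integrate the squared difference with
# the trapezoid rule on the non-uniform grid.  Just after each spike the
# left-limit value is used on the left edge of the subinterval.
vr_numeric_oracle <- function(u, v, tau, dt = 0.01, tail_tau = 30) {
  ev <- sort(unique(c(u$times, v$times)))
  Tmax <- max(c(ev, 0)) + tail_tau * tau
  tt <- sort(unique(c(seq(0, Tmax, by = dt), ev, ev - 1e-12)))
  eval_grid <- function(times) {
    f <- numeric(length(tt))
    acc <- 0; si <- 1; tprev <- tt[1]
    for (k in seq_along(tt)) {
      if (k > 1) { acc <- acc * exp(-(tt[k] - tprev) / tau); tprev <- tt[k] }
      while (si <= length(times) && times[si] <= tt[k] + 1e-15) {
        acc <- acc + exp(-(tt[k] - times[si]) / tau)
        si <- si + 1
      }
      f[k] <- acc
    }
    f * sqrt(2 / tau)
  }
  d2 <- (eval_grid(u$times) - eval_grid(v$times))^2
  h <- diff(tt)
  sqrt(sum((d2[-1] + d2[-length(d2)]) / 2 * h))
}

# brute-force filtered-function evaluation (direct sum over kernels)
filtered_eval_oracle <- function(times, weights, tau, kappa, t) {
  vapply(t, function(tt) {
    d <- tt - times
    live <- d >= 0
    sum(weights[live] * kappa * exp(-d[live] / tau))
  }, numeric(1))
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), .Machine$double.eps), tol)
}
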