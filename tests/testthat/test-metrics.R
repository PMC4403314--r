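test_that("van Rossum distance honours the metric identities", {
  set.seed(3)
  for (k in 1:10) {
    u <- rand_train(sample(0:30, 1), 1000)
    expect_equal(van_rossum_distance(u, u, tau = runif(1, 1, 100)), 0)
  }
  # one spike vs empty is exactly 1 under the unit normalization, any tau/t0
  for (t0 in c(0, 17.3, 999)) for (tau in c(1, 10, 250)) {
    expect_equal(van_rossum_distance(spike_train(t0, 1000),
                                     spike_train(numeric(0), 1000), tau), 1,
                 tolerance = 1e-12)
  }
  # closed form for two single-spike trains 5 ms apart at tau = 10
  expect_equal(van_rossum_distance(spike_train(0, 100), spike_train(5, 100), 10),
               sqrt(2 - 2 * exp(-0.5)), tolerance = 1e-12)
  expect_error(van_rossum_distance(spike_train(0, 10), spike_train(1, 10), -1), "tau")
})

test_that("efficient and brute-force van Rossum agree to 1e-10", {
  set.seed(4)
  for (k in 1:100) {
    u <- rand_train(sample(1:200, 1), 2000)
    v <- rand_train(sample(1:200, 1), 2000)
    tau <- runif(1, 1, 200)
    de <- van_rossum_distance(u, v, tau, method = "efficient")
    db <- van_rossum_distance(u, v, tau, method = "brute")
    expect_rel_equal(de, db, 1e-10)
  }
})

test_that("both van Rossum algorithms match dense numerical integration", {
  set.seed(5)
  for (k in 1:10) {
    u <- rand_train(sample(3:40, 1), 500)
    v <- rand_train(sample(3:40, 1), 500)
    tau <- runif(1, 5, 50)
    dn <- vr_numeric_oracle(u, v, tau)
    expect_rel_equal(van_rossum_distance(u, v, tau, "efficient"), dn, 1e-6)
    expect_rel_equal(van_rossum_distance(u, v, tau, "brute"), dn, 1e-6)
  }
})

test_that("van Rossum satisfies metric axioms on random triples", {
  set.seed(6)
  for (k in 1:200) {
    tau <- runif(1, 2, 50)
    a <- rand_train(sample(0:15, 1), 300)
    b <- rand_train(sample(0:15, 1), 300)
    c <- rand_train(sample(0:15, 1), 300)
    dab <- van_rossum_distance(a, b, tau)
    dba <- van_rossum_distance(b, a, tau)
    dac <- van_rossum_distance(a, c, tau)
    dcb <- van_rossum_distance(c, b, tau)
    expect_gte(dab, 0)
    expect_equal(dab, dba, tolerance = 1e-12)
    expect_lte(dab, dac + dcb + 1e-10)
  }
})

test_that("distance between fixed single-spike trains shrinks as tau grows", {
  u <- spike_train(100, 1000); v <- spike_train(130, 1000)
  d <- vapply(c(5, 10, 20, 50, 100, 400), function(tau)
    van_rossum_distance(u, v, tau), numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("van Rossum to a filtered function reduces to the quadratic form", {
  set.seed(7)
  tau <- 15
  u <- rand_train(12, 400)
  expect_lt(van_rossum_to_function(u, filter_train(u, tau)), 1e-5)
  expect_lt(van_rossum_to_function(u, average_function(trial_set(list(u, u)), tau)),
            1e-5)

  a <- rand_train(10, 400); b <- rand_train(14, 400)
  g <- average_function(trial_set(list(a, b)), tau)
  expect_equal(van_rossum_to_function(a, g),
               van_rossum_distance(a, b, tau) / 2, tolerance = 1e-10)

  # mismatched tau is refused
  expect_error(van_rossum_to_function(u, filter_train(u, tau), tau = tau + 1),
               "mismatch")

  # the numeric branch agrees with the analytic one
  fb <- filter_train(b, tau)
  dn <- van_rossum_to_function(a, function(t) evaluate_filtered(fb, t), tau = tau)
  expect_equal(dn, van_rossum_distance(a, b, tau), tolerance = 1e-5)
})

test_that("coincidence factor is 1 on self, and exact on degenerate cases", {
  set.seed(8)
  for (k in 1:10) {
    u <- rand_train(sample(5:60, 1), 2000)
    expect_equal(coincidence_factor(u, u, delta = 2)$gamma, 1, tolerance = 1e-12)
  }
  # empty model train: gamma = -4 delta f / (1 - 2 delta f)
  targ <- rand_train(40, 2000)
  f <- 40 / 2000; delta <- 2
  g <- coincidence_factor(spike_train(numeric(0), 2000), targ, delta)
  expect_equal(g$gamma, -4 * delta * f / (1 - 2 * delta * f), tolerance = 1e-12)
  expect_equal(g$n_c, 0)

  # two empty trains agree by convention
  e <- spike_train(numeric(0), 100)
  expect_equal(coincidence_factor(e, e, 2)$gamma, 1)
  # empty target alone is undefined
  expect_error(coincidence_factor(targ, e, 2), "N_e")
  # inadmissible window
  expect_error(coincidence_factor(targ, targ, delta = 30), ">= 1")
  # the counter never exceeds either train and gamma never exceeds 1
  for (k in 1:20) {
    m <- rand_train(sample(1:50, 1), 1000); t <- rand_train(sample(1:50, 1), 1000)
    res <- coincidence_factor(m, t, 2)
    expect_lte(res$n_c, min(res$n_e, res$n_m))
    expect_lte(res$gamma, 1 + 1e-12)
  }
})

test_that("a Poisson model at the target rate scores chance level (Gamma ~ 0)", {
  set.seed(9)
  targ <- rand_train(20, 2000)
  rate <- sampled_trace(rep(20 / 2000, 201), dt = 10)
  g <- vapply(1:300, function(k) {
    m <- generate_poisson_train(rate, seed = 1000 + k)
    coincidence_factor(m, targ, 2)$gamma
  }, numeric(1))
  # allow the small O((2 delta f)^2) bias of one-to-one matching
  expect_lt(abs(mean(g)), 3 * sd(g) / sqrt(length(g)) + (2 * 2 * 0.01)^2)
})

test_that("intrinsic reliability separates jittered from independent trials", {
  u <- rand_train(30, 2000)
  copies <- trial_set(lapply(1:4, function(i) u))
  rel <- intrinsic_reliability(copies, delta = 2, tau = 10)
  expect_equal(rel$gamma_i, 1, tolerance = 1e-12)
  expect_equal(rel$cluster_size, 0, tolerance = 1e-12)

  # two trials: the mean of the two directed values
  a <- rand_train(20, 2000); b <- rand_train(25, 2000)
  rel2 <- intrinsic_reliability(trial_set(list(a, b)), delta = 2, tau = 10)
  expect_equal(rel2$gamma_i,
               mean(c(coincidence_factor(a, b, 2)$gamma,
                      coincidence_factor(b, a, 2)$gamma)), tolerance = 1e-12)
  expect_error(intrinsic_reliability(trial_set(list(a)), 2), "2 trials")

  # jittered copies are more reliable than independent Poisson trains
  set.seed(10)
  jit <- trial_set(lapply(1:5, function(i)
    spike_train(sort(pmin(pmax(u$times + rnorm(30, 0, 1), 0), 2000)), 2000)))
  rate <- sampled_trace(rep(30 / 2000, 201), dt = 10)
  poi <- trial_set(lapply(1:5, function(i) generate_poisson_train(rate, seed = 60 + i)))
  expect_gt(intrinsic_reliability(jit, 2)$gamma_i,
            intrinsic_reliability(poi, 2)$gamma_i)

  # performance factor when a model train is supplied
  relm <- intrinsic_reliability(jit, 2, model = u)
  expect_equal(relm$gamma_a, relm$gamma_model / relm$gamma_i)
})

test_that("expected Poisson coincidence matches its analytic limits", {
  targ <- rand_train(30, 2000)
  f <- 30 / 2000; delta <- 2

  zero <- sampled_trace(rep(0, 201), dt = 10)
  g0 <- expected_coincidence_poisson(zero, targ, delta, n_mc = 10, seed = 1)
  expect_equal(as.numeric(g0), -4 * delta * f / (1 - 2 * delta * f),
               tolerance = 1e-12)

  # narrow unit-area rate bumps at the target's spikes approach the Poisson
  # ceiling: with bump area a, <N_c> = N_e (1 - e^-a) while <N_m> = a N_e,
  # so the expectation peaks near 2(1 - e^-1)/2 ~ 0.63 at a ~ 1 — far above
  # chance, but a Poisson process cannot reach a perfect match
  dt <- 0.1
  tt <- seq(0, 2000, by = dt)
  rv <- numeric(length(tt))
  rv[round(targ$times / dt) + 1] <- 10 # triangular bump, area ~1 per spike
  bump <- sampled_trace(rv, dt = dt)
  g1 <- expected_coincidence_poisson(bump, targ, delta, n_mc = 100, seed = 2)
  expect_gt(as.numeric(g1), 0.5)

  # doubling the Monte Carlo size moves the estimate by < 3 SE
  rate <- sampled_trace(rep(f, 201), dt = 10)
  ga <- expected_coincidence_poisson(rate, targ, delta, n_mc = 100, seed = 3)
  gb <- expected_coincidence_poisson(rate, targ, delta, n_mc = 200, seed = 4)
  se <- sqrt(attr(ga, "se")^2 + attr(gb, "se")^2)
  expect_lt(abs(as.numeric(ga) - as.numeric(gb)), 3 * se + 1e-9)

  expect_error(expected_coincidence_poisson(sampled_trace(c(-1, 0), 1), targ, 2),
               "non-negative")
})

test_that("expected Poisson van Rossum distance matches limits and bounds", {
  set.seed(12)
  u <- rand_train(15, 1000)
  tau <- 10
  zero <- sampled_trace(rep(0, 60001), dt = 0.02)
  # with zero rate the expression is the norm of the filtered train (the
  # grid quadrature carries O(dt) error at the spike discontinuities)
  expect_equal(expected_van_rossum_poisson(zero, u, tau),
               van_rossum_distance(u, spike_train(numeric(0), 1000), tau),
               tolerance = 1e-3)
  # empty train and zero rate -> 0
  expect_equal(expected_van_rossum_poisson(zero, spike_train(numeric(0), 1000), tau), 0)

  # the distance of expectations is below the Monte Carlo expected distance
  rate <- sampled_trace(rep(15 / 1000, 10001), dt = 0.1)
  v <- expected_van_rossum_poisson(rate, u, tau)
  mc <- mean(vapply(1:200, function(k)
    van_rossum_distance(generate_poisson_train(rate, seed = 300 + k), u, tau),
    numeric(1)))
  expect_lte(v, mc)
})
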