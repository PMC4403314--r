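test_that("the annealed timescale schedule interpolates geometrically", {
  expect_equal(tau_schedule(0, 200, 1000, 10), 1000)
  expect_equal(tau_schedule(200, 200, 1000, 10), 10)
  expect_equal(tau_schedule(100, 200, 1000, 10), 100) # geometric midpoint
  sched <- vapply(0:50, function(i) tau_schedule(i, 50, 500, 20), numeric(1))
  expect_true(all(diff(sched) < 0))
  expect_error(tau_schedule(1, 10, 5, 10), "tau_start")
})

test_that("the mutation-scale schedule decays from 0.2 to 0.01", {
  expect_equal(epsilon_schedule(0, 100), 0.2)
  expect_equal(epsilon_schedule(100, 100), 0.01)
  eps <- vapply(0:100, function(i) epsilon_schedule(i, 100), numeric(1))
  expect_true(all(diff(eps) < 0))
})

test_that("roulette selection prefers low fitness and degrades to uniform", {
  set.seed(31)
  # fitness {0, 1}: the better gene dominates as eta -> 0
  idx <- select_roulette(c(0, 1), n = 2000)
  expect_gt(mean(idx == 1), 0.99)

  # all-equal fitness: uniform within 3 SE
  idx <- select_roulette(rep(2.5, 4), n = 10000)
  freq <- tabulate(idx, 4) / 10000
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freq - 0.25) < 3 * se))

  # selection frequency is non-increasing in fitness value
  fit <- c(0.1, 0.5, 1.0, 2.0)
  idx <- select_roulette(fit, n = 20000)
  freq <- tabulate(idx, 4)
  expect_true(all(diff(freq) <= 0))
})

test_that("crossover operators combine parents as defined", {
  set.seed(32)
  x <- c(a = 1, b = 2, c = 3)
  y <- c(a = 10, b = 20, c = 30)
  expect_equal(crossover_genes(x, x, "uniform"), x)
  expect_equal(crossover_genes(x, x, "arithmetic"), x)

  # uniform: every child coordinate is copied from one parent, each with
  # empirical frequency 1/2
  for (k in 1:50) {
    ch <- crossover_genes(x, y, "uniform")
    expect_true(all(ch == x | ch == y))
  }
  inherit1 <- replicate(10000, crossover_genes(x, y, "uniform")["a"] == 1)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(inherit1) - 0.5), 3 * se)

  # arithmetic: children lie on the segment between the parents, with the
  # same mixing weight on every coordinate (mean weight 1/2)
  u_obs <- replicate(5000, {
    ch <- crossover_genes(x, y, "arithmetic")
    w <- (ch - y) / (x - y)
    expect_true(all(w >= -1e-12 & w <= 1 + 1e-12))
    expect_lt(diff(range(w)), 1e-12)
    w[1]
  })
  expect_lt(abs(mean(u_obs) - 0.5), 3 * sd(u_obs) / sqrt(5000))

  expect_error(crossover_genes(x, c(a = 1, b = 2)), "layout")
})

test_that("mutation rescales exactly one coordinate with zero-mean factor", {
  set.seed(33)
  x <- c(p = 4, q = -8, r = 0.5)
  for (k in 1:50) {
    m <- mutate_gene(x, eps_m = 0.2)
    expect_equal(sum(m != x), 1)
  }
  # E[mutated coordinate] equals the original (r has mean zero)
  vals <- replicate(10000, mutate_gene(c(p = 4), eps_m = 0.04))
  se <- 4 * sqrt(0.04) / sqrt(10000)
  expect_lt(abs(mean(vals) - 4), 3 * se)
  # vanishing scale leaves the gene essentially unchanged
  m <- mutate_gene(x, eps_m = 1e-18)
  expect_equal(m, x, tolerance = 1e-6)
  # clipping keeps the result inside the feasible region
  rng <- rbind(low = c(3, -9, 0.1), high = c(5, -7, 1))
  for (k in 1:100) {
    m <- mutate_gene(x, eps_m = 5, ranges = rng)
    expect_true(all(m >= rng[1, ] & m <= rng[2, ]))
  }
  expect_error(mutate_gene(x, eps_m = 0), "eps_m")
})

test_that("generation turnover keeps elites and breeds the rest", {
  set.seed(34)
  # toy fitness: distance of the gene from a known optimum
  opt <- c(2, -3, 5)
  evalf <- function(g) apply(g, 1, function(x) sum((x - opt)^2))
  rng <- rbind(low = c(-10, -10, -10), high = c(10, 10, 10))
  genes <- matrix(runif(30 * 3, -10, 10), 30)
  pop <- list(genes = genes, fitness = evalf(genes), generation = 0L)

  # full elitism: the next generation is the current one re-ranked
  cfg_all <- ga_config(population = 30, elites = 30, seed = 1)
  nxt <- evolve_generation(pop, evalf, cfg_all, eps_m = 0.1, ranges = rng)
  expect_equal(sort(nxt$fitness), sort(pop$fitness))

  # elitism keeps the best fitness non-increasing at fixed evaluation
  cfg <- ga_config(population = 30, elites = 3, seed = 1)
  best <- min(pop$fitness)
  for (i in 1:25) {
    pop <- evolve_generation(pop, evalf, cfg, eps_m = 0.1, ranges = rng)
    expect_lte(min(pop$fitness), best + 1e-12)
    best <- min(pop$fitness)
  }

  # with (effectively) no mutation and uniform crossover, all children are
  # coordinate mixtures of current members
  cfg0 <- ga_config(population = 20, elites = 1, mutation_prob = 1e-12,
                    crossover = "uniform", seed = 2)
  genes <- matrix(runif(20 * 3, -10, 10), 20)
  pop0 <- list(genes = genes, fitness = evalf(genes), generation = 0L)
  nxt <- evolve_generation(pop0, evalf, cfg0, eps_m = 0.1, ranges = rng)
  for (r in 2:20) {
    child <- nxt$genes[r, ]
    from_parent <- vapply(seq_len(3), function(j)
      any(abs(genes[, j] - child[j]) < 1e-12), logical(1))
    expect_true(all(from_parent))
  }
  # with arithmetic crossover, children stay inside the population's box
  cfga <- ga_config(population = 20, elites = 1, mutation_prob = 1e-12,
                    crossover = "arithmetic", seed = 3)
  nxa <- evolve_generation(pop0, evalf, cfga, eps_m = 0.1, ranges = rng)
  for (j in 1:3) {
    expect_true(all(nxa$genes[, j] >= min(genes[, j]) - 1e-12))
    expect_true(all(nxa$genes[, j] <= max(genes[, j]) + 1e-12))
  }
})

test_that("ga_config rejects inadmissible settings", {
  expect_error(ga_config(population = 10, elites = 0), "elites")
  expect_error(ga_config(population = 10, elites = 11), "elites")
  expect_error(ga_config(mutation_prob = 0), "mutation_prob")
  expect_error(ga_config(mutation_prob = 1), "mutation_prob")
})

test_that("fit_neuron keeps a seeded exact solution and drives the distance to ~0", {
  ds <- make_table2_dataset(seed = 301, duration = 1600)
  truth <- c(tau_m = 10, tau_w = 144, b = 0.001, V_T = -50, E_L = -70,
             alpha = 1, Delta_T = 2)
  fit <- fit_neuron(ds$train$spikes, ds$train$current, model = "aEIF",
                    ranges = table2_ranges(),
                    config = ga_config(population = 20, max_generations = 15, seed = 9),
                    fixed = list(R = 1, V_c = 0), ties = list(V_r = "E_L"),
                    init_genes = matrix(truth, nrow = 1))
  expect_lt(fit$best_fitness, 1e-9)
  expect_equal(unname(fit$best_gene), unname(truth))
  # elitism: best training distance never increases at fixed tau endpoints
  expect_true(all(is.finite(fit$history$best_d)))
})

test_that("fit_neuron reproduces bit-identically from (seed, config)", {
  ds <- make_table2_dataset(seed = 302, duration = 1200)
  cfg <- ga_config(population = 12, max_generations = 8, seed = 77)
  f1 <- fit_neuron(ds$train$spikes, ds$train$current, "aEIF", table2_ranges(),
                   config = cfg, fixed = list(R = 1, V_c = 0), ties = list(V_r = "E_L"))
  f2 <- fit_neuron(ds$train$spikes, ds$train$current, "aEIF", table2_ranges(),
                   config = cfg, fixed = list(R = 1, V_c = 0), ties = list(V_r = "E_L"))
  expect_identical(f1$best_gene, f2$best_gene)
  expect_identical(f1$history$best_d, f2$history$best_d)
})

test_that("all genes remain inside the feasible region during a fit", {
  ds <- make_table2_dataset(seed = 303, duration = 1200)
  rng <- table2_ranges()
  fit <- fit_neuron(ds$train$spikes, ds$train$current, "aEIF", rng,
                    config = ga_config(population = 15, max_generations = 10, seed = 5),
                    fixed = list(R = 1, V_c = 0), ties = list(V_r = "E_L"))
  g <- fit$population$genes
  for (nm in names(rng))
    expect_true(all(g[, nm] >= rng[[nm]][1] & g[, nm] <= rng[[nm]][2]))
})
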