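#' Genetic-algorithm configuration
#'
#' @param population population size `N` (default 240).
#' @param elites elite count `k`: the fittest `k` genes are copied unchanged
#'   into the next generation (default 5% of the population).
#' @param mutation_prob probability that a non-elite child undergoes
#'   mutation (default 0.05).
#' @param eps_m0 initial mutation scale: the mutation rescales one
#'   coordinate by `1 + r` with `r ~ Normal(0, eps_m)` — `eps_m` is a
#'   *variance* (default 0.2).
#' @param eps_min final mutation scale of the geometric decay (default
#'   0.01).
#' @param max_generations maximum number of generations (default 200).
#' @param eps_stop stop early when the best validation van Rossum distance
#'   falls below this value (0 disables early stopping).
#' @param tau_start,tau_end fitness-timescale schedule endpoints in ms;
#'   when `NULL`, [fit_neuron()] uses half the training duration and the
#'   target's mean inter-spike interval respectively.  Setting both to the
#'   same value gives a fixed timescale.
#' @param validation_delta coincidence window (ms) used when tracking the
#'   validation coincidence factor (default 0.5).
#' @param crossover crossover operator, `"arithmetic"` (default) or
#'   `"uniform"`; see [crossover_genes()].
#' @param seed RNG seed; the full run is reproducible from `(seed, config)`.
#' @return a list of class `ga_config`.
#' @export
ga_config <- function(population = 240, elites = max(1L, ceiling(0.05 * population)),
                      mutation_prob = 0.05, eps_m0 = 0.2, eps_min = 0.01,
                      max_generations = 200, eps_stop = 0,
                      tau_start = NULL, tau_end = NULL,
                      validation_delta = 0.5,
                      crossover = c("arithmetic", "uniform"), seed = 1) {
  if (elites < 1 || elites > population) stopf("need 1 <= elites <= population")
  if (mutation_prob <= 0 || mutation_prob >= 1) stopf("need 0 < mutation_prob < 1")
  structure(list(population = as.integer(population), elites = as.integer(elites),
                 mutation_prob = mutation_prob, eps_m0 = eps_m0, eps_min = eps_min,
                 max_generations = as.integer(max_generations), eps_stop = eps_stop,
                 tau_start = tau_start, tau_end = tau_end,
                 validation_delta = validation_delta,
                 crossover = match.arg(crossover), seed = seed),
            class = "ga_config")
}

#' Annealed fitness-timescale schedule
#'
#' Geometric interpolation from `tau_start` at generation 0 to `tau_end` at
#' generation `N`: the decrement in `tau` is logarithmic with the base set
#' by the maximum number of generations.
#'
#' @param i generation index, `0 <= i <= N`.
#' @param N maximum number of generations.
#' @param tau_start,tau_end schedule endpoints in ms, `tau_start >= tau_end > 0`.
#' @return `tau_i` in ms.
#' @export
tau_schedule <- function(i, N, tau_start, tau_end) {
  if (tau_end <= 0 || tau_start < tau_end) stopf("need tau_start >= tau_end > 0")
  tau_start * (tau_end / tau_start)^(i / N)
}

#' Decaying mutation-scale schedule
#'
#' Geometric decay of the mutation variance from `eps_m0` to `eps_min`
#' across the run, so the search is wide early and fine late.
#'
#' @inheritParams tau_schedule
#' @param eps_m0 initial mutation variance (default 0.2).
#' @param eps_min final mutation variance (default 0.01).
#' @return `eps_m(i)`.
#' @export
epsilon_schedule <- function(i, N, eps_m0 = 0.2, eps_min = 0.01) {
  eps_m0 * (eps_min / eps_m0)^(i / N)
}

# selection weights for fitness minimization: w_j = (max - fit_j) + eta
roulette_weights <- function(fitness) {
  rng <- max(fitness) - min(fitness)
  w <- (max(fitness) - fitness) + 1e-6 * rng
  if (all(w <= 0) || rng == 0) w <- rep(1, length(fitness))
  w
}

#' Roulette-wheel selection
#'
#' Selects gene indices with probability proportional to `(max_fit - fit) +
#' eta` (fitness is a distance, minimized; the floor `eta = 1e-6 * range`
#' keeps the worst gene selectable).  All-equal fitnesses give uniform
#' selection.
#'
#' @param fitness numeric vector of fitness values (lower is better).
#' @param n number of draws.
#' @return integer vector of selected indices.
#' @export
select_roulette <- function(fitness, n = 1) {
  w <- roulette_weights(fitness)
  sample.int(length(fitness), n, replace = TRUE, prob = w)
}

#' Crossover of two real-valued genes
#'
#' Two standard real-coded operators: `"arithmetic"` (the default) draws one
#' `u ~ U(0, 1)` per child and returns the convex combination
#' `u*x1 + (1-u)*x2`, which can travel along correlated valleys of the
#' fitness landscape; `"uniform"` copies each coordinate from either parent
#' with probability 1/2.  Children of feasible parents are feasible for
#' both (the feasible region is a box).
#'
#' @param x1,x2 named numeric genes of equal layout.
#' @param method `"arithmetic"` or `"uniform"`.
#' @return child gene.
#' @export
crossover_genes <- function(x1, x2, method = c("arithmetic", "uniform")) {
  method <- match.arg(method)
  if (length(x1) != length(x2) || !identical(names(x1), names(x2)))
    stopf("crossover requires genes with identical layout")
  out <- if (method == "arithmetic") {
    u <- runif(1)
    u * x1 + (1 - u) * x2
  } else {
    pick <- runif(length(x1)) < 0.5
    ifelse(pick, x1, x2)
  }
  names(out) <- names(x1)
  out
}

#' Non-uniform mutation of a gene
#'
#' Rescales exactly one uniformly chosen coordinate by `1 + r` with
#' `r ~ Normal(0, eps_m)` (`eps_m` is the variance), then clips the result
#' to the feasible region.
#'
#' @param x named numeric gene.
#' @param eps_m mutation variance (> 0).
#' @param ranges 2-row matrix (rows `low`, `high`) with one column per
#'   coordinate, or `NULL` for no clipping.
#' @return mutated gene.
#' @export
mutate_gene <- function(x, eps_m, ranges = NULL) {
  if (eps_m <= 0) stopf("eps_m must be > 0")
  j <- sample.int(length(x), 1)
  x[j] <- x[j] * (1 + rnorm(1, 0, sqrt(eps_m)))
  if (!is.null(ranges)) x[j] <- clip_range(x[j], ranges[1, j], ranges[2, j])
  x
}

ranges_matrix <- function(ranges) {
  m <- vapply(ranges, function(r) {
    if (length(r) != 2 || r[1] >= r[2]) stopf("each range must be c(low, high) with low < high")
    as.numeric(r)
  }, numeric(2))
  rownames(m) <- c("low", "high")
  m
}

#' Produce the next GA generation
#'
#' The fittest `k` genes are copied unchanged (elitism; ties broken by gene
#' index), the remaining `N - k` are children of roulette-selected parents
#' combined by uniform crossover; each non-elite child is then mutated
#' independently with the configured probability, and all fitnesses are
#' re-evaluated at the generation's timescale.
#'
#' @param pop list with `genes` (N x p matrix) and `fitness` (length N).
#' @param evaluate function `(genes_matrix) -> fitness vector` for the new
#'   generation (already bound to the generation's `tau_i`).
#' @param config a [ga_config()].
#' @param eps_m mutation variance for this generation.
#' @param ranges 2-row feasible-region matrix (see [mutate_gene()]).
#' @return the next population (same structure, `generation` incremented).
#' @export
evolve_generation <- function(pop, evaluate, config, eps_m, ranges = NULL) {
  N <- nrow(pop$genes)
  k <- min(config$elites, N)
  ord <- order(pop$fitness) # stable: ties broken by index
  elite_idx <- ord[seq_len(k)]
  newg <- pop$genes
  newg[seq_len(k), ] <- pop$genes[elite_idx, , drop = FALSE]
  n_child <- N - k
  if (n_child > 0) {
    parents <- matrix(select_roulette(pop$fitness, 2 * n_child), ncol = 2)
    xover <- config$crossover %||% "arithmetic"
    for (c in seq_len(n_child)) {
      child <- crossover_genes(pop$genes[parents[c, 1], ],
                               pop$genes[parents[c, 2], ], method = xover)
      if (runif(1) < config$mutation_prob)
        child <- mutate_gene(child, eps_m, ranges)
      newg[k + c, ] <- child
    }
  }
  list(genes = newg, fitness = evaluate(newg), generation = pop$generation + 1L)
}

# build a full parameter_set from a gene vector + fixed values + ties
gene_to_params <- function(gene, model, fixed = list(), ties = NULL) {
  vals <- as.list(gene)
  for (nm in names(fixed)) vals[[nm]] <- fixed[[nm]]
  if (!is.null(ties)) for (nm in names(ties)) vals[[nm]] <- vals[[ties[[nm]]]]
  do.call(parameter_set, c(list(model = model), vals))
}

# fast inner-loop path: canonical parameter vector without constructor
# validation (the feasible region already guarantees validity)
gene_vector_template <- function(model, fixed = list(), ties = NULL) {
  ps <- do.call(parameter_set, c(list(model = model), fixed))
  list(values = ps$values, code = model_code(model), ties = ties)
}

gene_fill <- function(tmpl, gene) {
  v <- tmpl$values
  v[names(gene)] <- gene
  if (!is.null(tmpl$ties))
    for (nm in names(tmpl$ties)) v[nm] <- v[tmpl$ties[[nm]]]
  v
}

#' Fit a spiking neuron model to a target spike train
#'
#' The end-to-end evolutionary loop: a population of parameter genes is
#' initialized uniformly inside the feasible region, and each generation is
#' produced by elitism, roulette selection, uniform crossover, and
#' non-uniform decaying mutation ([evolve_generation()]).  Fitness is the
#' van Rossum distance between the simulated and target spike trains,
#' evaluated at the annealed timescale [tau_schedule()] of the current
#' generation (all members of a generation, elites included, are scored at
#' the same `tau_i`).  The best gene of the final generation — scored at
#' `tau_end` — is returned together with the full convergence history.
#'
#' @param target a [spike_train()] (training target), or a
#'   `filtered_function` average target.
#' @param current training input current, a [sampled_trace()].
#' @param model model kind (see [parameter_set()]).
#' @param ranges named list of `c(low, high)` feasible intervals, one per
#'   free gene coordinate.
#' @param config a [ga_config()].
#' @param fixed named list of parameters fixed at given values.
#' @param ties named character list tying parameters to gene coordinates,
#'   e.g. `list(V_r = "E_L")`.
#' @param validation optional list with elements `train` (a
#'   [spike_train()]) and `current` (a [sampled_trace()]); when given, the
#'   best gene's coincidence factor on the validation pair is tracked each
#'   generation.
#' @param dt integration step in ms.
#' @param init_genes optional matrix of genes injected into the initial
#'   population (rows replace the first uniform draws; used e.g. to seed a
#'   known solution).
#' @param map a `lapply`-like function used to evaluate the population
#'   (pluggable parallel map; the sequential default keeps runs
#'   deterministic).
#' @return an object of class `neuron_fit`: list with `best_params`
#'   (a [parameter_set()]), `best_gene`, `best_fitness`, `history`
#'   (data.frame: generation, tau_ms, eps_m, best_d, mean_d,
#'   best_gamma_validation), `config`.
#' @export
fit_neuron <- function(target, current, model, ranges, config = ga_config(),
                       fixed = list(), ties = NULL, validation = NULL,
                       dt = 0.1, init_genes = NULL, map = lapply) {
  stopifnot(inherits(current, "sampled_trace"))
  rmat <- ranges_matrix(ranges)
  p <- ncol(rmat)
  pnames <- names(ranges)
  colnames(rmat) <- pnames
  N <- config$population
  Ngen <- config$max_generations

  T_train <- length(current$values) * current$dt
  tau_start <- config$tau_start %||% (T_train / 2)
  tau_end <- config$tau_end
  if (is.null(tau_end)) {
    if (!is_spike_train(target) || n_spikes(target) < 2)
      stopf("tau_end must be given when the target has fewer than 2 spikes")
    tau_end <- mean_isi_and_rate(target)$mean_isi
  }

  tmpl <- gene_vector_template(model, fixed, ties)
  cvals <- current$values; cdt <- current$dt
  fitness_at <- function(genes, tau_i) {
    tgt <- if (is_spike_train(target)) target$times else target$times
    tw <- if (is_spike_train(target)) rep(1, length(tgt)) else target$weights
    unlist(map(seq_len(nrow(genes)), function(r) {
      pv <- gene_fill(tmpl, genes[r, ])
      st <- simulate_model_cpp(tmpl$code, unname(pv), cvals, cdt, dt,
                               FALSE, FALSE, 0)$spikes
      wu <- rep(1, length(st))
      base <- cross_sum(st, wu, st, wu, tau_i) +
        cross_sum(tgt, tw, tgt, tw, tau_i) -
        2 * cross_sum(st, wu, tgt, tw, tau_i)
      sqrt(max(0, base)) # kappa^2 * tau/2 = 1 under the default normalization
    }))
  }

  with_seed(config$seed, {
    genes <- matrix(runif(N * p, rmat[1, ], rmat[2, ]), nrow = N, byrow = TRUE,
                    dimnames = list(NULL, pnames))
    if (!is.null(init_genes)) {
      init_genes <- matrix(init_genes, ncol = p,
                           dimnames = list(NULL, pnames))
      ni <- min(nrow(init_genes), N)
      genes[seq_len(ni), ] <- init_genes[seq_len(ni), , drop = FALSE]
    }
    pop <- list(genes = genes, fitness = fitness_at(genes, tau_start),
                generation = 0L)
    hist_rows <- vector("list", Ngen + 1)
    track <- function(pop, tau_i, eps_i) {
      best <- which.min(pop$fitness)
      gam <- NA_real_; vd <- NA_real_
      if (!is.null(validation)) {
        ps <- gene_to_params(pop$genes[best, ], model, fixed, ties)
        uv <- simulate_neuron(ps, validation$current, dt = dt)$spikes
        gam <- tryCatch(coincidence_factor(uv, validation$train,
                                           config$validation_delta)$gamma,
                        error = function(e) NA_real_)
        vd <- van_rossum_distance(uv, validation$train, tau_end)
      }
      data.frame(generation = pop$generation, tau_ms = tau_i, eps_m = eps_i,
                 best_d = min(pop$fitness), mean_d = mean(pop$fitness),
                 best_gamma_validation = gam, best_d_validation = vd)
    }
    hist_rows[[1]] <- track(pop, tau_start, config$eps_m0)
    for (i in seq_len(Ngen)) {
      tau_i <- tau_schedule(i, Ngen, tau_start, tau_end)
      eps_i <- epsilon_schedule(i, Ngen, config$eps_m0, config$eps_min)
      pop <- evolve_generation(pop, function(g) fitness_at(g, tau_i),
                               config, eps_i, rmat)
      hist_rows[[i + 1]] <- track(pop, tau_i, eps_i)
      if (config$eps_stop > 0 &&
          isTRUE(hist_rows[[i + 1]]$best_d_validation < config$eps_stop)) break
    }
    history <- do.call(rbind, hist_rows[!vapply(hist_rows, is.null, logical(1))])
    best <- which.min(pop$fitness)
    structure(list(best_params = gene_to_params(pop$genes[best, ], model, fixed, ties),
                   best_gene = pop$genes[best, ],
                   best_fitness = pop$fitness[best],
                   population = pop, history = history, config = config,
                   tau_start = tau_start, tau_end = tau_end, model = model),
              class = "neuron_fit")
  })
}

#' @export
print.neuron_fit <- function(x, ...) {
  cat(sprintf("<neuron_fit> %s model, %d generations, best d = %.4f (tau_end = %.1f ms)\n",
              x$model, max(x$history$generation), x$best_fitness, x$tau_end))
  invisible(x)
}
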