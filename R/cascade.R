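#' STRF-to-neuron cascade genome
#'
#' The full in-vivo model: an L1-normalized STRF whose convolution with the
#' stimulus, scaled by `C`, is the estimated input current to an aEIF
#' neuron.  The scale `C` is optimized with the neuron genes, separating the
#' overall drive scale from the STRF shape.
#'
#' @param strf a [strf_kernel()] with unit L1 norm.
#' @param C drive scale constant.
#' @param neuron an aEIF [parameter_set()].
#' @return an object of class `cascade_genome`.
#' @export
cascade_genome <- function(strf, C, neuron) {
  stopifnot(inherits(strf, "strf"), inherits(neuron, "parameter_set"))
  if (abs(sum(abs(strf$values)) - 1) > 1e-6)
    stopf("cascade STRF must be L1-normalized")
  if (neuron$model != "aEIF")
    stopf("the cascade uses the aEIF neuron")
  structure(list(strf = strf, C = C, neuron = neuron), class = "cascade_genome")
}

#' @export
print.cascade_genome <- function(x, ...) {
  cat(sprintf("<cascade_genome> %dx%d STRF, C = %.4g, aEIF neuron\n",
              nrow(x$strf$values), ncol(x$strf$values), x$C))
  invisible(x)
}

#' Estimated input current of a cascade genome
#'
#' `I(t) = C * (h * s)(t)`: the STRF convolved with the stimulus, scaled.
#'
#' @param genome a [cascade_genome()].
#' @param s a [spectrogram()].
#' @return a [sampled_trace()].
#' @export
drive_current <- function(genome, s) {
  stopifnot(inherits(genome, "cascade_genome"))
  r <- predict_rate(genome$strf, s)
  sampled_trace(genome$C * r$values, dt = r$dt, t0 = 0, unit = "current")
}

#' Simulate the cascade model on a stimulus
#'
#' Deterministic: the drive current is fed to the aEIF neuron via
#' [simulate_neuron()].
#'
#' @param genome a [cascade_genome()].
#' @param s a [spectrogram()].
#' @param dt neuron integration step in ms.
#' @return a [spike_train()].
#' @export
simulate_cascade <- function(genome, s, dt = 0.1) {
  simulate_neuron(genome$neuron, drive_current(genome, s), dt = dt)$spikes
}

#' Patch mutation of an STRF
#'
#' Adds zero-mean Gaussian noise (sd = `scale * mean(|h|)`) to a randomly
#' chosen contiguous rectangular patch of at most 4 x 4 coefficients, then
#' re-normalizes to unit L1 norm.
#'
#' @param h a [strf_kernel()].
#' @param scale mutation scale (> 0).
#' @return a mutated, L1-normalized [strf_kernel()].
#' @export
mutate_strf <- function(h, scale) {
  stopifnot(inherits(h, "strf"))
  if (scale <= 0) stopf("scale must be > 0")
  v <- h$values
  M <- nrow(v); L <- ncol(v)
  a <- sample.int(min(4L, M), 1); b <- sample.int(min(4L, L), 1)
  r0 <- sample.int(M - a + 1L, 1); c0 <- sample.int(L - b + 1L, 1)
  rows <- r0:(r0 + a - 1); cols <- c0:(c0 + b - 1)
  v[rows, cols] <- v[rows, cols] + rnorm(a * b, 0, scale * mean(abs(v)))
  s <- sum(abs(v))
  if (s == 0) return(h)
  strf_kernel(v / s, lag_ms = h$lag_ms, band_edges = h$band_edges)
}

#' Uniform crossover of two STRFs
#'
#' Per-coefficient uniform mix of the parent kernels followed by L1
#' re-normalization.
#'
#' @param h1,h2 [strf_kernel()] objects of equal shape.
#' @return an L1-normalized child [strf_kernel()].
#' @export
crossover_strf <- function(h1, h2) {
  stopifnot(inherits(h1, "strf"), inherits(h2, "strf"),
            all(dim(h1$values) == dim(h2$values)))
  pick <- matrix(runif(length(h1$values)) < 0.5, nrow(h1$values))
  v <- ifelse(pick, h1$values, h2$values)
  s <- sum(abs(v))
  if (s == 0) v <- h1$values else v <- v / s
  strf_kernel(v, lag_ms = h1$lag_ms, band_edges = h1$band_edges)
}

#' Tandem-evolution configuration
#'
#' @param neuron_config [ga_config()] for the neuron-parameter population.
#' @param strf_config [ga_config()] for the STRF population.
#' @param phase_length generations per alternation between the two
#'   populations (default 50).
#' @param max_iterations total generation budget across both populations
#'   (default 600).
#' @param strf_mutation_scale mutation scale for [mutate_strf()] (default
#'   0.1).
#' @param seed master RNG seed.
#' @return a list of class `tandem_config`.
#' @export
tandem_config <- function(neuron_config = ga_config(population = 60, seed = 1),
                          strf_config = ga_config(population = 60, seed = 2),
                          phase_length = 50, max_iterations = 600,
                          strf_mutation_scale = 0.1, seed = 1) {
  if (phase_length < 1) stopf("phase_length must be >= 1")
  structure(list(neuron_config = neuron_config, strf_config = strf_config,
                 phase_length = as.integer(phase_length),
                 max_iterations = as.integer(max_iterations),
                 strf_mutation_scale = strf_mutation_scale, seed = seed),
            class = "tandem_config")
}

#' Fit an STRF-neuron cascade by tandem evolution
#'
#' Two populations — aEIF parameter genes (including the drive scale `C`)
#' and L1-normalized STRFs seeded as patch mutations of the
#' reverse-correlation initial estimate — are evolved in alternating phases
#' of `phase_length` generations.  During a neuron phase every gene is
#' evaluated against the current best STRF; during an STRF phase every
#' kernel is evaluated against the current best neuron gene.  The fitness
#' of a candidate is the sum over training stimuli of the van Rossum
#' distance between its simulated train and the stimulus's average filtered
#' function, with the timescale annealing per stimulus from half the
#' stimulus duration down to the mean inter-spike interval of its trials.
#' The best-ever combined genome, scored at the final timescales, is
#' tracked across phases and returned.
#'
#' @param stimuli list of [spectrogram()] training stimuli.
#' @param responses list of [trial_set()] responses, aligned with `stimuli`.
#' @param init_strf initial STRF (typically from [estimate_strf()]).
#' @param ranges named list of feasible intervals for the neuron gene; must
#'   include an entry `"C"` for the drive scale.
#' @param config a [tandem_config()].
#' @param fixed named list of aEIF parameters fixed at given values.
#' @param ties optional parameter ties (see [fit_neuron()]).
#' @param validation optional list with `stimuli` and `responses` used to
#'   track the validation coincidence factor (delta = 2 ms) of the best
#'   genome at each phase boundary.
#' @param dt neuron integration step in ms.
#' @param average one of `"mean"` or `"sum"`: how the per-stimulus target
#'   function aggregates trials.
#' @return an object of class `cascade_fit`: list with `best_genome`,
#'   `best_fitness`, `history` (one row per generation), `config`.
#' @export
tandem_fit <- function(stimuli, responses, init_strf, ranges,
                       config = tandem_config(), fixed = list(), ties = NULL,
                       validation = NULL, dt = 0.1,
                       average = c("mean", "sum")) {
  average <- match.arg(average)
  if (length(stimuli) == 0) stopf("empty training set")
  stopifnot(length(stimuli) == length(responses))
  ns <- length(stimuli)
  if (!"C" %in% names(ranges)) stopf("ranges must include the drive scale C")

  # per-stimulus target spike mass and timescale schedule endpoints
  targ <- lapply(seq_len(ns), function(i) {
    tr <- responses[[i]]
    times <- unlist(lapply(tr$trains, function(u) u$times))
    o <- order(times)
    w <- if (average == "mean") rep(1 / n_trials(tr), length(times)) else rep(1, length(times))
    pooled <- sort(times)
    isi <- if (length(pooled) >= 2) mean(diff(pooled)) * n_trials(tr) else tr$T / 4
    list(times = times[o], weights = w[o],
         tau_start = tr$T / 2, tau_end = max(1, min(isi, tr$T / 2)))
  })

  rmat <- ranges_matrix(ranges)
  pnames <- names(ranges)
  colnames(rmat) <- pnames
  ncfg <- config$neuron_config
  scfg <- config$strf_config
  Ntot <- config$max_iterations

  taus_at <- function(gen) vapply(targ, function(tg)
    tau_schedule(min(gen, Ntot), Ntot, tg$tau_start, tg$tau_end), numeric(1))

  genome_of <- function(gene, h) {
    ps <- gene_to_params(gene[setdiff(pnames, "C")], "aEIF", fixed, ties)
    cascade_genome(h, unname(gene["C"]), ps)
  }

  # precomputed lagged design matrices turn every kernel convolution into a
  # BLAS matrix-vector product; a fixed kernel's unscaled drive is shared by
  # all neuron genes of a phase
  n_lag <- ncol(init_strf$values)
  designs <- lapply(stimuli, build_design_matrix, n_lag = n_lag)
  tmpl <- gene_vector_template("aEIF", fixed, ties)
  sim_dist <- function(gene, drives, taus) {
    pv <- gene_fill(tmpl, gene[setdiff(pnames, "C")])
    C <- unname(gene["C"])
    sum(vapply(seq_len(ns), function(i) {
      st <- simulate_model_cpp(3L, unname(pv), C * drives[[i]],
                               stimuli[[i]]$bin_ms, dt, FALSE, FALSE, 0)$spikes
      tg <- targ[[i]]
      f <- filtered_function(tg$times, tg$weights, taus[i], sqrt(2 / taus[i]))
      van_rossum_to_function(spike_train(st, stimuli[[i]]$bin_ms *
                                           ncol(stimuli[[i]]$values)), f)
    }, numeric(1)))
  }
  drives_of <- function(h) lapply(designs, function(X)
    as.numeric(X %*% as.vector(h$values)))
  fitness_of <- function(gene, h, taus) sim_dist(gene, drives_of(h), taus)

  with_seed(config$seed, {
    p <- length(pnames)
    genes <- matrix(runif(ncfg$population * p, rmat[1, ], rmat[2, ]),
                    nrow = ncfg$population, byrow = TRUE,
                    dimnames = list(NULL, pnames))
    strfs <- c(list(init_strf),
               replicate(scfg$population - 1,
                         mutate_strf(init_strf, config$strf_mutation_scale),
                         simplify = FALSE))
    taus0 <- taus_at(0)
    best_h_idx <- 1L
    drives0 <- drives_of(strfs[[best_h_idx]])
    nfit <- vapply(seq_len(nrow(genes)), function(r)
      sim_dist(genes[r, ], drives0, taus0), numeric(1))
    best_g_idx <- which.min(nfit)
    sfit <- rep(NA_real_, scfg$population)

    taus_end <- taus_at(Ntot)
    best_ever <- list(genome = genome_of(genes[best_g_idx, ], strfs[[best_h_idx]]),
                      fitness = fitness_of(genes[best_g_idx, ], strfs[[best_h_idx]],
                                           taus_end))
    hist_rows <- vector("list", Ntot)

    npop <- list(genes = genes, fitness = nfit, generation = 0L)
    for (gen in seq_len(Ntot)) {
      taus <- taus_at(gen)
      phase <- if ((floor((gen - 1) / config$phase_length) %% 2) == 0)
        "neuron" else "strf"
      eps_i <- epsilon_schedule(gen, Ntot, ncfg$eps_m0, ncfg$eps_min)
      if (phase == "neuron") {
        h <- strfs[[best_h_idx]]
        drives <- drives_of(h)
        # re-evaluate against the (possibly new) best partner at a phase start
        if (gen > 1 && (gen - 1) %% config$phase_length == 0)
          npop$fitness <- vapply(seq_len(nrow(npop$genes)), function(r)
            sim_dist(npop$genes[r, ], drives, taus), numeric(1))
        npop <- evolve_generation(npop, function(gm)
          vapply(seq_len(nrow(gm)), function(r) sim_dist(gm[r, ], drives, taus),
                 numeric(1)),
          ncfg, eps_i, rmat)
        best_g_idx <- which.min(npop$fitness)
        genes <- npop$genes
        phase_best <- min(npop$fitness)
      } else {
        # evolve the STRF population against the current best neuron gene
        gbest <- genes[best_g_idx, ]
        if (anyNA(sfit))
          sfit <- vapply(strfs, function(h) fitness_of(gbest, h, taus), numeric(1))
        ord <- order(sfit)
        k <- min(scfg$elites, length(strfs))
        new_strfs <- strfs[ord[seq_len(k)]]
        n_child <- length(strfs) - k
        if (n_child > 0) {
          parents <- matrix(select_roulette(sfit, 2 * n_child), ncol = 2)
          for (c in seq_len(n_child)) {
            child <- crossover_strf(strfs[[parents[c, 1]]], strfs[[parents[c, 2]]])
            if (runif(1) < scfg$mutation_prob)
              child <- mutate_strf(child, config$strf_mutation_scale)
            new_strfs <- c(new_strfs, list(child))
          }
        }
        strfs <- new_strfs
        sfit <- vapply(strfs, function(h) fitness_of(gbest, h, taus), numeric(1))
        best_h_idx <- which.min(sfit)
        phase_best <- min(sfit)
      }
      # track the best combined genome at the final timescales
      cand_fit <- fitness_of(genes[best_g_idx, ], strfs[[best_h_idx]], taus_end)
      if (cand_fit < best_ever$fitness) {
        best_ever$genome <- genome_of(genes[best_g_idx, ], strfs[[best_h_idx]])
        best_ever$fitness <- cand_fit
      }
      val_gamma <- NA_real_
      if (!is.null(validation) && (gen %% config$phase_length == 0 || gen == Ntot)) {
        val_gamma <- mean(vapply(seq_along(validation$stimuli), function(i) {
          u <- simulate_cascade(best_ever$genome, validation$stimuli[[i]], dt = dt)
          mean(vapply(validation$responses[[i]]$trains, function(tr)
            tryCatch(coincidence_factor(u, tr, 2)$gamma, error = function(e) NA_real_),
            numeric(1)), na.rm = TRUE)
        }, numeric(1)), na.rm = TRUE)
      }
      hist_rows[[gen]] <- data.frame(generation = gen, phase = phase,
                                     tau_ms = taus[1], eps_m = eps_i,
                                     phase_best_d = phase_best,
                                     best_ever_d = best_ever$fitness,
                                     val_gamma = val_gamma)
      # phase change invalidates the cached strf fitnesses
      if (gen %% config$phase_length == 0) sfit <- rep(NA_real_, length(strfs))
    }
    structure(list(best_genome = best_ever$genome,
                   best_fitness = best_ever$fitness,
                   history = do.call(rbind, hist_rows), config = config),
              class = "cascade_fit")
  })
}

#' @export
print.cascade_fit <- function(x, ...) {
  cat(sprintf("<cascade_fit> best combined fitness %.4f after %d generations\n",
              x$best_fitness, nrow(x$history)))
  invisible(x)
}

#' Benchmark a cascade genome against Poisson rate models
#'
#' Compares the deterministic cascade spike predictions with an
#' inhomogeneous Poisson realization of an STRF rate model on validation
#' data: per stimulus, the cascade's mean coincidence factor and van Rossum
#' distance against the trials, the Poisson model's expected coincidence
#' factor ([expected_coincidence_poisson()]) and expected distance
#' ([expected_van_rossum_poisson()]), plus aggregate means and the fraction
#' of stimuli where the cascade wins.
#'
#' @param genome a [cascade_genome()].
#' @param rates list of non-negative rate [sampled_trace()]s (one per
#'   stimulus), e.g. the reverse-correlation STRF rates floored at zero;
#'   see `calibrate_mean_rate`.
#' @param stimuli list of validation [spectrogram()]s.
#' @param responses list of validation [trial_set()]s.
#' @param delta coincidence window in ms (default 2).
#' @param tau van Rossum timescale in ms (default 10).
#' @param n_mc Monte Carlo draws for the expected coincidence count.
#' @param seed RNG seed for the Poisson draws.
#' @param calibrate_mean_rate optional target mean rate (spikes/ms); when
#'   given, all rates are floored at zero and rescaled so their pooled mean
#'   matches it (calibration to the training data's mean rate).
#' @return an object of class `poisson_benchmark`: list with `per_stimulus`
#'   (data.frame) and `summary`.
#' @export
benchmark_vs_poisson <- function(genome, rates, stimuli, responses,
                                 delta = 2, tau = 10, n_mc = 100, seed = 1,
                                 calibrate_mean_rate = NULL) {
  stopifnot(length(rates) == length(stimuli), length(stimuli) == length(responses))
  rates <- lapply(rates, function(r)
    sampled_trace(pmax(r$values, 0), dt = r$dt, t0 = r$t0, unit = r$unit))
  if (!is.null(calibrate_mean_rate)) {
    pooled <- mean(unlist(lapply(rates, function(r) r$values)))
    if (pooled > 0)
      rates <- lapply(rates, function(r)
        sampled_trace(r$values * calibrate_mean_rate / pooled, dt = r$dt,
                      t0 = r$t0, unit = r$unit))
  }
  seeds <- derive_seeds(seed, length(stimuli))
  rows <- lapply(seq_along(stimuli), function(i) {
    u <- simulate_cascade(genome, stimuli[[i]])
    trs <- responses[[i]]$trains
    g_cas <- mean(vapply(trs, function(tr)
      tryCatch(coincidence_factor(u, tr, delta)$gamma, error = function(e) NA_real_),
      numeric(1)), na.rm = TRUE)
    d_cas <- mean(vapply(trs, function(tr)
      van_rossum_distance(u, tr, tau), numeric(1)))
    g_poi <- mean(vapply(trs, function(tr)
      tryCatch(as.numeric(expected_coincidence_poisson(rates[[i]], tr, delta,
                                                       n_mc = n_mc, seed = seeds[i])),
               error = function(e) NA_real_), numeric(1)), na.rm = TRUE)
    d_poi <- mean(vapply(trs, function(tr)
      expected_van_rossum_poisson(rates[[i]], tr, tau), numeric(1)))
    data.frame(stimulus = i, gamma_cascade = g_cas, gamma_poisson = g_poi,
               d_cascade = d_cas, d_poisson = d_poi)
  })
  per <- do.call(rbind, rows)
  summary <- list(mean_gamma_cascade = mean(per$gamma_cascade, na.rm = TRUE),
                  mean_gamma_poisson = mean(per$gamma_poisson, na.rm = TRUE),
                  mean_d_cascade = mean(per$d_cascade),
                  mean_d_poisson = mean(per$d_poisson),
                  win_fraction_gamma = mean(per$gamma_cascade > per$gamma_poisson,
                                            na.rm = TRUE),
                  win_fraction_d = mean(per$d_cascade < per$d_poisson))
  structure(list(per_stimulus = per, summary = summary),
            class = "poisson_benchmark")
}

#' @export
print.poisson_benchmark <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<poisson_benchmark> %d stimuli\n", nrow(x$per_stimulus)))
  cat(sprintf("  mean Gamma: cascade %.3f vs Poisson %.3f (win fraction %.2f)\n",
              s$mean_gamma_cascade, s$mean_gamma_poisson, s$win_fraction_gamma))
  cat(sprintf("  mean d:     cascade %.3f vs Poisson %.3f (win fraction %.2f)\n",
              s$mean_d_cascade, s$mean_d_poisson, s$win_fraction_d))
  invisible(x)
}
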