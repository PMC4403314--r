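#' Synthetic aEIF parameter-recovery experiment
#'
#' Runs the full recovery pipeline once per seed: generate a synthetic
#' dataset ([make_table2_dataset()]), fit an aEIF gene of 7 free parameters
#' (`tau_m`, `tau_w`, `b`, `V_T`, `V_r = E_L` tied, `alpha`, `Delta_T`;
#' `R` and `V_c` fixed) to the 2 s training half with the annealed-timescale
#' genetic algorithm, and collect the best gene.  Reported values are the
#' across-seed means of the recovered parameters.
#'
#' @param seeds integer vector of seeds, one independent run per seed (used
#'   for both the dataset and the GA stream of that run).
#' @param population GA population size.
#' @param generations number of GA generations.
#' @param eps_min terminal mutation variance of the decay schedule.
#' @param track_validation also track the validation coincidence factor per
#'   generation (slower; needed for schedule comparisons).
#' @return an object of class `recovery_experiment`: list with `genes`
#'   (seeds x parameters matrix), `means`, `target`, `fits` (the individual
#'   [fit_neuron()] results).
#' @export
run_table2_recovery <- function(seeds = 1:5, population = 120,
                                generations = 400, eps_min = 1e-4,
                                track_validation = FALSE) {
  target <- c(tau_m = 10, tau_w = 144, b = 0.001, V_T = -50, E_L = -70,
              alpha = 1, Delta_T = 2)
  fits <- lapply(seq_along(seeds), function(k) {
    ds <- make_table2_dataset(seed = seeds[k])
    fit_neuron(ds$train$spikes, ds$train$current, model = "aEIF",
               ranges = table2_ranges(),
               config = ga_config(population = population,
                                  max_generations = generations,
                                  eps_min = eps_min, seed = seeds[k]),
               fixed = list(R = 1, V_c = 0), ties = list(V_r = "E_L"),
               validation = if (track_validation)
                 list(train = ds$validation$spikes,
                      current = ds$validation$current))
  })
  genes <- do.call(rbind, lapply(fits, function(f) f$best_gene))
  structure(list(genes = genes, means = colMeans(genes), target = target,
                 fits = fits, seeds = seeds),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat(sprintf("<recovery_experiment> %d runs\n", nrow(x$genes)))
  m <- rbind(target = x$target, mean_recovered = x$means)
  print(round(m, 4))
  invisible(x)
}
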