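model_kinds <- c("IF", "aIF", "atIF", "aEIF", "a2EIF", "aQIF")

param_slots <- c("tau_m", "tau_w", "tau_t", "E_L", "Delta_T", "V_T", "V_t0",
                 "b", "alpha", "beta", "V_r", "V_c", "R",
                 "izh_a", "izh_b", "izh_c", "izh_d")

#' Free (optimized) parameters of each model kind
#'
#' The remaining slots are fixed at their supplied or default values and do
#' not enter the genetic-algorithm gene.
#'
#' @param model one of `"IF"`, `"aIF"`, `"atIF"`, `"aEIF"`, `"a2EIF"`,
#'   `"aQIF"`.
#' @return character vector of parameter names.
#' @export
free_parameters <- function(model) {
  switch(match.arg(model, model_kinds),
    IF    = c("tau_m", "R"),
    aIF   = c("tau_m", "tau_w", "alpha", "R"),
    atIF  = c("tau_m", "tau_t", "alpha", "b", "R"),
    aEIF  = c("tau_m", "tau_w", "E_L", "Delta_T", "V_T", "b", "alpha", "V_r", "R"),
    a2EIF = c("tau_m", "tau_w", "tau_t", "E_L", "Delta_T", "b", "alpha", "beta",
              "V_r", "V_t0", "R"),
    aQIF  = c("izh_a", "izh_b", "izh_c", "izh_d", "R"))
}

#' Neuron model parameter set
#'
#' A model-tagged vector of parameters.  Unspecified parameters take
#' canonical defaults.  Parameter meaning (all voltages mV, times ms):
#' `tau_m` membrane time constant; `tau_w` adaptation time constant; `tau_t`
#' threshold-adaptation time constant; `E_L` resting potential; `Delta_T`
#' exponential slope factor; `V_T` exponential threshold (aEIF); `V_t0`
#' baseline adaptive threshold (a2EIF); `b` subthreshold adaptation
#' coupling; `alpha` spike-triggered adaptation increment; `beta`
#' spike-triggered threshold increment; `V_r` reset voltage; `V_c` spike
#' cutoff voltage (fixed at 30 mV for aQIF regardless of input); `R` input
#' current scale; `izh_a`, `izh_b`, `izh_c`, `izh_d` the Izhikevich
#' parameters (reset `c` and increment `d` replace `V_r` and `alpha`).
#'
#' For the IF-family models without an explicit reset parameter (IF, aIF,
#' atIF) the reset voltage defaults to `E_L`.
#'
#' @param model model kind.
#' @param ... named parameter values overriding the defaults.
#' @return an object of class `parameter_set` with fields `model` and
#'   `values` (full named vector over all slots).
#' @export
parameter_set <- function(model, ...) {
  model <- match.arg(model, model_kinds)
  vals <- c(tau_m = 10, tau_w = 144, tau_t = 50, E_L = -70, Delta_T = 2,
            V_T = -50, V_t0 = -50, b = 0.001, alpha = 1, beta = 2,
            V_r = NA_real_, V_c = 0, R = 1,
            izh_a = 0.02, izh_b = 0.2, izh_c = -65, izh_d = 8)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(vals))
    if (length(bad)) stopf("unknown parameter(s): %s", paste(bad, collapse = ", "))
    vals[names(dots)] <- as.numeric(unlist(dots))
  }
  if (is.na(vals["V_r"]))
    vals["V_r"] <- if (model == "aQIF") vals["izh_c"] else vals["E_L"]
  if (model == "aQIF") {
    vals["V_c"] <- 30            # fixed cutoff, not a gene
    vals["V_r"] <- vals["izh_c"]
    vals["alpha"] <- vals["izh_d"]
    vals["E_L"] <- vals["izh_c"] # initial condition v0 = c
  }
  for (nm in c("tau_m", "tau_w", "tau_t"))
    if (vals[nm] <= 0) stopf("%s must be > 0", nm)
  if (model %in% c("aEIF", "a2EIF") && vals["Delta_T"] <= 0)
    stopf("Delta_T must be > 0 for exponential models")
  if (vals["V_r"] >= vals["V_c"]) stopf("V_r must be below V_c")
  structure(list(model = model, values = vals), class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  free <- free_parameters(x$model)
  cat(sprintf("<parameter_set> %s\n", x$model))
  v <- x$values[free]
  cat(paste(sprintf("  %s = %g", names(v), v), collapse = "\n"), "\n")
  invisible(x)
}

model_code <- function(model) match(match.arg(model, model_kinds), model_kinds) - 1L

#' Model right-hand side
#'
#' Returns the instantaneous rate of change of the state `(v, w, v_thr)` for
#' the given model at input current `I`.  The exponential argument is
#' clipped at 40 before exponentiation so the right-hand side is always
#' finite (the trajectory above the cutoff is discarded by the reset
#' anyway).
#'
#' @param params a [parameter_set()].
#' @param state numeric vector `c(v, w, v_thr)`; `v_thr` is the adaptive
#'   cutoff for atIF and the adaptive exponential threshold for a2EIF
#'   (ignored otherwise).
#' @param I input current (model units).
#' @return numeric vector `c(dv, dw, dv_thr)`.
#' @export
neuron_derivative <- function(params, state, I) {
  stopifnot(inherits(params, "parameter_set"))
  p <- params$values
  v <- state[1]; w <- if (length(state) > 1) state[2] else 0
  x3 <- if (length(state) > 2) state[3] else 0
  # above the cutoff the trajectory is discarded by the reset; clamp so the
  # exponential/quadratic terms cannot blow up intermediate RK4 stages
  if (params$model %in% c("aEIF", "a2EIF", "aQIF")) v <- min(v, p["V_c"])
  eclip <- function(a) exp(pmin(a, 40))
  switch(params$model,
    IF = c(-(v - p["E_L"]) / p["tau_m"] + p["R"] * I, 0, 0),
    aIF = c(-(v - p["E_L"]) / p["tau_m"] - w + p["R"] * I, -w / p["tau_w"], 0),
    atIF = c(-(v - p["E_L"]) / p["tau_m"] + p["R"] * I, 0,
             (p["b"] * v - x3) / p["tau_t"]),
    aEIF = c(((p["E_L"] - v) + p["Delta_T"] * eclip((v - p["V_T"]) / p["Delta_T"])) /
               p["tau_m"] - w + p["R"] * I,
             (p["b"] * v - w) / p["tau_w"], 0),
    a2EIF = c((p["E_L"] - v + p["Delta_T"] * eclip((v - x3) / p["Delta_T"]) -
                 w + p["R"] * I) / p["tau_m"],
              (p["b"] * v - w) / p["tau_w"],
              (p["V_t0"] - x3) / p["tau_t"]),
    aQIF = c(0.04 * v^2 + 5 * v + 140 - w + p["R"] * I,
             p["izh_a"] * (p["izh_b"] * v - w), 0)) |> unname()
}

#' Simulate a spiking neuron model
#'
#' Deterministic 4th-order Runge-Kutta integration with step `dt`.  The
#' input current is held constant within its own sampling interval
#' (zero-order hold; `current$dt` must be an integer multiple of `dt`).
#' When the voltage reaches the cutoff after a step, the spike time is
#' placed at the linear interpolation of the crossing within the step, the
#' voltage is reset to `V_r`, the adaptation variable is incremented by
#' `alpha` (`d` for aQIF), and for a2EIF / atIF the adaptive threshold /
#' cutoff is incremented by `beta` / `alpha`.  Initial conditions:
#' `v = E_L` (aQIF: `c`), `w = 0` (aQIF: `b*c`), `v_t = V_t0` (a2EIF),
#' `v_c = V_c0` (atIF).
#'
#' @param params a [parameter_set()].
#' @param current a [sampled_trace()] of input current.
#' @param dt integration step in ms (default 0.1; must divide `current$dt`).
#' @param record_voltage also return the voltage and adaptation traces.
#' @param use_fast_exp replace `exp()` in the model right-hand side by the
#'   low-order approximation [fast_exp()] (never used in the metrics).
#' @param settle_ms settle-in period simulated with the first current value
#'   before recording starts (default 0).
#' @return an object of class `simulation_result`: list with `spikes`
#'   (a [spike_train()] on the trace's duration) and, if requested,
#'   `voltage`, `adaptation`, `threshold` as [sampled_trace()] objects.
#' @export
simulate_neuron <- function(params, current, dt = 0.1, record_voltage = FALSE,
                            use_fast_exp = FALSE, settle_ms = 0) {
  stopifnot(inherits(params, "parameter_set"), inherits(current, "sampled_trace"))
  if (any(!is.finite(current$values))) stopf("current contains non-finite values")
  if (dt > current$dt + 1e-12) stopf("dt must not exceed the current's sampling step")
  ratio <- current$dt / dt
  if (abs(ratio - round(ratio)) > 1e-8)
    stopf("current$dt must be an integer multiple of dt")
  res <- simulate_model_cpp(model_code(params$model), unname(params$values),
                            current$values, current$dt, dt,
                            record_voltage, use_fast_exp, settle_ms)
  out <- list(spikes = spike_train(res$spikes, T = res$T), params = params, dt = dt)
  if (record_voltage) {
    out$voltage <- sampled_trace(res$voltage, dt = dt, t0 = 0, unit = "mV")
    out$adaptation <- sampled_trace(res$adaptation, dt = dt, t0 = 0)
    out$threshold <- sampled_trace(res$threshold, dt = dt, t0 = 0, unit = "mV")
  }
  structure(out, class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %s model, %d spikes on [0, %g] ms\n",
              x$params$model, n_spikes(x$spikes), x$spikes$T))
  invisible(x)
}

#' Fast exponential approximation
#'
#' A low-order approximation of `exp(x)` (piecewise-linear in the IEEE-754
#' representation) with relative error below 4% over `[-20, 20]`.  Intended
#' only for model right-hand sides via `use_fast_exp` in
#' [simulate_neuron()]; the metrics always use the exact exponential.
#'
#' @param x numeric vector, `|x| <= 700`.
#' @return approximate `exp(x)`.
#' @export
fast_exp <- function(x) fast_exp_cpp(as.numeric(x))
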