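---
title: "Fitting spiking neuron models by annealed-metric evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting spiking neuron models by annealed-metric evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikefit)
```

## The problem

Given a time-varying input — an injected somatic current, or a sensory
stimulus — and one or more recorded spike trains, we want the parameters of a
simple spiking neuron model that reproduce the recorded spike times.  For
current injection the model is a two- or three-variable adaptive
integrate-and-fire neuron; for sensory (auditory-style) data a cascade is
used: a linear spectro-temporal receptive field (STRF) converts the stimulus
spectrogram into an estimated input current that drives the neuron.  Because
the map from parameters to spike trains is discontinuous and gradient-free,
the fit is done with a genetic algorithm whose fitness is a spike-train
metric.

## Neuron models

All models share the form

$$\frac{dv}{dt} = f(v) - w + RI, \qquad \frac{dw}{dt} = a(bv - w),$$

with a hard reset when $v$ reaches a cutoff $v_c$: $v \to v_r$,
$w \to w + \alpha$.  The choice of $f(v)$ gives the leaky IF
($f = -(v-E_L)/\tau_m$, no adaptation), the aIF (same $f$, $a = 1/\tau_w$,
$b = 0$), the aEIF
($f = [(E_L - v) + \Delta_T e^{(v - V_T)/\Delta_T}]/\tau_m$), and the
quadratic aQIF/Izhikevich neuron ($f = 0.04v^2 + 5v + 140$, cutoff fixed at
30 mV, reset parameters $c$, $d$).  Two variants adapt a threshold instead:
the atIF moves its cutoff with $\tau_t \dot v_c = b v - v_c$ (incremented by
$\alpha$ at spikes), and the a$^2$EIF extends the aEIF with a third variable
$\tau_t \dot v_t = V_{t0} - v_t$, $v_t \to v_t + \beta$ at spikes, so the
exponential threshold itself adapts.  In the a$^2$EIF the drive enters inside
the $\tau_m$ bracket, as its defining equations state; the two conventions
differ only by a rescaling of $R$, $\alpha$ and $b$.

Units: times in ms, voltages in mV, current in model units absorbed by $R$.
The known scaling invariances of these models are deliberately not quotiented
out; instead each free parameter carries a user-specified feasible interval.

**Numerical scheme.**  Classical RK4 with default `dt = 0.1` ms; the input
current is held constant within its own sampling interval (zero-order hold),
so `current$dt` must be an integer multiple of `dt`.  When a step ends at or
above the cutoff, the spike time is placed by linear interpolation of the
crossing inside the step — the same convention used when extracting spikes
from recorded voltage traces — giving an $O(dt)$ bound on spike placement
(RK4's $O(dt^4)$ applies to the subthreshold trajectory).  Two guards keep
the exponential models finite: the exponent is clipped at 40, and the voltage
fed into the right-hand side is clamped at the cutoff.  The clamp matters:
without it the RK4 stages evaluate the supra-cutoff upswing at astronomically
large $v$, and the $bv$ term poisons the adaptation variable before the reset
can discard the excursion.  Both guards only touch the part of the trajectory
the reset throws away.  Initial conditions are $v_0 = E_L$ (aQIF: $c$),
$w_0 = 0$ (aQIF: $bc$), $v_{t0} = V_{t0}$; an optional settle-in period can
be simulated before recording.  Models without an explicit reset parameter
(IF, aIF, atIF) reset to $E_L$.

An optional fast exponential (a piecewise-linear approximation assembled in
the IEEE-754 bit layout, maximum relative error ~3% on $[-20, 20]$) can
replace `exp()` in the model right-hand side only; all metrics always use the
exact exponential.

## The fitness metric

A spike train $u = \{u_1, \dots, u_m\}$ is filtered with a causal exponential
kernel $h(t) = \kappa\, e^{-t/\tau}$ ($t \ge 0$) into
$f(t; u) = \sum_i h(t - u_i)$, and the van Rossum distance is the $L^2$
distance between filtered trains.  The kernel height is configurable because
the constant is typeset ambiguously in the literature; the default
$\kappa = \sqrt{2/\tau}$ makes $d(\{t_0\}, \varnothing) = 1$ at every $\tau$,
which gives distances a scale-free interpretation (roughly "number of
unmatched spikes").  With this normalization

$$d^2(u, v) = \sum_{ij} e^{-|u_i-u_j|/\tau} + \sum_{ij} e^{-|v_i-v_j|/\tau}
 - 2\sum_{ij} e^{-|u_i-v_j|/\tau},$$

evaluated either by the brute-force double sum or by an $O(m+n)$
sorted-merge recursion; the package carries both and its tests require
agreement to $10^{-10}$ relative.  Filtered functions are exponential sums,
so distances to *average functions* (the mean of the trials' filtered
functions — the package's multi-trial target) are computed with the same
closed form, exactly.

The **timescale $\tau$ is the knob**: large $\tau$ compares firing rates,
small $\tau$ compares individual spike times.  During a fit the timescale is
annealed geometrically from $\tau_{\mathrm{start}} = T/2$ (half the training
duration) down to $\tau_{\mathrm{end}} =$ the target's mean inter-spike
interval over the run, so early generations find the right rate and late
generations refine spike placement.

For benchmarking (never as fitness) the package carries the coincidence
factor

$$\Gamma = \frac{2}{1 - 2\delta f}\,
  \frac{N_c - 2\delta f N_e}{N_e + N_m},$$

with $N_c$ counted by greedy earliest-first one-to-one matching within
$|\Delta t| \le \delta$ (inclusive).  Greedy one-to-one counting prevents
$N_c$ inflation when several model spikes crowd one target spike.  $\Gamma$
of a train with itself is exactly 1; two empty trains are defined to agree
($\Gamma = 1$); an empty target leaves $\Gamma$ undefined and is an error.
Intrinsic reliability $\Gamma_i$ is the mean inter-trial $\Gamma$, with each
pair symmetrized by averaging the two directed values because the formula is
asymmetric in which train supplies $f$.  Expected values against an
inhomogeneous Poisson rate model use the expected spike count
$\langle N_m\rangle = \int \tilde r\,dt$ and a Monte-Carlo
$\langle N_c\rangle$ over thinning-sampled trains; the expected van Rossum
distance is computed, as defined, as the distance between the filtered train
and the kernel-filtered rate — the distance between *expectations*, a lower
bound on the expectation of the distance, and the tests assert exactly that
inequality rather than equality.

## The genetic algorithm

Real-valued genes (one coordinate per free model parameter, feasible
intervals defining the search region $S$), with:

* **elitism** — the best $k$ genes are copied unchanged (default 5% of the
  population; ties broken by index), so the best training fitness is
  monotone at fixed $\tau$;
* **roulette selection** — the statistic is a distance, so selection weights
  are $(\max f - f_j) + \eta$ with floor $\eta = 10^{-6}\times$range;
* **crossover** — whole-arithmetic by default: one $u \sim U(0,1)$ per child
  gives $u\,x_1 + (1-u)\,x_2$, the classical real-coded operator.  The
  alternative per-coordinate uniform crossover (each coordinate copied from
  either parent) is available, but it cannot move *along* correlated valleys
  of the fitness landscape: in the aEIF recovery problem the voltage
  parameters ($E_L$, $V_T$, $V_r$) form such a valley, and with
  coordinate-wise mixing the runs stall in separate local minima spread along
  it (a simplex polish confirms they are true local minima), while arithmetic
  crossover lets the population contract along the valley toward the optimum.
  Children of feasible parents are feasible under both operators (the region
  is a box);
* **non-uniform mutation** — with probability 5% a child has exactly one
  coordinate rescaled by $1 + r$, $r \sim N(0, \varepsilon_m)$
  ($\varepsilon_m$ a *variance*), clipped to $S$; $\varepsilon_m$ decays
  geometrically from 0.2 to `eps_min` across the run.

Every member of a generation — elites included — is re-scored at that
generation's $\tau_i$, so ranking is always internally consistent.  The
decay's terminal variance defaults to `eps_min = 0.01` (terminal kicks of
~10%); the shipped recovery experiment lowers it to `1e-4` (~1% kicks)
because it asks for parameters to about a percent, and a terminal kick an
order of magnitude larger than the sought precision stalls the end game of
the search.  Each generation costs exactly `population` fitness
evaluations; evaluation is embarrassingly parallel and exposed through a
pluggable `map` argument (the sequential default keeps runs bit-for-bit
reproducible from the seed).

## STRF estimation and the cascade

The linear stage is estimated by normalized reverse correlation: with the
lagged-stimulus design matrix $S$ (vectorized lag-major; history before the
first bin zero-padded), $h = (S^{\top}S)^{+}_{\lambda} S^{\top} r$, where the
pseudo-inverse keeps the largest $m$ singular values whose cumulative
fraction of the total stays below $\lambda$ (at least one dimension is always
kept; $\lambda \ge 1$ keeps all — the strict inequality cannot hold at
$\lambda = 1$ where the full cumulative fraction is exactly 1).  $\lambda$
can be chosen by `folds`-fold cross-validation on contiguous time blocks,
maximizing held-out correlation with the PSTH (largest candidate on ties).
The PSTH divides spike counts per bin (default 1 ms) by trials and bin
width; optional edge-corrected Gaussian smoothing is available because raw
1 ms bins of sparse spike trains are nearly binary and the regression then
chases bin noise.  Normal equations from several stimuli can be pooled.

The cascade model feeds $\tilde I = C\,(h * s)$ to an aEIF neuron.  The STRF
is constrained to unit $L^1$ norm and the scale $C$ is a neuron-side gene,
separating kernel shape from drive strength.  **Tandem evolution** alternates
(default every 50 generations, 600 total) between evolving the neuron genes
(including $C$) against the current best STRF and evolving an STRF population
against the current best neuron gene.  STRF variation operators are patch
mutation (Gaussian noise on a ≤4×4 rectangle, then $L^1$ re-normalization)
and per-coefficient uniform crossover; these operators are this package's
own choices — the field does not prescribe STRF genetic operators — and the
population is seeded from the reverse-correlation estimate, which anchors the
search near a sensible kernel.  Populations are re-scored at phase
boundaries (the partner changed), and the best *combined* genome is tracked
at the final timescales so the reported best never worsens.  The fitness of
a candidate is the sum over training stimuli of the distance to that
stimulus's average function, each stimulus annealing its own timescale from
$T_s/2$ to its trials' mean inter-spike interval.

**Measuring the annealing advantage.**  The shipped schedule-comparison
experiment contrasts the annealed timescale with a fixed
$\tau = \tau_{\mathrm{start}}$ over paired seeds, scoring each run by the
number of generations needed to reach 90% of its final validation
coincidence factor *and never drop below it again* (a first-crossing count
is degenerate: noisy $\Gamma$ trajectories graze the threshold in the first
few generations).  The comparison is run with uniform crossover and a
0.5 ms validation window: with arithmetic crossover the population
contracts to its basin within a handful of generations at this problem
size, both schedules land in the same basin (paired seeds share the initial
population), and the schedule effect is within noise — annealing matters in
the selection-limited regime, where the shape of the fitness landscape over
generations steers the search.

## Synthetic data generators

The generators are first-class code: they define the study conditions under
which everything else is validated.

**Injected current** is an Ornstein–Uhlenbeck process (Euler recursion
$I \mathrel{+}= (\mu - I)\,dt/\tau_c + \sigma\sqrt{2\,dt/\tau_c}\,z$),
defaults $\mu = 1.0$, $\sigma = 2.5$, $\tau_c = 5$ ms, 4 s at 0.1 ms.  The
defaults put the reference aEIF target (the recovery experiment's neuron:
$\tau_m = 10$ ms, $\tau_w = 144$ ms, $b = 0.001$, $V_T = -50$ mV,
$V_r = E_L = -70$ mV, $\alpha = 1$ mV, $\Delta_T = 2$ mV, $R = 1$ and
$V_c = 0$ mV fixed) in the 5–15 Hz band, and deliberately in the
*fluctuation-driven* regime ($\sigma$ large relative to $\mu$): spike times
then lock to current transients and carry information about the voltage
parameters.  Under a mean-driven current the aEIF is nearly non-identifiable
along the shift direction ($E_L$, $V_T$, $V_r$ moving together — only the
brief supra-threshold upswing to the fixed cutoff breaks the symmetry), and
no optimizer can recover what the data do not constrain.  The recovery
experiment fits 7 free parameters with $V_r = E_L$ tied and the ranges of
roughly $[0.3\times, 1.7\times]$ the target values; fixing $R$ and $V_c$ is
what makes the remaining parameters identifiable at all.

**Auditory datasets** drive a known cascade — a Gabor-shaped, $L^1$-normalized
20×40 STRF, scale $C = 55$ (about 20 Hz on the default stimuli), and the
reference aEIF — with band-limited noise spectrograms (white per band,
lightly smoothed in time, zero mean, ~2 s, 20 bands on 0–8 kHz).  Trials are
the deterministic cascade train jittered by a Gaussian of chosen sd with a
small per-spike deletion probability: an explicit, minimal model of
trial-to-trial variability sufficient to exercise $\Gamma_i$ and the
benchmark pipeline.  What these trials do **not** emulate: rate-dependent
variability, bursting, adaptation of reliability across the stimulus, or any
acoustic structure of real song — so passing tests demonstrate machinery
correctness and recoverability under the stated noise model, not performance
on real recordings.  An inhomogeneous Poisson generator (thinning against the
rate's maximum, linear interpolation between rate samples) provides the
stochastic benchmark.

All generators are pure functions of (specification, seed).

## Degenerate inputs and conventions

Empty spike trains are valid everywhere they can be ($d$ to an empty train is
the filtered norm; $\Gamma$ with an empty *target* is an error, two empty
trains agree).  Spike times are strictly increasing with duplicates rejected
at 1 ms × 10⁻⁹.  Traces are point samples: a trace of $n$ samples spans
$(n-1)\,dt$.  Spectrograms and STRFs are band × bin matrices, lag 0 first,
low band first, and their text files carry bin width and band edges in `#`
headers.  Grid-based quadratures (the expected-distance formula) carry
$O(dt)$ error at spike discontinuities; tests compare them at tolerances that
acknowledge this.

## Problem sizes used by the test-suite and acceptance runs

The shipped experiments are sized for a single CPU: the recovery experiment
uses population 120 for 400 generations over 5 seeds (2 s of training data
each); the schedule comparison uses population 48 for 150 generations over
10 paired seeds; the cascade ground-truth recovery uses 5 training / 5
validation stimuli of 2 s with tandem populations of 40 (neuron genes) and
24 (kernels) over 200 alternating generations.  These sizes are
choices, and every one of them can be raised by the user; the defaults in
`ga_config()` (population 240) and `tandem_config()` (600 iterations, phase
length 50) reflect the regime the method is normally run at.

## Known limitations

* Spike placement inside an integration step is linear, so spike times carry
  $O(dt)$ error during the explosive upswing; halving `dt` halves it.
* The atIF threshold equation drives $v_c$ toward $bv$ with no $E_L$ offset,
  as printed in its source; with small $b$ this parks the cutoff near 0 mV.
* The a$^2$EIF subthreshold adaptation uses $\tau_w \dot w = bv - w$ (no
  $E_L$ offset), as printed.
* The expected-coincidence of a Poisson rate model cannot approach 1 even
  for a rate concentrated at the target's spikes: with per-spike bump area
  $a$, $\langle N_c\rangle \le N_e(1 - e^{-a})$ while
  $\langle N_m\rangle = aN_e$, so the expectation peaks around 0.63 near
  $a = 1$.  A deterministic model can beat a Poisson realization of the
  right rate for this structural reason, which is exactly what the
  benchmark measures.
* Reverse correlation on spiking (rather than linear-Gaussian) responses is
  consistent in direction but noisy at realistic spike counts; the cascade
  fit treats it only as an initial condition.  This is the binding
  constraint on synthetic ground-truth cascade recovery: a 20×40 kernel has
  800 coefficients while a few stimuli of ~2 s at ~20 Hz provide a few
  hundred spikes, so the initial kernel estimate plateaus well short of the
  truth, and evolutionary search cannot realistically refine a kernel of
  that dimensionality within desk-scale evaluation budgets.  Pairing such a
  kernel with even the *generating* neuron parameters caps the validation
  coincidence factor far below a perfect match, so spike-level agreement
  with a synthetic ground truth should not be expected from this pipeline at
  these data sizes — the tandem stage's job is to reach that ceiling, which
  it does.  Noiseless trials do not help: identical repeats carry no
  averaging gain, so they are no more informative than a single trial.
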