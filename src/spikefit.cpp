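#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Fast exponential: piecewise-linear approximation of 2^y written directly
// into the IEEE-754 bit layout (exponent field carries floor(y), the mantissa
// the linear remainder).  The additive shift 0.0437 centres the interpolation
// error, giving a maximum relative error of ~3% — used only inside model
// right-hand sides, never in the metrics.
static inline double fexp1(double x) {
  if (x < -700.0) return 0.0;
  if (x > 700.0) x = 700.0;
  double y = x * 1.4426950408889634 + (1023.0 - 0.0437);
  if (y < 1.0) return 0.0; // deep underflow; exact exp would be < 1e-307
  int64_t bits = (int64_t)(y * 4503599627370496.0); // 2^52
  double out;
  std::memcpy(&out, &bits, sizeof(double));
  return out;
}

// [[Rcpp::export]]
NumericVector fast_exp_cpp(NumericVector x) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = fexp1(x[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Weighted exponential cross-sum  sum_ij wu_i wv_j exp(-|tu_i - tv_j|/tau)
// for sorted tu, tv: the O(m+n) sorted-merge recursion that underlies the
// efficient van Rossum algorithm.  Ties are charged to the forward pass.
// [[Rcpp::export]]
double exp_cross_sum_cpp(NumericVector tu, NumericVector wu,
                         NumericVector tv, NumericVector wv, double tau) {
  int nu = tu.size(), nv = tv.size();
  if (nu == 0 || nv == 0) return 0.0;
  double total = 0.0;

  // forward: contributions from tu_i <= tv_j
  {
    double A = 0.0, tA = 0.0;
    bool have = false;
    int iu = 0;
    for (int iv = 0; iv < nv; ++iv) {
      while (iu < nu && tu[iu] <= tv[iv]) {
        A = have ? A * std::exp(-(tu[iu] - tA) / tau) + wu[iu] : wu[iu];
        tA = tu[iu];
        have = true;
        ++iu;
      }
      if (have) total += wv[iv] * A * std::exp(-(tv[iv] - tA) / tau);
    }
  }
  // backward: contributions from tu_i > tv_j (strict)
  {
    double B = 0.0, tB = 0.0;
    bool have = false;
    int iu = nu - 1;
    for (int iv = nv - 1; iv >= 0; --iv) {
      while (iu >= 0 && tu[iu] > tv[iv]) {
        B = have ? B * std::exp(-(tB - tu[iu]) / tau) + wu[iu] : wu[iu];
        tB = tu[iu];
        have = true;
        --iu;
      }
      if (have) total += wv[iv] * B * std::exp(-(tB - tv[iv]) / tau);
    }
  }
  return total;
}

// ---------------------------------------------------------------------------
// Greedy earliest-first one-to-one coincidence count within |dt| <= delta.
// [[Rcpp::export]]
int coincidence_count_cpp(NumericVector a, NumericVector b, double delta) {
  int na = a.size(), nb = b.size(), i = 0, j = 0, c = 0;
  while (i < na && j < nb) {
    double d = a[i] - b[j];
    if (std::fabs(d) <= delta + 1e-12) { ++c; ++i; ++j; }
    else if (a[i] < b[j]) ++i;
    else ++j;
  }
  return c;
}

// ---------------------------------------------------------------------------
// Spiking neuron model simulation with RK4 and interpolated reset times.
//
// model codes: 0 IF, 1 aIF, 2 atIF, 3 aEIF, 4 a2EIF, 5 aQIF
// parameter slots (canonical order, prepared by the R layer):
//  0 tau_m  1 tau_w  2 tau_t  3 E_L  4 Delta_T  5 V_T  6 V_t0  7 b
//  8 alpha  9 beta  10 V_r  11 V_c  12 R  13 izh_a  14 izh_b
// For aQIF the R layer maps V_r <- c, alpha <- d, E_L <- c, V_c <- 30.
// State: v, w, x3 (x3 = adaptive threshold v_t for a2EIF, cutoff v_c for atIF).

struct Deriv { double dv, dw, dx3; };

static inline Deriv rhs(int model, const double *p, double v, double w,
                        double x3, double I, bool fast) {
  Deriv d;
  d.dv = 0.0; d.dw = 0.0; d.dx3 = 0.0;
  switch (model) {
  case 0: // IF
    d.dv = -(v - p[3]) / p[0] + p[12] * I;
    break;
  case 1: // aIF: f(v) leak, dw/dt = -w/tau_w
    d.dv = -(v - p[3]) / p[0] - w + p[12] * I;
    d.dw = -w / p[1];
    break;
  case 2: // atIF: adaptive cutoff x3, no adaptation current
    d.dv = -(v - p[3]) / p[0] + p[12] * I;
    d.dx3 = (p[7] * v - x3) / p[2];
    break;
  case 3: { // aEIF; v clamped at the cutoff: the supra-cutoff trajectory is
            // discarded by the reset, clamping keeps the stage values sane
    if (v > p[11]) v = p[11];
    double arg = (v - p[5]) / p[4];
    if (arg > 40.0) arg = 40.0;
    double e = fast ? fexp1(arg) : std::exp(arg);
    d.dv = ((p[3] - v) + p[4] * e) / p[0] - w + p[12] * I;
    d.dw = (p[7] * v - w) / p[1];
    break;
  }
  case 4: { // a2EIF: threshold x3 adapts; tau_m multiplies the whole RHS
    if (v > p[11]) v = p[11];
    double arg = (v - x3) / p[4];
    if (arg > 40.0) arg = 40.0;
    double e = fast ? fexp1(arg) : std::exp(arg);
    d.dv = (p[3] - v + p[4] * e - w + p[12] * I) / p[0];
    d.dw = (p[7] * v - w) / p[1];
    d.dx3 = (p[6] - x3) / p[2];
    break;
  }
  case 5: // aQIF / Izhikevich
    if (v > p[11]) v = p[11];
    d.dv = 0.04 * v * v + 5.0 * v + 140.0 - w + p[12] * I;
    d.dw = p[13] * (p[14] * v - w);
    break;
  }
  return d;
}

// [[Rcpp::export]]
List simulate_model_cpp(int model, NumericVector par, NumericVector current,
                        double current_dt, double dt, bool record,
                        bool use_fast, double settle_ms) {
  const double *p = par.begin();
  int nc = current.size();
  double T = nc * current_dt;
  int n_steps = (int)std::lround(T / dt);
  int per = (int)std::lround(current_dt / dt); // dt steps per current sample

  double v = p[3], w = 0.0, x3 = 0.0;
  if (model == 2) x3 = p[11];      // atIF: cutoff starts at fixed V_c0
  if (model == 4) x3 = p[6];       // a2EIF: threshold starts at V_t0
  if (model == 5) w = p[14] * v;   // aQIF: u0 = b*v0

  // settle-in with the first current value, not recorded
  int n_settle = (int)std::lround(settle_ms / dt);
  for (int i = 0; i < n_settle; ++i) {
    double I = current[0];
    Deriv k1 = rhs(model, p, v, w, x3, I, use_fast);
    Deriv k2 = rhs(model, p, v + 0.5 * dt * k1.dv, w + 0.5 * dt * k1.dw, x3 + 0.5 * dt * k1.dx3, I, use_fast);
    Deriv k3 = rhs(model, p, v + 0.5 * dt * k2.dv, w + 0.5 * dt * k2.dw, x3 + 0.5 * dt * k2.dx3, I, use_fast);
    Deriv k4 = rhs(model, p, v + dt * k3.dv, w + dt * k3.dw, x3 + dt * k3.dx3, I, use_fast);
    v += dt / 6.0 * (k1.dv + 2 * k2.dv + 2 * k3.dv + k4.dv);
    w += dt / 6.0 * (k1.dw + 2 * k2.dw + 2 * k3.dw + k4.dw);
    x3 += dt / 6.0 * (k1.dx3 + 2 * k2.dx3 + 2 * k3.dx3 + k4.dx3);
    double vc = (model == 2) ? x3 : p[11];
    if (v >= vc) {
      v = p[10];
      if (model == 2) x3 += p[8]; else w += p[8];
      if (model == 4) x3 += p[9];
    }
  }

  std::vector<double> spikes;
  NumericVector vt, wt, x3t;
  if (record) { vt = NumericVector(n_steps + 1); wt = NumericVector(n_steps + 1); x3t = NumericVector(n_steps + 1); }
  if (record) { vt[0] = v; wt[0] = w; x3t[0] = x3; }

  for (int i = 0; i < n_steps; ++i) {
    int ci = i / per;
    if (ci >= nc) ci = nc - 1;
    double I = current[ci];
    double v0 = v;
    Deriv k1 = rhs(model, p, v, w, x3, I, use_fast);
    Deriv k2 = rhs(model, p, v + 0.5 * dt * k1.dv, w + 0.5 * dt * k1.dw, x3 + 0.5 * dt * k1.dx3, I, use_fast);
    Deriv k3 = rhs(model, p, v + 0.5 * dt * k2.dv, w + 0.5 * dt * k2.dw, x3 + 0.5 * dt * k2.dx3, I, use_fast);
    Deriv k4 = rhs(model, p, v + dt * k3.dv, w + dt * k3.dw, x3 + dt * k3.dx3, I, use_fast);
    v += dt / 6.0 * (k1.dv + 2 * k2.dv + 2 * k3.dv + k4.dv);
    w += dt / 6.0 * (k1.dw + 2 * k2.dw + 2 * k3.dw + k4.dw);
    x3 += dt / 6.0 * (k1.dx3 + 2 * k2.dx3 + 2 * k3.dx3 + k4.dx3);

    double vc = (model == 2) ? x3 : p[11];
    if (v >= vc) {
      double frac = (v > v0) ? (vc - v0) / (v - v0) : 1.0;
      if (frac < 0.0) frac = 0.0;
      if (frac > 1.0) frac = 1.0;
      spikes.push_back((i + frac) * dt);
      v = p[10];
      if (model == 2) x3 += p[8]; else w += p[8];
      if (model == 4) x3 += p[9];
    }
    if (record) { vt[i + 1] = v; wt[i + 1] = w; x3t[i + 1] = x3; }
  }

  List out = List::create(
    Named("spikes") = NumericVector(spikes.begin(), spikes.end()),
    Named("T") = T, Named("dt") = dt);
  if (record) { out["voltage"] = vt; out["adaptation"] = wt; out["threshold"] = x3t; }
  return out;
}
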