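// Network integration engine: classical RK4 over the coupled membrane,
// gating, calcium and synaptic kinetic equations of the AL model, with
// spike detection (upward 0 mV crossing, 2 ms refractory) and lazily
// decayed spike-triggered facilitation of the inhibitory synapses.
//
// Units: mV, ms, mS, uA, uF, mM. Neuron order: PNs first, then LNs.
// Voltage-dependent rate functions are tabulated on a fine grid and
// linearly interpolated; synaptic kinetic state is kept per presynaptic
// neuron (all edges of a class share rate constants and drive).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <cstring>
#include <random>
using namespace Rcpp;

namespace {

constexpr double VMIN = -150.0, VMAX = 80.0, DV = 0.025;
constexpr int NV = static_cast<int>((VMAX - VMIN) / DV) + 2;

enum Col {
  NA_M_INF, NA_M_TAU, NA_H_INF, NA_H_TAU,
  K_N_INF, K_N_TAU,
  A_M_INF, A_M_TAU, A_H_INF, A_H_TAU,
  T_M_INF, T_M_TAU, T_H_INF, T_H_TAU,
  H_M_INF, H_M_TAU,
  GABA_T, NCOL
};

std::vector<float> g_lut;  // NV * NCOL, row-major by voltage index

double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

// evaluate all voltage-dependent steady states / time constants at V
void rate_row(double V, double* row) {
  double u = V + 50.0;
  double am = 0.32 * vtrap(13.0 - u, 4.0);
  double bm = 0.28 * vtrap(u - 40.0, 5.0);
  double ah = 0.128 * std::exp((17.0 - u) / 18.0);
  double bh = 4.0 / (1.0 + std::exp((40.0 - u) / 5.0));
  double an = 0.032 * vtrap(15.0 - u, 5.0);
  double bn = 0.5 * std::exp((10.0 - u) / 40.0);
  row[NA_M_INF] = am / (am + bm);
  row[NA_M_TAU] = 1.0 / (am + bm);
  row[NA_H_INF] = ah / (ah + bh);
  row[NA_H_TAU] = 1.0 / (ah + bh);
  row[K_N_INF] = an / (an + bn);
  row[K_N_TAU] = 1.0 / (an + bn);
  row[A_M_INF] = 1.0 / (1.0 + std::exp(-(V + 60.0) / 8.5));
  row[A_M_TAU] = 0.37 + 1.0 / (std::exp((V + 35.8) / 19.7) +
                               std::exp(-(V + 79.7) / 12.7));
  row[A_H_INF] = 1.0 / (1.0 + std::exp((V + 78.0) / 6.0));
  row[A_H_TAU] = (V < -63.0)
    ? 1.0 / (std::exp((V + 46.0) / 5.0) + std::exp(-(V + 238.0) / 37.5))
    : 19.0;
  row[T_M_INF] = 1.0 / (1.0 + std::exp(-(V + 52.0) / 7.4));
  row[T_M_TAU] = 0.44 + 0.15 / (std::exp((V + 27.0) / 10.0) +
                                std::exp(-(V + 102.0) / 15.0));
  row[T_H_INF] = 1.0 / (1.0 + std::exp((V + 80.0) / 5.0));
  row[T_H_TAU] = 22.7 + 0.27 / (std::exp((V + 48.0) / 4.0) +
                                std::exp(-(V + 407.0) / 50.0));
  row[H_M_INF] = 1.0 / (1.0 + std::exp((V + 75.0) / 5.5));
  row[H_M_TAU] = 1.0 / (std::exp(-14.59 - 0.086 * V) +
                        std::exp(-1.87 + 0.0701 * V));
  row[GABA_T] = 1.0 / (1.0 + std::exp(-(V + 20.0) / 1.5));
}

void build_lut() {
  if (!g_lut.empty()) return;
  g_lut.resize(static_cast<size_t>(NV) * NCOL);
  double row[NCOL];
  for (int iv = 0; iv < NV; ++iv) {
    rate_row(VMIN + iv * DV, row);
    float* out = &g_lut[static_cast<size_t>(iv) * NCOL];
    for (int c = 0; c < NCOL; ++c) out[c] = static_cast<float>(row[c]);
  }
}

inline const float* lut_row(double V, double& frac, const float*& next) {
  double x = (V - VMIN) / DV;
  if (x < 0.0) x = 0.0;
  if (x > NV - 2) x = NV - 2;
  int i = static_cast<int>(x);
  frac = x - i;
  const float* row = &g_lut[static_cast<size_t>(i) * NCOL];
  next = row + NCOL;
  return row;
}

inline double lerp(const float* a, const float* b, int col, double f) {
  return a[col] + (b[col] - a[col]) * f;
}

// dot product with 8 independent accumulators: breaks the floating-point
// reduction dependency chain so the loop pipelines/vectorizes under strict
// FP semantics
inline float dot_f(const float* __restrict a, const float* __restrict b,
                   int n) {
  float s0 = 0, s1 = 0, s2 = 0, s3 = 0, s4 = 0, s5 = 0, s6 = 0, s7 = 0;
  int k = 0;
  for (; k + 8 <= n; k += 8) {
    s0 += a[k] * b[k];         s1 += a[k + 1] * b[k + 1];
    s2 += a[k + 2] * b[k + 2]; s3 += a[k + 3] * b[k + 3];
    s4 += a[k + 4] * b[k + 4]; s5 += a[k + 5] * b[k + 5];
    s6 += a[k + 6] * b[k + 6]; s7 += a[k + 7] * b[k + 7];
  }
  float s = ((s0 + s1) + (s2 + s3)) + ((s4 + s5) + (s6 + s7));
  for (; k < n; ++k) s += a[k] * b[k];
  return s;
}

// deterministic Gaussian via Box-Muller on a 64-bit Mersenne Twister
struct Gauss {
  std::mt19937_64 eng;
  bool have;
  double cached;
  explicit Gauss(uint64_t seed) : eng(seed), have(false), cached(0) {}
  double u01() {
    return (eng() >> 11) * (1.0 / 9007199254740992.0);
  }
  double operator()() {
    if (have) { have = false; return cached; }
    double u1 = u01(), u2 = u01();
    while (u1 <= 1e-300) u1 = u01();
    double r = std::sqrt(-2.0 * std::log(u1));
    cached = r * std::sin(6.283185307179586 * u2);
    have = true;
    return r * std::cos(6.283185307179586 * u2);
  }
};

struct CellPar {
  double Cm, gL, gKL, gNa, gK, gA, gT, gh;  // totals (mS) after area scaling
  double EL, EKL, ENa, EK, ECa, Eh, A_ca, tau_ca, Ca_inf;
};

CellPar unpack_params(const NumericVector& p) {
  CellPar c;
  double area = p["area"];
  c.Cm = p["Cm"];
  c.gL = static_cast<double>(p["gL"]) * area;
  c.gKL = static_cast<double>(p["gKL"]) * area;
  c.gNa = static_cast<double>(p["gNa"]) * area;
  c.gK = static_cast<double>(p["gK"]) * area;
  c.gA = static_cast<double>(p["gA"]) * area;
  c.gT = static_cast<double>(p["gT"]) * area;
  c.gh = static_cast<double>(p["gh"]) * area;
  c.EL = p["EL"]; c.EKL = p["EKL"]; c.ENa = p["ENa"]; c.EK = p["EK"];
  c.ECa = p["ECa"]; c.Eh = p["Eh"];
  c.A_ca = p["A_ca"]; c.tau_ca = p["tau_ca"]; c.Ca_inf = p["Ca_inf"];
  return c;
}

}  // namespace

// State layout within the flat vector Y (dimension D):
//   V[N], Ca[N], 8 gate blocks of N (na_m, na_h, k_n, a_m, a_h, t_m, t_h,
//   h_m), O_gaba[n_ln], R[n_ln], G[n_ln], O_ach[n_pn].
// [[Rcpp::export(name = ".al_run_trial_cpp")]]
List al_run_trial_cpp(int n_pn, int n_ln,
                      IntegerVector p2l_pre, IntegerVector p2l_post,
                      IntegerVector l2p_pre, IntegerVector l2p_post,
                      IntegerVector l2l_pre, IntegerVector l2l_post,
                      NumericVector g_pl, NumericVector g_lp,
                      NumericVector g_ll, double slow_ratio,
                      NumericVector F_l2p, NumericVector Ft_l2p,
                      NumericVector F_l2l, NumericVector Ft_l2l,
                      NumericVector pn_par, NumericVector ln_par,
                      NumericVector peak, NumericVector tau_r,
                      NumericVector tau_d,
                      double t_on, double stim_dur,
                      NumericVector dc, double noise_sd,
                      double trial_ms, double dt,
                      int seed, double t0_abs,
                      double df_pre, double df_post, double tau_F,
                      bool plastic, bool record_v, double v_every_ms,
                      int record_n, bool exact_kinetics = false) {
  build_lut();
  const int N = n_pn + n_ln;
  const CellPar P = unpack_params(pn_par);
  const CellPar L = unpack_params(ln_par);

  // synaptic constants
  const double alpha_g = 10.0, beta_g = 0.2;
  const double alpha_a = 1.0, beta_a = 0.2, A_T = 0.5, t_maxT = 0.3;
  const double r1 = 0.5, r2 = 0.0013, r3 = 0.1, r4 = 0.033, Khill = 100.0;
  const double E_gaba = -70.0, E_ach = 0.0, E_kslow = -95.0;

  const int nE_pl = p2l_pre.size();
  const int nE_lp = l2p_pre.size();
  const int nE_ll = l2l_pre.size();

  // 0-based edge index arrays; presynaptic LN indices are within-LN (0..n_ln)
  std::vector<int32_t> pl_pre(nE_pl), pl_post(nE_pl);
  for (int e = 0; e < nE_pl; ++e) { pl_pre[e] = p2l_pre[e] - 1; pl_post[e] = p2l_post[e] - 1; }
  std::vector<int32_t> lp_pre(nE_lp), lp_post(nE_lp);
  for (int e = 0; e < nE_lp; ++e) { lp_pre[e] = l2p_pre[e] - 1; lp_post[e] = l2p_post[e] - 1; }
  std::vector<int32_t> ll_pre(nE_ll), ll_post(nE_ll);
  for (int e = 0; e < nE_ll; ++e) { ll_pre[e] = l2l_pre[e] - 1; ll_post[e] = l2l_post[e] - 1; }

  // facilitation state (absolute event times) and effective weights.
  // Weights are held in dense row-major (postsynaptic-major) float
  // matrices so the per-stage conductance sums vectorize as dot products;
  // absent connections are zero.
  std::vector<double> Flp(F_l2p.begin(), F_l2p.end());
  std::vector<double> Ftlp(Ft_l2p.begin(), Ft_l2p.end());
  std::vector<double> Fll(F_l2l.begin(), F_l2l.end());
  std::vector<double> Ftll(Ft_l2l.begin(), Ft_l2l.end());
  // the matrices hold the facilitation multiplier F per connection (0 for
  // absent edges); class conductances multiply the dot products. Fast and
  // slow LN->PN receptors share the connection and its F, so one matrix
  // serves both currents.
  std::vector<float> W_lp(static_cast<size_t>(n_pn) * n_ln, 0.0f);
  std::vector<float> W_ll(static_cast<size_t>(n_ln) * n_ln, 0.0f);
  std::vector<float> W_ach(static_cast<size_t>(n_ln) * n_pn, 0.0f);
  for (int e = 0; e < nE_pl; ++e)
    W_ach[static_cast<size_t>(pl_post[e]) * n_pn + pl_pre[e]] =
      static_cast<float>(g_pl[e]);
  auto eff_F = [&](double F, double t_last, double t_abs) {
    if (!plastic) return F;  // frozen weights are used as-is
    double d = t_abs - t_last;
    return d <= 0 ? F : 1.0 + (F - 1.0) * std::exp(-d / tau_F);
  };
  auto refresh_weights = [&](double t_abs) {
    for (int e = 0; e < nE_lp; ++e)
      W_lp[static_cast<size_t>(lp_post[e]) * n_ln + lp_pre[e]] =
        static_cast<float>(g_lp[e] * eff_F(Flp[e], Ftlp[e], t_abs));
    for (int e = 0; e < nE_ll; ++e)
      W_ll[static_cast<size_t>(ll_post[e]) * n_ln + ll_pre[e]] =
        static_cast<float>(g_ll[e] * eff_F(Fll[e], Ftll[e], t_abs));
  };
  refresh_weights(t0_abs);

  // out/in edge lists for plastic classes (built only when needed)
  std::vector<std::vector<int32_t>> out_lp, out_ll, in_lp, in_ll;
  if (plastic && (df_pre > 0 || df_post > 0)) {
    out_lp.assign(n_ln, {}); out_ll.assign(n_ln, {});
    in_lp.assign(n_pn, {}); in_ll.assign(n_ln, {});
    for (int e = 0; e < nE_lp; ++e) {
      out_lp[lp_pre[e]].push_back(e);
      in_lp[lp_post[e]].push_back(e);
    }
    for (int e = 0; e < nE_ll; ++e) {
      out_ll[ll_pre[e]].push_back(e);
      in_ll[ll_post[e]].push_back(e);
    }
  }

  // stimulus groups: unique (tau_r, tau_d) pairs
  std::vector<int> sgrp(N);
  std::vector<double> g_tr, g_td;
  for (int i = 0; i < N; ++i) {
    int gidx = -1;
    for (size_t k = 0; k < g_tr.size(); ++k)
      if (g_tr[k] == tau_r[i] && g_td[k] == tau_d[i]) { gidx = k; break; }
    if (gidx < 0) { g_tr.push_back(tau_r[i]); g_td.push_back(tau_d[i]); gidx = g_tr.size() - 1; }
    sgrp[i] = gidx;
  }
  const int nG = g_tr.size();
  std::vector<double> gshape(nG);
  auto stim_shape = [&](double t) {
    for (int k = 0; k < nG; ++k) {
      if (t < t_on) { gshape[k] = 0.0; continue; }
      if (t <= t_on + stim_dur)
        gshape[k] = 1.0 - std::exp(-(t - t_on) / g_tr[k]);
      else
        gshape[k] = (1.0 - std::exp(-stim_dur / g_tr[k])) *
                    std::exp(-(t - t_on - stim_dur) / g_td[k]);
    }
  };

  // state
  const int D = 10 * N + 3 * n_ln + n_pn;
  const int oV = 0, oCa = N, oGate = 2 * N;
  const int oOg = 10 * N, oR = 10 * N + n_ln, oG = 10 * N + 2 * n_ln,
            oOa = 10 * N + 3 * n_ln;
  std::vector<double> Y(D, 0.0), k1(D), k2(D), k3(D), k4(D), tmp(D);

  // initial conditions: rest at EL with steady-state gates
  for (int i = 0; i < N; ++i) {
    const CellPar& c = (i < n_pn) ? P : L;
    double V0 = c.EL;
    Y[oV + i] = V0;
    Y[oCa + i] = c.Ca_inf;
    double vals[NCOL];
    rate_row(V0, vals);
    Y[oGate + 0 * N + i] = vals[NA_M_INF];
    Y[oGate + 1 * N + i] = vals[NA_H_INF];
    Y[oGate + 2 * N + i] = vals[K_N_INF];
    if (i < n_pn) {
      Y[oGate + 3 * N + i] = vals[A_M_INF];
      Y[oGate + 4 * N + i] = vals[A_H_INF];
      Y[oGate + 7 * N + i] = vals[H_M_INF];
    }
    Y[oGate + 5 * N + i] = vals[T_M_INF];
    Y[oGate + 6 * N + i] = vals[T_H_INF];
  }

  std::vector<double> last_spike(N, -1e9);
  std::vector<double> I_noise(N, 0.0);
  Gauss rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 1442695040888963407ULL);

  // scratch for the derivative evaluation (float copies feed the dense dots)
  std::vector<double> Tg(n_ln);
  std::vector<float> Og_f(n_ln), Bh_f(n_ln), Oa_f(n_pn);
  std::vector<double> sF(n_pn), sS(n_pn), sLL(n_ln), sA(n_ln);

  // Synaptic conductance sums, evaluated from the state at the start of
  // each step and held over the four RK4 stages (the synaptic kinetic
  // variables move by < 1% of their range within dt; the postsynaptic
  // driving force V - E_syn is still evaluated at every stage).
  auto compute_sums = [&](const double* y) {
    for (int j = 0; j < n_ln; ++j) {
      Og_f[j] = static_cast<float>(y[oOg + j]);
      double G = y[oG + j];
      double g4 = G * G; g4 *= g4;
      Bh_f[j] = static_cast<float>(g4 / (g4 + Khill));
    }
    for (int i = 0; i < n_pn; ++i)
      Oa_f[i] = static_cast<float>(y[oOa + i]);
    for (int i = 0; i < n_pn; ++i) {
      const float* w = &W_lp[static_cast<size_t>(i) * n_ln];
      sF[i] = dot_f(w, Og_f.data(), n_ln);
      sS[i] = slow_ratio * dot_f(w, Bh_f.data(), n_ln);
    }
    for (int j = 0; j < n_ln; ++j) {
      sLL[j] = dot_f(&W_ll[static_cast<size_t>(j) * n_ln], Og_f.data(), n_ln);
      sA[j] = dot_f(&W_ach[static_cast<size_t>(j) * n_pn], Oa_f.data(), n_pn);
    }
  };

  auto deriv = [&](const double* y, double t, double* dy) {
    stim_shape(t);
    // per-presynaptic-LN transmitter drive (per stage: feeds the synaptic
    // kinetic equations)
    for (int j = 0; j < n_ln; ++j) {
      double Vp = y[oV + n_pn + j];
      if (exact_kinetics) {
        Tg[j] = 1.0 / (1.0 + std::exp(-(Vp + 20.0) / 1.5));
      } else {
        double f; const float* nx; const float* row = lut_row(Vp, f, nx);
        Tg[j] = lerp(row, nx, GABA_T, f);
      }
    }
    // neurons
    for (int i = 0; i < N; ++i) {
      const bool is_pn = i < n_pn;
      const CellPar& c = is_pn ? P : L;
      double V = y[oV + i];
      double vals[NCOL];
      if (exact_kinetics) {
        rate_row(V, vals);
      } else {
        double f; const float* nx; const float* row = lut_row(V, f, nx);
        for (int cc = 0; cc < NCOL; ++cc) vals[cc] = lerp(row, nx, cc, f);
      }
      double na_m = y[oGate + 0 * N + i], na_h = y[oGate + 1 * N + i];
      double k_n = y[oGate + 2 * N + i];
      double t_m = y[oGate + 5 * N + i], t_h = y[oGate + 6 * N + i];
      double m2 = na_m * na_m;
      double I = c.gL * (V - c.EL) + c.gKL * (V - c.EKL);
      I += c.gNa * m2 * na_m * na_h * (V - c.ENa);
      double n2 = k_n * k_n;
      I += c.gK * n2 * n2 * (V - c.EK);
      double iT = c.gT * t_m * t_m * t_h * (V - c.ECa);
      I += iT;
      if (is_pn) {
        double a_m = y[oGate + 3 * N + i], a_h = y[oGate + 4 * N + i];
        double h_m = y[oGate + 7 * N + i];
        double a2 = a_m * a_m;
        I += c.gA * a2 * a2 * a_h * (V - c.EK);
        I += c.gh * h_m * (V - c.Eh);
        I += sF[i] * (V - E_gaba) + sS[i] * (V - E_kslow);
        dy[oGate + 3 * N + i] = (vals[A_M_INF] - a_m) /
                                vals[A_M_TAU];
        dy[oGate + 4 * N + i] = (vals[A_H_INF] - a_h) /
                                vals[A_H_TAU];
        dy[oGate + 7 * N + i] = (vals[H_M_INF] - h_m) /
                                vals[H_M_TAU];
      } else {
        int j = i - n_pn;
        I += sLL[j] * (V - E_gaba) + sA[j] * (V - E_ach);
        dy[oGate + 3 * N + i] = 0.0;
        dy[oGate + 4 * N + i] = 0.0;
        dy[oGate + 7 * N + i] = 0.0;
      }
      double Istim = peak[i] * gshape[sgrp[i]] + dc[i] + I_noise[i];
      dy[oV + i] = (-I + Istim) / c.Cm;
      dy[oGate + 0 * N + i] = (vals[NA_M_INF] - na_m) /
                              vals[NA_M_TAU];
      dy[oGate + 1 * N + i] = (vals[NA_H_INF] - na_h) /
                              vals[NA_H_TAU];
      dy[oGate + 2 * N + i] = (vals[K_N_INF] - k_n) /
                              vals[K_N_TAU];
      dy[oGate + 5 * N + i] = (vals[T_M_INF] - t_m) /
                              vals[T_M_TAU];
      dy[oGate + 6 * N + i] = (vals[T_H_INF] - t_h) /
                              vals[T_H_TAU];
      double Ca = y[oCa + i];
      dy[oCa + i] = -c.A_ca * iT - (Ca - c.Ca_inf) / c.tau_ca;
    }
    // synaptic kinetic states
    for (int j = 0; j < n_ln; ++j) {
      double O = y[oOg + j];
      dy[oOg + j] = alpha_g * (1.0 - O) * Tg[j] - beta_g * O;
      double R = y[oR + j];
      dy[oR + j] = r1 * (1.0 - R) * Tg[j] - r2 * R;
      dy[oG + j] = r3 * R - r4 * y[oG + j];
    }
    for (int i = 0; i < n_pn; ++i) {
      double Ta = (t - last_spike[i] <= t_maxT && t >= last_spike[i]) ? A_T : 0.0;
      double O = y[oOa + i];
      dy[oOa + i] = alpha_a * (1.0 - O) * Ta - beta_a * O;
    }
  };

  const int n_steps = static_cast<int>(std::ceil(trial_ms / dt));
  const int v_every = record_v ? std::max(1, static_cast<int>(v_every_ms / dt)) : 0;
  const int n_rec = record_v ? (record_n > 0 ? std::min(record_n, N) : N) : 0;
  const int n_samples = record_v ? (n_steps / v_every + 1) : 0;
  NumericMatrix Vrec(record_v ? n_rec : 0, record_v ? n_samples : 0);
  int sample_idx = 0;
  if (record_v) {
    for (int i = 0; i < n_rec; ++i) Vrec(i, 0) = Y[oV + i];
    sample_idx = 1;
  }

  std::vector<int> spike_nrn;
  std::vector<double> spike_t;
  spike_nrn.reserve(4096); spike_t.reserve(4096);

  const int refresh_every = std::max(1, static_cast<int>(50.0 / dt));
  const double refractory = 2.0;

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    // per-step noise current, constant over the RK4 stages
    if (noise_sd > 0)
      for (int i = 0; i < N; ++i) I_noise[i] = noise_sd * rng();
    compute_sums(Y.data());
    deriv(Y.data(), t, k1.data());
    for (int d = 0; d < D; ++d) tmp[d] = Y[d] + 0.5 * dt * k1[d];
    deriv(tmp.data(), t + 0.5 * dt, k2.data());
    for (int d = 0; d < D; ++d) tmp[d] = Y[d] + 0.5 * dt * k2[d];
    deriv(tmp.data(), t + 0.5 * dt, k3.data());
    for (int d = 0; d < D; ++d) tmp[d] = Y[d] + dt * k3[d];
    deriv(tmp.data(), t + dt, k4.data());

    double t_new = t + dt;
    for (int i = 0; i < N; ++i) {
      double v_old = Y[oV + i];
      double v_new = v_old + dt / 6.0 * (k1[oV + i] + 2 * k2[oV + i] +
                                         2 * k3[oV + i] + k4[oV + i]);
      Y[oV + i] = v_new;
      if (v_old < 0.0 && v_new >= 0.0 && t_new - last_spike[i] >= refractory) {
        last_spike[i] = t_new;
        spike_nrn.push_back(i + 1);
        spike_t.push_back(t_new);
        if (plastic) {
          double t_abs = t0_abs + t_new;
          if (i >= n_pn) {
            int j = i - n_pn;
            if (df_pre > 0) {  // presynaptic (associative) facilitation
              for (int32_t e : out_lp[j]) {
                Flp[e] = eff_F(Flp[e], Ftlp[e], t_abs) + df_pre;
                Ftlp[e] = t_abs;
                W_lp[static_cast<size_t>(lp_post[e]) * n_ln + lp_pre[e]] =
                  static_cast<float>(g_lp[e] * Flp[e]);
              }
              for (int32_t e : out_ll[j]) {
                Fll[e] = eff_F(Fll[e], Ftll[e], t_abs) + df_pre;
                Ftll[e] = t_abs;
                W_ll[static_cast<size_t>(ll_post[e]) * n_ln + ll_pre[e]] =
                  static_cast<float>(g_ll[e] * Fll[e]);
              }
            }
            if (df_post > 0) {  // LN as postsynaptic target of LN->LN
              for (int32_t e : in_ll[j]) {
                Fll[e] = eff_F(Fll[e], Ftll[e], t_abs) + df_post;
                Ftll[e] = t_abs;
                W_ll[static_cast<size_t>(ll_post[e]) * n_ln + ll_pre[e]] =
                  static_cast<float>(g_ll[e] * Fll[e]);
              }
            }
          } else if (df_post > 0) {  // PN as postsynaptic target of LN->PN
            for (int32_t e : in_lp[i]) {
              Flp[e] = eff_F(Flp[e], Ftlp[e], t_abs) + df_post;
              Ftlp[e] = t_abs;
              W_lp[static_cast<size_t>(lp_post[e]) * n_ln + lp_pre[e]] =
                static_cast<float>(g_lp[e] * Flp[e]);
            }
          }
        }
      }
    }
    // remaining state: Ca, gates (clamped), synaptic kinetics (clamped)
    for (int d = N; d < D; ++d)
      Y[d] += dt / 6.0 * (k1[d] + 2 * k2[d] + 2 * k3[d] + k4[d]);
    for (int gblk = 0; gblk < 8; ++gblk) {
      double* g = &Y[oGate + gblk * N];
      for (int i = 0; i < N; ++i) {
        if (g[i] < 0.0) g[i] = 0.0; else if (g[i] > 1.0) g[i] = 1.0;
      }
    }
    for (int j = 0; j < n_ln; ++j) {
      double& O = Y[oOg + j];
      if (O < 0) O = 0; else if (O > 1) O = 1;
      double& R = Y[oR + j];
      if (R < 0) R = 0; else if (R > 1) R = 1;
      if (Y[oG + j] < 0) Y[oG + j] = 0;
    }
    for (int i = 0; i < n_pn; ++i) {
      double& O = Y[oOa + i];
      if (O < 0) O = 0; else if (O > 1) O = 1;
    }
    if (plastic && (step + 1) % refresh_every == 0)
      refresh_weights(t0_abs + t_new);
    if (record_v && (step + 1) % v_every == 0 && sample_idx < n_samples) {
      for (int i = 0; i < n_rec; ++i) Vrec(i, sample_idx) = Y[oV + i];
      ++sample_idx;
    }
    if ((step + 1) % 250 == 0) {
      for (int i = 0; i < N; ++i) {
        if (!std::isfinite(Y[oV + i]))
          stop("integration failure: non-finite membrane potential V[%d] at t = %.2f ms",
               i + 1, t_new);
      }
    }
  }

  return List::create(
    _["spike_neuron"] = IntegerVector(spike_nrn.begin(), spike_nrn.end()),
    _["spike_time"] = NumericVector(spike_t.begin(), spike_t.end()),
    _["F_l2p"] = NumericVector(Flp.begin(), Flp.end()),
    _["Ft_l2p"] = NumericVector(Ftlp.begin(), Ftlp.end()),
    _["F_l2l"] = NumericVector(Fll.begin(), Fll.end()),
    _["Ft_l2l"] = NumericVector(Ftll.begin(), Ftll.end()),
    _["V"] = Vrec,
    _["t_end_abs"] = t0_abs + n_steps * dt);
}
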