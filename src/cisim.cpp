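#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---- small per-fiber RNG (xorshift128+ seeded via splitmix64) so that each
// fiber's noise stream is independent of the presence of other fibers ----
struct FiberRng {
  uint64_t s0, s1;
  bool have_spare = false;
  double spare = 0.0;
  explicit FiberRng(uint64_t seed) {
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s0 = z ^ (z >> 31);
    z = seed + 2 * 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s1 = z ^ (z >> 31);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  double unif() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    uint64_t r = s1 + y;
    return ((r >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() { // Box-Muller
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double m = std::sqrt(-2.0 * std::log(u1));
    spare = m * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return m * std::cos(2.0 * M_PI * u2);
  }
};

// ---- induced current per fiber and stimulation slot --------------------
//
// cfgA: node activation per unit electrode-pair current for every steering
//   configuration in use, dim [n_nodes, n_fibers, n_cfg] (A per A).
// support: [n_fibers, n_cfg] flags; fibers outside every active support
//   receive exactly zero induced current for that slot.
// slot_ptr: CSR-style offsets (length K+1) into slot_cfg/slot_amp.
// slot_cfg: 0-based configuration index per slot entry.
// slot_amp: channel current (A) per slot entry (anodic-phase sign).
//
// Returns [n_fibers, K]: M_C times the combined activation at the node with
// the maximum absolute combined activation (signed value at that node).
// [[Rcpp::export]]
NumericMatrix cpp_slot_currents(NumericVector cfgA, IntegerVector dims,
                                LogicalMatrix support,
                                IntegerVector slot_ptr,
                                IntegerVector slot_cfg,
                                NumericVector slot_amp,
                                double M_C) {
  const int n_nodes = dims[0], n_fib = dims[1];
  const int K = slot_ptr.size() - 1;
  NumericMatrix out(n_fib, K);
  double *po = REAL(out);
  const double *A = REAL(cfgA);
  const int *sup = LOGICAL(support);
  const int *ptr = INTEGER(slot_ptr);
  const int *cfg = INTEGER(slot_cfg);
  const double *amp = REAL(slot_amp);
  for (int k = 0; k < K; ++k) {
    const int j0 = ptr[k], j1 = ptr[k + 1];
    double *ocol = po + (size_t)k * n_fib;
    for (int f = 0; f < n_fib; ++f) {
      bool any = false;
      for (int j = j0; j < j1; ++j)
        if (sup[f + (size_t)cfg[j] * n_fib]) { any = true; break; }
      if (!any) continue;
      double best = 0.0, best_abs = 0.0;
      if (j1 - j0 == 1) { // single active configuration (sequential coding)
        const double *col = A + (size_t)cfg[j0] * n_nodes * n_fib
                              + (size_t)f * n_nodes;
        const double a0 = amp[j0];
        for (int a = 0; a < n_nodes; ++a) {
          double acc = a0 * col[a];
          double ab = std::fabs(acc);
          if (ab > best_abs) { best_abs = ab; best = acc; }
        }
      } else {
        for (int a = 0; a < n_nodes; ++a) {
          double acc = 0.0;
          for (int j = j0; j < j1; ++j)
            acc += amp[j] * A[(size_t)cfg[j] * n_nodes * n_fib
                              + (size_t)f * n_nodes + a];
          double ab = std::fabs(acc);
          if (ab > best_abs) { best_abs = ab; best = acc; }
        }
      }
      ocol[f] = M_C * best;
    }
  }
  return out;
}

// ---- dual adaptive integrate-and-fire population ------------------------
//
// Two circuits per fiber (cathodic-excitatory, anodic-excitatory) share the
// induced current I(t) but receive phase-split drives:
//   cathodic: -(I_minus + beta * I_plus)
//   anodic:     I_plus + beta * I_minus
// Membrane: C dV/dt = -g_leak V - I_sub - I_supra + I_noise + I_stim, with
// g_leak = C / tau_m, integrated with the exponential-Euler update (exact
// for the piecewise-constant drives between grid points). A threshold
// crossing in either circuit emits one spike, resets both circuits and
// silences the fiber for the absolute refractory period.
//
// The Ornstein-Uhlenbeck noise current is refreshed on its own subgrid
// (every noise_dt_us at most, aligned to integration steps) with the exact
// discrete OU update for the elapsed time, and held constant in between;
// its correlation time is much longer than a pulse phase, so the coarser
// refresh does not change the statistics seen by the membrane.
//
// Fibers that provably cannot spike are skipped: the membrane voltage is
// bounded by max|drive|/g plus a 6-sigma stationary noise excursion, and
// the adaptation currents only lower it. If that bound stays below
// threshold the fiber emits no spikes (up to a ~1e-9 noise tail).
//
// I is [n_fibers, K] (anodic-phase value per biphasic slot); each slot k
// occupies [onset_us[k], onset_us[k] + 2*phase_us) with the cathodic phase
// first (drive -I) and the anodic phase second (drive +I).
//
// params: c(beta, C_cath, C_anod, tau_m_us, v_thr, v_reset, arp_us,
//           tau_sub_us, q_sub, tau_supra_us, a_supra,
//           tau_noise_us, sigma_noise)
// [[Rcpp::export]]
List cpp_lif_population(NumericMatrix I, NumericVector onset_us,
                        double phase_us, double duration_us,
                        NumericVector params,
                        double dt_pulse_us, double dt_gap_us,
                        NumericVector seeds, double noise_dt_us = 36.0) {
  const int n_fib = I.nrow(), K = I.ncol();
  const double beta = params[0];
  const double Cc = params[1], Ca = params[2];
  const double tau_m = params[3] * 1e-6;
  const double v_thr = params[4], v_reset = params[5];
  const double arp = params[6] * 1e-6;
  const double tau_sub = params[7] * 1e-6, q_sub = params[8];
  const double tau_supra = params[9] * 1e-6, a_supra = params[10];
  const double tau_noise = params[11] * 1e-6, sigma = params[12];
  const double gc = Cc / tau_m, ga = Ca / tau_m;
  const double *pI = REAL(I);

  // shared integration grid: (dt, slot index or -1, sign)
  std::vector<double> step_dt;
  std::vector<int> step_slot;
  std::vector<double> step_sign;
  double t = 0.0;
  const double ph = phase_us * 1e-6, dur = duration_us * 1e-6;
  auto add_span = [&](double len, int slot, double sign, double dt_target) {
    if (len <= 1e-12) return;
    int ns = (int)std::ceil(len / (dt_target * 1e-6) - 1e-9);
    if (ns < 1) ns = 1;
    double dt = len / ns;
    for (int i = 0; i < ns; ++i) {
      step_dt.push_back(dt);
      step_slot.push_back(slot);
      step_sign.push_back(sign);
    }
  };
  for (int k = 0; k < K; ++k) {
    double on = onset_us[k] * 1e-6;
    if (on > t) add_span(on - t, -1, 0.0, dt_gap_us);
    add_span(ph, k, -1.0, dt_pulse_us); // cathodic phase of the slot
    add_span(ph, k, +1.0, dt_pulse_us); // anodic phase
    t = on + 2.0 * ph;
  }
  if (dur > t) add_span(dur - t, -1, 0.0, dt_gap_us);
  const int n_steps = step_dt.size();

  // per-step exponential factors
  std::vector<double> eL(n_steps), eSub(n_steps), eSup(n_steps);
  for (int i = 0; i < n_steps; ++i) {
    double dt = step_dt[i];
    eL[i] = std::exp(-dt / tau_m);
    eSub[i] = std::exp(-dt / tau_sub);
    eSup[i] = std::exp(-dt / tau_supra);
  }

  // stationary membrane-noise sd and the no-spike voltage bound
  const double sd_v = (sigma / gc) *
    std::sqrt(tau_noise / (tau_noise + tau_m));
  const bool noisy = sigma > 0.0;
  const double noise_dt = noise_dt_us * 1e-6;

  List spikes(n_fib);
  for (int f = 0; f < n_fib; ++f) {
    double maxI = 0.0;
    for (int k = 0; k < K; ++k) {
      double v = std::fabs(pI[f + (size_t)k * n_fib]);
      if (v > maxI) maxI = v;
    }
    if (maxI / gc + 6.0 * sd_v + v_reset < v_thr) {
      spikes[f] = NumericVector(0);
      continue;
    }
    FiberRng rng((uint64_t)seeds[f]);
    double Vc = v_reset, Va = v_reset;
    double subC = 0.0, subA = 0.0, supra = 0.0;
    double noiC = 0.0, noiA = 0.0;
    double arp_until = -1.0, since_noise = 1e9;
    std::vector<double> st;
    double tt = 0.0;
    for (int i = 0; i < n_steps; ++i) {
      double dt = step_dt[i];
      double drvC = 0.0, drvA = 0.0;
      int k = step_slot[i];
      if (k >= 0) {
        double Ik = pI[f + (size_t)k * n_fib] * step_sign[i];
        double Ip = Ik > 0 ? Ik : 0.0, Im = Ik < 0 ? Ik : 0.0;
        drvC = -(Im + beta * Ip);
        drvA = Ip + beta * Im;
      }
      if (noisy) {
        since_noise += dt;
        if (since_noise >= noise_dt - 1e-12) {
          double e = std::exp(-since_noise / tau_noise);
          double sc = sigma * std::sqrt(1.0 - e * e);
          noiC = noiC * e + sc * rng.norm();
          noiA = noiA * e + sc * rng.norm();
          since_noise = 0.0;
        }
      }
      supra *= eSup[i];
      subC = subC * eSub[i] + q_sub * Vc * (1.0 - eSub[i]);
      subA = subA * eSub[i] + q_sub * Va * (1.0 - eSub[i]);
      if (tt < arp_until) {
        Vc = v_reset; Va = v_reset;
      } else {
        double IinC = drvC - subC - supra + noiC;
        double IinA = drvA - subA - supra + noiA;
        Vc = Vc * eL[i] + (IinC / gc) * (1.0 - eL[i]);
        Va = Va * eL[i] + (IinA / ga) * (1.0 - eL[i]);
        if (Vc >= v_thr || Va >= v_thr) {
          st.push_back(tt + dt);
          Vc = v_reset; Va = v_reset;
          supra += a_supra;
          arp_until = tt + dt + arp;
        }
      }
      tt += dt;
    }
    spikes[f] = NumericVector(st.begin(), st.end());
  }
  return spikes;
}
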