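#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of the conductance-based leaky integrate-and-fire
// neuron:
//   tau dV/dt = V_rest - V - R * I_ext(t),
//   I_ext(t)  = I_gj(t) + (V - V_rev_inh) * g_inh(t)
// with threshold/reset spiking and a temporarily increased time constant
// (tau_refractory) for refractory_duration after each spike.
//
// Units: V in mV, time in ms, I in pA, g in nS, R in MOhm
// (R[MOhm] * I[pA] = 1e-3 mV, hence the 1e-3 scale factor).
// Outward current is positive and hyperpolarizes (the minus sign).
// [[Rcpp::export]]
List lif_euler_cpp(NumericVector I_gj, NumericVector g_inh,
                   double dt_ms, double tau_ms, double R_mohm,
                   double V_rest, double V_th, double V_reset,
                   double tau_refractory_ms, double refractory_ms,
                   double V_rev_inh, double V0) {
  const R_xlen_t n = I_gj.size();
  if (g_inh.size() != n) stop("I_gj and g_inh must have equal length");
  NumericVector V(n);
  std::vector<double> spikes;
  const double RI = R_mohm * 1e-3; // mV per pA
  double v = V0;
  double refr_until = -1.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double t = i * dt_ms;
    const double tau = (t < refr_until) ? tau_refractory_ms : tau_ms;
    const double I_ext = I_gj[i] + (v - V_rev_inh) * g_inh[i];
    v += dt_ms / tau * (V_rest - v - RI * I_ext);
    if (!std::isfinite(v))
      stop("membrane potential overflow: dt = %g ms is too large", dt_ms);
    if (v >= V_th) {
      spikes.push_back((i + 1) * dt_ms); // spike assigned to end of step
      v = V_reset;
      refr_until = (i + 1) * dt_ms + refractory_ms;
    }
    V[i] = v;
  }
  return List::create(_["V_mV"] = V, _["spike_times_ms"] = wrap(spikes));
}

// ---------------------------------------------------------------------------
// Hartigan's dip statistic.
//
// dip(F_n) = min over unimodal distribution functions G of sup_x |F_n - G|.
// Computed directly from the definition by bisection on t: G exists within
// the +/- t band around the ECDF iff, for some mode position, a convex
// function fits the band to the left of the mode and a concave function fits
// it to the right. Band feasibility for the convex side holds iff the lower
// convex hull of the upper band bounds stays above the lower bounds
// (the hull is the largest convex function below the upper bounds);
// the concave side is the mirror image. An atom of G is permitted at the
// mode, which splits that point's constraint into its left-limit and value
// parts. O(n^2) per bisection step; bisection to 1e-12.

// Lower convex hull of (x, hi) evaluated at every x; returns false early if
// the hull drops below lo anywhere.
static bool convex_feasible(const std::vector<double>& x,
                            const std::vector<double>& hi,
                            const std::vector<double>& lo) {
  const int k = (int)x.size();
  if (k <= 2) { // any 1-2 point band set admits a line if bands are nonempty
    for (int i = 0; i < k; ++i) if (hi[i] < lo[i]) return false;
    return true;
  }
  for (int i = 0; i < k; ++i) if (hi[i] < lo[i]) return false;
  // build lower hull of (x, hi), checking lo under each hull segment
  std::vector<int> st; st.reserve(k);
  for (int i = 0; i < k; ++i) {
    while (st.size() >= 2) {
      int a = st[st.size() - 2], b = st[st.size() - 1];
      // remove b if it lies above segment a-i
      double cross = (x[b] - x[a]) * (hi[i] - hi[a]) -
                     (hi[b] - hi[a]) * (x[i] - x[a]);
      if (cross <= 0.0) st.pop_back(); else break;
    }
    st.push_back(i);
  }
  // hull value at each point must be >= lo
  int seg = 0;
  for (int i = 0; i < k; ++i) {
    while (seg + 1 < (int)st.size() && x[st[seg + 1]] < x[i]) ++seg;
    double hv;
    if (i == st[seg] || seg + 1 >= (int)st.size()) hv = hi[st[seg]];
    else {
      int a = st[seg], b = st[seg + 1];
      hv = hi[a] + (hi[b] - hi[a]) * (x[i] - x[a]) / (x[b] - x[a]);
    }
    if (hv < lo[i] - 1e-12) return false;
  }
  return true;
}

static bool concave_feasible(const std::vector<double>& x,
                             const std::vector<double>& hi,
                             const std::vector<double>& lo) {
  // mirror: concave within [lo, hi] iff -G convex within [-hi, -lo]
  const int k = (int)x.size();
  std::vector<double> nhi(k), nlo(k);
  for (int i = 0; i < k; ++i) { nhi[i] = -lo[i]; nlo[i] = -hi[i]; }
  return convex_feasible(x, nhi, nlo);
}

// band feasibility at tolerance t for ECDF with unique points xu,
// left-limit values Fm and values Fv (as probabilities)
static bool dip_feasible(const std::vector<double>& xu,
                         const std::vector<double>& Fm,
                         const std::vector<double>& Fv, double t) {
  const int u = (int)xu.size();
  std::vector<double> x1, hi1, lo1, x2, hi2, lo2;
  // mode candidates: an atom of G at data point m, or a mode inside the gap
  // (x_m, x_{m+1}). For a gap mode the junction point (where F is flat at
  // Fv[m]) constrains *both* halves: the convex half may not overshoot it
  // and the concave half may not rise after being flat across it. Its exact
  // position within the gap is free, so a few positions are tried.
  auto try_mode = [&](int m, bool atom, double xstar) -> bool {
    x1.clear(); hi1.clear(); lo1.clear();
    x2.clear(); hi2.clear(); lo2.clear();
    // left (convex) part: points 0..m
    for (int i = 0; i <= m; ++i) {
      double hi_i, lo_i;
      if (atom && i == m) { // left limit only; the atom covers the jump
        hi_i = Fm[i] + t; lo_i = Fm[i] - t;
      } else {
        hi_i = Fm[i] + t; lo_i = Fv[i] - t;
      }
      if (lo_i > 0.0 && hi_i < lo_i) return false;
      x1.push_back(xu[i]);
      hi1.push_back(hi_i);
      lo1.push_back(lo_i < 0.0 ? 0.0 : lo_i); // G >= 0, clamp is convex-safe
    }
    if (!atom) { // junction point inside the gap
      x1.push_back(xstar);
      hi1.push_back(Fv[m] + t);
      lo1.push_back(Fv[m] - t < 0.0 ? 0.0 : Fv[m] - t);
      x2.push_back(xstar);
      hi2.push_back(Fv[m] + t > 1.0 ? 1.0 : Fv[m] + t);
      lo2.push_back(Fv[m] - t);
    }
    // right (concave) part: points m..u-1 (atom mode: value constraint at m)
    const int r0 = atom ? m : m + 1;
    for (int i = r0; i < u; ++i) {
      double hi_i, lo_i;
      if (atom && i == m) {
        hi_i = Fv[i] + t; lo_i = Fv[i] - t;
      } else {
        hi_i = Fm[i] + t; lo_i = Fv[i] - t;
      }
      if (hi_i < 1.0 && hi_i < lo_i) return false;
      x2.push_back(xu[i]);
      hi2.push_back(hi_i > 1.0 ? 1.0 : hi_i); // G <= 1
      lo2.push_back(lo_i);
    }
    return convex_feasible(x1, hi1, lo1) && concave_feasible(x2, hi2, lo2);
  };
  for (int m = 0; m < u; ++m) {
    if (try_mode(m, true, 0.0)) return true;
    if (m + 1 < u) {
      const double a = xu[m], b = xu[m + 1], w = b - a;
      for (double f : {1e-9, 0.5, 1.0 - 1e-9})
        if (try_mode(m, false, a + f * w)) return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector x_sorted) {
  const R_xlen_t n = x_sorted.size();
  if (n < 2) return 0.0;
  // collapse ties into unique points with left-limit / value ECDF heights
  std::vector<double> xu, Fm, Fv;
  R_xlen_t i = 0;
  while (i < n) {
    R_xlen_t j = i;
    while (j + 1 < n && x_sorted[j + 1] == x_sorted[i]) ++j;
    xu.push_back(x_sorted[i]);
    Fm.push_back((double)i / n);
    Fv.push_back((double)(j + 1) / n);
    i = j + 1;
  }
  if (xu.size() == 1) return 0.0; // point mass: a unimodal atom fits exactly
  double lo = 0.0, hi = 0.5;
  for (int it = 0; it < 45; ++it) {
    double mid = 0.5 * (lo + hi);
    if (dip_feasible(xu, Fm, Fv, mid)) hi = mid; else lo = mid;
  }
  return hi;
}
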