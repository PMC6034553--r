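// Implicit compartmental cable engine.
//
// Units: mV, ms, nA, uS, nF, MOhm (1/uS), um^2. With these, C dV/dt (nF*mV/ms)
// and g*V (uS*mV) are both nA, so no conversion factors appear below.
//
// The tree is supplied in parent-before-child order (parent[i] < i, root has
// parent -1), which allows a single backward elimination + forward substitution
// per time step (Hines ordering). Backward Euler is used throughout: membrane
// and axial terms are implicit in V; gating variables and the NMDA Mg-block
// factor are advanced from the previous-step voltage (staggered update).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

inline double gate_inf(double v, double vhalf, double k) {
  // k > 0: activation-like (opens with depolarisation); k < 0: inactivation
  return 1.0 / (1.0 + std::exp(-(v - vhalf) / k));
}

inline double gate_tau(double v, double tmin, double tamp, double tv, double tk) {
  if (tamp <= 0.0) return tmin;
  double x = (v - tv) / tk;
  return tmin + 2.0 * tamp / (std::exp(x) + std::exp(-x));
}

// column layout of the channel-instance matrix (one row per instance)
enum ChanCol {
  C_COMP = 0, C_GBAR, C_EREV, C_P, C_Q,
  C_AVH, C_AK, C_ATMIN, C_ATAMP, C_ATV, C_ATK,
  C_IVH, C_IK, C_ITMIN, C_ITAMP, C_ITV, C_ITK,
  C_CAGATED, C_CAKD, C_CAHILL, C_ISCA, C_NCOL
};

inline double ipow(double x, int p) {
  double r = 1.0;
  for (int i = 0; i < p; ++i) r *= x;
  return r;
}

} // namespace

// Solve the tree-structured linear system  d[i]*V[i] - ga[i]*(V[parent]) ... = rhs
// in place. d is the diagonal already containing +ga couplings.
static void hines_solve(const IntegerVector &parent, const NumericVector &ga,
                        std::vector<double> &d, std::vector<double> &rhs,
                        std::vector<double> &v) {
  const int n = d.size();
  for (int i = n - 1; i > 0; --i) {
    int p = parent[i];
    double f = ga[i] / d[i];
    d[p] -= ga[i] * f;
    rhs[p] += rhs[i] * f;
  }
  v[0] = rhs[0] / d[0];
  for (int i = 1; i < n; ++i) {
    v[i] = (rhs[i] + ga[i] * v[parent[i]]) / d[i];
  }
}

// [[Rcpp::export]]
List engine_simulate(IntegerVector parent,   // 0-based, -1 for root; parent[i] < i
                     NumericVector ga,       // uS, axial conductance to parent (root: 0)
                     NumericVector cm,       // nF
                     NumericVector gl,       // uS (leak)
                     NumericVector el,       // mV (leak reversal per compartment)
                     NumericVector area,     // um^2 (for Ca influx scaling)
                     NumericMatrix syn,      // cols: comp, gmax_uS, tr, td, N, esyn, onset, vdep, gamma, mg_n
                     NumericMatrix stim,     // cols: comp, onset, offset, amp_nA
                     NumericMatrix chan,     // channel instances, C_NCOL cols
                     NumericVector ca_tau,   // per comp; <= 0 means no Ca pool
                     NumericVector ca_influx,
                     double ca_rest,
                     double dt, double duration, double v_init,
                     IntegerVector record) { // 0-based compartment indices
  const int n = parent.size();
  const int nstep = (int)std::lround(duration / dt);
  const int nsyn = syn.nrow(), nstim = stim.nrow(), nchan = chan.nrow();
  const int nrec = record.size();

  std::vector<double> v(n, v_init), d(n), rhs(n), ica(n, 0.0), ca(n, ca_rest);
  // gating state: activation m, inactivation h per channel instance
  std::vector<double> m(nchan, 0.0), h(nchan, 1.0);
  for (int c = 0; c < nchan; ++c) {
    int ci = (int)chan(c, C_COMP);
    if (chan(c, C_CAGATED) > 0.5) {
      double kd = chan(c, C_CAKD), hill = chan(c, C_CAHILL);
      double cr = ipow(ca[ci] / kd, (int)hill);
      m[c] = cr / (1.0 + cr);
    } else {
      m[c] = gate_inf(v_init, chan(c, C_AVH), chan(c, C_AK));
    }
    if (chan(c, C_Q) > 0.5) h[c] = gate_inf(v_init, chan(c, C_IVH), chan(c, C_IK));
  }

  NumericMatrix out(nstep + 1, nrec);
  NumericVector tout(nstep + 1);
  for (int r = 0; r < nrec; ++r) out(0, r) = v[record[r]];

  for (int s = 1; s <= nstep; ++s) {
    double t = s * dt; // solve for state at time t
    for (int i = 0; i < n; ++i) {
      d[i] = cm[i] / dt + gl[i];
      rhs[i] = cm[i] / dt * v[i] + gl[i] * el[i];
      ica[i] = 0.0;
    }
    // axial couplings on the diagonal
    for (int i = 1; i < n; ++i) {
      d[i] += ga[i];
      d[parent[i]] += ga[i];
    }
    // synapses: double-exponential conductance, implicit in V, B from v(t-dt)
    for (int k = 0; k < nsyn; ++k) {
      double ts = t - syn(k, 6);
      if (ts <= 0.0) continue;
      double g = syn(k, 1) * syn(k, 4) *
                 (std::exp(-ts / syn(k, 3)) - std::exp(-ts / syn(k, 2)));
      if (g <= 0.0) continue;
      int ci = (int)syn(k, 0);
      if (syn(k, 7) > 0.5) { // voltage-dependent Mg block
        g /= 1.0 + syn(k, 9) * std::exp(-syn(k, 8) * v[ci]);
      }
      d[ci] += g;
      rhs[ci] += g * syn(k, 5);
    }
    // current steps
    for (int k = 0; k < nstim; ++k) {
      if (t > stim(k, 1) && t <= stim(k, 2)) rhs[(int)stim(k, 0)] += stim(k, 3);
    }
    // channels: advance gates from previous V/Ca, then add conductance
    for (int c = 0; c < nchan; ++c) {
      int ci = (int)chan(c, C_COMP);
      double vv = v[ci];
      double minf, mtau;
      if (chan(c, C_CAGATED) > 0.5) {
        double cr = ipow(ca[ci] / chan(c, C_CAKD), (int)chan(c, C_CAHILL));
        minf = cr / (1.0 + cr);
        mtau = chan(c, C_ATMIN);
      } else {
        minf = gate_inf(vv, chan(c, C_AVH), chan(c, C_AK));
        mtau = gate_tau(vv, chan(c, C_ATMIN), chan(c, C_ATAMP), chan(c, C_ATV), chan(c, C_ATK));
      }
      m[c] = minf + (m[c] - minf) * std::exp(-dt / mtau);
      double open = ipow(m[c], (int)chan(c, C_P));
      if (chan(c, C_Q) > 0.5) {
        double hinf = gate_inf(vv, chan(c, C_IVH), chan(c, C_IK));
        double htau = gate_tau(vv, chan(c, C_ITMIN), chan(c, C_ITAMP), chan(c, C_ITV), chan(c, C_ITK));
        h[c] = hinf + (h[c] - hinf) * std::exp(-dt / htau);
        open *= ipow(h[c], (int)chan(c, C_Q));
      }
      double g = chan(c, C_GBAR) * open;
      d[ci] += g;
      rhs[ci] += g * chan(c, C_EREV);
      if (chan(c, C_ISCA) > 0.5) ica[ci] += g; // reversal applied after solve
    }

    hines_solve(parent, ga, d, rhs, v);

    if (!std::isfinite(v[0])) {
      stop("integration failure: non-finite state at step %d (t = %.3f ms)", s, t);
    }
    // calcium pool update (exponential Euler on the decay, explicit influx)
    for (int i = 0; i < n; ++i) {
      if (ca_tau[i] <= 0.0) continue;
      double ica_nA = ica[i] * (v[i] - 130.0); // Ca reversal fixed at +130 mV
      double influx = ca_influx[i] * std::max(0.0, -ica_nA) / area[i];
      double cinf = ca_rest + influx * ca_tau[i];
      ca[i] = cinf + (ca[i] - cinf) * std::exp(-dt / ca_tau[i]);
    }
    tout[s] = t;
    for (int r = 0; r < nrec; ++r) out(s, r) = v[record[r]];
  }
  return List::create(_["t"] = tout, _["v"] = out);
}

// Steady-state solve of the passive tree: (G_leak + G_axial) V = I.
// Returns the voltage deviation (mV) produced by injected currents (nA).
// [[Rcpp::export]]
NumericVector engine_steady(IntegerVector parent, NumericVector ga,
                            NumericVector gl, NumericVector inj) {
  const int n = parent.size();
  std::vector<double> d(n), rhs(n), v(n);
  for (int i = 0; i < n; ++i) { d[i] = gl[i]; rhs[i] = inj[i]; }
  for (int i = 1; i < n; ++i) { d[i] += ga[i]; d[parent[i]] += ga[i]; }
  hines_solve(parent, ga, d, rhs, v);
  return NumericVector(v.begin(), v.end());
}
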