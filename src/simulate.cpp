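#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Single-compartment conductance-based network dynamics: Hodgkin-Huxley
// Na/K spiking currents (instantaneous Na activation), leak, a slow
// spike-triggered K adaptation conductance (burst termination), exponential
// synaptic conductances routed through the structural adjacency, and
// independent Poisson trains of excitatory presynaptic potentials per
// neuron. Fixed-step Heun (RK2) integration; gating rate functions are
// tabulated over the voltage range and linearly interpolated. Membrane
// units: mV, ms, uF/cm^2, mS/cm^2.

namespace {

struct RateTables {
  double vmin, vmax, step, inv_step;
  std::vector<double> minf3, ah, bh, an, bn;
  void build() {
    vmin = -130.0;
    vmax = 80.0;
    step = 0.05;
    inv_step = 1.0 / step;
    const int n = (int)((vmax - vmin) / step) + 2;
    minf3.resize(n);
    ah.resize(n);
    bh.resize(n);
    an.resize(n);
    bn.resize(n);
    for (int i = 0; i < n; ++i) {
      const double v = vmin + i * step;
      double am;
      if (std::fabs(v + 35.0) < 1e-7)
        am = 1.0; // limit of -0.1(v+35)/(exp(-0.1(v+35))-1)
      else
        am = -0.1 * (v + 35.0) / (std::exp(-0.1 * (v + 35.0)) - 1.0);
      const double bm = 4.0 * std::exp(-(v + 60.0) / 18.0);
      const double mi = am / (am + bm);
      minf3[i] = mi * mi * mi;
      ah[i] = 0.07 * std::exp(-(v + 58.0) / 20.0);
      bh[i] = 1.0 / (std::exp(-0.1 * (v + 28.0)) + 1.0);
      if (std::fabs(v + 34.0) < 1e-7)
        an[i] = 0.1;
      else
        an[i] = -0.01 * (v + 34.0) / (std::exp(-0.1 * (v + 34.0)) - 1.0);
      bn[i] = 0.125 * std::exp(-(v + 44.0) / 80.0);
    }
  }
  inline double clampv(double v) const {
    if (std::isnan(v)) return vmin;
    if (v < vmin) return vmin;
    if (v > vmax - step) return vmax - step;
    return v;
  }
};

struct Derivs {
  double dv, dh, dn;
};

inline Derivs rhs(const RateTables &tab, double v, double h, double nvar,
                  double ga, double ge, double gi, double cm_inv, double gl,
                  double el, double gna, double ena, double gk, double ek,
                  double ea, double ee, double ei, double phi) {
  const double vc = tab.clampv(v);
  const double pos = (vc - tab.vmin) * tab.inv_step;
  const int i0 = (int)pos;
  const double w = pos - i0;
  const double m3 = tab.minf3[i0] + w * (tab.minf3[i0 + 1] - tab.minf3[i0]);
  const double ahv = tab.ah[i0] + w * (tab.ah[i0 + 1] - tab.ah[i0]);
  const double bhv = tab.bh[i0] + w * (tab.bh[i0 + 1] - tab.bh[i0]);
  const double anv = tab.an[i0] + w * (tab.an[i0 + 1] - tab.an[i0]);
  const double bnv = tab.bn[i0] + w * (tab.bn[i0 + 1] - tab.bn[i0]);
  const double n4 = nvar * nvar * nvar * nvar;
  const double i_ion = gl * (v - el) + gna * m3 * h * (v - ena) +
                       gk * n4 * (v - ek) + ga * (v - ea) + ge * (v - ee) +
                       gi * (v - ei);
  Derivs d;
  d.dv = -i_ion * cm_inv;
  d.dh = phi * (ahv * (1.0 - h) - bhv * h);
  d.dn = phi * (anv * (1.0 - nvar) - bnv * nvar);
  return d;
}

} // namespace

// [[Rcpp::export]]
List simulate_hh_cpp(IntegerVector edge_src, IntegerVector edge_tgt,
                     IntegerVector types, List params, double duration_s,
                     double dt_ms) {
  const int n = types.size();
  const double cm = as<double>(params["cm"]);
  const double gl = as<double>(params["g_leak"]);
  const double el = as<double>(params["e_leak"]);
  const double gna = as<double>(params["g_na"]);
  const double ena = as<double>(params["e_na"]);
  const double gk = as<double>(params["g_k"]);
  const double ek = as<double>(params["e_k"]);
  const double phi = as<double>(params["phi"]);
  const double a_inc = as<double>(params["adapt_increment"]);
  const double tau_a = as<double>(params["tau_adapt"]) * 1000.0; // s -> ms
  const double ea = ek;
  const double tau_e = as<double>(params["tau_exc"]) * 1000.0;
  const double tau_i = as<double>(params["tau_inh"]) * 1000.0;
  const double ee = as<double>(params["e_exc"]);
  const double ei = as<double>(params["e_inh"]);
  const double w_ee = as<double>(params["w_ee"]);
  const double w_ei = as<double>(params["w_ei"]);
  const double w_ie = as<double>(params["w_ie"]);
  const double w_ii = as<double>(params["w_ii"]);
  const double w_ext = as<double>(params["w_ext"]);
  const double nu_ext = as<double>(params["nu_ext"]); // Hz
  const double v_thresh = as<double>(params["v_thresh"]);
  const double refrac = as<double>(params["refractory"]) * 1000.0;
  const double tau_adapt_cv = as<double>(params["tau_adapt_cv"]);
  const double e_leak_sd = as<double>(params["e_leak_sd"]);

  const double duration = duration_s * 1000.0; // ms
  const long n_steps = (long)std::ceil(duration / dt_ms);
  const double cm_inv = 1.0 / cm;
  const double dec_e = std::exp(-dt_ms / tau_e);
  const double dec_i = std::exp(-dt_ms / tau_i);
  const double rate_ms = nu_ext / 1000.0; // events per ms

  RateTables tab;
  tab.build();

  // CSR adjacency: outgoing targets per source
  std::vector<int> ptr(n + 1, 0), tgt(edge_src.size());
  for (int e = 0; e < edge_src.size(); ++e) ptr[edge_src[e]]++; // 1-based src
  for (int i = 0; i < n; ++i) ptr[i + 1] += ptr[i];
  {
    std::vector<int> cur(ptr.begin(), ptr.end() - 1);
    for (int e = 0; e < edge_src.size(); ++e)
      tgt[cur[edge_src[e] - 1]++] = edge_tgt[e] - 1;
  }

  std::vector<double> v(n), h(n), nv(n), ga(n, 0.0), ge(n, 0.0), gi(n, 0.0);
  std::vector<double> next_ext(n), last_spike(n, -1e18);
  std::vector<double> dec_a(n), el_i(n);
  std::vector<char> above(n, 0);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    // per-neuron heterogeneity: lognormal adaptation time constant,
    // Gaussian leak reversal (staggers burst-recovery clocks)
    const double tau_i_ms =
        tau_a * std::exp(tau_adapt_cv * norm_rand() -
                         0.5 * tau_adapt_cv * tau_adapt_cv);
    dec_a[i] = std::exp(-dt_ms / tau_i_ms);
    el_i[i] = el + e_leak_sd * norm_rand();
    v[i] = el_i[i] + 5.0 * (unif_rand() - 0.5);
    const double vc = tab.clampv(v[i]);
    const double pos = (vc - tab.vmin) * tab.inv_step;
    const int i0 = (int)pos;
    h[i] = tab.ah[i0] / (tab.ah[i0] + tab.bh[i0]);
    nv[i] = tab.an[i0] / (tab.an[i0] + tab.bn[i0]);
    next_ext[i] = rate_ms > 0 ? exp_rand() / rate_ms : 2.0 * duration;
  }

  std::vector<int> spk_neuron;
  std::vector<double> spk_time;
  std::vector<int> fired;
  fired.reserve(n);
  // neuron 1 voltage sampled every ms (diagnostics / integrator checks)
  const long rec_stride = std::max(1L, (long)(1.0 / dt_ms));
  std::vector<double> v_trace;
  v_trace.reserve(n_steps / rec_stride + 1);

  for (long s = 0; s < n_steps; ++s) {
    const double t = s * dt_ms;
    if (s % rec_stride == 0) v_trace.push_back(v[0]);
    // external Poisson EPSP trains (exponential inter-event skipping)
    if (rate_ms > 0) {
      for (int i = 0; i < n; ++i) {
        while (next_ext[i] <= t + dt_ms) {
          ge[i] += w_ext;
          next_ext[i] += exp_rand() / rate_ms;
        }
      }
    }
    fired.clear();
    for (int i = 0; i < n; ++i) {
      const double ge0 = ge[i], gi0 = gi[i], ga0 = ga[i];
      Derivs k1 = rhs(tab, v[i], h[i], nv[i], ga0, ge0, gi0, cm_inv, gl,
                      el_i[i], gna, ena, gk, ek, ea, ee, ei, phi);
      const double v1 = v[i] + dt_ms * k1.dv;
      const double h1 = h[i] + dt_ms * k1.dh;
      const double n1 = nv[i] + dt_ms * k1.dn;
      Derivs k2 = rhs(tab, v1, h1, n1, ga0, ge0, gi0, cm_inv, gl, el_i[i],
                      gna, ena, gk, ek, ea, ee, ei, phi);
      v[i] += 0.5 * dt_ms * (k1.dv + k2.dv);
      h[i] += 0.5 * dt_ms * (k1.dh + k2.dh);
      nv[i] += 0.5 * dt_ms * (k1.dn + k2.dn);
      ge[i] = ge0 * dec_e;
      gi[i] = gi0 * dec_i;
      ga[i] = ga0 * dec_a[i];
      const bool now_above = v[i] >= v_thresh;
      if (now_above && !above[i] && (t - last_spike[i]) >= refrac) {
        last_spike[i] = t;
        spk_neuron.push_back(i + 1);
        spk_time.push_back((t + dt_ms) / 1000.0);
        ga[i] += a_inc;
        fired.push_back(i);
      }
      above[i] = now_above;
    }
    // synaptic routing of this step's spikes (arrive next step)
    for (size_t f = 0; f < fired.size(); ++f) {
      const int i = fired[f];
      const bool inhib = types[i] == 2; // 0 = excitatory, 1 = DA, 2 = inhibitory
      for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
        const int post = tgt[e];
        const bool post_inhib = types[post] == 2;
        if (inhib)
          gi[post] += post_inhib ? w_ii : w_ie;
        else
          ge[post] += post_inhib ? w_ei : w_ee;
      }
    }
    if ((s & 2047) == 0) {
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(v[i]))
          stop("numerical divergence at t = %.3f ms (neuron %d)", t, i + 1);
      }
    }
  }
  return List::create(_["neuron"] = wrap(spk_neuron),
                      _["time"] = wrap(spk_time),
                      _["v_trace"] = wrap(v_trace),
                      _["v_dt"] = rec_stride * dt_ms / 1000.0);
}
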