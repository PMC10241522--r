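// Single-compartment conductance-based neuron: Nav (m^3 h), low-threshold
// delayed rectifier (n^4), high-threshold fast Kv3 (p^2), inactivating
// A-type (a^3 b), leak and bias current.
//
// Units: mV, ms, nS, pF, pA (nS * mV = pA; pA / pF = mV/ms).
// Integration: exponential Euler for gates, forward Euler for V.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Gate {
  double vhalf, slope;             // Boltzmann steady state
  double tau_base, tau_amp;        // bell-shaped voltage-dependent tau (ms)
  double tau_vhalf, tau_sigma;
  double xinf(double v) const {
    return 1.0 / (1.0 + std::exp(-(v - vhalf) / slope));
  }
  double tau(double v) const {
    if (tau_amp == 0.0) return tau_base;
    double u = (v - tau_vhalf) / tau_sigma;
    return tau_base + tau_amp / (std::exp(u) + std::exp(-u));
  }
};

static Gate as_gate(const List& g) {
  Gate out;
  out.vhalf = as<double>(g["vhalf"]);
  out.slope = as<double>(g["slope"]);
  out.tau_base = as<double>(g["tau_base"]);
  out.tau_amp = as<double>(g["tau_amp"]);
  out.tau_vhalf = as<double>(g["tau_vhalf"]);
  out.tau_sigma = as<double>(g["tau_sigma"]);
  return out;
}

static inline double step_gate(double x, double v, const Gate& g, double dt,
                               double rate_scale) {
  double tau = g.tau(v) / rate_scale;
  return g.xinf(v) + (x - g.xinf(v)) * std::exp(-dt / tau);
}

// [[Rcpp::export(name = ".hh_simulate")]]
List hh_simulate(List params, NumericVector stim, double dt, int record_every,
                 double temperature, std::string mode,
                 bool na_disabled = false, bool leak_subtract = false) {
  const double cap = as<double>(params["capacitance"]);
  const List leak = params["leak"];
  const double g_leak0 = as<double>(leak["g"]);
  const double e_leak = as<double>(leak["e"]);

  const List nav = params["nav"], kvl = params["kv_low"], kv3 = params["kv3"],
             kva = params["kv_a"];
  const double g_nav0 = as<double>(nav["g"]), e_nav = as<double>(nav["e"]);
  const double g_kvl0 = as<double>(kvl["g"]), e_k = as<double>(kvl["e"]);
  const double g_kv30 = as<double>(kv3["g"]);
  const double g_kva0 = as<double>(kva["g"]);
  const Gate nav_m = as_gate(nav["act"]), nav_h = as_gate(nav["inact"]);
  const Gate kvl_n = as_gate(kvl["act"]);
  const Gate kv3_p = as_gate(kv3["act"]);
  const Gate kva_a = as_gate(kva["act"]), kva_b = as_gate(kva["inact"]);

  const double bias = as<double>(params["bias_current"]);
  const double q10_r = as<double>(params["q10_rates"]);
  const double q10_g = as<double>(params["q10_conductance"]);
  const double t_ref = as<double>(params["reference_temperature"]);

  const double rate_scale = std::pow(q10_r, (temperature - t_ref) / 10.0);
  const double g_scale = std::pow(q10_g, (temperature - t_ref) / 10.0);
  const double g_leak = g_leak0;  // conductance Q10 applies to active channels only
  const double g_nav = (na_disabled ? 0.0 : g_nav0) * g_scale;
  const double g_kvl = g_kvl0 * g_scale;
  const double g_kv3 = g_kv30 * g_scale;
  const double g_kva = g_kva0 * g_scale;

  const bool vclamp = (mode == "voltage-clamp");
  const int n_steps = stim.size();
  const int n_out = (n_steps + record_every - 1) / record_every;
  NumericVector out(n_out), stim_out(n_out);

  // initial state: steady state at the initial command/rest
  double v = vclamp ? stim[0] : e_leak + bias / g_leak;
  double m = nav_m.xinf(v), h = nav_h.xinf(v);
  double n = kvl_n.xinf(v), p = kv3_p.xinf(v);
  double a = kva_a.xinf(v), b = kva_b.xinf(v);

  double max_dvdt = 0.0;
  int k = 0;
  for (int i = 0; i < n_steps; ++i) {
    if (vclamp) v = stim[i];
    const double i_nav = g_nav * m * m * m * h * (v - e_nav);
    const double i_kvl = g_kvl * n * n * n * n * (v - e_k);
    const double i_kv3 = g_kv3 * p * p * (v - e_k);
    const double i_kva = g_kva * a * a * a * b * (v - e_k);
    const double i_leak = g_leak * (v - e_leak);

    if (i % record_every == 0) {
      if (vclamp) {
        double i_total = i_nav + i_kvl + i_kv3 + i_kva;
        if (!leak_subtract) i_total += i_leak;
        out[k] = i_total;
      } else {
        out[k] = v;
      }
      stim_out[k] = stim[i];
      ++k;
    }

    if (!vclamp) {
      const double dvdt = (-(i_nav + i_kvl + i_kv3 + i_kva + i_leak) +
                           bias + stim[i]) / cap;
      if (std::fabs(dvdt) > max_dvdt) max_dvdt = std::fabs(dvdt);
      v += dt * dvdt;
      if (!std::isfinite(v) || std::fabs(v) > 500.0) {
        stop("integration blow-up at t = %f ms (dt = %f ms, max |dV/dt| = "
             "%f mV/ms); reduce dt", i * dt, dt, max_dvdt);
      }
    }
    m = step_gate(m, v, nav_m, dt, rate_scale);
    h = step_gate(h, v, nav_h, dt, rate_scale);
    n = step_gate(n, v, kvl_n, dt, rate_scale);
    p = step_gate(p, v, kv3_p, dt, rate_scale);
    a = step_gate(a, v, kva_a, dt, rate_scale);
    b = step_gate(b, v, kva_b, dt, rate_scale);
  }

  return List::create(_["samples"] = out, _["stimulus"] = stim_out,
                      _["dt"] = dt * record_every);
}
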