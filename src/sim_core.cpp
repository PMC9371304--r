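// Fixed-step (50 us) hybrid integrator for the astrocytic compartment:
// explicit Euler for the continuous Ca/IP3/buffer variables, independent
// Markov jumps for the IP3R subunits, sub-stepped RK4 for the (linear)
// sensor master equations, Bernoulli release draws and binomial pool
// transitions. All randomness comes from R's RNG so runs are reproducible
// under set.seed().
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Pars {
  double er_cyt_ratio;
  int n_ip3r, n_subunits;
  double a1, d1, a2, d2, a3, d3, a4, d4, a5, d5;
  double b1, b2, b3, b4, b5;
  double v_ip3r, v_er_leak, v_serca, k_serca;
  double pmca_kf, pmca_kb, v_pmca, v_pm_leak;
  double bt_cyt, kon_cyt, koff_cyt, bt_er, kon_er, koff_er;
  double v_mglur, k_mglur, n_mglur, v_plcd, k_plcd, k_5p, v_3k, k_3k;
  double syt4_kon, syt4_koff, syt4_gamma;
  double syt7_kon, syt7_koff, syt7_b, syt7_gamma;
  int syt7_sites;
  double kr_recycle, ff_recycle, k_dock;
  int docked_max;
};

double getp(const List& p, const char* nm) {
  return as<double>(p[nm]);
}

Pars unpack(const List& p) {
  Pars q;
  q.er_cyt_ratio = getp(p, "er_cyt_ratio");
  q.n_ip3r = (int)getp(p, "n_ip3r");
  q.n_subunits = (int)getp(p, "n_subunits");
  q.a1 = getp(p, "ip3r_a1"); q.d1 = getp(p, "ip3r_d1");
  q.a2 = getp(p, "ip3r_a2"); q.d2 = getp(p, "ip3r_d2");
  q.a3 = getp(p, "ip3r_a3"); q.d3 = getp(p, "ip3r_d3");
  q.a4 = getp(p, "ip3r_a4"); q.d4 = getp(p, "ip3r_d4");
  q.a5 = getp(p, "ip3r_a5"); q.d5 = getp(p, "ip3r_d5");
  q.b1 = q.a1 * q.d1; q.b2 = q.a2 * q.d2; q.b3 = q.a3 * q.d3;
  q.b4 = q.a4 * q.d4; q.b5 = q.a5 * q.d5;
  q.v_ip3r = getp(p, "v_ip3r"); q.v_er_leak = getp(p, "v_er_leak");
  q.v_serca = getp(p, "v_serca"); q.k_serca = getp(p, "k_serca");
  q.pmca_kf = getp(p, "pmca_kf"); q.pmca_kb = getp(p, "pmca_kb");
  q.v_pmca = getp(p, "v_pmca"); q.v_pm_leak = getp(p, "v_pm_leak");
  q.bt_cyt = getp(p, "bt_cyt"); q.kon_cyt = getp(p, "kon_cyt");
  q.koff_cyt = getp(p, "koff_cyt");
  q.bt_er = getp(p, "bt_er"); q.kon_er = getp(p, "kon_er");
  q.koff_er = getp(p, "koff_er");
  q.v_mglur = getp(p, "v_mglur"); q.k_mglur = getp(p, "k_mglur");
  q.n_mglur = getp(p, "n_mglur");
  q.v_plcd = getp(p, "v_plcd"); q.k_plcd = getp(p, "k_plcd");
  q.k_5p = getp(p, "k_5p"); q.v_3k = getp(p, "v_3k"); q.k_3k = getp(p, "k_3k");
  q.syt4_kon = getp(p, "syt4_kon"); q.syt4_koff = getp(p, "syt4_koff");
  q.syt4_gamma = getp(p, "syt4_gamma");
  q.syt7_kon = getp(p, "syt7_kon"); q.syt7_koff = getp(p, "syt7_koff");
  q.syt7_b = getp(p, "syt7_b"); q.syt7_gamma = getp(p, "syt7_gamma");
  q.syt7_sites = (int)getp(p, "syt7_sites");
  q.kr_recycle = getp(p, "kr_recycle"); q.ff_recycle = getp(p, "ff_recycle");
  q.k_dock = getp(p, "k_dock");
  q.docked_max = (int)getp(p, "docked_max");
  return q;
}

inline double hill2(double x, double k) {
  double x2 = x * x;
  return x2 / (x2 + k * k);
}

// subunit transition rates out of state s (= 4i + 2j + k): toggle of the
// IP3 site, the activating Ca site and the inhibitory Ca site
inline void subunit_rates(const Pars& q, int s, double ca, double ip3,
                          double* r, int* tgt) {
  int i = s >> 2, j = (s >> 1) & 1, k = s & 1;
  r[0] = (i == 0) ? ip3 * (k == 0 ? q.a1 : q.a3) : (k == 0 ? q.b1 : q.b3);
  tgt[0] = s + (i == 0 ? 4 : -4);
  r[1] = (j == 0) ? ca * q.a5 : q.b5;
  tgt[1] = s + (j == 0 ? 2 : -2);
  r[2] = (k == 0) ? ca * (i == 1 ? q.a2 : q.a4) : (i == 1 ? q.b2 : q.b4);
  tgt[2] = s + (k == 0 ? 1 : -1);
}

// sensor master equations (Syt4 two-state + Syt7 chain), y = (p4, occ0..5)
void sensor_derivs(const Pars& q, double ca, const double* y, double* dy) {
  dy[0] = q.syt4_kon * ca * (1.0 - y[0]) - q.syt4_koff * y[0];
  int n = q.syt7_sites;
  for (int i = 0; i <= n; ++i) {
    double d = 0.0;
    if (i > 0) d += (n - (i - 1)) * q.syt7_kon * ca * y[i];       // in from i-1
    if (i < n) d += (i + 1) * q.syt7_koff * std::pow(q.syt7_b, i) * y[i + 2]; // in from i+1
    double out = 0.0;
    if (i < n) out += (n - i) * q.syt7_kon * ca;
    if (i > 0) out += i * q.syt7_koff * std::pow(q.syt7_b, i - 1);
    dy[i + 1] = d - out * y[i + 1];
  }
}

void sensor_rk4(const Pars& q, double ca, double dt, double* y) {
  double lmax = q.syt4_kon * ca + q.syt4_koff;
  double l7 = q.syt7_sites * (q.syt7_kon * ca + q.syt7_koff);
  if (l7 > lmax) lmax = l7;
  int m = (int)std::ceil(lmax * dt / 0.05);
  if (m < 1) m = 1;
  double h = dt / m;
  const int ny = 7;
  double k1[ny], k2[ny], k3[ny], k4[ny], tmp[ny];
  for (int step = 0; step < m; ++step) {
    sensor_derivs(q, ca, y, k1);
    for (int i = 0; i < ny; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
    sensor_derivs(q, ca, tmp, k2);
    for (int i = 0; i < ny; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
    sensor_derivs(q, ca, tmp, k3);
    for (int i = 0; i < ny; ++i) tmp[i] = y[i] + h * k3[i];
    sensor_derivs(q, ca, tmp, k4);
    for (int i = 0; i < ny; ++i)
      y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_sensor_update(double p4, NumericVector occ7, double ca, double dt,
                       List pars) {
  Pars q = unpack(pars);
  double y[7];
  y[0] = p4;
  for (int i = 0; i < 6; ++i) y[i + 1] = occ7[i];
  sensor_rk4(q, ca, dt, y);
  NumericVector out7(6);
  for (int i = 0; i < 6; ++i) out7[i] = y[i + 1];
  return List::create(y[0], out7);
}

// Clamped-input gating: simulates `n_sub` independent subunits for
// `n_steps` and returns the accumulated time-in-state counts (length 8).
// [[Rcpp::export]]
NumericVector cpp_gate_clamped(List pars, double ca, double ip3,
                               int n_steps, double dt, IntegerVector init) {
  Pars q = unpack(pars);
  int n_sub = init.size();
  std::vector<int> st(init.begin(), init.end());
  NumericVector counts(8);
  double r[3]; int tgt[3];
  for (int s = 0; s < n_steps; ++s) {
    for (int u = 0; u < n_sub; ++u) {
      subunit_rates(q, st[u], ca, ip3, r, tgt);
      double c1 = r[0] * dt, c2 = c1 + r[1] * dt, c3 = c2 + r[2] * dt;
      double x = unif_rand();
      if (x < c1) st[u] = tgt[0];
      else if (x < c2) st[u] = tgt[1];
      else if (x < c3) st[u] = tgt[2];
      counts[st[u]] += 1.0;
    }
  }
  return counts;
}

// [[Rcpp::export]]
List cpp_simulate_trial(List pars, NumericVector glu, double dhpg,
                        double dhpg_on, double dhpg_dur, double dt,
                        int n_steps, int record_every,
                        NumericVector init_cont, IntegerVector init_subunits,
                        double init_p4, NumericVector init_occ7,
                        IntegerVector init_pools,
                        bool stochastic_channels, bool membrane_on,
                        bool release_on) {
  Pars q = unpack(pars);
  double ca = init_cont[0], er = init_cont[1], ip3 = init_cont[2];
  double bc = init_cont[3], be = init_cont[4];
  std::vector<int> sub(init_subunits.begin(), init_subunits.end());
  const int n_sub_total = (int)sub.size();
  double sens[7];
  sens[0] = init_p4;
  for (int i = 0; i < 6; ++i) sens[i + 1] = init_occ7[i];
  int docked = init_pools[0], mobile = init_pools[1];
  int kr_endo = init_pools[2], ff_endo = init_pools[3];

  const int n_out = n_steps / record_every + 1;
  NumericVector o_t(n_out), o_ca(n_out), o_er(n_out), o_ip3(n_out),
      o_bc(n_out), o_be(n_out), o_glu(n_out);
  IntegerVector o_open(n_out), o_docked(n_out), o_mobile(n_out),
      o_kr(n_out), o_ff(n_out);
  std::vector<double> rel_t;
  std::vector<int> rel_mode;
  int n_clip = 0, n_bigp = 0;

  const double p_kr_rec = -std::expm1(-q.kr_recycle * dt);
  const double p_ff_rec = -std::expm1(-q.ff_recycle * dt);
  const double p_dock = -std::expm1(-q.k_dock * dt);

  double r[3]; int tgt[3];
  int row = 0;

  auto count_open = [&]() {
    int open = 0;
    for (int c = 0; c < q.n_ip3r; ++c) {
      bool all_active = true;
      for (int u = 0; u < q.n_subunits; ++u)
        if (sub[c * q.n_subunits + u] != 6) { all_active = false; break; }
      if (all_active) ++open;
    }
    return open;
  };

  auto record = [&](double t, int open) {
    o_t[row] = t; o_ca[row] = ca; o_er[row] = er; o_ip3[row] = ip3;
    o_bc[row] = bc; o_be[row] = be; o_open[row] = open;
    o_docked[row] = docked; o_mobile[row] = mobile;
    o_kr[row] = kr_endo; o_ff[row] = ff_endo;
    o_glu[row] = 0.0;
    ++row;
  };

  int open0 = count_open();
  record(0.0, open0);

  for (int s = 0; s < n_steps; ++s) {
    const double t = s * dt;
    const double g = glu[s];
    const double a =
        (dhpg > 0 && t >= dhpg_on && t < dhpg_on + dhpg_dur) ? dhpg : 0.0;
    const double drive = g + a;
    const int n_open = (s == 0) ? open0 : count_open();

    // deterministic fluxes at the start-of-step state
    const double J_ip3r = q.v_ip3r * n_open * (er - ca);
    const double J_leak = q.v_er_leak * (er - ca);
    const double J_serca = q.v_serca * hill2(ca, q.k_serca);
    double J_pmca = q.v_pmca * q.pmca_kf * ca / (q.pmca_kf * ca + q.pmca_kb);
    double J_in = q.v_pm_leak;
    if (!membrane_on) { J_pmca = 0.0; J_in = 0.0; }
    const double J_bc = q.kon_cyt * (q.bt_cyt - bc) * ca - q.koff_cyt * bc;
    const double J_be = q.kon_er * (q.bt_er - be) * er - q.koff_er * be;
    double J_mglur = 0.0;
    if (drive > 0) {
      double dn = std::pow(drive, q.n_mglur);
      J_mglur = q.v_mglur * dn / (dn + std::pow(q.k_mglur, q.n_mglur));
    }
    const double J_plcd = q.v_plcd * hill2(ca, q.k_plcd);
    const double J_deg = q.k_5p * ip3 + q.v_3k * hill2(ca, q.k_3k) * ip3;

    const double ca0 = ca, ip30 = ip3;
    ca += dt * (J_ip3r + J_leak - J_serca - J_pmca + J_in - J_bc);
    er += dt * ((-J_ip3r - J_leak + J_serca) / q.er_cyt_ratio - J_be);
    ip3 += dt * (J_mglur + J_plcd - J_deg);
    bc += dt * J_bc;
    be += dt * J_be;
    if (ca < 0) { ca = 0; ++n_clip; }
    if (er < 0) { er = 0; ++n_clip; }
    if (ip3 < 0) { ip3 = 0; ++n_clip; }
    if (bc < 0) { bc = 0; ++n_clip; }
    if (be < 0) { be = 0; ++n_clip; }
    if (!R_finite(ca) || !R_finite(er) || !R_finite(ip3) ||
        !R_finite(bc) || !R_finite(be)) {
      stop("non-finite state at t = %g s (fluxes: ip3r %g, serca %g, "
           "pmca %g, mglur %g)", t, J_ip3r, J_serca, J_pmca, J_mglur);
    }

    // stochastic channel gating at the start-of-step concentrations
    if (stochastic_channels) {
      for (int u = 0; u < n_sub_total; ++u) {
        subunit_rates(q, sub[u], ca0, ip30, r, tgt);
        double c1 = r[0] * dt, c2 = c1 + r[1] * dt, c3 = c2 + r[2] * dt;
        if (c3 > 0.1) ++n_bigp;
        double x = unif_rand();
        if (x < c1) sub[u] = tgt[0];
        else if (x < c2) sub[u] = tgt[1];
        else if (x < c3) sub[u] = tgt[2];
      }
    }

    if (release_on) {
      // sensors see the start-of-step Ca
      sensor_rk4(q, ca0, dt, sens);
      const double rate_kr = q.syt4_gamma * sens[0] * docked;
      const double rate_ff = q.syt7_gamma * sens[q.syt7_sites + 1] * mobile;
      const double u1 = unif_rand(), u2 = unif_rand();
      if (docked > 0 && u1 < rate_kr * dt) {
        --docked; ++kr_endo;
        rel_t.push_back(t); rel_mode.push_back(1);
      }
      if (mobile > 0 && u2 < rate_ff * dt) {
        --mobile; ++ff_endo;
        rel_t.push_back(t); rel_mode.push_back(2);
      }
      const int kr_mv = (int)R::rbinom(kr_endo, p_kr_rec);
      const int ff_mv = (int)R::rbinom(ff_endo, p_ff_rec);
      int free_sites = q.docked_max - docked;
      if (free_sites < 0) free_sites = 0;
      int dk_mv = (int)R::rbinom(mobile, p_dock);
      if (dk_mv > free_sites) dk_mv = free_sites;
      kr_endo -= kr_mv; ff_endo -= ff_mv;
      mobile += kr_mv + ff_mv - dk_mv;
      docked += dk_mv;
    }

    if ((s + 1) % record_every == 0) {
      record((s + 1) * dt, count_open());
      o_glu[row - 1] = g;
    }
    if ((s & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerVector final_sub(sub.begin(), sub.end());
  NumericVector final_occ7(6);
  for (int i = 0; i < 6; ++i) final_occ7[i] = sens[i + 1];
  return List::create(
      _["time"] = o_t, _["ca_cyt"] = o_ca, _["ca_er"] = o_er,
      _["ip3"] = o_ip3, _["b_cyt"] = o_bc, _["b_er"] = o_be,
      _["glu"] = o_glu, _["n_open"] = o_open, _["docked"] = o_docked,
      _["mobile"] = o_mobile, _["kr_endo"] = o_kr, _["ff_endo"] = o_ff,
      _["rel_time"] = NumericVector(rel_t.begin(), rel_t.end()),
      _["rel_mode"] = IntegerVector(rel_mode.begin(), rel_mode.end()),
      _["n_clip"] = n_clip, _["n_bigp"] = n_bigp,
      _["final"] = List::create(
          _["ca_cyt"] = ca, _["ca_er"] = er, _["ip3"] = ip3,
          _["b_cyt"] = bc, _["b_er"] = be, _["subunits"] = final_sub,
          _["p4"] = sens[0], _["occ7"] = final_occ7,
          _["pools"] = IntegerVector::create(docked, mobile, kr_endo,
                                             ff_endo)));
}
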