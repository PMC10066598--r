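// Conductance-based network engine.
//
// Two-compartment (soma + lumped dendrite) neuron models with
// Hodgkin-Huxley-style channels (NaT, Kd, NaP, KA, Kv3.1, low-threshold
// CaT in TC and Rt variants, high-threshold Ca, SK, Ih, leak), an
// exponential-decay calcium pool, event-driven stochastic Tsodyks-Markram
// synapses with double-exponential receptor kinetics (AMPA, NMDA with Mg
// block, GABA_A), and gap junctions as ohmic couplings.
//
// Integration: exponential Euler per compartment at fixed dt; gating
// variables advance with voltage-indexed lookup tables of m_inf(V) and
// exp(-dt/tau(V)), built once per run.
//
// Units: mV, ms, nA, nF, uS (1 nS = 1e-3 uS), conductance densities in
// S/cm2, areas in cm2, calcium in mM.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
using namespace Rcpp;

static const double E_NA = 50.0, E_K = -90.0, E_H = -43.0, E_CA = 120.0;
static const double VMIN = -130.0, VMAX = 70.0, DV = 0.05;
static const int NV = (int)((VMAX - VMIN) / DV) + 2;

struct Gate { std::vector<double> inf, dec; Gate() : inf(NV), dec(NV) {} };

static inline int vidx(double v) {
  int i = (int)((v - VMIN) / DV);
  if (i < 0) i = 0;
  if (i >= NV) i = NV - 1;
  return i;
}

// rate helpers -------------------------------------------------------------
static inline double vtrap(double x, double y) {
  // x/(exp(x/y)-1) with singularity removed
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

struct Kinetics {
  Gate na_m, na_h, kd_n, catc_m, catc_h, catr_m, catr_h, ih_m, ka_m, ka_h, kv3_m;
  void build(double dt) {
    for (int i = 0; i < NV; i++) {
      double v = VMIN + i * DV;
      // Traub-style spike currents, threshold shifted by vtraub = -50
      double vt = v + 50.0;
      double am = 0.32 * vtrap(13.0 - vt, 4.0);
      double bm = 0.28 * vtrap(vt - 40.0, 5.0);
      double ah = 0.128 * std::exp((17.0 - vt) / 18.0);
      double bh = 4.0 / (1.0 + std::exp((40.0 - vt) / 5.0));
      double an = 0.032 * vtrap(15.0 - vt, 5.0);
      double bn = 0.5 * std::exp((10.0 - vt) / 40.0);
      set(na_m, i, am / (am + bm), 1.0 / (am + bm), dt);
      set(na_h, i, ah / (ah + bh), 1.0 / (ah + bh), dt);
      set(kd_n, i, an / (an + bn), 1.0 / (an + bn), dt);
      // Low-threshold Ca, thalamocortical variant (Huguenard-McCormick
      // style steady states, 34-36 C time constants)
      double mi = 1.0 / (1.0 + std::exp(-(v + 57.0) / 6.2));
      double hi = 1.0 / (1.0 + std::exp((v + 81.0) / 4.0));
      double tm = (0.612 + 1.0 / (std::exp(-(v + 132.0) / 16.7) + std::exp((v + 16.8) / 18.2))) / 3.74;
      double th;
      if (v >= -81.0) th = (28.0 + std::exp(-(v + 22.0) / 10.5)) / 3.73;
      else th = std::exp((v + 467.0) / 66.6) / 3.73;
      set(catc_m, i, mi, std::max(tm, 0.05), dt);
      set(catc_h, i, hi, std::max(th, 0.5), dt);
      // Low-threshold Ca, reticular variant (more depolarized activation,
      // slower inactivation recovery)
      double mir = 1.0 / (1.0 + std::exp(-(v + 52.0) / 7.4));
      double hir = 1.0 / (1.0 + std::exp((v + 80.0) / 5.0));
      double tmr = (3.0 + 1.0 / (std::exp((v + 27.0) / 10.0) + std::exp(-(v + 102.0) / 15.0))) / 6.81;
      double thr = (85.0 + 1.0 / (std::exp((v + 48.0) / 4.0) + std::exp(-(v + 407.0) / 50.0))) / 3.73;
      set(catr_m, i, mir, std::max(tmr, 0.05), dt);
      set(catr_h, i, hir, std::max(thr, 0.5), dt);
      // anomalous rectifier Ih
      double hinf = 1.0 / (1.0 + std::exp((v + 75.0) / 5.5));
      double htau = 20.0 + 1000.0 / (std::exp((v + 71.5) / 14.2) + std::exp(-(v + 89.0) / 11.6));
      set(ih_m, i, hinf, htau, dt);
      // A-type K
      double kami = 1.0 / (1.0 + std::exp(-(v + 60.0) / 8.5));
      double katm = (0.37 + 1.0 / (std::exp((v + 35.8) / 19.7) + std::exp(-(v + 79.7) / 12.7))) / 3.7;
      double kahi = 1.0 / (1.0 + std::exp((v + 78.0) / 6.0));
      double kath;
      if (v >= -63.0) kath = 19.0 / 3.7;
      else kath = (1.0 / (std::exp((v + 46.0) / 5.0) + std::exp(-(v + 238.0) / 37.5))) / 3.7;
      set(ka_m, i, kami, std::max(katm, 0.05), dt);
      set(ka_h, i, kahi, std::max(kath, 0.5), dt);
      // Kv3.1 fast rectifier (interneurons)
      double k3i = 1.0 / (1.0 + std::exp(-(v - 18.7) / 9.7));
      double k3t = 4.0 / (1.0 + std::exp(-(v + 46.56) / 44.14));
      set(kv3_m, i, k3i, std::max(k3t, 0.05), dt);
    }
  }
 private:
  static void set(Gate& g, int i, double inf, double tau, double dt) {
    g.inf[i] = inf;
    g.dec[i] = std::exp(-dt / tau);
  }
};

// parameter matrix column order (keep in sync with emodel_matrix() in R)
enum PCol {
  P_AREA_S, P_AREA_D, P_CM, P_GNA, P_GKD, P_GNAP, P_GKA, P_GKV3,
  P_GCAT_S, P_GCAT_D, P_GCAH, P_GSK_S, P_GSK_D, P_GIH_S, P_GIH_D,
  P_GLEAK_S, P_GLEAK_D, P_ELEAK, P_GCOUPLE, P_TAUCA, P_GAMMA,
  P_CATVAR, P_VINIT, P_NCOL
};

struct SynClass { double tau_r, tau_d, e_rev, norm; bool nmda; };

// Mg block (Jahr-Stevens), [Mg] = 1 mM
static inline double mgblock(double v) {
  return 1.0 / (1.0 + std::exp(-0.062 * v) / 3.57);
}

// [[Rcpp::export]]
List cpp_run_network(NumericMatrix par,        // n_cells x P_NCOL
                     NumericMatrix syn_classes, // n_class x 4: tau_r tau_d e_rev is_nmda
                     IntegerVector e_pre_kind,  // 0 cell, 1 fiber
                     IntegerVector e_pre,       // 0-based pre index
                     IntegerVector e_post,      // 0-based post cell
                     IntegerVector e_comp,      // 0 soma, 1 dend
                     IntegerVector e_class1,    // AMPA/GABA class id (0-based)
                     IntegerVector e_class2,    // NMDA class id or -1
                     NumericVector e_g,         // nS per release site
                     NumericVector e_nmda_ratio,
                     NumericVector e_u, NumericVector e_d, NumericVector e_f,
                     IntegerVector e_nsites,
                     NumericVector e_delay,     // ms
                     NumericMatrix gj,          // n_gj x 5: cell_a comp_a cell_b comp_b g_nS
                     NumericVector fiber_spike_t, IntegerVector fiber_spike_id,
                     NumericVector mini_t, IntegerVector mini_edge,
                     NumericMatrix pulses,      // n x 4: cell t0 t1 amp_nA (soma)
                     NumericVector hold_i,      // per-cell constant soma current nA
                     double dt, double duration, int seed,
                     IntegerVector record_cells, double record_dt,
                     double spike_thresh, double vinit_override) {
  const int n_cells = par.nrow();
  const int n_edges = e_pre.size();
  const int n_steps = (int)std::round(duration / dt);

  Kinetics kin;
  kin.build(dt);
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761u + 1013904223u);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  const int n_class = syn_classes.nrow();
  std::vector<SynClass> classes(n_class);
  for (int c = 0; c < n_class; c++) {
    SynClass& sc = classes[c];
    sc.tau_r = syn_classes(c, 0);
    sc.tau_d = syn_classes(c, 1);
    sc.e_rev = syn_classes(c, 2);
    sc.nmda = syn_classes(c, 3) > 0.5;
    double tp = sc.tau_r * sc.tau_d / (sc.tau_d - sc.tau_r) * std::log(sc.tau_d / sc.tau_r);
    sc.norm = 1.0 / (std::exp(-tp / sc.tau_d) - std::exp(-tp / sc.tau_r));
  }
  std::vector<double> cls_dec_r(n_class), cls_dec_d(n_class);
  for (int c = 0; c < n_class; c++) {
    cls_dec_r[c] = std::exp(-dt / classes[c].tau_r);
    cls_dec_d[c] = std::exp(-dt / classes[c].tau_d);
  }

  // per (cell, comp, class) double-exponential states A (rise) and B (decay)
  const size_t nslot = (size_t)n_cells * 2 * n_class;
  std::vector<double> synA(nslot, 0.0), synB(nslot, 0.0);
  auto slot = [&](int cell, int comp, int cls) -> size_t {
    return ((size_t)cell * 2 + comp) * n_class + cls;
  };

  // cell state
  std::vector<double> vs(n_cells), vd(n_cells), cas(n_cells, 5e-5), cad(n_cells, 5e-5);
  std::vector<double> g_na_m(n_cells), g_na_h(n_cells), g_kd_n(n_cells);
  std::vector<double> g_cat_m(n_cells), g_cat_h(n_cells);
  std::vector<double> g_catd_m(n_cells), g_catd_h(n_cells);
  std::vector<double> g_ih_s(n_cells), g_ih_d(n_cells);
  std::vector<double> g_ka_m(n_cells), g_ka_h(n_cells), g_kv3(n_cells);

  for (int i = 0; i < n_cells; i++) {
    double v0 = vinit_override > -999 ? vinit_override : par(i, P_VINIT);
    vs[i] = v0; vd[i] = v0;
    int iv = vidx(v0);
    g_na_m[i] = kin.na_m.inf[iv]; g_na_h[i] = kin.na_h.inf[iv];
    g_kd_n[i] = kin.kd_n.inf[iv];
    bool re = par(i, P_CATVAR) > 0.5;
    g_cat_m[i] = re ? kin.catr_m.inf[iv] : kin.catc_m.inf[iv];
    g_cat_h[i] = re ? kin.catr_h.inf[iv] : kin.catc_h.inf[iv];
    g_catd_m[i] = g_cat_m[i]; g_catd_h[i] = g_cat_h[i];
    g_ih_s[i] = kin.ih_m.inf[iv]; g_ih_d[i] = kin.ih_m.inf[iv];
    g_ka_m[i] = kin.ka_m.inf[iv]; g_ka_h[i] = kin.ka_h.inf[iv];
    g_kv3[i] = kin.kv3_m.inf[iv];
  }

  // TM state
  std::vector<double> tm_u(n_edges, 0.0), tm_tlast(n_edges, -1e18);
  std::vector<int> site_off(n_edges + 1, 0);
  for (int e = 0; e < n_edges; e++) site_off[e + 1] = site_off[e] + e_nsites[e];
  int n_sites_tot = site_off[n_edges];
  std::vector<uint8_t> site_rec(n_sites_tot, 1);
  std::vector<double> site_trel(n_sites_tot, -1e18);

  // adjacency: pre (cell or fiber) -> outgoing edges
  int n_fibers = 0;
  for (int e = 0; e < n_edges; e++)
    if (e_pre_kind[e] == 1 && e_pre[e] + 1 > n_fibers) n_fibers = e_pre[e] + 1;
  std::vector< std::vector<int> > cell_out(n_cells), fiber_out(n_fibers);
  for (int e = 0; e < n_edges; e++) {
    if (e_pre_kind[e] == 0) cell_out[e_pre[e]].push_back(e);
    else fiber_out[e_pre[e]].push_back(e);
  }

  // delay ring buffer of pending arrivals
  int max_delay_steps = 1;
  for (int e = 0; e < n_edges; e++) {
    int ds = (int)std::round(e_delay[e] / dt);
    if (ds < 1) ds = 1;
    if (ds > max_delay_steps) max_delay_steps = ds;
  }
  std::vector<int> delay_steps(n_edges);
  for (int e = 0; e < n_edges; e++)
    delay_steps[e] = std::max(1, (int)std::round(e_delay[e] / dt));
  int ring_n = max_delay_steps + 1;
  std::vector< std::vector<int> > ring(ring_n);

  // gap junctions
  const int n_gj = gj.nrow();

  // recording
  std::vector<int> rec(record_cells.begin(), record_cells.end());
  int rec_every = std::max(1, (int)std::round(record_dt / dt));
  int n_rec_steps = n_steps / rec_every + 1;
  NumericMatrix traces((int)rec.size() > 0 ? n_rec_steps : 0, (int)rec.size());
  std::vector<double> rec_time;
  if (!rec.empty()) rec_time.reserve(n_rec_steps);

  std::vector<double> spike_cell_out, spike_time_out;
  std::vector<double> last_spike(n_cells, -1e18);

  // TM release on event arrival; returns quanta released
  auto tm_arrive = [&](int e, double t, bool mini) -> int {
    double U = e_u[e];
    if (!mini) {
      double u = tm_u[e];
      if (tm_tlast[e] < -1e17) u = U;
      else u = U + u * (1.0 - U) * std::exp(-(t - tm_tlast[e]) / std::max(e_f[e], 1e-9));
      tm_u[e] = u;
      tm_tlast[e] = t;
      int k = 0;
      for (int s = site_off[e]; s < site_off[e + 1]; s++) {
        if (!site_rec[s]) {
          double prec = 1.0 - std::exp(-(t - site_trel[s]) / std::max(e_d[e], 1e-9));
          if (unif(rng) < prec) site_rec[s] = 1;
          else site_trel[s] = t; // memoryless recovery clock
        }
        if (site_rec[s] && unif(rng) < u) {
          site_rec[s] = 0;
          site_trel[s] = t;
          k++;
        }
      }
      return k;
    } else {
      // spontaneous release: a single site, probability = baseline U
      int ns = e_nsites[e];
      if (ns <= 0) return 0;
      int s = site_off[e] + (int)(unif(rng) * ns);
      if (s >= site_off[e + 1]) s = site_off[e + 1] - 1;
      if (!site_rec[s]) {
        double prec = 1.0 - std::exp(-(t - site_trel[s]) / std::max(e_d[e], 1e-9));
        if (unif(rng) < prec) site_rec[s] = 1;
        else site_trel[s] = t; // memoryless recovery clock
      }
      if (site_rec[s] && unif(rng) < e_u[e]) {
        site_rec[s] = 0;
        site_trel[s] = t;
        return 1;
      }
      return 0;
    }
  };

  auto deposit = [&](int e, int quanta) {
    if (quanta <= 0) return;
    double w = e_g[e] * 1e-3 * quanta; // nS -> uS
    int c1 = e_class1[e];
    double w1 = w * classes[c1].norm;
    size_t s1 = slot(e_post[e], e_comp[e], c1);
    synA[s1] += w1; synB[s1] += w1;
    if (e_class2[e] >= 0 && e_nmda_ratio[e] > 0) {
      int c2 = e_class2[e];
      double w2 = w * e_nmda_ratio[e] * classes[c2].norm;
      size_t s2 = slot(e_post[e], e_comp[e], c2);
      synA[s2] += w2; synB[s2] += w2;
    }
  };

  size_t fs_ptr = 0, mini_ptr = 0;
  const size_t n_fs = fiber_spike_t.size(), n_mini = mini_t.size();
  const int n_pulse = pulses.nrow();

  bool diverged = false;
  double diverge_t = -1;
  int diverge_cell = -1;

  for (int step = 0; step < n_steps && !diverged; step++) {
    double t = step * dt;

    // fiber spikes scheduled for this step window
    while (fs_ptr < n_fs && fiber_spike_t[fs_ptr] < t + dt) {
      int fid = fiber_spike_id[fs_ptr];
      if (fid >= 0 && fid < n_fibers)
        for (int e : fiber_out[fid])
          ring[(step + delay_steps[e]) % ring_n].push_back(e);
      fs_ptr++;
    }
    // minis release immediately (no axonal delay)
    while (mini_ptr < n_mini && mini_t[mini_ptr] < t + dt) {
      int e = mini_edge[mini_ptr];
      if (e >= 0 && e < n_edges) deposit(e, tm_arrive(e, t, true));
      mini_ptr++;
    }
    // arrivals due now
    std::vector<int>& due = ring[step % ring_n];
    for (int e : due) deposit(e, tm_arrive(e, t, false));
    due.clear();

    // decay synaptic states
    for (int c = 0; c < n_class; c++) {
      double dr = cls_dec_r[c], dd = cls_dec_d[c];
      for (int i = 0; i < n_cells; i++) {
        synA[((size_t)i * 2) * n_class + c] *= dr;
        synB[((size_t)i * 2) * n_class + c] *= dd;
        synA[((size_t)i * 2 + 1) * n_class + c] *= dr;
        synB[((size_t)i * 2 + 1) * n_class + c] *= dd;
      }
    }

    // gap junction currents based on previous-step voltages
    std::vector<double> gj_g_s(n_cells, 0.0), gj_i_s(n_cells, 0.0);
    std::vector<double> gj_g_d(n_cells, 0.0), gj_i_d(n_cells, 0.0);
    for (int g = 0; g < n_gj; g++) {
      int ca = (int)gj(g, 0), cmpa = (int)gj(g, 1);
      int cb = (int)gj(g, 2), cmpb = (int)gj(g, 3);
      double gg = gj(g, 4) * 1e-3; // uS
      double va = cmpa == 0 ? vs[ca] : vd[ca];
      double vb = cmpb == 0 ? vs[cb] : vd[cb];
      if (cmpa == 0) { gj_g_s[ca] += gg; gj_i_s[ca] += gg * vb; }
      else { gj_g_d[ca] += gg; gj_i_d[ca] += gg * vb; }
      if (cmpb == 0) { gj_g_s[cb] += gg; gj_i_s[cb] += gg * va; }
      else { gj_g_d[cb] += gg; gj_i_d[cb] += gg * va; }
    }

    // timed current pulses
    std::vector<double> ipulse;
    if (n_pulse > 0) {
      ipulse.assign(n_cells, 0.0);
      for (int p = 0; p < n_pulse; p++) {
        if (t >= pulses(p, 1) && t < pulses(p, 2)) {
          int c = (int)pulses(p, 0);
          if (c >= 0 && c < n_cells) ipulse[c] += pulses(p, 3);
        }
      }
    }

    for (int i = 0; i < n_cells; i++) {
      double v_s = vs[i], v_d = vd[i];
      int ivs = vidx(v_s), ivd = vidx(v_d);
      bool re = par(i, P_CATVAR) > 0.5;
      const Gate& cat_m = re ? kin.catr_m : kin.catc_m;
      const Gate& cat_h = re ? kin.catr_h : kin.catc_h;

      // advance gating (soma)
      g_na_m[i] = kin.na_m.inf[ivs] + (g_na_m[i] - kin.na_m.inf[ivs]) * kin.na_m.dec[ivs];
      g_na_h[i] = kin.na_h.inf[ivs] + (g_na_h[i] - kin.na_h.inf[ivs]) * kin.na_h.dec[ivs];
      g_kd_n[i] = kin.kd_n.inf[ivs] + (g_kd_n[i] - kin.kd_n.inf[ivs]) * kin.kd_n.dec[ivs];
      g_cat_m[i] = cat_m.inf[ivs] + (g_cat_m[i] - cat_m.inf[ivs]) * cat_m.dec[ivs];
      g_cat_h[i] = cat_h.inf[ivs] + (g_cat_h[i] - cat_h.inf[ivs]) * cat_h.dec[ivs];
      g_ih_s[i] = kin.ih_m.inf[ivs] + (g_ih_s[i] - kin.ih_m.inf[ivs]) * kin.ih_m.dec[ivs];
      g_ka_m[i] = kin.ka_m.inf[ivs] + (g_ka_m[i] - kin.ka_m.inf[ivs]) * kin.ka_m.dec[ivs];
      g_ka_h[i] = kin.ka_h.inf[ivs] + (g_ka_h[i] - kin.ka_h.inf[ivs]) * kin.ka_h.dec[ivs];
      g_kv3[i] = kin.kv3_m.inf[ivs] + (g_kv3[i] - kin.kv3_m.inf[ivs]) * kin.kv3_m.dec[ivs];
      // dendrite
      g_catd_m[i] = cat_m.inf[ivd] + (g_catd_m[i] - cat_m.inf[ivd]) * cat_m.dec[ivd];
      g_catd_h[i] = cat_h.inf[ivd] + (g_catd_h[i] - cat_h.inf[ivd]) * cat_h.dec[ivd];
      g_ih_d[i] = kin.ih_m.inf[ivd] + (g_ih_d[i] - kin.ih_m.inf[ivd]) * kin.ih_m.dec[ivd];

      double area_s = par(i, P_AREA_S), area_d = par(i, P_AREA_D);
      double cs = par(i, P_CM) * area_s * 1e3; // nF
      double cd = par(i, P_CM) * area_d * 1e3;
      double gc = par(i, P_GCOUPLE); // uS

      // soma conductances (uS): S/cm2 * cm2 * 1e6
      double m = g_na_m[i], h = g_na_h[i], n = g_kd_n[i];
      double gna = par(i, P_GNA) * area_s * 1e6 * m * m * m * h;
      double gkd = par(i, P_GKD) * area_s * 1e6 * n * n * n * n;
      double mnap = 1.0 / (1.0 + std::exp(-(v_s + 57.9) / 6.4));
      double gnap = par(i, P_GNAP) * area_s * 1e6 * mnap;
      double gka = par(i, P_GKA) * area_s * 1e6 * std::pow(g_ka_m[i], 4.0) * g_ka_h[i];
      double gkv3 = par(i, P_GKV3) * area_s * 1e6 * g_kv3[i];
      double gcat = par(i, P_GCAT_S) * area_s * 1e6 * g_cat_m[i] * g_cat_m[i] * g_cat_h[i];
      double mcah = 1.0 / (1.0 + std::exp(-(v_s + 20.0) / 9.0));
      double gcah = par(i, P_GCAH) * area_s * 1e6 * mcah * mcah;
      double ca2 = cas[i] * cas[i];
      double gsk = par(i, P_GSK_S) * area_s * 1e6 * ca2 / (ca2 + 0.0009); // k = 0.03 mM
      double gih = par(i, P_GIH_S) * area_s * 1e6 * g_ih_s[i];
      double gl = par(i, P_GLEAK_S) * area_s * 1e6;

      double Gs = gna + gkd + gnap + gka + gkv3 + gcat + gcah + gsk + gih + gl + gc + gj_g_s[i];
      double Is = gna * E_NA + gnap * E_NA + (gkd + gka + gkv3 + gsk) * E_K +
                  (gcat + gcah) * E_CA + gih * E_H + gl * par(i, P_ELEAK) +
                  gc * v_d + gj_i_s[i] + hold_i[i];
      if (!ipulse.empty()) Is += ipulse[i];

      // dendrite conductances
      double gcatd = par(i, P_GCAT_D) * area_d * 1e6 * g_catd_m[i] * g_catd_m[i] * g_catd_h[i];
      double cad2 = cad[i] * cad[i];
      double gskd = par(i, P_GSK_D) * area_d * 1e6 * cad2 / (cad2 + 0.0009);
      double gihd = par(i, P_GIH_D) * area_d * 1e6 * g_ih_d[i];
      double gld = par(i, P_GLEAK_D) * area_d * 1e6;
      double Gd = gcatd + gskd + gihd + gld + gc + gj_g_d[i];
      double Id = gcatd * E_CA + gskd * E_K + gihd * E_H + gld * par(i, P_ELEAK) +
                  gc * v_s + gj_i_d[i];

      // synaptic inputs
      for (int c = 0; c < n_class; c++) {
        size_t ss = ((size_t)i * 2) * n_class + c;
        size_t sd = ((size_t)i * 2 + 1) * n_class + c;
        double gsyn_s = synB[ss] - synA[ss];
        double gsyn_d = synB[sd] - synA[sd];
        if (classes[c].nmda) {
          gsyn_s *= mgblock(v_s);
          gsyn_d *= mgblock(v_d);
        }
        if (gsyn_s > 0) { Gs += gsyn_s; Is += gsyn_s * classes[c].e_rev; }
        if (gsyn_d > 0) { Gd += gsyn_d; Id += gsyn_d * classes[c].e_rev; }
      }

      // exponential Euler
      double vinf_s = Is / Gs;
      double vinf_d = Id / Gd;
      double nvs = vinf_s + (v_s - vinf_s) * std::exp(-dt * Gs / cs);
      double nvd = vinf_d + (v_d - vinf_d) * std::exp(-dt * Gd / cd);

      // calcium pools: influx from CaT + CaH; density current mA/cm2
      double ica_s = (gcat + gcah) * (v_s - E_CA) * 1e-6 / area_s; // uS*mV=nA -> mA/cm2
      double ica_d = gcatd * (v_d - E_CA) * 1e-6 / area_d;
      double drive_s = -par(i, P_GAMMA) * ica_s * 5.1821; // mM/ms, depth 0.1 um
      double drive_d = -par(i, P_GAMMA) * ica_d * 5.1821;
      if (drive_s < 0) drive_s = 0;
      if (drive_d < 0) drive_d = 0;
      double tca = par(i, P_TAUCA);
      cas[i] += dt * (drive_s - (cas[i] - 5e-5) / tca);
      cad[i] += dt * (drive_d - (cad[i] - 5e-5) / tca);

      // spike detection on soma, 1 ms refractory
      if (v_s < spike_thresh && nvs >= spike_thresh && t - last_spike[i] >= 1.0) {
        last_spike[i] = t;
        spike_cell_out.push_back(i);
        spike_time_out.push_back(t + dt);
        for (int e : cell_out[i])
          ring[(step + delay_steps[e]) % ring_n].push_back(e);
      }

      vs[i] = nvs; vd[i] = nvd;
      if (!(std::fabs(nvs) < 200.0) || !(std::fabs(nvd) < 200.0)) {
        diverged = true; diverge_t = t; diverge_cell = i;
      }
    }

    if (!rec.empty() && step % rec_every == 0) {
      int ri = step / rec_every;
      for (size_t k = 0; k < rec.size(); k++) traces(ri, (int)k) = vs[rec[k]];
      rec_time.push_back(t);
    }
  }

  if (diverged)
    stop("numerical divergence (|V| > 200 mV) at t = %f ms in cell %d",
         diverge_t, diverge_cell);

  return List::create(
    _["spike_cell"] = wrap(spike_cell_out),
    _["spike_time"] = wrap(spike_time_out),
    _["trace_time"] = wrap(rec_time),
    _["traces"] = traces,
    _["v_final"] = wrap(vs));
}

// Single-cell simulation with an arbitrary injected soma current vector
// (nA, one value per step). Returns soma and dendrite voltage traces.
// [[Rcpp::export]]
List cpp_simulate_cell(NumericVector prow, double dt, NumericVector inj,
                       double vinit) {
  int n_steps = inj.size();
  Kinetics kin;
  kin.build(dt);

  double v_s = vinit, v_d = vinit;
  double cas = 5e-5, cad = 5e-5;
  int iv = vidx(v_s);
  bool re = prow[P_CATVAR] > 0.5;
  const Gate& cat_m = re ? kin.catr_m : kin.catc_m;
  const Gate& cat_h = re ? kin.catr_h : kin.catc_h;
  double m = kin.na_m.inf[iv], h = kin.na_h.inf[iv], n = kin.kd_n.inf[iv];
  double mt = cat_m.inf[iv], ht = cat_h.inf[iv];
  double mtd = mt, htd = ht;
  double mih = kin.ih_m.inf[iv], mihd = mih;
  double mka = kin.ka_m.inf[iv], hka = kin.ka_h.inf[iv];
  double mkv = kin.kv3_m.inf[iv];

  NumericVector out_vs(n_steps), out_vd(n_steps);
  double area_s = prow[P_AREA_S], area_d = prow[P_AREA_D];
  double cs = prow[P_CM] * area_s * 1e3, cd = prow[P_CM] * area_d * 1e3;
  double gc = prow[P_GCOUPLE];

  for (int step = 0; step < n_steps; step++) {
    int ivs = vidx(v_s), ivd = vidx(v_d);
    m = kin.na_m.inf[ivs] + (m - kin.na_m.inf[ivs]) * kin.na_m.dec[ivs];
    h = kin.na_h.inf[ivs] + (h - kin.na_h.inf[ivs]) * kin.na_h.dec[ivs];
    n = kin.kd_n.inf[ivs] + (n - kin.kd_n.inf[ivs]) * kin.kd_n.dec[ivs];
    mt = cat_m.inf[ivs] + (mt - cat_m.inf[ivs]) * cat_m.dec[ivs];
    ht = cat_h.inf[ivs] + (ht - cat_h.inf[ivs]) * cat_h.dec[ivs];
    mih = kin.ih_m.inf[ivs] + (mih - kin.ih_m.inf[ivs]) * kin.ih_m.dec[ivs];
    mka = kin.ka_m.inf[ivs] + (mka - kin.ka_m.inf[ivs]) * kin.ka_m.dec[ivs];
    hka = kin.ka_h.inf[ivs] + (hka - kin.ka_h.inf[ivs]) * kin.ka_h.dec[ivs];
    mkv = kin.kv3_m.inf[ivs] + (mkv - kin.kv3_m.inf[ivs]) * kin.kv3_m.dec[ivs];
    mtd = cat_m.inf[ivd] + (mtd - cat_m.inf[ivd]) * cat_m.dec[ivd];
    htd = cat_h.inf[ivd] + (htd - cat_h.inf[ivd]) * cat_h.dec[ivd];
    mihd = kin.ih_m.inf[ivd] + (mihd - kin.ih_m.inf[ivd]) * kin.ih_m.dec[ivd];

    double gna = prow[P_GNA] * area_s * 1e6 * m * m * m * h;
    double gkd = prow[P_GKD] * area_s * 1e6 * n * n * n * n;
    double mnap = 1.0 / (1.0 + std::exp(-(v_s + 57.9) / 6.4));
    double gnap = prow[P_GNAP] * area_s * 1e6 * mnap;
    double gka = prow[P_GKA] * area_s * 1e6 * std::pow(mka, 4.0) * hka;
    double gkv3 = prow[P_GKV3] * area_s * 1e6 * mkv;
    double gcat = prow[P_GCAT_S] * area_s * 1e6 * mt * mt * ht;
    double mcah = 1.0 / (1.0 + std::exp(-(v_s + 20.0) / 9.0));
    double gcah = prow[P_GCAH] * area_s * 1e6 * mcah * mcah;
    double ca2 = cas * cas;
    double gsk = prow[P_GSK_S] * area_s * 1e6 * ca2 / (ca2 + 0.0009);
    double gih = prow[P_GIH_S] * area_s * 1e6 * mih;
    double gl = prow[P_GLEAK_S] * area_s * 1e6;

    double Gs = gna + gkd + gnap + gka + gkv3 + gcat + gcah + gsk + gih + gl + gc;
    double Is = gna * E_NA + gnap * E_NA + (gkd + gka + gkv3 + gsk) * E_K +
                (gcat + gcah) * E_CA + gih * E_H + gl * prow[P_ELEAK] +
                gc * v_d + inj[step];

    double gcatd = prow[P_GCAT_D] * area_d * 1e6 * mtd * mtd * htd;
    double cad2 = cad * cad;
    double gskd = prow[P_GSK_D] * area_d * 1e6 * cad2 / (cad2 + 0.0009);
    double gihd = prow[P_GIH_D] * area_d * 1e6 * mihd;
    double gld = prow[P_GLEAK_D] * area_d * 1e6;
    double Gd = gcatd + gskd + gihd + gld + gc;
    double Id = gcatd * E_CA + gskd * E_K + gihd * E_H + gld * prow[P_ELEAK] + gc * v_s;

    double vinf_s = Is / Gs, vinf_d = Id / Gd;
    double nvs = vinf_s + (v_s - vinf_s) * std::exp(-dt * Gs / cs);
    double nvd = vinf_d + (v_d - vinf_d) * std::exp(-dt * Gd / cd);

    double ica_s = (gcat + gcah) * (v_s - E_CA) * 1e-6 / area_s;
    double ica_d = gcatd * (v_d - E_CA) * 1e-6 / area_d;
    double drive_s = std::max(0.0, -prow[P_GAMMA] * ica_s * 5.1821);
    double drive_d = std::max(0.0, -prow[P_GAMMA] * ica_d * 5.1821);
    cas += dt * (drive_s - (cas - 5e-5) / prow[P_TAUCA]);
    cad += dt * (drive_d - (cad - 5e-5) / prow[P_TAUCA]);

    v_s = nvs; v_d = nvd;
    if (!(std::fabs(v_s) < 200.0))
      stop("numerical divergence (|V| > 200 mV) at t = %f ms", step * dt);
    out_vs[step] = v_s;
    out_vd[step] = v_d;
  }
  return List::create(_["v_soma"] = out_vs, _["v_dend"] = out_vd);
}
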