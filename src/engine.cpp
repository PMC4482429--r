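// Lattice tissue engine: pressure/ischemia-reperfusion injury plus
// threshold-gated inflammation on a toroidal grid. One tick = one hour.
// All stochastic draws come from a single per-simulation Mersenne twister
// whose state travels inside the SimState, so checkpointed runs resume
// bit-exactly.

#include <Rcpp.h>
#include <random>
#include <sstream>
#include <vector>
#include <cmath>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

static const int NLAY = 9;
static const char* LAYER_NAMES[NLAY] = {
  "oxygen", "damp", "tnf", "il1", "tgf", "ros", "steroid", "antidamp", "antiox"
};
enum { L_OXY = 0, L_DAMP, L_TNF, L_IL1, L_TGF, L_ROS, L_STER, L_AD, L_AOX };

// ---------------------------------------------------------------- config ---

struct Cfg {
  int W, H;
  double vessel_density, vsize_min, vsize_max;
  double oxy_rate, oxy_cons;
  double diff[NLAY], deg[NLAY];
  int substeps;
  double thr_isch, o2_sens, tnf_sens, tgf_sens, ros_sens;
  double heal_rate, isch_pen, ox_acc, ros_coeff, conv_frac, reperf_o2_cost;
  double ros_thr; int ros_limit; double ros_pen;
  double damp_rate, death_damp_burst, tnf_rate, il1_rate, tgf_rate;
  double tnf_coeff, tnf_sat, tgf_coeff;
  double thr_damp_N, thr_tnf_M1, thr_il1_M1, thr_il1_M2, thr_tgf_M2, thr_direct;
  double p_act_N, p_M1, p_M2, o2_act_thr;
  int n_ls_min, n_ls_max, n_act_bonus, m_ls_min, m_ls_max;
  double n_death_ros;
  double rec_N, rec_M;
  double chemo_floor;
  int site_cap;
  double p_intensity; int p_half; double p_plateau, p_falloff, p_constrict;
  int p_profile;               // 0 linear, 1 gaussian
  std::vector<int> p_on_ticks; // explicit schedule (sorted); empty = cyclic
  double inj_frac, inj_radius;
  int stress_mode;             // 0 = decreasing life, 1 = life below 100
  double ster_thr, ster_ros_burst;
  int ster_mode;               // 0 kill_all, 1 kill_activated, 2 disable
  int ster_delivery;           // 0 infusion, 1 bolus
  double ad_quench;
  double aox_rate, aox_quench;
  int tr_agent;                // 0 none, 1 steroid, 2 antidamp
  double tr_dose; int tr_onset;
};

static double getd(const List& l, const char* nm) {
  if (!l.containsElementNamed(nm)) stop("config field missing: %s", nm);
  return as<double>(l[nm]);
}
static int geti(const List& l, const char* nm) {
  if (!l.containsElementNamed(nm)) stop("config field missing: %s", nm);
  return as<int>(l[nm]);
}
static std::string gets(const List& l, const char* nm) {
  if (!l.containsElementNamed(nm)) stop("config field missing: %s", nm);
  return as<std::string>(l[nm]);
}

static Cfg parse_cfg(const List& cl) {
  Cfg c;
  c.W = geti(cl, "grid_width"); c.H = geti(cl, "grid_height");
  if (c.W < 1 || c.H < 1) stop("grid dimensions must be positive");
  c.vessel_density = getd(cl, "vessel_density");
  c.vsize_min = getd(cl, "vessel_size_min");
  c.vsize_max = getd(cl, "vessel_size_max");
  if (c.vsize_max >= 2.0 * c.vsize_min)
    stop("vessel_size_max must be smaller than twice vessel_size_min");
  c.oxy_rate = getd(cl, "oxygen_production_rate");
  c.oxy_cons = getd(cl, "oxygen_consumption_rate");
  for (int k = 0; k < NLAY; ++k) {
    std::string f = std::string(LAYER_NAMES[k]) + "_diffusion_fraction";
    std::string g = std::string(LAYER_NAMES[k]) + "_degradation_rate";
    c.diff[k] = getd(cl, f.c_str());
    c.deg[k]  = getd(cl, g.c_str());
  }
  c.substeps = geti(cl, "diffusion_substeps");
  c.thr_isch = getd(cl, "oxygen_ischemia_threshold");
  c.o2_sens = getd(cl, "oxygen_sensitivity");
  c.tnf_sens = getd(cl, "tnf_sensitivity");
  c.tgf_sens = getd(cl, "tgf_sensitivity");
  c.ros_sens = getd(cl, "ros_sensitivity");
  c.heal_rate = getd(cl, "heal_rate");
  c.isch_pen = getd(cl, "ischemia_penalty");
  c.ox_acc = getd(cl, "oxidase_accumulation_rate");
  c.ros_coeff = getd(cl, "reperfusion_ros_coeff");
  c.conv_frac = getd(cl, "reperfusion_conversion_fraction");
  c.reperf_o2_cost = getd(cl, "reperfusion_oxygen_cost");
  c.ros_thr = getd(cl, "ros_event_threshold");
  c.ros_limit = geti(cl, "ros_insult_limit");
  c.ros_pen = getd(cl, "ros_insult_penalty");
  c.damp_rate = getd(cl, "damp_secretion_rate");
  c.death_damp_burst = getd(cl, "tissue_death_damp_burst");
  c.tnf_rate = getd(cl, "tnf_secretion_rate");
  c.il1_rate = getd(cl, "il1_secretion_rate");
  c.tgf_rate = getd(cl, "tgf_secretion_rate");
  c.tnf_coeff = getd(cl, "tnf_damage_coeff");
  c.tnf_sat = getd(cl, "tnf_damage_saturation");
  c.tgf_coeff = getd(cl, "tgf_heal_coeff");
  c.thr_damp_N = getd(cl, "thr_damp_activate_N");
  c.thr_tnf_M1 = getd(cl, "thr_tnf_to_M1");
  c.thr_il1_M1 = getd(cl, "thr_il1_to_M1");
  c.thr_il1_M2 = getd(cl, "thr_il1_to_M2");
  if (c.thr_il1_M2 <= c.thr_il1_M1)
    stop("thr_il1_to_M2 must exceed thr_il1_to_M1");
  c.thr_tgf_M2 = getd(cl, "thr_tgf_to_M2");
  c.thr_direct = getd(cl, "thr_direct_damage_activation");
  c.p_act_N = getd(cl, "p_activate_N");
  c.o2_act_thr = getd(cl, "o2_activation_threshold");
  c.p_M1 = getd(cl, "p_switch_M1");
  c.p_M2 = getd(cl, "p_switch_M2");
  c.n_ls_min = geti(cl, "neutrophil_lifespan_min");
  c.n_ls_max = geti(cl, "neutrophil_lifespan_max");
  c.n_act_bonus = geti(cl, "neutrophil_activated_lifespan_bonus");
  c.m_ls_min = geti(cl, "macrophage_lifespan_min");
  c.m_ls_max = geti(cl, "macrophage_lifespan_max");
  c.n_death_ros = getd(cl, "neutrophil_death_ros_burst");
  c.rec_N = getd(cl, "recruitment_rate_N");
  c.rec_M = getd(cl, "recruitment_rate_M");
  c.chemo_floor = getd(cl, "chemotaxis_floor");
  c.site_cap = geti(cl, "leukocyte_site_capacity");
  c.p_intensity = getd(cl, "pressure_intensity");
  c.p_half = geti(cl, "pressure_half_period");
  c.p_plateau = getd(cl, "pressure_plateau_radius");
  c.p_falloff = getd(cl, "pressure_falloff_radius");
  if (c.p_falloff < c.p_plateau)
    stop("pressure_falloff_radius must be >= pressure_plateau_radius");
  c.p_constrict = getd(cl, "pressure_constriction_coeff");
  std::string prof = gets(cl, "pressure_profile");
  c.p_profile = (prof == "gaussian") ? 1 : 0;
  if (cl.containsElementNamed("pressure_on_ticks") &&
      !Rf_isNull(cl["pressure_on_ticks"])) {
    IntegerVector ot = cl["pressure_on_ticks"];
    c.p_on_ticks.assign(ot.begin(), ot.end());
    std::sort(c.p_on_ticks.begin(), c.p_on_ticks.end());
  }
  c.inj_frac = getd(cl, "initial_injury_fraction");
  c.inj_radius = getd(cl, "initial_injury_radius");
  std::string sm = gets(cl, "stress_mode");
  c.stress_mode = (sm == "below_max") ? 1 : 0;
  c.ster_thr = getd(cl, "steroid_threshold");
  c.ster_ros_burst = getd(cl, "steroid_neutrophil_ros_burst");
  std::string smode = gets(cl, "steroid_mode");
  c.ster_mode = (smode == "kill_activated") ? 1 : (smode == "disable") ? 2 : 0;
  std::string sdel = gets(cl, "steroid_delivery");
  c.ster_delivery = (sdel == "bolus") ? 1 : 0;
  c.ad_quench = getd(cl, "antidamp_quench_coeff");
  c.aox_rate = getd(cl, "antiox_production_rate");
  c.aox_quench = getd(cl, "antiox_quench_coeff");
  std::string ag = gets(cl, "treatment_agent");
  c.tr_agent = (ag == "steroid") ? 1 : (ag == "antidamp") ? 2 : 0;
  c.tr_dose = getd(cl, "treatment_dose");
  c.tr_onset = geti(cl, "treatment_onset_tick");
  return c;
}

// ------------------------------------------------------------------- rng ---

static inline double runif01(std::mt19937& g) {
  // 32-bit mantissa uniform in [0, 1); portable across standard libraries
  return g() * (1.0 / 4294967296.0);
}
static inline int runif_int(std::mt19937& g, int a, int b) {
  int n = b - a + 1;
  int k = (int)(runif01(g) * n);
  if (k >= n) k = n - 1;
  return a + k;
}

static std::string rng_save(const std::mt19937& g) {
  std::ostringstream os; os << g; return os.str();
}
static void rng_load(std::mt19937& g, const std::string& s) {
  std::istringstream is(s); is >> g;
  if (is.fail()) stop("corrupt RNG state in checkpoint");
}

// ----------------------------------------------------------------- world ---

struct World {
  int W, H, tick;
  std::vector<double> life, prev_life, oxidase;
  std::vector<int> insults, alive;
  std::vector<double> lay[NLAY];
  std::vector<int> vx, vy; std::vector<double> vbase, vcur;
  std::vector<int> valive;
  std::vector<int> kkind, kstate, kage, klifespan, kx, ky; // leukocytes
  bool antidamp_applied;
  std::mt19937 rng;
};

static World world_from_list(const List& st) {
  World w;
  w.W = as<int>(st["width"]); w.H = as<int>(st["height"]);
  w.tick = as<int>(st["tick"]);
  size_t n = (size_t)w.W * w.H;
  NumericMatrix life = st["life"], prev = st["prev_life"], oxid = st["oxidase"];
  IntegerMatrix ins = st["insults"], alv = st["alive"];
  if ((size_t)life.size() != n) stop("state/grid size mismatch");
  w.life.assign(life.begin(), life.end());
  w.prev_life.assign(prev.begin(), prev.end());
  w.oxidase.assign(oxid.begin(), oxid.end());
  w.insults.assign(ins.begin(), ins.end());
  w.alive.assign(alv.begin(), alv.end());
  List lays = st["layers"];
  for (int k = 0; k < NLAY; ++k) {
    NumericMatrix m = lays[LAYER_NAMES[k]];
    if ((size_t)m.size() != n) stop("layer size mismatch: %s", LAYER_NAMES[k]);
    w.lay[k].assign(m.begin(), m.end());
  }
  List vs = st["vessels"];
  IntegerVector vx = vs["x"], vy = vs["y"], va = vs["alive"];
  NumericVector vb = vs["base_size"], vc = vs["current_size"];
  w.vx.assign(vx.begin(), vx.end()); w.vy.assign(vy.begin(), vy.end());
  w.vbase.assign(vb.begin(), vb.end()); w.vcur.assign(vc.begin(), vc.end());
  w.valive.assign(va.begin(), va.end());
  List lk = st["leukocytes"];
  IntegerVector kk = lk["kind"], ks = lk["state"], ka = lk["age"],
    kl = lk["lifespan"], kxx = lk["x"], kyy = lk["y"];
  w.kkind.assign(kk.begin(), kk.end()); w.kstate.assign(ks.begin(), ks.end());
  w.kage.assign(ka.begin(), ka.end()); w.klifespan.assign(kl.begin(), kl.end());
  w.kx.assign(kxx.begin(), kxx.end()); w.ky.assign(kyy.begin(), kyy.end());
  w.antidamp_applied = as<bool>(st["antidamp_applied"]);
  rng_load(w.rng, as<std::string>(st["rng_state"]));
  return w;
}

static List world_to_list(const World& w) {
  size_t n = (size_t)w.W * w.H;
  NumericMatrix life(w.W, w.H), prev(w.W, w.H), oxid(w.W, w.H);
  IntegerMatrix ins(w.W, w.H), alv(w.W, w.H);
  std::copy(w.life.begin(), w.life.end(), life.begin());
  std::copy(w.prev_life.begin(), w.prev_life.end(), prev.begin());
  std::copy(w.oxidase.begin(), w.oxidase.end(), oxid.begin());
  std::copy(w.insults.begin(), w.insults.end(), ins.begin());
  std::copy(w.alive.begin(), w.alive.end(), alv.begin());
  List lays(NLAY);
  CharacterVector lnm(NLAY);
  for (int k = 0; k < NLAY; ++k) {
    NumericMatrix m(w.W, w.H);
    std::copy(w.lay[k].begin(), w.lay[k].end(), m.begin());
    lays[k] = m; lnm[k] = LAYER_NAMES[k];
  }
  lays.attr("names") = lnm;
  List vs = List::create(
    _["x"] = IntegerVector(w.vx.begin(), w.vx.end()),
    _["y"] = IntegerVector(w.vy.begin(), w.vy.end()),
    _["base_size"] = NumericVector(w.vbase.begin(), w.vbase.end()),
    _["current_size"] = NumericVector(w.vcur.begin(), w.vcur.end()),
    _["alive"] = IntegerVector(w.valive.begin(), w.valive.end()));
  List lk = List::create(
    _["kind"] = IntegerVector(w.kkind.begin(), w.kkind.end()),
    _["state"] = IntegerVector(w.kstate.begin(), w.kstate.end()),
    _["age"] = IntegerVector(w.kage.begin(), w.kage.end()),
    _["lifespan"] = IntegerVector(w.klifespan.begin(), w.klifespan.end()),
    _["x"] = IntegerVector(w.kx.begin(), w.kx.end()),
    _["y"] = IntegerVector(w.ky.begin(), w.ky.end()));
  List st = List::create(
    _["tick"] = w.tick, _["width"] = w.W, _["height"] = w.H,
    _["life"] = life, _["prev_life"] = prev, _["oxidase"] = oxid,
    _["insults"] = ins, _["alive"] = alv, _["layers"] = lays,
    _["vessels"] = vs, _["leukocytes"] = lk,
    _["antidamp_applied"] = w.antidamp_applied,
    _["rng_state"] = rng_save(w.rng));
  st.attr("class") = "sim_state";
  return st;
}

// ------------------------------------------------------------- geometry ---

static inline int wrap(int a, int n) { a %= n; return a < 0 ? a + n : a; }

static inline double tor_dist(double x1, double y1, double x2, double y2,
                              int W, int H) {
  double dx = std::fabs(x1 - x2); if (dx > W - dx) dx = W - dx;
  double dy = std::fabs(y1 - y2); if (dy > H - dy) dy = H - dy;
  return std::sqrt(dx * dx + dy * dy);
}

// neighbour offsets, fixed order
static const int NBX[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int NBY[8] = {-1, -1, -1, 0, 0, 1, 1, 1};

// --------------------------------------------------------------- kernels ---

static inline double pressure_value(double r, double intensity,
                                    double plateau, double falloff,
                                    bool on, int profile) {
  if (!on || intensity <= 0) return 0.0;
  if (r <= plateau) return intensity;
  if (profile == 1) { // gaussian shoulder beyond the plateau
    double s = (falloff - plateau) / 2.0;
    if (s <= 0) return 0.0;
    double z = (r - plateau) / s;
    return intensity * std::exp(-0.5 * z * z);
  }
  if (r >= falloff) return 0.0;
  return intensity * (falloff - r) / (falloff - plateau);
}

static inline double vessel_size_under(double base, double pressure,
                                       double coeff) {
  double s = base * (1.0 - coeff * pressure);
  return s > 0 ? s : 0.0;
}

struct TissueOut {
  double life, oxidase, o2_after, ros_add, damp_add;
  int insults;
  bool died;
};

// Per-cell, per-tick tissue rule: oxygen consumption, ischemia vs healing,
// oxidase handling, reperfusion ROS burst, stepwise ROS insults, TNF damage,
// TGF healing, clamping, death, DAMP release.
static inline TissueOut tissue_update(double life0, double oxid, int ins,
                                      double o2, double tnf, double tgf,
                                      double ros_in, const Cfg& c) {
  TissueOut out;
  double take = o2 < c.oxy_cons ? o2 : c.oxy_cons;
  o2 -= take;
  double delta = 0.0, ros_add = 0.0;
  if (o2 < c.thr_isch) {                  // ischemic
    oxid += c.ox_acc;
    delta -= c.isch_pen * c.o2_sens;
  } else {                                // perfused (threshold counts as fed)
    delta += c.heal_rate * c.o2_sens;
    if (oxid > 0) {                       // reperfusion: oxidase -> ROS
      double conv = c.conv_frac * oxid;
      ros_add += c.ros_coeff * conv;
      oxid -= conv;
      double cost = o2 < c.reperf_o2_cost ? o2 : c.reperf_o2_cost;
      o2 -= cost;
    }
  }
  double ros_level = ros_in + ros_add;
  if (c.ros_sens > 0 && ros_level > c.ros_thr / c.ros_sens) {
    ins += 1;
    if (ins >= c.ros_limit) { delta -= c.ros_pen; ins = 0; }
  }
  delta -= c.tnf_sens * c.tnf_coeff * (tnf < c.tnf_sat ? tnf : c.tnf_sat);
  delta += c.tgf_sens * c.tgf_coeff * tgf;
  double nl = life0 + delta;
  if (nl > 100.0) nl = 100.0;
  if (nl < 0.0) nl = 0.0;
  double damp_add = 0.0;
  if (c.stress_mode == 0) {
    if (nl < life0) damp_add = c.damp_rate * (life0 - nl) / 100.0;
  } else {
    if (nl < 100.0) damp_add = c.damp_rate * (100.0 - nl) / 100.0;
  }
  out.life = nl; out.oxidase = oxid; out.insults = ins;
  out.o2_after = o2; out.ros_add = ros_add; out.damp_add = damp_add;
  out.died = (nl <= 0.0);
  return out;
}

// pick a neighbour index 0..7: argmax attractant above the sensing floor
// (ties broken uniformly), else uniform random walk
static inline int chemo_pick(const double* a, double floor_, std::mt19937& g) {
  double mx = a[0];
  for (int i = 1; i < 8; ++i) if (a[i] > mx) mx = a[i];
  if (mx > floor_) {
    int ties[8], nt = 0;
    for (int i = 0; i < 8; ++i) if (a[i] == mx) ties[nt++] = i;
    if (nt == 1) return ties[0];
    int k = (int)(runif01(g) * nt); if (k >= nt) k = nt - 1;
    return ties[k];
  }
  int k = (int)(runif01(g) * 8); if (k >= 8) k = 7;
  return k;
}

// crowding-aware variant: neighbours at the occupancy cap are not enterable;
// if every neighbour is full the agent stays put (returns -1)
static inline int chemo_pick_masked(const double* a, const int* occ, int cap,
                                    double floor_, std::mt19937& g) {
  int free_[8], nf = 0;
  for (int i = 0; i < 8; ++i) if (occ[i] < cap) free_[nf++] = i;
  if (nf == 0) return -1;
  double mx = a[free_[0]];
  for (int i = 1; i < nf; ++i) if (a[free_[i]] > mx) mx = a[free_[i]];
  if (mx > floor_) {
    int ties[8], nt = 0;
    for (int i = 0; i < nf; ++i) if (a[free_[i]] == mx) ties[nt++] = free_[i];
    if (nt == 1) return ties[0];
    int k = (int)(runif01(g) * nt); if (k >= nt) k = nt - 1;
    return ties[k];
  }
  int k = (int)(runif01(g) * nf); if (k >= nf) k = nf - 1;
  return free_[k];
}

// ------------------------------------------------------------ diffusion ---

// mass-conserving 8-neighbour lattice diffusion on the torus: each cell
// keeps (1-f) of its content and sends f/8 to each Moore neighbour
static void diffuse_once(std::vector<double>& v, std::vector<double>& tmp,
                         double f, int W, int H) {
  const double keep = 1.0 - f, give = f / 8.0;
  for (int y = 0; y < H; ++y) {
    int ym = (y == 0 ? H - 1 : y - 1), yp = (y == H - 1 ? 0 : y + 1);
    const double* rm = &v[(size_t)W * ym];
    const double* r0 = &v[(size_t)W * y];
    const double* rp = &v[(size_t)W * yp];
    double* t = &tmp[(size_t)W * y];
    for (int x = 0; x < W; ++x) {
      int xm = (x == 0 ? W - 1 : x - 1), xp = (x == W - 1 ? 0 : x + 1);
      double nb = rm[xm] + rm[x] + rm[xp] + r0[xm] + r0[xp] +
                  rp[xm] + rp[x] + rp[xp];
      t[x] = keep * r0[x] + give * nb;
    }
  }
  v.swap(tmp);
}

static void transport_layer(World& w, const Cfg& c, int k,
                            std::vector<double>& tmp) {
  if (c.diff[k] > 0) {
    bool any = false;
    for (double x : w.lay[k]) if (x > 0) { any = true; break; }
    if (any)
      for (int s = 0; s < c.substeps; ++s)
        diffuse_once(w.lay[k], tmp, c.diff[k], w.W, w.H);
  }
  if (c.deg[k] > 0) {
    double keep = 1.0 - c.deg[k];
    for (double& x : w.lay[k]) x *= keep;
  }
}

// --------------------------------------------------------- oxygen equil ---

static void release_oxygen(World& w, const Cfg& c, double base_mean) {
  for (size_t i = 0; i < w.vx.size(); ++i) {
    if (!w.valive[i]) continue;
    double amt = c.oxy_rate * (w.vcur[i] / base_mean);
    if (amt > 0) w.lay[L_OXY][w.vx[i] + (size_t)w.W * w.vy[i]] += amt;
    if (c.aox_rate > 0)
      w.lay[L_AOX][w.vx[i] + (size_t)w.W * w.vy[i]] +=
        c.aox_rate * (w.vcur[i] / base_mean);
  }
}

static void consume_oxygen(World& w, const Cfg& c) {
  if (c.oxy_cons <= 0) return;
  size_t n = (size_t)w.W * w.H;
  for (size_t i = 0; i < n; ++i) {
    if (!w.alive[i]) continue;
    double& o = w.lay[L_OXY][i];
    o = o < c.oxy_cons ? 0.0 : o - c.oxy_cons;
  }
}

// iterate source -> transport -> sink to a fixed point so healthy tissue is
// oxygen-stable from tick 0
static void equilibrate_oxygen(World& w, const Cfg& c, double tol, int maxit) {
  size_t n = (size_t)w.W * w.H;
  std::vector<double> tmp(n), prev(n);
  double base_mean = 0;
  for (double b : w.vbase) base_mean += b;
  base_mean /= std::max((size_t)1, w.vbase.size());
  for (int it = 0; it < maxit; ++it) {
    prev = w.lay[L_OXY];
    release_oxygen(w, c, base_mean);
    transport_layer(w, c, L_OXY, tmp);
    consume_oxygen(w, c);
    double mx = 0;
    for (size_t i = 0; i < n; ++i) {
      double d = std::fabs(w.lay[L_OXY][i] - prev[i]);
      if (d > mx) mx = d;
    }
    if (mx < tol) break;
  }
}

// ------------------------------------------------------------- the tick ---

static bool pressure_on(const Cfg& c, int t) {
  if (c.p_intensity <= 0) return false;
  if (!c.p_on_ticks.empty())
    return std::binary_search(c.p_on_ticks.begin(), c.p_on_ticks.end(), t);
  if (c.p_half <= 0) return true;
  return (((t - 1) / c.p_half) % 2) == 0;
}

struct TickStats { double feat[13]; int dead; };

static void record_features(const World& w, TickStats& s) {
  size_t n = (size_t)w.W * w.H;
  double dmg = 0; int dead = 0;
  for (size_t i = 0; i < n; ++i) {
    dmg += 100.0 - w.life[i];
    if (!w.alive[i]) ++dead;
  }
  double lays[NLAY];
  for (int k = 0; k < NLAY; ++k) {
    double t = 0; for (double x : w.lay[k]) t += x; lays[k] = t;
  }
  double oxid = 0; for (double x : w.oxidase) oxid += x;
  double flow = 0; for (double x : w.vcur) flow += x;
  int actn = 0, m1 = 0, m2 = 0;
  for (size_t j = 0; j < w.kkind.size(); ++j) {
    if (w.kkind[j] == 1) { if (w.kstate[j] == 1) ++actn; }
    else { if (w.kstate[j] == 1) ++m1; else if (w.kstate[j] == 2) ++m2; }
  }
  s.feat[0] = dmg;            // total-damage
  s.feat[1] = lays[L_DAMP];   // total-danger
  s.feat[2] = lays[L_TNF];    // total-tnf
  s.feat[3] = lays[L_IL1];    // total-il1
  s.feat[4] = lays[L_TGF];    // total-tgf
  s.feat[5] = lays[L_ROS];    // total-radical
  s.feat[6] = oxid;           // total-oxidase
  s.feat[7] = lays[L_AOX];    // total-antiox
  s.feat[8] = lays[L_OXY];    // total-oxygen
  s.feat[9] = flow;           // blood-flow
  s.feat[10] = actn;          // activated-neutrophils
  s.feat[11] = m1;            // m1-count
  s.feat[12] = m2;            // m2-count
  s.dead = dead;
}

static void one_tick(World& w, const Cfg& c, double base_mean,
                     std::vector<double>& tmp) {
  const int t = ++w.tick;
  const int W = w.W, H = w.H;
  const double cx = (W - 1) / 2.0, cy = (H - 1) / 2.0;

  // (1) pressure field and vessel constriction
  const bool on = pressure_on(c, t);
  for (size_t i = 0; i < w.vx.size(); ++i) {
    if (!w.valive[i]) { w.vcur[i] = 0.0; continue; }
    double p = pressure_value(tor_dist(w.vx[i], w.vy[i], cx, cy, W, H),
                              c.p_intensity, c.p_plateau, c.p_falloff,
                              on, c.p_profile);
    w.vcur[i] = vessel_size_under(w.vbase[i], p, c.p_constrict);
  }

  // (2) vessel oxygen release and leukocyte recruitment
  release_oxygen(w, c, base_mean);
  for (size_t i = 0; i < w.vx.size(); ++i) {
    if (!w.valive[i]) continue;
    double ratio = w.vbase[i] > 0 ? w.vcur[i] / w.vbase[i] : 0.0;
    if (c.rec_N > 0 && runif01(w.rng) < c.rec_N * ratio) {
      w.kkind.push_back(1); w.kstate.push_back(0); w.kage.push_back(0);
      w.klifespan.push_back(runif_int(w.rng, c.n_ls_min, c.n_ls_max));
      w.kx.push_back(w.vx[i]); w.ky.push_back(w.vy[i]);
    }
    if (c.rec_M > 0 && runif01(w.rng) < c.rec_M * ratio) {
      w.kkind.push_back(2); w.kstate.push_back(0); w.kage.push_back(0);
      w.klifespan.push_back(runif_int(w.rng, c.m_ls_min, c.m_ls_max));
      w.kx.push_back(w.vx[i]); w.ky.push_back(w.vy[i]);
    }
  }

  // (3) transport: diffusion then degradation, then antioxidant quenching
  for (int k = 0; k < NLAY; ++k) transport_layer(w, c, k, tmp);
  if (c.aox_quench > 0) {
    size_t n = (size_t)W * H;
    for (size_t i = 0; i < n; ++i) {
      double a = w.lay[L_AOX][i], r = w.lay[L_ROS][i];
      if (a > 0 && r > 0) {
        double d = c.aox_quench * (a < r ? a : r);
        w.lay[L_AOX][i] = a - d; w.lay[L_ROS][i] = r - d;
      }
    }
  }

  // (4) tissue cells: consumption, ischemia/healing, reperfusion ROS,
  //     insults, mediator-driven life change, DAMP release
  {
    size_t n = (size_t)W * H;
    (void)n;
    for (size_t i = 0; i < n; ++i) {
      if (!w.alive[i]) continue;
      double life0 = w.life[i];
      TissueOut o = tissue_update(life0, w.oxidase[i], w.insults[i],
                                  w.lay[L_OXY][i], w.lay[L_TNF][i],
                                  w.lay[L_TGF][i], w.lay[L_ROS][i], c);
      w.lay[L_OXY][i] = o.o2_after;
      w.lay[L_ROS][i] += o.ros_add;
      w.lay[L_DAMP][i] += o.damp_add;
      w.oxidase[i] = o.oxidase;
      w.insults[i] = o.insults;
      w.life[i] = o.life;
      w.prev_life[i] = life0;
      if (o.died) {
        w.alive[i] = 0; w.life[i] = 0.0; w.oxidase[i] = 0.0;
        // necrotic death releases a DAMP burst and destroys local vasculature
        w.lay[L_DAMP][i] += c.death_damp_burst;
        for (size_t v = 0; v < w.vx.size(); ++v)
          if (w.valive[v] && (size_t)(w.vx[v] + (size_t)W * w.vy[v]) == i) {
            w.valive[v] = 0; w.vcur[v] = 0.0;
          }
      }
    }
  }

  // (5) leukocytes: chemotaxis, activation/polarisation, secretion
  {
    size_t nk = w.kkind.size();
    std::vector<int> occN((size_t)W * H, 0), occM((size_t)W * H, 0);
    for (size_t j = 0; j < nk; ++j) {
      size_t ii = w.kx[j] + (size_t)W * w.ky[j];
      if (w.kkind[j] == 1) ++occN[ii]; else ++occM[ii];
    }
    for (size_t j = 0; j < nk; ++j) {
      int x = w.kx[j], y = w.ky[j];
      // attractant field by kind/state (Table-1 chemoattraction map)
      double att[8];
      for (int d = 0; d < 8; ++d) {
        int xn = wrap(x + NBX[d], W), yn = wrap(y + NBY[d], H);
        size_t ii = xn + (size_t)W * yn;
        double a;
        if (w.kkind[j] == 1) a = w.lay[L_DAMP][ii];
        else if (w.kstate[j] == 0)
          a = w.lay[L_TNF][ii] + w.lay[L_IL1][ii] + w.lay[L_TGF][ii];
        else if (w.kstate[j] == 1) a = w.lay[L_TNF][ii] + w.lay[L_IL1][ii];
        else a = w.lay[L_TGF][ii];
        att[d] = a;
      }
      int occ[8];
      std::vector<int>& oc = (w.kkind[j] == 1) ? occN : occM;
      for (int d = 0; d < 8; ++d) {
        int xn = wrap(x + NBX[d], W), yn = wrap(y + NBY[d], H);
        occ[d] = oc[xn + (size_t)W * yn];
      }
      int d = chemo_pick_masked(att, occ, c.site_cap, c.chemo_floor, w.rng);
      if (d >= 0) {
        --oc[x + (size_t)W * y];
        x = wrap(x + NBX[d], W); y = wrap(y + NBY[d], H);
        ++oc[x + (size_t)W * y];
        w.kx[j] = x; w.ky[j] = y;
      }
      size_t here = x + (size_t)W * y;

      bool suppressed = (c.ster_mode == 2 && c.tr_agent == 1 &&
                         w.lay[L_STER][here] >= c.ster_thr);
      if (suppressed) continue;

      if (w.kkind[j] == 1) { // neutrophil
        if (w.kstate[j] == 0) {
          // DAMP receptor signalling works regardless of oxygenation;
          // contact activation by damaged tissue needs an oxygenated site
          bool elig = w.lay[L_DAMP][here] > c.thr_damp_N;
          if (!elig && c.thr_direct < 100 &&
              w.lay[L_OXY][here] >= c.o2_act_thr) {
            // direct activation by badly damaged adjacent tissue
            double mx = w.alive[here] ? 100.0 - w.life[here] : 0.0;
            for (int dd = 0; dd < 8 && mx <= c.thr_direct; ++dd) {
              int xn = wrap(x + NBX[dd], W), yn = wrap(y + NBY[dd], H);
              size_t ii = xn + (size_t)W * yn;
              if (w.alive[ii]) {
                double dmg = 100.0 - w.life[ii];
                if (dmg > mx) mx = dmg;
              }
            }
            elig = mx > c.thr_direct;
          }
          if (elig && runif01(w.rng) < c.p_act_N) {
            w.kstate[j] = 1;
            w.klifespan[j] += c.n_act_bonus;
          }
        }
        if (w.kstate[j] == 1) w.lay[L_TNF][here] += c.tnf_rate;
      } else {               // macrophage
        int target = -1;
        if (w.lay[L_IL1][here] > c.thr_il1_M2 ||
            w.lay[L_TGF][here] > c.thr_tgf_M2) target = 2;
        else if (w.lay[L_TNF][here] > c.thr_tnf_M1 ||
                 w.lay[L_IL1][here] > c.thr_il1_M1) target = 1;
        if (target >= 0 && target != w.kstate[j]) {
          double p = target == 2 ? c.p_M2 : c.p_M1;
          if (runif01(w.rng) < p) w.kstate[j] = target;
        }
        if (w.kstate[j] == 1) w.lay[L_IL1][here] += c.il1_rate;
        else if (w.kstate[j] == 2) w.lay[L_TGF][here] += c.tgf_rate;
      }
    }
  }

  // (6) treatments
  std::vector<char> killed(w.kkind.size(), 0);
  if (c.tr_agent == 1 && c.tr_dose > 0 && t >= c.tr_onset) {
    bool deposit = (c.ster_delivery == 0) || (t == c.tr_onset);
    if (deposit)
      for (size_t i = 0; i < w.vx.size(); ++i) {
        if (!w.valive[i]) continue;
        double ratio = w.vbase[i] > 0 ? w.vcur[i] / w.vbase[i] : 0.0;
        w.lay[L_STER][w.vx[i] + (size_t)w.W * w.vy[i]] += c.tr_dose * ratio;
      }
    if (c.ster_mode != 2) {
      for (size_t j = 0; j < w.kkind.size(); ++j) {
        size_t here = w.kx[j] + (size_t)W * w.ky[j];
        if (w.lay[L_STER][here] < c.ster_thr) continue;
        if (c.ster_mode == 1 && w.kstate[j] == 0) continue;
        killed[j] = 1;
        if (w.kkind[j] == 1 && c.ster_ros_burst > 0)
          w.lay[L_ROS][here] += c.ster_ros_burst;
      }
    }
  }
  if (c.tr_agent == 2 && c.tr_dose > 0 && t >= c.tr_onset) {
    size_t n = (size_t)W * H;
    if (t == c.tr_onset && !w.antidamp_applied) {
      for (size_t i = 0; i < n; ++i) w.lay[L_AD][i] = c.tr_dose;
      w.antidamp_applied = true;
    }
    if (c.ad_quench > 0)
      for (size_t i = 0; i < n; ++i) {
        double a = w.lay[L_AD][i], dm = w.lay[L_DAMP][i];
        if (a > 0 && dm > 0) {
          double d = c.ad_quench * (a < dm ? a : dm);
          w.lay[L_AD][i] = a - d; w.lay[L_DAMP][i] = dm - d;
        }
      }
  }

  // (7) aging and death; compact the roster preserving order
  {
    size_t nk = w.kkind.size(), out = 0;
    for (size_t j = 0; j < nk; ++j) {
      w.kage[j] += 1;
      bool dead = killed.size() > j && killed[j];
      if (!dead && w.kage[j] >= w.klifespan[j]) {
        dead = true;
        if (w.kkind[j] == 1 && c.n_death_ros > 0)
          w.lay[L_ROS][w.kx[j] + (size_t)W * w.ky[j]] += c.n_death_ros;
      }
      if (!dead) {
        if (out != j) {
          w.kkind[out] = w.kkind[j]; w.kstate[out] = w.kstate[j];
          w.kage[out] = w.kage[j]; w.klifespan[out] = w.klifespan[j];
          w.kx[out] = w.kx[j]; w.ky[out] = w.ky[j];
        }
        ++out;
      }
    }
    w.kkind.resize(out); w.kstate.resize(out); w.kage.resize(out);
    w.klifespan.resize(out); w.kx.resize(out); w.ky.resize(out);
  }
}

// ------------------------------------------------------------- exports ----

// [[Rcpp::export]]
List cpp_init_state(List config, int seed) {
  Cfg c = parse_cfg(config);
  World w;
  w.W = c.W; w.H = c.H; w.tick = 0; w.antidamp_applied = false;
  size_t n = (size_t)c.W * c.H;
  w.life.assign(n, 100.0); w.prev_life.assign(n, 100.0);
  w.oxidase.assign(n, 0.0);
  w.insults.assign(n, 0); w.alive.assign(n, 1);
  for (int k = 0; k < NLAY; ++k) w.lay[k].assign(n, 0.0);
  w.rng.seed((uint32_t)seed);

  // vessels on a jittered regular lattice
  int s = (int)std::lround(1.0 / std::sqrt(c.vessel_density));
  if (s < 1) s = 1;
  int nx = std::max(1, c.W / s), ny = std::max(1, c.H / s);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int jx = runif_int(w.rng, -1, 1), jy = runif_int(w.rng, -1, 1);
      double sz = c.vsize_min + runif01(w.rng) * (c.vsize_max - c.vsize_min);
      w.vx.push_back(wrap(i * s + s / 2 + jx, c.W));
      w.vy.push_back(wrap(j * s + s / 2 + jy, c.H));
      w.vbase.push_back(sz);
      w.vcur.push_back(sz);
      w.valive.push_back(1);
    }

  // central initial injury (multiplicative life reduction on a disc)
  if (c.inj_frac > 0 && c.inj_radius > 0) {
    double cx = (c.W - 1) / 2.0, cy = (c.H - 1) / 2.0;
    for (int y = 0; y < c.H; ++y)
      for (int x = 0; x < c.W; ++x)
        if (tor_dist(x, y, cx, cy, c.W, c.H) <= c.inj_radius) {
          size_t i = x + (size_t)c.W * y;
          w.life[i] = 100.0 * (1.0 - c.inj_frac);
          w.prev_life[i] = w.life[i];
          // the injury itself is a stress event: it releases the same
          // drop-scaled DAMP burst a within-run life drop would
          w.lay[L_DAMP][i] += c.damp_rate * (100.0 - w.life[i]) / 100.0;
        }
  }

  equilibrate_oxygen(w, c, 1e-6, 20000);
  return world_to_list(w);
}

// Advance the simulation n_ticks; returns the final state plus a per-tick
// feature matrix (tick, the 13 whole-field features, cumulative dead cells).
// [[Rcpp::export]]
List cpp_run(List state, List config, int n_ticks, bool record = true) {
  Cfg c = parse_cfg(config);
  World w = world_from_list(state);
  if (w.W != c.W || w.H != c.H) stop("state and config grid sizes differ");
  size_t n = (size_t)w.W * w.H;
  std::vector<double> tmp(n);
  double base_mean = 0;
  for (double b : w.vbase) base_mean += b;
  base_mean /= std::max((size_t)1, w.vbase.size());

  NumericMatrix feats(record ? n_ticks : 0, 15);
  TickStats ts;
  for (int it = 0; it < n_ticks; ++it) {
    one_tick(w, c, base_mean, tmp);
    if (record) {
      record_features(w, ts);
      feats(it, 0) = w.tick;
      for (int k = 0; k < 13; ++k) feats(it, k + 1) = ts.feat[k];
      feats(it, 14) = ts.dead;
    }
  }
  CharacterVector cn = CharacterVector::create(
    "tick", "total-damage", "total-danger", "total-tnf", "total-il1",
    "total-tgf", "total-radical", "total-oxidase", "total-antiox",
    "total-oxygen", "blood-flow", "activated-neutrophils", "m1-count",
    "m2-count", "dead-cells");
  colnames(feats) = cn;
  return List::create(_["state"] = world_to_list(w), _["features"] = feats);
}

// [[Rcpp::export]]
NumericVector cpp_features(List state) {
  World w = world_from_list(state);
  TickStats ts;
  record_features(w, ts);
  NumericVector out(14);
  for (int k = 0; k < 13; ++k) out[k] = ts.feat[k];
  out[13] = ts.dead;
  out.attr("names") = CharacterVector::create(
    "total-damage", "total-danger", "total-tnf", "total-il1", "total-tgf",
    "total-radical", "total-oxidase", "total-antiox", "total-oxygen",
    "blood-flow", "activated-neutrophils", "m1-count", "m2-count",
    "dead-cells");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_pressure_at(NumericVector r, double intensity,
                              double plateau, double falloff, bool on,
                              std::string profile = "linear") {
  int prof = profile == "gaussian" ? 1 : 0;
  NumericVector out(r.size());
  for (int i = 0; i < r.size(); ++i)
    out[i] = pressure_value(r[i], intensity, plateau, falloff, on, prof);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_vessel_size(NumericVector base, NumericVector pressure,
                              double coeff) {
  if (base.size() != pressure.size()) stop("length mismatch");
  NumericVector out(base.size());
  for (int i = 0; i < base.size(); ++i)
    out[i] = vessel_size_under(base[i], pressure[i], coeff);
  return out;
}

// [[Rcpp::export]]
List cpp_tissue_kernel(double life, double oxidase, int insults, double o2,
                       double tnf, double tgf, double ros, List config) {
  Cfg c = parse_cfg(config);
  TissueOut o = tissue_update(life, oxidase, insults, o2, tnf, tgf, ros, c);
  return List::create(
    _["life"] = o.life, _["oxidase"] = o.oxidase, _["insults"] = o.insults,
    _["oxygen_after"] = o.o2_after, _["ros_add"] = o.ros_add,
    _["damp_add"] = o.damp_add, _["died"] = o.died);
}

// [[Rcpp::export]]
int cpp_chemotax_pick(NumericVector neigh8, double floor_, int seed) {
  if (neigh8.size() != 8) stop("need 8 neighbour values");
  std::mt19937 g((uint32_t)seed);
  double a[8];
  for (int i = 0; i < 8; ++i) a[i] = neigh8[i];
  return chemo_pick(a, floor_, g) + 1; // 1-based for R
}

// [[Rcpp::export]]
NumericMatrix cpp_diffuse(NumericMatrix m, double fraction, int substeps = 1) {
  int W = m.nrow(), H = m.ncol();
  std::vector<double> v(m.begin(), m.end()), tmp(v.size());
  for (int s = 0; s < substeps; ++s) diffuse_once(v, tmp, fraction, W, H);
  NumericMatrix out(W, H);
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
std::string cpp_rng_state(int seed) {
  std::mt19937 g((uint32_t)seed);
  return rng_save(g);
}
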