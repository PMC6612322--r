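// Multiscale Brownian-Dynamics engine.
//
// Three coupled subsystems, advanced by operator splitting within one fixed
// time step dt (minutes, micrometres everywhere):
//   (f) extracellular field: EGF introduction on an outer shell, diffusion,
//       reflection at the domain boundary and at cell membranes, degradation,
//       reversible binding to membrane EGFR clusters;
//   (i) per-cell interior: Ras/Raf/ERK/TF particles diffusing in their
//       compartments, bimolecular activation on reaction-radius overlap,
//       first-order switch-off with exponentially distributed residence times;
//   (m) mechanics: cycle clock, G1 transcription-factor checkpoint, linear
//       growth, division, apoptosis, and centre-based repulsive motion.
//
// All randomness flows through per-subsystem mt19937_64 streams seeded from
// (master seed, subsystem id, call epoch) so that adding a cell does not
// perturb the draws of other subsystems.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <map>
#include <string>
#include <cmath>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------- seeding --

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t mix3(uint64_t a, uint64_t b, uint64_t c) {
  return splitmix64(splitmix64(splitmix64(a) + b) + c);
}

// ----------------------------------------------------------- random stream --

struct Stream {
  std::mt19937_64 g;
  std::normal_distribution<double> nd;
  explicit Stream(uint64_t s) : g(s), nd(0.0, 1.0) {}
  double unif() { return std::uniform_real_distribution<double>(0.0, 1.0)(g); }
  double norm() { return nd(g); }
  double expo(double rate) {
    return std::exponential_distribution<double>(rate)(g);
  }
  int pois(double mean) {
    if (mean <= 0.0) return 0;
    return std::poisson_distribution<int>(mean)(g);
  }
  void unit_vec(double* u) {
    double x = norm(), y = norm(), z = norm();
    double r = std::sqrt(x * x + y * y + z * z);
    if (r < 1e-300) { u[0] = 0; u[1] = 0; u[2] = 1; }
    else { u[0] = x / r; u[1] = y / r; u[2] = z / r; }
  }
};

static Stream* get_stream(SEXP p) {
  XPtr<Stream> xp(p);
  return xp.get();
}

// [[Rcpp::export]]
SEXP cpp_rng_new(double seed, double stream_id) {
  XPtr<Stream> p(new Stream(mix3((uint64_t)seed, (uint64_t)stream_id, 0ULL)),
                 true);
  return p;
}

// [[Rcpp::export]]
NumericVector cpp_runif(SEXP rng, int n) {
  Stream* s = get_stream(rng);
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = s->unif();
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rnorm(SEXP rng, int n) {
  Stream* s = get_stream(rng);
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = s->norm();
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rexp(SEXP rng, double rate, int n) {
  Stream* s = get_stream(rng);
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = s->expo(rate);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_rpois(SEXP rng, double mean, int n) {
  Stream* s = get_stream(rng);
  IntegerVector out(n);
  for (int i = 0; i < n; i++) out[i] = s->pois(mean);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_runit(SEXP rng, int n) {
  Stream* s = get_stream(rng);
  NumericMatrix out(n, 3);
  double u[3];
  for (int i = 0; i < n; i++) {
    s->unit_vec(u);
    out(i, 0) = u[0]; out(i, 1) = u[1]; out(i, 2) = u[2];
  }
  return out;
}

// --------------------------------------------------------------- geometry --

// Mirror reflection of a radial coordinate into [rin, rout], iterated so that
// large steps near a boundary still land inside the shell.
static inline double reflect_radial(double r, double rin, double rout) {
  int it = 0;
  while ((r < rin || r > rout) && it++ < 64) {
    if (r > rout) r = 2.0 * rout - r;
    if (r < 0.0) r = -r;
    if (r < rin) r = 2.0 * rin - r;
  }
  if (r < rin || r > rout) r = 0.5 * (rin + rout);
  return r;
}

static inline void reflect_pt(double& x, double& y, double& z,
                              double cx, double cy, double cz,
                              double rin, double rout) {
  double dx = x - cx, dy = y - cy, dz = z - cz;
  double r = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (r >= rin && r <= rout) return;
  if (r < 1e-12) {  // degenerate: at the centre of a shell with rin > 0
    x = cx; y = cy; z = cz + rin;
    return;
  }
  double rn = reflect_radial(r, rin, rout);
  double sc = rn / r;
  x = cx + dx * sc; y = cy + dy * sc; z = cz + dz * sc;
}

// [[Rcpp::export]]
NumericMatrix cpp_reflect_shell(NumericMatrix p, NumericVector centre,
                                double r_inner, double r_outer) {
  NumericMatrix out = clone(p);
  for (int i = 0; i < out.nrow(); i++) {
    double x = out(i, 0), y = out(i, 1), z = out(i, 2);
    reflect_pt(x, y, z, centre[0], centre[1], centre[2], r_inner, r_outer);
    out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_brownian_step(NumericMatrix p, double D, double dt,
                                SEXP rng) {
  Stream* s = get_stream(rng);
  double sd = std::sqrt(2.0 * D * dt);
  NumericMatrix out = clone(p);
  for (int i = 0; i < out.nrow(); i++)
    for (int j = 0; j < 3; j++) out(i, j) += sd * s->norm();
  return out;
}

// Uniform point in the spherical shell [rin, rout] (volume-weighted radius).
static inline void sample_shell(Stream& s, double rin, double rout,
                                double* p) {
  double u[3];
  s.unit_vec(u);
  double a = rin * rin * rin, b = rout * rout * rout;
  double r = std::cbrt(a + (b - a) * s.unif());
  p[0] = u[0] * r; p[1] = u[1] * r; p[2] = u[2] * r;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_shell(SEXP rng, double r_inner, double r_outer,
                               int n) {
  Stream* s = get_stream(rng);
  NumericMatrix out(n, 3);
  double p[3];
  for (int i = 0; i < n; i++) {
    sample_shell(*s, r_inner, r_outer, p);
    out(i, 0) = p[0]; out(i, 1) = p[1]; out(i, 2) = p[2];
  }
  return out;
}

// ----------------------------------------------------------- neighbor grid --

// Uniform binning of catalyst positions over the cube [-L, L]^3.  Box size is
// never smaller than the query radius so a 27-box neighborhood is sufficient.
struct Grid {
  double lo, cell;
  int n;
  std::vector<int> head, nxt;
  const std::vector<double>*X, *Y, *Z;

  void build(double L, double cellsize,
             const std::vector<double>& xs, const std::vector<double>& ys,
             const std::vector<double>& zs) {
    lo = -L;
    cell = cellsize;
    n = std::max(1, (int)std::ceil(2.0 * L / cell));
    head.assign((size_t)n * n * n, -1);
    nxt.assign(xs.size(), -1);
    X = &xs; Y = &ys; Z = &zs;
    for (size_t i = 0; i < xs.size(); i++) {
      int b = bin3(xs[i], ys[i], zs[i]);
      nxt[i] = head[b];
      head[b] = (int)i;
    }
  }
  inline int bin1(double v) const {
    int i = (int)std::floor((v - lo) / cell);
    if (i < 0) i = 0;
    if (i >= n) i = n - 1;
    return i;
  }
  inline int bin3(double x, double y, double z) const {
    return (bin1(x) * n + bin1(y)) * n + bin1(z);
  }
  // returns index of first stored point within radius sig of (x,y,z), or -1
  inline int find_within(double x, double y, double z, double sig) const {
    double s2 = sig * sig;
    int bx = bin1(x), by = bin1(y), bz = bin1(z);
    for (int ix = std::max(0, bx - 1); ix <= std::min(n - 1, bx + 1); ix++)
      for (int iy = std::max(0, by - 1); iy <= std::min(n - 1, by + 1); iy++)
        for (int iz = std::max(0, bz - 1); iz <= std::min(n - 1, bz + 1);
             iz++) {
          int k = head[(ix * n + iy) * n + iz];
          while (k >= 0) {
            double dx = (*X)[k] - x, dy = (*Y)[k] - y, dz = (*Z)[k] - z;
            if (dx * dx + dy * dy + dz * dz < s2) return k;
            k = nxt[k];
          }
        }
    return -1;
  }
};

// ------------------------------------------------------------- data model --

// species codes
enum { RAS = 0, RAF = 1, ERKP = 2, TFP = 3 };
// cell phases
enum { PH_G1 = 0, PH_COMMITTED = 1, PH_CORPSE = 2 };

struct Mut {
  bool kras, braf;
  double krasMult, brafMult;
  int nEgfr;
};

struct Interior {
  std::vector<int> sp, on;
  std::vector<double> x, y, z, soff;
  size_t size() const { return sp.size(); }
};

struct CellC {
  int id;
  double pos[3], vel[3];
  double R, Rn, birthV, cclock, clen;
  int phase;
  Mut mut;
  Interior in;
  // receptors: unit anchor directions + state
  std::vector<double> rax, ray, raz, rsoff;
  std::vector<int> ron;
};

struct Cfg {
  double Rdom, shell, Degf, intro, degr, rEgf, rRec, kOffRec;
  bool rerelease;
  double Rc, Rnuc;
  int nRas, nRaf, nErk, nTf;
  double Dprot, rBD, kRas, kRaf, kErk, kTf, krasMult, brafMult;
  int nEgfr;
  double dt, mass, mu, K, g1, cycMin, cycMax, NtfStar;
  bool useGrid, fieldOn, mechOn, fateOn, keepCorpses;
  std::string order;
};

static Cfg parse_cfg(List cfg) {
  Cfg f;
  f.Rdom = as<double>(cfg["domain_radius"]);
  f.shell = as<double>(cfg["shell_thickness"]);
  f.Degf = as<double>(cfg["d_egf"]);
  f.intro = as<double>(cfg["introduction_rate"]);
  f.degr = as<double>(cfg["degradation_rate"]);
  f.rEgf = as<double>(cfg["r_egf"]);
  f.rRec = as<double>(cfg["r_receptor"]);
  f.kOffRec = as<double>(cfg["k_off_receptor"]);
  f.rerelease = as<bool>(cfg["egf_rerelease"]);
  f.Rc = as<double>(cfg["cell_radius"]);
  f.Rnuc = as<double>(cfg["nucleus_radius"]);
  f.nRas = as<int>(cfg["n_ras"]);
  f.nRaf = as<int>(cfg["n_raf"]);
  f.nErk = as<int>(cfg["n_erk"]);
  f.nTf = as<int>(cfg["n_tf"]);
  f.Dprot = as<double>(cfg["d_protein"]);
  f.rBD = as<double>(cfg["r_bd"]);
  f.kRas = as<double>(cfg["k_inact_ras"]);
  f.kRaf = as<double>(cfg["k_inact_raf"]);
  f.kErk = as<double>(cfg["k_inact_erk"]);
  f.kTf = as<double>(cfg["k_inact_tf"]);
  f.krasMult = as<double>(cfg["kras_multiplier"]);
  f.brafMult = as<double>(cfg["braf_multiplier"]);
  f.nEgfr = as<int>(cfg["n_egfr"]);
  f.dt = as<double>(cfg["dt"]);
  f.mass = as<double>(cfg["mass"]);
  f.mu = as<double>(cfg["friction"]);
  f.K = as<double>(cfg["k_repulsion"]);
  f.g1 = as<double>(cfg["g1_duration"]);
  f.cycMin = as<double>(cfg["cycle_min"]);
  f.cycMax = as<double>(cfg["cycle_max"]);
  f.NtfStar = as<double>(cfg["n_tf_star"]);
  f.useGrid = as<bool>(cfg["use_grid"]);
  f.fieldOn = as<bool>(cfg["field_enabled"]);
  f.mechOn = as<bool>(cfg["mechanics_enabled"]);
  f.fateOn = as<bool>(cfg["fate_enabled"]);
  f.keepCorpses = as<bool>(cfg["keep_corpses"]);
  f.order = as<std::string>(cfg["operator_order"]);
  return f;
}

struct World {
  double clock;
  int nextId;
  uint64_t seed;
  int epoch;
  Cfg cfg;
  std::vector<double> ex, ey, ez, edeg;  // free EGF particles
  std::vector<CellC> cells;
  std::map<int, Stream> streams;  // per-cell
  Stream fieldS, mechS;

  World(uint64_t sd, int ep)
      : clock(0), nextId(1), seed(sd), epoch(ep),
        fieldS(mix3(sd, 0xF1E1DULL, (uint64_t)ep)),
        mechS(mix3(sd, 0x3EC4ULL, (uint64_t)ep)) {}

  Stream& cs(int id) {
    auto it = streams.find(id);
    if (it == streams.end())
      it = streams
               .emplace(id, Stream(mix3(seed, 1000ULL + (uint64_t)id,
                                        (uint64_t)epoch)))
               .first;
    return it->second;
  }
};

// ------------------------------------------------------------- marshaling --

static Interior interior_from_list(List li) {
  Interior in;
  IntegerVector sp = li["species"], on = li["state"];
  NumericMatrix pos = li["pos"];
  NumericVector soff = li["soff"];
  int n = sp.size();
  in.sp.resize(n); in.on.resize(n);
  in.x.resize(n); in.y.resize(n); in.z.resize(n); in.soff.resize(n);
  for (int i = 0; i < n; i++) {
    in.sp[i] = sp[i] - 1;  // R uses 1..4
    in.on[i] = on[i];
    in.x[i] = pos(i, 0); in.y[i] = pos(i, 1); in.z[i] = pos(i, 2);
    in.soff[i] = soff[i];
  }
  return in;
}

static List interior_to_list(const Interior& in) {
  int n = (int)in.size();
  IntegerVector sp(n), on(n);
  NumericMatrix pos(n, 3);
  NumericVector soff(n);
  for (int i = 0; i < n; i++) {
    sp[i] = in.sp[i] + 1;
    on[i] = in.on[i];
    pos(i, 0) = in.x[i]; pos(i, 1) = in.y[i]; pos(i, 2) = in.z[i];
    soff[i] = in.soff[i];
  }
  return List::create(_["species"] = sp, _["state"] = on, _["pos"] = pos,
                      _["soff"] = soff);
}

static CellC cell_from_list(List lc) {
  CellC c;
  c.id = as<int>(lc["id"]);
  NumericVector p = lc["pos"], v = lc["vel"];
  for (int j = 0; j < 3; j++) { c.pos[j] = p[j]; c.vel[j] = v[j]; }
  c.R = as<double>(lc["radius"]);
  c.Rn = as<double>(lc["nucleus_radius"]);
  c.birthV = as<double>(lc["birth_volume"]);
  c.cclock = as<double>(lc["cycle_clock"]);
  c.clen = as<double>(lc["cycle_length"]);
  std::string ph = as<std::string>(lc["phase"]);
  c.phase = (ph == "committed") ? PH_COMMITTED
            : (ph == "corpse") ? PH_CORPSE : PH_G1;
  List mu = lc["mutation"];
  c.mut.kras = as<bool>(mu["kras"]);
  c.mut.braf = as<bool>(mu["braf"]);
  c.mut.krasMult = as<double>(mu["kras_multiplier"]);
  c.mut.brafMult = as<double>(mu["braf_multiplier"]);
  c.mut.nEgfr = as<int>(mu["n_egfr"]);
  c.in = interior_from_list(lc["interior"]);
  List rc = lc["receptors"];
  NumericMatrix an = rc["anchor"];
  IntegerVector ron = rc["state"];
  NumericVector rs = rc["soff"];
  int m = an.nrow();
  c.rax.resize(m); c.ray.resize(m); c.raz.resize(m);
  c.ron.resize(m); c.rsoff.resize(m);
  for (int k = 0; k < m; k++) {
    c.rax[k] = an(k, 0); c.ray[k] = an(k, 1); c.raz[k] = an(k, 2);
    c.ron[k] = ron[k]; c.rsoff[k] = rs[k];
  }
  return c;
}

static List cell_to_list(const CellC& c) {
  int m = (int)c.ron.size();
  NumericMatrix an(m, 3);
  IntegerVector ron(m);
  NumericVector rs(m);
  for (int k = 0; k < m; k++) {
    an(k, 0) = c.rax[k]; an(k, 1) = c.ray[k]; an(k, 2) = c.raz[k];
    ron[k] = c.ron[k]; rs[k] = c.rsoff[k];
  }
  std::string ph = (c.phase == PH_COMMITTED) ? "committed"
                   : (c.phase == PH_CORPSE) ? "corpse" : "g1";
  return List::create(
      _["id"] = c.id,
      _["pos"] = NumericVector::create(c.pos[0], c.pos[1], c.pos[2]),
      _["vel"] = NumericVector::create(c.vel[0], c.vel[1], c.vel[2]),
      _["radius"] = c.R, _["nucleus_radius"] = c.Rn,
      _["birth_volume"] = c.birthV, _["phase"] = ph,
      _["cycle_clock"] = c.cclock, _["cycle_length"] = c.clen,
      _["mutation"] = List::create(
          _["kras"] = c.mut.kras, _["braf"] = c.mut.braf,
          _["kras_multiplier"] = c.mut.krasMult,
          _["braf_multiplier"] = c.mut.brafMult, _["n_egfr"] = c.mut.nEgfr),
      _["interior"] = interior_to_list(c.in),
      _["receptors"] = List::create(_["anchor"] = an, _["state"] = ron,
                                    _["soff"] = rs));
}

// ------------------------------------------------------- interior stepping --

// Initial (and post-division) placement domain for one molecule.
static inline void place_molecule(Stream& s, int sp, int on, double Rc,
                                  double Rn, double* p) {
  if (sp == TFP) sample_shell(s, 0.0, Rn, p);
  else if (sp == ERKP && on) sample_shell(s, 0.0, Rc, p);
  else sample_shell(s, Rn, Rc, p);
}

// One interior step: (a) diffuse + reflect into compartments, (b) fire
// bimolecular activations on reaction-radius overlap (catalyst states frozen
// at the start of the sub-step), (c) switch off molecules past their
// switch-off time.  kEff holds the mutation-adjusted inactivation rates.
static void interior_step(Interior& in, double Rc, double Rn,
                          const std::vector<double>& icx,
                          const std::vector<double>& icy,
                          const std::vector<double>& icz,
                          const double kEff[4], double Dprot, double rBD,
                          double rRec, double dt, double now, Stream& s,
                          bool useGrid) {
  double sd = std::sqrt(2.0 * Dprot * dt);
  size_t n = in.size();
  for (size_t i = 0; i < n; i++) {
    int sp = in.sp[i];
    double rin, rout;
    if (sp == RAS || sp == RAF) { rin = Rn; rout = Rc; }
    else if (sp == TFP) { rin = 0.0; rout = Rn; }
    else {  // ERK: whole cell when active, cytoplasm when inactive; an ERK
            // switched off inside the nucleus diffuses out freely first.
      if (in.on[i]) { rin = 0.0; rout = Rc; }
      else {
        double r0 = std::sqrt(in.x[i] * in.x[i] + in.y[i] * in.y[i] +
                              in.z[i] * in.z[i]);
        if (r0 < Rn) { rin = 0.0; rout = Rc; }
        else { rin = Rn; rout = Rc; }
      }
    }
    in.x[i] += sd * s.norm();
    in.y[i] += sd * s.norm();
    in.z[i] += sd * s.norm();
    reflect_pt(in.x[i], in.y[i], in.z[i], 0, 0, 0, rin, rout);
  }

  // catalyst snapshot (positions + indices per species)
  std::vector<double> cx[3], cy[3], cz[3];
  for (size_t i = 0; i < n; i++)
    if (in.on[i] && in.sp[i] < 3) {
      int sp = in.sp[i];
      cx[sp].push_back(in.x[i]);
      cy[sp].push_back(in.y[i]);
      cz[sp].push_back(in.z[i]);
    }

  std::vector<int> newly;
  double sigRec = rRec + rBD, s2rec = sigRec * sigRec;
  double sig = 2.0 * rBD;

  // reaction 1: Ras_off activated by the G-protein (inner) sphere of an
  // active receptor cluster
  if (!icx.empty()) {
    for (size_t i = 0; i < n; i++) {
      if (in.sp[i] != RAS || in.on[i]) continue;
      for (size_t k = 0; k < icx.size(); k++) {
        double dx = in.x[i] - icx[k], dy = in.y[i] - icy[k],
               dz = in.z[i] - icz[k];
        if (dx * dx + dy * dy + dz * dz < s2rec) {
          newly.push_back((int)i);
          break;
        }
      }
    }
  }

  // reactions 2, 4, 6: target species t activated by catalyst species t-1
  Grid grid;
  for (int t = RAF; t <= TFP; t++) {
    const std::vector<double>& kx = cx[t - 1];
    if (kx.empty()) continue;
    bool grd = useGrid && kx.size() > 8;
    if (grd) {
      double cellsize = std::max(sig, Rc / 6.0);
      grid.build(Rc, cellsize, cx[t - 1], cy[t - 1], cz[t - 1]);
    }
    double s2 = sig * sig;
    for (size_t i = 0; i < n; i++) {
      if (in.sp[i] != t || in.on[i]) continue;
      if (grd) {
        if (grid.find_within(in.x[i], in.y[i], in.z[i], sig) >= 0)
          newly.push_back((int)i);
      } else {
        for (size_t k = 0; k < kx.size(); k++) {
          double dx = in.x[i] - cx[t - 1][k], dy = in.y[i] - cy[t - 1][k],
                 dz = in.z[i] - cz[t - 1][k];
          if (dx * dx + dy * dy + dz * dz < s2) {
            newly.push_back((int)i);
            break;
          }
        }
      }
    }
  }

  for (size_t j = 0; j < newly.size(); j++) {
    int i = newly[j];
    in.on[i] = 1;
    in.soff[i] = now + s.expo(kEff[in.sp[i]]);
  }

  // first-order switch-off (reactions 1-reverse, 3, 5, 7)
  for (size_t i = 0; i < n; i++)
    if (in.on[i] && in.soff[i] <= now) in.on[i] = 0;
}

// G-protein sphere centres of the active receptors, in cell-local
// coordinates (the interior is simulated in the cell frame, so cell motion
// does not advect interior particles).
static void cell_inner_centres(const CellC& c, double rRec,
                               std::vector<double>& icx,
                               std::vector<double>& icy,
                               std::vector<double>& icz) {
  icx.clear(); icy.clear(); icz.clear();
  double a = c.R - rRec;
  for (size_t k = 0; k < c.ron.size(); k++)
    if (c.ron[k]) {
      icx.push_back(c.rax[k] * a);
      icy.push_back(c.ray[k] * a);
      icz.push_back(c.raz[k] * a);
    }
}

static Interior init_molecules(Stream& s, int nRas, int nRaf, int nErk,
                               int nTf, double Rc, double Rn) {
  Interior in;
  int tot = nRas + nRaf + nErk + nTf;
  in.sp.reserve(tot);
  double p[3];
  int counts[4] = {nRas, nRaf, nErk, nTf};
  for (int sp = 0; sp < 4; sp++)
    for (int i = 0; i < counts[sp]; i++) {
      in.sp.push_back(sp);
      in.on.push_back(0);
      place_molecule(s, sp, 0, Rc, Rn, p);
      in.x.push_back(p[0]); in.y.push_back(p[1]); in.z.push_back(p[2]);
      in.soff.push_back(R_PosInf);
    }
  return in;
}

// [[Rcpp::export]]
List cpp_init_molecules(IntegerVector counts, double cell_radius,
                        double nucleus_radius, SEXP rng) {
  Stream* s = get_stream(rng);
  Interior in = init_molecules(*s, counts[0], counts[1], counts[2], counts[3],
                               cell_radius, nucleus_radius);
  return interior_to_list(in);
}

// [[Rcpp::export]]
List cpp_step_interior(List interior, double cell_radius,
                       double nucleus_radius, NumericMatrix inner_centres,
                       NumericVector k_eff, double d_protein, double r_bd,
                       double r_receptor, double dt, double clock, SEXP rng,
                       bool use_grid) {
  Stream* s = get_stream(rng);
  Interior in = interior_from_list(interior);
  std::vector<double> icx, icy, icz;
  for (int k = 0; k < inner_centres.nrow(); k++) {
    icx.push_back(inner_centres(k, 0));
    icy.push_back(inner_centres(k, 1));
    icz.push_back(inner_centres(k, 2));
  }
  double kE[4] = {k_eff[0], k_eff[1], k_eff[2], k_eff[3]};
  interior_step(in, cell_radius, nucleus_radius, icx, icy, icz, kE, d_protein,
                r_bd, r_receptor, dt, clock, *s, use_grid);
  return interior_to_list(in);
}

// Split a mother interior between two daughters: per-species counts halved
// exactly (odd molecule assigned by fair coin), states and pending switch-off
// times inherited per molecule, positions re-drawn in the daughter's domain.
static void halve_interior(const Interior& mo, double Rc, double Rn,
                           Stream& s, Interior& d1, Interior& d2) {
  for (int sp = 0; sp < 4; sp++) {
    std::vector<int> idx;
    for (size_t i = 0; i < mo.size(); i++)
      if (mo.sp[i] == sp) idx.push_back((int)i);
    // Fisher-Yates shuffle with the cell stream
    for (int i = (int)idx.size() - 1; i > 0; i--) {
      int j = (int)std::floor(s.unif() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    size_t n1 = idx.size() / 2;
    if (idx.size() % 2 == 1 && s.unif() < 0.5) n1++;
    double p[3];
    for (size_t j = 0; j < idx.size(); j++) {
      Interior& d = (j < n1) ? d1 : d2;
      int i = idx[j];
      d.sp.push_back(sp);
      d.on.push_back(mo.on[i]);
      place_molecule(s, sp, mo.on[i], Rc, Rn, p);
      d.x.push_back(p[0]); d.y.push_back(p[1]); d.z.push_back(p[2]);
      d.soff.push_back(mo.soff[i]);
    }
  }
}

// [[Rcpp::export]]
List cpp_halve_interior(List interior, double cell_radius,
                        double nucleus_radius, SEXP rng) {
  Stream* s = get_stream(rng);
  Interior mo = interior_from_list(interior);
  Interior d1, d2;
  halve_interior(mo, cell_radius, nucleus_radius, *s, d1, d2);
  return List::create(interior_to_list(d1), interior_to_list(d2));
}

// ------------------------------------------------------------ field phase --

static void field_phase(World& w) {
  const Cfg& f = w.cfg;
  Stream& s = w.fieldS;
  double now = w.clock, dt = f.dt;

  // introduce: Poisson number of new EGFs on the outer shell
  int add = s.pois(f.intro * dt);
  double p[3];
  for (int i = 0; i < add; i++) {
    sample_shell(s, std::max(0.0, f.Rdom - f.shell), f.Rdom, p);
    w.ex.push_back(p[0]); w.ey.push_back(p[1]); w.ez.push_back(p[2]);
    w.edeg.push_back(now + s.expo(f.degr));
  }

  // diffuse free EGFs; reflect at the domain boundary and at cell membranes
  double sd = std::sqrt(2.0 * f.Degf * dt);
  size_t nE = w.ex.size();
  for (size_t i = 0; i < nE; i++) {
    w.ex[i] += sd * s.norm();
    w.ey[i] += sd * s.norm();
    w.ez[i] += sd * s.norm();
    reflect_pt(w.ex[i], w.ey[i], w.ez[i], 0, 0, 0, 0.0, f.Rdom);
    for (int it = 0; it < 8; it++) {
      bool viol = false;
      for (size_t ci = 0; ci < w.cells.size(); ci++) {
        const CellC& c = w.cells[ci];
        double dx = w.ex[i] - c.pos[0], dy = w.ey[i] - c.pos[1],
               dz = w.ez[i] - c.pos[2];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < c.R * c.R) {
          double d = std::sqrt(d2);
          if (d < 1e-9) {
            w.ex[i] = c.pos[0]; w.ey[i] = c.pos[1];
            w.ez[i] = c.pos[2] + c.R * 1.0001;
          } else {
            double rn = 2.0 * c.R - d;
            double sc = rn / d;
            w.ex[i] = c.pos[0] + dx * sc;
            w.ey[i] = c.pos[1] + dy * sc;
            w.ez[i] = c.pos[2] + dz * sc;
          }
          viol = true;
        }
      }
      if (!viol) break;
      reflect_pt(w.ex[i], w.ey[i], w.ez[i], 0, 0, 0, 0.0, f.Rdom);
      if (it == 7) {
        // pathological corner: push out of the first violating cell surface
        for (size_t ci = 0; ci < w.cells.size(); ci++) {
          const CellC& c = w.cells[ci];
          double dx = w.ex[i] - c.pos[0], dy = w.ey[i] - c.pos[1],
                 dz = w.ez[i] - c.pos[2];
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (d < c.R) {
            double sc = (d < 1e-9) ? 0.0 : (c.R * 1.0001) / d;
            if (sc == 0.0) {
              w.ex[i] = c.pos[0]; w.ey[i] = c.pos[1];
              w.ez[i] = c.pos[2] + c.R * 1.0001;
            } else {
              w.ex[i] = c.pos[0] + dx * sc;
              w.ey[i] = c.pos[1] + dy * sc;
              w.ez[i] = c.pos[2] + dz * sc;
            }
          }
        }
      }
    }
  }

  // degradation: drop particles past their degradation time (stable order)
  size_t keep = 0;
  for (size_t i = 0; i < w.ex.size(); i++) {
    if (w.edeg[i] > now) {
      w.ex[keep] = w.ex[i]; w.ey[keep] = w.ey[i]; w.ez[keep] = w.ez[i];
      w.edeg[keep] = w.edeg[i];
      keep++;
    }
  }
  w.ex.resize(keep); w.ey.resize(keep); w.ez.resize(keep);
  w.edeg.resize(keep);

  // binding: globally nearest-pair greedy matching of free EGFs to
  // overlapping 'off' receptors
  struct Cand { double d; int e, ci, ri; };
  std::vector<Cand> cands;
  double sigB = f.rRec + f.rEgf;
  for (size_t i = 0; i < w.ex.size(); i++) {
    for (size_t ci = 0; ci < w.cells.size(); ci++) {
      const CellC& c = w.cells[ci];
      if (c.phase == PH_CORPSE) continue;
      double dx = w.ex[i] - c.pos[0], dy = w.ey[i] - c.pos[1],
             dz = w.ez[i] - c.pos[2];
      double d2 = dx * dx + dy * dy + dz * dz;
      double reach = c.R + f.rRec + sigB;
      if (d2 > reach * reach) continue;
      double a = c.R + f.rRec;
      for (size_t k = 0; k < c.ron.size(); k++) {
        if (c.ron[k]) continue;
        double ox = c.pos[0] + c.rax[k] * a, oy = c.pos[1] + c.ray[k] * a,
               oz = c.pos[2] + c.raz[k] * a;
        double bx = w.ex[i] - ox, by = w.ey[i] - oy, bz = w.ez[i] - oz;
        double b2 = bx * bx + by * by + bz * bz;
        if (b2 < sigB * sigB) {
          Cand cd; cd.d = std::sqrt(b2); cd.e = (int)i; cd.ci = (int)ci;
          cd.ri = (int)k;
          cands.push_back(cd);
        }
      }
    }
  }
  std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
    if (a.d != b.d) return a.d < b.d;
    if (a.e != b.e) return a.e < b.e;
    if (a.ci != b.ci) return a.ci < b.ci;
    return a.ri < b.ri;
  });
  std::vector<char> eUsed(w.ex.size(), 0);
  for (size_t q = 0; q < cands.size(); q++) {
    const Cand& cd = cands[q];
    CellC& c = w.cells[cd.ci];
    if (eUsed[cd.e] || c.ron[cd.ri]) continue;
    c.ron[cd.ri] = 1;
    c.rsoff[cd.ri] = now + s.expo(f.kOffRec);
    eUsed[cd.e] = 1;
  }
  keep = 0;
  for (size_t i = 0; i < w.ex.size(); i++) {
    if (!eUsed[i]) {
      w.ex[keep] = w.ex[i]; w.ey[keep] = w.ey[i]; w.ez[keep] = w.ez[i];
      w.edeg[keep] = w.edeg[i];
      keep++;
    }
  }
  w.ex.resize(keep); w.ey.resize(keep); w.ez.resize(keep);
  w.edeg.resize(keep);

  // release expired receptors; bound ligand is consumed unless re-release is
  // configured, in which case it reappears at the receptor position
  for (size_t ci = 0; ci < w.cells.size(); ci++) {
    CellC& c = w.cells[ci];
    double a = c.R + f.rRec;
    for (size_t k = 0; k < c.ron.size(); k++) {
      if (c.ron[k] && c.rsoff[k] <= now) {
        c.ron[k] = 0;
        if (f.rerelease) {
          w.ex.push_back(c.pos[0] + c.rax[k] * (a + f.rRec + f.rEgf));
          w.ey.push_back(c.pos[1] + c.ray[k] * (a + f.rRec + f.rEgf));
          w.ez.push_back(c.pos[2] + c.raz[k] * (a + f.rRec + f.rEgf));
          w.edeg.push_back(now + s.expo(f.degr));
        }
      }
    }
  }
}

// Receptor residence expiry must also happen when the extracellular field is
// disabled (single-cell scenarios with a prescribed activation window).
static void release_receptors_only(World& w) {
  for (size_t ci = 0; ci < w.cells.size(); ci++) {
    CellC& c = w.cells[ci];
    for (size_t k = 0; k < c.ron.size(); k++)
      if (c.ron[k] && c.rsoff[k] <= w.clock) c.ron[k] = 0;
  }
}

// -------------------------------------------------------- mechanics phase --

static void make_daughter(World& w, const CellC& m, Stream& s, double sign,
                          const double* u, CellC& d) {
  const Cfg& f = w.cfg;
  double Rd = std::cbrt(3.0 * m.birthV / (4.0 * M_PI));
  d.id = w.nextId++;
  for (int j = 0; j < 3; j++) {
    d.pos[j] = m.pos[j] + sign * Rd * u[j];
    d.vel[j] = m.vel[j];
  }
  d.R = Rd;
  d.Rn = m.Rn;
  d.birthV = m.birthV;
  d.cclock = 0.0;
  d.clen = f.cycMin + (f.cycMax - f.cycMin) * s.unif();
  d.phase = PH_G1;
  d.mut = m.mut;
  int nr = m.mut.nEgfr;
  d.rax.resize(nr); d.ray.resize(nr); d.raz.resize(nr);
  d.ron.assign(nr, 0); d.rsoff.assign(nr, R_PosInf);
  double uv[3];
  for (int k = 0; k < nr; k++) {
    s.unit_vec(uv);
    d.rax[k] = uv[0]; d.ray[k] = uv[1]; d.raz[k] = uv[2];
  }
}

static void mech_phase(World& w) {
  const Cfg& f = w.cfg;
  double dt = f.dt;

  if (f.fateOn) {
    // cycle clock + G1 checkpoint
    std::vector<CellC> survivors;
    survivors.reserve(w.cells.size());
    for (size_t ci = 0; ci < w.cells.size(); ci++) {
      CellC& c = w.cells[ci];
      if (c.phase == PH_CORPSE) { survivors.push_back(std::move(c)); continue; }
      c.cclock += dt;
      if (c.phase == PH_G1 && c.cclock >= f.g1) {
        int tf = 0;
        for (size_t i = 0; i < c.in.size(); i++)
          if (c.in.sp[i] == TFP && c.in.on[i]) tf++;
        if (tf > f.NtfStar) {
          c.phase = PH_COMMITTED;
        } else {
          if (f.keepCorpses) {
            c.phase = PH_CORPSE;
            c.in = Interior();
            c.ron.clear(); c.rax.clear(); c.ray.clear(); c.raz.clear();
            c.rsoff.clear();
          } else {
            continue;  // apoptosis: removed this step
          }
        }
      }
      survivors.push_back(std::move(c));
    }
    w.cells = std::move(survivors);

    // linear volume growth of committed cells up to twice birth volume
    for (size_t ci = 0; ci < w.cells.size(); ci++) {
      CellC& c = w.cells[ci];
      if (c.phase != PH_COMMITTED) continue;
      double frac = (c.cclock - f.g1) / (c.clen - f.g1);
      if (frac < 0) frac = 0;
      if (frac > 1) frac = 1;
      double V = c.birthV * (1.0 + frac);
      c.R = std::cbrt(3.0 * V / (4.0 * M_PI));
    }

    // division at the end of the cycle
    std::vector<CellC> next;
    next.reserve(w.cells.size() + 2);
    for (size_t ci = 0; ci < w.cells.size(); ci++) {
      CellC& c = w.cells[ci];
      if (c.phase == PH_COMMITTED && c.cclock >= c.clen) {
        Stream& s = w.cs(c.id);
        double u[3];
        s.unit_vec(u);
        CellC d1, d2;
        make_daughter(w, c, s, +1.0, u, d1);
        make_daughter(w, c, s, -1.0, u, d2);
        halve_interior(c.in, d1.R, d1.Rn, s, d1.in, d2.in);
        next.push_back(std::move(d1));
        next.push_back(std::move(d2));
      } else {
        next.push_back(std::move(c));
      }
    }
    w.cells = std::move(next);
  }

  // centre-based motion: pairwise repulsion, semi-implicit Euler with the
  // inertial term retained
  size_t n = w.cells.size();
  if (n == 0) return;
  std::vector<double> fx(n, 0.0), fy(n, 0.0), fz(n, 0.0);
  for (size_t i = 0; i + 1 < n; i++) {
    for (size_t j = i + 1; j < n; j++) {
      CellC& a = w.cells[i];
      CellC& b = w.cells[j];
      double dx = a.pos[0] - b.pos[0], dy = a.pos[1] - b.pos[1],
             dz = a.pos[2] - b.pos[2];
      double h2 = dx * dx + dy * dy + dz * dz;
      double h0 = a.R + b.R;
      if (h2 >= h0 * h0) continue;
      double h = std::sqrt(h2);
      double h1 = a.Rn + b.Rn;
      double floor_h = h0 - h1;
      double heff = (h <= floor_h) ? floor_h + 1e-9 : h;
      double fm = f.K * (h0 - heff) / (heff - floor_h);
      double ux, uy, uz;
      if (h < 1e-9) { ux = 0; uy = 0; uz = 1; }
      else { ux = dx / h; uy = dy / h; uz = dz / h; }
      fx[i] += fm * ux; fy[i] += fm * uy; fz[i] += fm * uz;
      fx[j] -= fm * ux; fy[j] -= fm * uy; fz[j] -= fm * uz;
    }
  }
  double denom = 1.0 + f.mu * dt;
  for (size_t i = 0; i < n; i++) {
    CellC& c = w.cells[i];
    c.vel[0] = (c.vel[0] + dt * fx[i] / f.mass) / denom;
    c.vel[1] = (c.vel[1] + dt * fy[i] / f.mass) / denom;
    c.vel[2] = (c.vel[2] + dt * fz[i] / f.mass) / denom;
    for (int j = 0; j < 3; j++) c.pos[j] += dt * c.vel[j];
  }
}

// --------------------------------------------------------------- stepping --

static void interior_phase(World& w) {
  const Cfg& f = w.cfg;
  std::vector<double> icx, icy, icz;
  for (size_t ci = 0; ci < w.cells.size(); ci++) {
    CellC& c = w.cells[ci];
    if (c.phase == PH_CORPSE) continue;
    Stream& s = w.cs(c.id);
    cell_inner_centres(c, f.rRec, icx, icy, icz);
    double kEff[4] = {f.kRas * (c.mut.kras ? c.mut.krasMult : 1.0),
                      f.kRaf * (c.mut.braf ? c.mut.brafMult : 1.0),
                      f.kErk, f.kTf};
    interior_step(c.in, c.R, c.Rn, icx, icy, icz, kEff, f.Dprot, f.rBD,
                  f.rRec, f.dt, w.clock, s, f.useGrid);
  }
}

static void do_step(World& w) {
  const Cfg& f = w.cfg;
  for (size_t q = 0; q < f.order.size(); q++) {
    char ph = f.order[q];
    if (ph == 'f') {
      if (f.fieldOn) field_phase(w);
      else release_receptors_only(w);
    }
    else if (ph == 'i') interior_phase(w);
    else if (ph == 'm' && f.mechOn) mech_phase(w);
  }
  w.clock += f.dt;
}

static World world_from_state(List state) {
  List cfg = state["config"];
  World w((uint64_t)as<double>(state["seed"]), as<int>(state["epoch"]));
  w.cfg = parse_cfg(cfg);
  w.clock = as<double>(state["clock"]);
  w.nextId = as<int>(state["next_id"]);
  List fl = state["field"];
  NumericMatrix fp = fl["pos"];
  NumericVector fd = fl["deg_time"];
  for (int i = 0; i < fp.nrow(); i++) {
    w.ex.push_back(fp(i, 0));
    w.ey.push_back(fp(i, 1));
    w.ez.push_back(fp(i, 2));
    w.edeg.push_back(fd[i]);
  }
  List cl = state["cells"];
  for (int i = 0; i < cl.size(); i++)
    w.cells.push_back(cell_from_list(cl[i]));
  return w;
}

static List world_to_state(const World& w, List origState) {
  int nE = (int)w.ex.size();
  NumericMatrix fp(nE, 3);
  NumericVector fd(nE);
  for (int i = 0; i < nE; i++) {
    fp(i, 0) = w.ex[i]; fp(i, 1) = w.ey[i]; fp(i, 2) = w.ez[i];
    fd[i] = w.edeg[i];
  }
  List cl((int)w.cells.size());
  for (size_t i = 0; i < w.cells.size(); i++)
    cl[i] = cell_to_list(w.cells[i]);
  return List::create(
      _["clock"] = w.clock, _["next_id"] = w.nextId, _["seed"] = (double)w.seed,
      _["epoch"] = w.epoch + 1,
      _["config"] = origState["config"],
      _["field"] = List::create(_["pos"] = fp, _["deg_time"] = fd),
      _["cells"] = cl);
}

// Advance a simulation state by n_steps steps of config dt, optionally
// recording (time, cell count, free-EGF count, summed active species counts)
// every record_every steps.
// [[Rcpp::export]]
List cpp_engine_run(List state, int n_steps, int record_every) {
  World w = world_from_state(state);
  std::vector<double> rt;
  std::vector<int> rn, rE, rras, rraf, rerk, rtf, rrec;
  auto record = [&]() {
    rt.push_back(w.clock);
    rn.push_back((int)std::count_if(
        w.cells.begin(), w.cells.end(),
        [](const CellC& c) { return c.phase != PH_CORPSE; }));
    rE.push_back((int)w.ex.size());
    int a[4] = {0, 0, 0, 0};
    int ron = 0;
    for (size_t ci = 0; ci < w.cells.size(); ci++) {
      const CellC& c = w.cells[ci];
      for (size_t i = 0; i < c.in.size(); i++)
        if (c.in.on[i]) a[c.in.sp[i]]++;
      for (size_t k = 0; k < c.ron.size(); k++)
        if (c.ron[k]) ron++;
    }
    rras.push_back(a[0]); rraf.push_back(a[1]);
    rerk.push_back(a[2]); rtf.push_back(a[3]);
    rrec.push_back(ron);
  };
  if (record_every > 0) record();
  double clock0 = w.clock;
  for (int k = 0; k < n_steps; k++) {
    do_step(w);
    w.clock = clock0 + (k + 1) * w.cfg.dt;  // avoid accumulation drift
    if (record_every > 0 && ((k + 1) % record_every == 0)) record();
    if ((k & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }
  List rec = R_NilValue;
  if (record_every > 0) {
    rec = DataFrame::create(
        _["time"] = wrap(rt), _["n_cells"] = wrap(rn),
        _["n_egf"] = wrap(rE), _["ras"] = wrap(rras), _["raf"] = wrap(rraf),
        _["erk"] = wrap(rerk), _["tf"] = wrap(rtf),
        _["receptors_on"] = wrap(rrec));
  }
  return List::create(_["state"] = world_to_state(w, state),
                      _["records"] = rec);
}
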