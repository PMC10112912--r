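// Brownian-dynamics engine for 2D actomyosin networks.
//
// Filaments are discretized polylines (minus end = vertex 0). Inextensibility
// is enforced by stiff penalty springs; bending follows the discrete
// worm-like-chain energy E = (kappa/2l) * sum theta_i^2. Connectors
// (crosslinkers, Arp2/3 branch links, two-headed motors) are Hookean springs
// between points on fibers, with stochastic binding/unbinding and, for
// motors, load-dependent plus-end-directed stepping. Vertices obey the
// overdamped Langevin equation integrated by explicit Euler-Maruyama.
//
// All stochasticity inside the engine flows through one xoshiro256++ stream
// seeded from a single integer, so trajectories are bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG -----

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; i++) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0,1)
  // standard normals via the Marsaglia-Tsang ziggurat (128 layers), exact
  // tail handling; tables built once per process
  static double zig_x[129], zig_r[128];
  static bool zig_ready;
  static void zig_init() {
    const double R = 3.442619855899, V = 9.91256303526217e-3;
    double f = std::exp(-0.5 * R * R);
    zig_x[0] = V / f;        // virtual x0 so layer 0 covers the tail
    zig_x[1] = R;
    double x = R;
    for (int i = 2; i < 128; i++) {
      x = std::sqrt(-2.0 * std::log(V / x + std::exp(-0.5 * x * x)));
      zig_x[i] = x;
    }
    zig_x[128] = 0.0;
    for (int i = 0; i < 128; i++) zig_r[i] = zig_x[i + 1] / zig_x[i];
    zig_ready = true;
  }
  inline double norm() {
    if (!zig_ready) zig_init();
    const double R = 3.442619855899;
    for (;;) {
      uint64_t u = next();
      int i = (int)(u & 127);                       // layer
      double sign = (u & 128) ? 1.0 : -1.0;
      double f = ((u >> 11) * 0x1.0p-53);           // uniform in [0,1)
      double x = f * zig_x[i];
      if (f < zig_r[i]) return sign * x;            // inside the layer box
      if (i == 0) {                                 // tail beyond R
        double xx, yy;
        do {
          xx = -std::log(unif() + 1e-300) / R;
          yy = -std::log(unif() + 1e-300);
        } while (yy + yy < xx * xx);
        return sign * (R + xx);
      }
      // wedge: accept against the density
      double fx = std::exp(-0.5 * x * x);
      double f1 = std::exp(-0.5 * zig_x[i] * zig_x[i]);
      double f0 = std::exp(-0.5 * zig_x[i + 1] * zig_x[i + 1]);
      if (f1 + unif() * (f0 - f1) < fx) return sign * x;
    }
  }
};
double Xoshiro::zig_x[129];
double Xoshiro::zig_r[128];
bool Xoshiro::zig_ready = false;

// ------------------------------------------------------------- fibers -----

struct Fib {
  std::vector<double> x, y;     // vertex positions, index 0 = minus end
  std::vector<double> fx, fy;   // force accumulators
  double seg_rest;              // rest length of interior segments (um)
  double last_rest;             // rest length of the plus-most segment
  double rigidity;              // bending modulus kappa (pN um^2)
  bool frozen;                  // growth stopped
  int n() const { return (int)x.size(); }
  int nseg() const { return (int)x.size() - 1; }
  double rest_of(int i) const { return i == nseg() - 1 ? last_rest : seg_rest; }
  double length() const { return (nseg() - 1) * seg_rest + last_rest; }
};

struct Hand { int fib = -1; double abs = 0.0; };  // fib < 0 = unbound

struct Conn {
  int species;   // 0 crosslinker, 1 arp23, 2 motor
  Hand h[2];     // arp23: h[0] = mother attachment, h[1] = daughter base
  double ax = 0.0, ay = 0.0;  // anchor when fully unbound
  int side = 0;               // arp23: +1 left / -1 right
  double phi0 = 0.0;          // arp23 target angle offset (rad, signed)
};

struct SpeciesPar {
  double stiffness, rest_length, k_on, binding_range, k_off;
  double v0, f_s;      // motor only
  double torsion_k;    // arp23 only
  double kramers_f;    // characteristic force for slip-bond unbinding; 0 = off
};

struct Mech {
  double kT, drag_per_length, extension_stiffness, dt, gamma_vertex;
};

// abscissa (rest-length parametrization) -> segment index + fraction
static inline void locate(const Fib &f, double s, int &seg, double &u) {
  int m = f.nseg();
  int i = (int)std::floor(s / f.seg_rest);
  if (i > m - 1) i = m - 1;
  if (i < 0) i = 0;
  double r = f.rest_of(i);
  u = (s - i * f.seg_rest) / r;
  if (u < 0.0) u = 0.0;
  if (u > 1.0) u = 1.0;
  seg = i;
}

static inline void pos_at(const Fib &f, double s, double &px, double &py) {
  int i; double u;
  locate(f, s, i, u);
  px = f.x[i] + (f.x[i + 1] - f.x[i]) * u;
  py = f.y[i] + (f.y[i + 1] - f.y[i]) * u;
}

// ------------------------------------------------------------- forces -----

// discrete WLC bending: E = (kappa/2l) sum theta_i^2, theta = angle between
// consecutive segments; force = -grad E (analytic, checked against numerical
// gradients in the test suite)
static void add_bending(Fib &f, double /*unused*/) {
  int n = f.n();
  if (n < 3 || f.rigidity <= 0.0) return;
  double pref = f.rigidity / f.seg_rest;
  for (int i = 1; i < n - 1; i++) {
    double axv = f.x[i] - f.x[i - 1], ayv = f.y[i] - f.y[i - 1];
    double bxv = f.x[i + 1] - f.x[i], byv = f.y[i + 1] - f.y[i];
    double a2 = axv * axv + ayv * ayv, b2 = bxv * bxv + byv * byv;
    if (a2 < 1e-16 || b2 < 1e-16) continue;
    double cross = axv * byv - ayv * bxv, dot = axv * bxv + ayv * byv;
    double th = std::atan2(cross, dot);
    double c = -pref * th;
    double pax = -ayv / a2, pay = axv / a2;  // perp(a)/|a|^2
    double pbx = -byv / b2, pby = bxv / b2;
    f.fx[i - 1] += c * pax;          f.fy[i - 1] += c * pay;
    f.fx[i]     += c * (-pax - pbx); f.fy[i]     += c * (-pay - pby);
    f.fx[i + 1] += c * pbx;          f.fy[i + 1] += c * pby;
  }
}

static void add_extension(Fib &f, double k, double &max_strain) {
  int n = f.n();
  for (int i = 0; i < n - 1; i++) {
    double sx = f.x[i + 1] - f.x[i], sy = f.y[i + 1] - f.y[i];
    double d = std::sqrt(sx * sx + sy * sy);
    if (d < 1e-12) continue;
    double r = f.rest_of(i);
    double fmag = k * (d - r);
    double ux = sx / d, uy = sy / d;
    f.fx[i]     += fmag * ux; f.fy[i]     += fmag * uy;
    f.fx[i + 1] -= fmag * ux; f.fy[i + 1] -= fmag * uy;
    double st = std::fabs(d - r) / r;
    if (st > max_strain) max_strain = st;
  }
}

// distribute a force applied at abscissa s onto the two segment vertices
static inline void spread(Fib &f, double s, double gx, double gy) {
  int i; double u;
  locate(f, s, i, u);
  f.fx[i] += (1.0 - u) * gx;     f.fy[i] += (1.0 - u) * gy;
  f.fx[i + 1] += u * gx;         f.fy[i + 1] += u * gy;
}

// ------------------------------------------------------------ engine ------

struct World {
  std::vector<Fib> fibs;
  std::vector<Conn> conns;
  // tethers: external harmonic traps on single vertices (testing/confinement
  // utility; count toward the stability bound)
  std::vector<int> t_fib, t_vtx;
  std::vector<double> t_ax, t_ay, t_k;
  double time = 0.0;
};

struct CellGrid {
  double x0, y0, cell;
  int nx, ny;
  std::vector<std::vector<std::pair<int,int> > > bins;  // (fiber, segment)
  void build(const std::vector<Fib> &fibs, double cell_size) {
    cell = cell_size;
    double xmin = 1e30, xmax = -1e30, ymin = 1e30, ymax = -1e30;
    bool any = false;
    for (size_t i = 0; i < fibs.size(); i++)
      for (int v = 0; v < fibs[i].n(); v++) {
        any = true;
        xmin = std::min(xmin, fibs[i].x[v]); xmax = std::max(xmax, fibs[i].x[v]);
        ymin = std::min(ymin, fibs[i].y[v]); ymax = std::max(ymax, fibs[i].y[v]);
      }
    if (!any) { nx = ny = 1; x0 = y0 = 0; bins.assign(1, {}); return; }
    x0 = xmin - cell; y0 = ymin - cell;
    nx = std::max(1, (int)((xmax - x0) / cell) + 2);
    ny = std::max(1, (int)((ymax - y0) / cell) + 2);
    bins.assign((size_t)nx * ny, {});
    for (size_t i = 0; i < fibs.size(); i++)
      for (int s = 0; s < fibs[i].nseg(); s++) {
        double mx = 0.5 * (fibs[i].x[s] + fibs[i].x[s + 1]);
        double my = 0.5 * (fibs[i].y[s] + fibs[i].y[s + 1]);
        int cx = std::min(nx - 1, std::max(0, (int)((mx - x0) / cell)));
        int cy = std::min(ny - 1, std::max(0, (int)((my - y0) / cell)));
        bins[(size_t)cy * nx + cx].push_back(std::make_pair((int)i, s));
      }
  }
  template <class F>
  void near(double px, double py, F fun) const {
    int cx = std::min(nx - 1, std::max(0, (int)((px - x0) / cell)));
    int cy = std::min(ny - 1, std::max(0, (int)((py - y0) / cell)));
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        int gx = cx + dx, gy = cy + dy;
        if (gx < 0 || gy < 0 || gx >= nx || gy >= ny) continue;
        const std::vector<std::pair<int,int> > &b = bins[(size_t)gy * nx + gx];
        for (size_t j = 0; j < b.size(); j++) fun(b[j].first, b[j].second);
      }
  }
};

struct Candidate { int fib, seg; double abs, dist; };

// closest point of segment (fi,si) to (px,py); returns abscissa and distance
static inline bool closest_on_segment(const Fib &f, int si, double px, double py,
                                      double range, Candidate &out) {
  double x1 = f.x[si], y1 = f.y[si], x2 = f.x[si + 1], y2 = f.y[si + 1];
  double sx = x2 - x1, sy = y2 - y1;
  double l2 = sx * sx + sy * sy;
  double u = 0.0;
  if (l2 > 1e-16) u = ((px - x1) * sx + (py - y1) * sy) / l2;
  if (u < 0.0) u = 0.0;
  if (u > 1.0) u = 1.0;
  double cx = x1 + u * sx, cy = y1 + u * sy;
  double d = std::sqrt((px - cx) * (px - cx) + (py - cy) * (py - cy));
  if (d > range) return false;
  out.seg = si;
  out.abs = si * f.seg_rest + u * f.rest_of(si);
  out.dist = d;
  return true;
}

// One stochastic binding attempt for a free hand at (px,py). Binds with
// probability 1-exp(-k_on*dt) per eligible segment, evaluated in randomized
// order; never binds fiber `exclude` (the partner hand's fiber).
static bool try_bind(const World &w, const CellGrid &grid, double px, double py,
                     int exclude, const SpeciesPar &sp, double dt, Xoshiro &rng,
                     Hand &hand) {
  static thread_local std::vector<Candidate> cands;
  cands.clear();
  grid.near(px, py, [&](int fi, int si) {
    if (fi == exclude) return;
    Candidate c; c.fib = fi;
    if (closest_on_segment(w.fibs[fi], si, px, py, sp.binding_range, c))
      cands.push_back(c);
  });
  if (cands.empty()) return false;
  double p = 1.0 - std::exp(-sp.k_on * dt);
  if (p <= 0.0) return false;
  // Fisher-Yates shuffle for randomized evaluation order
  for (int i = (int)cands.size() - 1; i > 0; i--) {
    int j = (int)(rng.unif() * (i + 1));
    std::swap(cands[i], cands[j]);
  }
  for (size_t i = 0; i < cands.size(); i++) {
    if (rng.unif() < p) {
      hand.fib = cands[i].fib;
      hand.abs = cands[i].abs;
      return true;
    }
  }
  return false;
}

// ----------------------------------------------------- R <-> C++ state ----

static World unpack_state(List state) {
  World w;
  List fl = state["fibers"];
  for (int i = 0; i < fl.size(); i++) {
    List f = fl[i];
    NumericMatrix v = f["vertices"];
    Fib fb;
    fb.x.resize(v.nrow()); fb.y.resize(v.nrow());
    for (int j = 0; j < v.nrow(); j++) { fb.x[j] = v(j, 0); fb.y[j] = v(j, 1); }
    fb.fx.assign(v.nrow(), 0.0); fb.fy.assign(v.nrow(), 0.0);
    fb.seg_rest = as<double>(f["seg_rest"]);
    fb.last_rest = as<double>(f["last_rest"]);
    fb.rigidity = as<double>(f["rigidity"]);
    fb.frozen = as<bool>(f["frozen"]);
    w.fibs.push_back(fb);
  }
  DataFrame cd = as<DataFrame>(state["connectors"]);
  if (cd.nrows() > 0) {
    IntegerVector species = cd["species"];
    IntegerVector h1f = cd["h1_fib"]; NumericVector h1a = cd["h1_abs"];
    IntegerVector h2f = cd["h2_fib"]; NumericVector h2a = cd["h2_abs"];
    NumericVector ax = cd["anchor_x"], ay = cd["anchor_y"];
    IntegerVector side = cd["side"]; NumericVector phi0 = cd["phi0"];
    for (int i = 0; i < cd.nrows(); i++) {
      Conn c;
      c.species = species[i];
      c.h[0].fib = h1f[i] == NA_INTEGER ? -1 : h1f[i] - 1;  // R is 1-based
      c.h[0].abs = NumericVector::is_na(h1a[i]) ? 0.0 : h1a[i];
      c.h[1].fib = h2f[i] == NA_INTEGER ? -1 : h2f[i] - 1;
      c.h[1].abs = NumericVector::is_na(h2a[i]) ? 0.0 : h2a[i];
      c.ax = ax[i]; c.ay = ay[i];
      c.side = side[i] == NA_INTEGER ? 0 : side[i];
      c.phi0 = NumericVector::is_na(phi0[i]) ? 0.0 : phi0[i];
      w.conns.push_back(c);
    }
  }
  if (state.containsElementNamed("tethers") && !Rf_isNull(state["tethers"])) {
    DataFrame td = as<DataFrame>(state["tethers"]);
    if (td.nrows() > 0) {
      IntegerVector tf = td["fiber"], tv = td["vertex"];
      NumericVector tx = td["anchor_x"], ty = td["anchor_y"], tk = td["stiffness"];
      for (int i = 0; i < td.nrows(); i++) {
        w.t_fib.push_back(tf[i] - 1); w.t_vtx.push_back(tv[i] - 1);
        w.t_ax.push_back(tx[i]); w.t_ay.push_back(ty[i]); w.t_k.push_back(tk[i]);
      }
    }
  }
  w.time = as<double>(state["time"]);
  return w;
}

static List pack_state(const World &w, List tmpl) {
  List fl(w.fibs.size());
  for (size_t i = 0; i < w.fibs.size(); i++) {
    const Fib &f = w.fibs[i];
    NumericMatrix v(f.n(), 2);
    for (int j = 0; j < f.n(); j++) { v(j, 0) = f.x[j]; v(j, 1) = f.y[j]; }
    fl[i] = List::create(_["vertices"] = v, _["seg_rest"] = f.seg_rest,
                         _["last_rest"] = f.last_rest,
                         _["rigidity"] = f.rigidity, _["frozen"] = f.frozen);
  }
  int nc = (int)w.conns.size();
  IntegerVector species(nc), h1f(nc), h2f(nc), side(nc);
  NumericVector h1a(nc), h2a(nc), ax(nc), ay(nc), phi0(nc);
  for (int i = 0; i < nc; i++) {
    const Conn &c = w.conns[i];
    species[i] = c.species;
    h1f[i] = c.h[0].fib < 0 ? NA_INTEGER : c.h[0].fib + 1;
    h1a[i] = c.h[0].fib < 0 ? NA_REAL : c.h[0].abs;
    h2f[i] = c.h[1].fib < 0 ? NA_INTEGER : c.h[1].fib + 1;
    h2a[i] = c.h[1].fib < 0 ? NA_REAL : c.h[1].abs;
    ax[i] = c.ax; ay[i] = c.ay; side[i] = c.side; phi0[i] = c.phi0;
  }
  DataFrame cd = DataFrame::create(
      _["species"] = species, _["h1_fib"] = h1f, _["h1_abs"] = h1a,
      _["h2_fib"] = h2f, _["h2_abs"] = h2a, _["anchor_x"] = ax,
      _["anchor_y"] = ay, _["side"] = side, _["phi0"] = phi0);
  List out = clone(tmpl);
  out["fibers"] = fl;
  out["connectors"] = cd;
  out["time"] = w.time;
  return out;
}

static SpeciesPar read_species(List p) {
  SpeciesPar s;
  s.stiffness = as<double>(p["stiffness"]);
  s.rest_length = as<double>(p["rest_length"]);
  s.k_on = as<double>(p["k_on"]);
  s.binding_range = as<double>(p["binding_range"]);
  s.k_off = as<double>(p["k_off"]);
  s.v0 = p.containsElementNamed("v0") ? as<double>(p["v0"]) : 0.0;
  s.f_s = p.containsElementNamed("f_s") ? as<double>(p["f_s"]) : 1.0;
  s.torsion_k = p.containsElementNamed("torsion_k") ? as<double>(p["torsion_k"]) : 0.0;
  s.kramers_f = p.containsElementNamed("kramers_f") ? as<double>(p["kramers_f"]) : 0.0;
  return s;
}

static double network_radius_cpp(const World &w) {
  double cx = 0, cy = 0; long n = 0;
  for (size_t i = 0; i < w.fibs.size(); i++)
    for (int j = 0; j < w.fibs[i].n(); j++) { cx += w.fibs[i].x[j]; cy += w.fibs[i].y[j]; n++; }
  if (n == 0) return NA_REAL;
  cx /= n; cy /= n;
  double m2 = 0;
  for (size_t i = 0; i < w.fibs.size(); i++)
    for (int j = 0; j < w.fibs[i].n(); j++) {
      double dx = w.fibs[i].x[j] - cx, dy = w.fibs[i].y[j] - cy;
      m2 += dx * dx + dy * dy;
    }
  return std::sqrt(2.0 * m2 / n);
}

// ---------------------------------------------------------- main loop -----

// [[Rcpp::export]]
List cpp_run(List state, List mech_in, List binders, List ctrl) {
  World w = unpack_state(state);

  Mech mech;
  mech.kT = as<double>(mech_in["kT"]);
  mech.drag_per_length = as<double>(mech_in["drag_per_length"]);
  mech.extension_stiffness = as<double>(mech_in["extension_stiffness"]);
  mech.dt = as<double>(mech_in["dt"]);

  SpeciesPar sp[3] = { read_species(binders["crosslinker"]),
                       read_species(binders["arp23"]),
                       read_species(binders["motor"]) };

  int n_steps = as<int>(ctrl["n_steps"]);
  bool do_grow = as<bool>(ctrl["grow"]);
  bool do_branch = as<bool>(ctrl["branch"]);
  bool do_bind = as<bool>(ctrl["bind"]);
  double confine_radius = as<double>(ctrl["confine_radius"]);  // <0: off
  double confine_k = as<double>(ctrl["confine_k"]);
  double growth_speed = as<double>(ctrl["growth_speed"]);
  double pool = as<double>(ctrl["pool"]);
  int sample_every = as<int>(ctrl["sample_every"]);            // 0: no series
  bool record_frames = as<bool>(ctrl["record_frames"]);
  uint64_t seed = (uint64_t)as<double>(ctrl["seed"]);
  int arp_remaining = as<int>(ctrl["arp_remaining"]);
  double init_length = as<double>(ctrl["init_length"]);
  // binding/unbinding events are evaluated every bind_every steps with the
  // correspondingly longer effective time step (rates are slow compared to
  // the mechanical step, so this is statistically equivalent and saves the
  // neighbourhood searches)
  int bind_every = as<int>(ctrl["bind_every"]);
  if (bind_every < 1) bind_every = 1;
  double dt_ev = 0.0;  // set per step

  Xoshiro rng(seed);
  double dt = mech.dt;

  std::vector<double> s_time, s_radius, s_strain;  // strain: max since previous sample
  std::vector<double> branch_angles;   // creation angles (deg), diagnostics
  List frames;
  if (record_frames) frames = List(0);
  std::vector<List> frame_list;

  double max_strain = 0.0, frame_strain = 0.0;
  bool pool_empty = (pool <= 0.0);
  CellGrid grid;
  int grid_age = 1000000;  // force initial build
  const double cell_size = 0.45;

  // free Arp2/3 entities waiting to nucleate: anchors sampled on R side and
  // passed via the connector table as arp23 rows with both hands unbound
  // (species 1, h[0].fib < 0)

  // per-hand link force cache for motor load (index 2*ci + hand)
  std::vector<double> loadf;

  for (int step = 0; step <= n_steps; step++) {
    bool sample_now = (sample_every > 0) &&
                      (step % sample_every == 0 || step == n_steps);
    if (sample_now) {
      s_time.push_back(w.time);
      s_radius.push_back(network_radius_cpp(w));
      s_strain.push_back(frame_strain);
      frame_strain = 0.0;
      if (record_frames) {
        List fl((int)w.fibs.size());
        for (size_t i = 0; i < w.fibs.size(); i++) {
          NumericMatrix v(w.fibs[i].n(), 2);
          for (int j = 0; j < w.fibs[i].n(); j++) {
            v(j, 0) = w.fibs[i].x[j]; v(j, 1) = w.fibs[i].y[j];
          }
          fl[i] = v;
        }
        frame_list.push_back(List::create(_["time"] = w.time, _["fibers"] = fl));
      }
    }
    if (step == n_steps) break;

    // -- growth from the shared polymer pool ------------------------------
    if (do_grow && !pool_empty) {
      double want = 0.0;
      for (size_t i = 0; i < w.fibs.size(); i++)
        if (!w.fibs[i].frozen) want += growth_speed * dt;
      if (want > 0.0) {
        double scale = 1.0;
        if (want >= pool) { scale = pool / want; pool_empty = true; }
        double dl = growth_speed * dt * scale;
        for (size_t i = 0; i < w.fibs.size(); i++) {
          Fib &f = w.fibs[i];
          if (f.frozen) continue;
          f.last_rest += dl;
          pool -= dl;
          if (f.last_rest >= 1.5 * f.seg_rest) {
            // split plus segment into (seg_rest, remainder)
            int m = f.n();
            double frac = f.seg_rest / f.last_rest;
            double nxv = f.x[m - 2] + (f.x[m - 1] - f.x[m - 2]) * frac;
            double nyv = f.y[m - 2] + (f.y[m - 1] - f.y[m - 2]) * frac;
            f.x.insert(f.x.end() - 1, nxv);
            f.y.insert(f.y.end() - 1, nyv);
            f.fx.push_back(0.0); f.fy.push_back(0.0);
            f.last_rest -= f.seg_rest;
            grid_age = 1000000;  // topology changed
          }
        }
        if (pool_empty) {
          pool = 0.0;
          for (size_t i = 0; i < w.fibs.size(); i++) w.fibs[i].frozen = true;
        }
      }
    }

    bool events_now = (step % bind_every == 0);
    dt_ev = dt * bind_every;
    bool need_grid = false;
    if (events_now && do_branch && arp_remaining > 0) need_grid = true;
    if (events_now && do_bind) {
      for (size_t i = 0; i < w.conns.size() && !need_grid; i++) {
        const Conn &c = w.conns[i];
        if (c.species != 1 && (c.h[0].fib < 0 || c.h[1].fib < 0)) need_grid = true;
      }
    }
    if (need_grid && grid_age >= bind_every) { grid.build(w.fibs, cell_size); grid_age = 0; }
    grid_age++;

    // -- Arp2/3 branch nucleation -----------------------------------------
    if (events_now && do_branch && arp_remaining > 0 && !pool_empty) {
      for (size_t ci = 0; ci < w.conns.size(); ci++) {
        Conn &c = w.conns[ci];
        if (c.species != 1 || c.h[0].fib >= 0) continue;  // already nucleated
        Hand h;
        if (!try_bind(w, grid, c.ax, c.ay, -1, sp[1], dt_ev, rng, h)) continue;
        if (pool < init_length) continue;  // not enough material left
        // mother tangent at the attachment
        Fib &mf = w.fibs[h.fib];
        int si; double u;
        locate(mf, h.abs, si, u);
        double tx = mf.x[si + 1] - mf.x[si], ty = mf.y[si + 1] - mf.y[si];
        double tn = std::sqrt(tx * tx + ty * ty);
        if (tn < 1e-12) continue;
        tx /= tn; ty /= tn;
        int side = rng.unif() < 0.5 ? 1 : -1;
        double ang = side * 72.0 * M_PI / 180.0;
        double ca = std::cos(ang), sa = std::sin(ang);
        double dxv = ca * tx - sa * ty, dyv = sa * tx + ca * ty;
        double bx, by;
        pos_at(mf, h.abs, bx, by);
        Fib d;
        d.seg_rest = mf.seg_rest;
        d.last_rest = init_length;
        d.rigidity = mf.rigidity;
        d.frozen = false;
        d.x.push_back(bx); d.y.push_back(by);
        d.x.push_back(bx + dxv * init_length); d.y.push_back(by + dyv * init_length);
        d.fx.assign(2, 0.0); d.fy.assign(2, 0.0);
        w.fibs.push_back(d);
        pool -= init_length;
        c.h[0] = h;
        c.h[1].fib = (int)w.fibs.size() - 1;
        c.h[1].abs = 0.0;
        c.side = side;
        c.phi0 = ang;
        arp_remaining--;
        branch_angles.push_back(72.0);
        grid_age = 1000000;
        if (arp_remaining <= 0) break;
      }
    }

    // -- binding / unbinding of crosslinkers and motors -------------------
    if (do_bind && events_now) {
      for (size_t ci = 0; ci < w.conns.size(); ci++) {
        Conn &c = w.conns[ci];
        if (c.species == 1) continue;  // arp links are permanent
        const SpeciesPar &p = sp[c.species];
        // unbinding first; a connector that lets go completely keeps its
        // current position as the new anchor. With kramers_f > 0 the rate
        // grows as exp(F / f_char) in the instantaneous link force
        // (slip bond); default is force-independent.
        double off_rate = p.k_off;
        if (p.kramers_f > 0.0 && c.h[0].fib >= 0 && c.h[1].fib >= 0) {
          double x1, y1, x2, y2;
          pos_at(w.fibs[c.h[0].fib], c.h[0].abs, x1, y1);
          pos_at(w.fibs[c.h[1].fib], c.h[1].abs, x2, y2);
          double d = std::sqrt((x2 - x1) * (x2 - x1) + (y2 - y1) * (y2 - y1));
          double fm = std::fabs(p.stiffness * (d - p.rest_length));
          off_rate *= std::exp(fm / p.kramers_f);
        }
        double poff = 1.0 - std::exp(-off_rate * dt_ev);
        bool was_bound = c.h[0].fib >= 0 || c.h[1].fib >= 0;
        double lx = c.ax, ly = c.ay;
        if (was_bound) {
          int hb = c.h[0].fib >= 0 ? 0 : 1;
          pos_at(w.fibs[c.h[hb].fib], c.h[hb].abs, lx, ly);
        }
        for (int hi = 0; hi < 2; hi++) {
          if (c.h[hi].fib >= 0 && poff > 0.0 && rng.unif() < poff) {
            c.h[hi].fib = -1;
          }
        }
        if (was_bound && c.h[0].fib < 0 && c.h[1].fib < 0) {
          c.ax = lx; c.ay = ly;
        }
        // binding
        for (int hi = 0; hi < 2; hi++) {
          if (c.h[hi].fib >= 0) continue;
          int other = 1 - hi;
          double px, py;
          if (c.h[other].fib >= 0)
            pos_at(w.fibs[c.h[other].fib], c.h[other].abs, px, py);
          else { px = c.ax; py = c.ay; }
          Hand h;
          if (try_bind(w, grid, px, py,
                       c.h[other].fib >= 0 ? c.h[other].fib : -1,
                       p, dt_ev, rng, h))
            c.h[hi] = h;
        }
      }
    }

    // -- forces ------------------------------------------------------------
    for (size_t i = 0; i < w.fibs.size(); i++) {
      std::fill(w.fibs[i].fx.begin(), w.fibs[i].fx.end(), 0.0);
      std::fill(w.fibs[i].fy.begin(), w.fibs[i].fy.end(), 0.0);
    }
    for (size_t i = 0; i < w.fibs.size(); i++) {
      add_bending(w.fibs[i], 0.0);
      add_extension(w.fibs[i], mech.extension_stiffness, frame_strain);
    }
    if (frame_strain > max_strain) max_strain = frame_strain;
    loadf.assign(2 * w.conns.size(), 0.0);
    for (size_t ci = 0; ci < w.conns.size(); ci++) {
      Conn &c = w.conns[ci];
      if (c.h[0].fib < 0 || c.h[1].fib < 0) continue;
      const SpeciesPar &p = sp[c.species];
      double x1, y1, x2, y2;
      pos_at(w.fibs[c.h[0].fib], c.h[0].abs, x1, y1);
      pos_at(w.fibs[c.h[1].fib], c.h[1].abs, x2, y2);
      double dx = x2 - x1, dy = y2 - y1;
      double d = std::sqrt(dx * dx + dy * dy);
      if (d > 1e-12) {
        double fmag = p.stiffness * (d - p.rest_length);
        double ux = dx / d, uy = dy / d;
        // force on hand 0 is +fmag*(u), on hand 1 is -fmag*(u)
        spread(w.fibs[c.h[0].fib], c.h[0].abs,  fmag * ux,  fmag * uy);
        spread(w.fibs[c.h[1].fib], c.h[1].abs, -fmag * ux, -fmag * uy);
        if (c.species == 2) {
          // load opposing plus-end motion, per hand
          for (int hi = 0; hi < 2; hi++) {
            Fib &f = w.fibs[c.h[hi].fib];
            int si; double uu;
            locate(f, c.h[hi].abs, si, uu);
            double tx = f.x[si + 1] - f.x[si], ty = f.y[si + 1] - f.y[si];
            double tn = std::sqrt(tx * tx + ty * ty);
            if (tn < 1e-12) continue;
            tx /= tn; ty /= tn;
            double sgn = (hi == 0) ? 1.0 : -1.0;
            double fpar = sgn * (fmag * ux * tx + fmag * uy * ty);
            loadf[2 * ci + hi] = fpar < 0.0 ? -fpar : 0.0;
          }
        }
      }
      // Arp2/3 rotational link between mother tangent and daughter base
      if (c.species == 1 && p.torsion_k > 0.0) {
        Fib &mf = w.fibs[c.h[0].fib];
        Fib &df = w.fibs[c.h[1].fib];
        if (df.n() >= 2) {
          int si; double uu;
          locate(mf, c.h[0].abs, si, uu);
          double axv = mf.x[si + 1] - mf.x[si], ayv = mf.y[si + 1] - mf.y[si];
          double bxv = df.x[1] - df.x[0], byv = df.y[1] - df.y[0];
          double a2 = axv * axv + ayv * ayv, b2 = bxv * bxv + byv * byv;
          if (a2 > 1e-16 && b2 > 1e-16) {
            double phi_m = std::atan2(ayv, axv);
            double phi_d = std::atan2(byv, bxv);
            double dphi = phi_d - phi_m - c.phi0;
            while (dphi > M_PI) dphi -= 2.0 * M_PI;
            while (dphi < -M_PI) dphi += 2.0 * M_PI;
            double cc = -p.torsion_k * dphi;
            // dphi_d/dv1 = perp(b)/|b|^2 applied to daughter, opposite on base
            double pbx = -byv / b2, pby = bxv / b2;
            df.fx[1] += cc * pbx; df.fy[1] += cc * pby;
            df.fx[0] -= cc * pbx; df.fy[0] -= cc * pby;
            // -dphi_m/dv contributions on the mother segment (reaction)
            double pax = -ayv / a2, pay = axv / a2;
            mf.fx[si + 1] -= cc * pax; mf.fy[si + 1] -= cc * pay;
            mf.fx[si]     += cc * pax; mf.fy[si]     += cc * pay;
          }
        }
      }
    }
    // tethers
    for (size_t i = 0; i < w.t_fib.size(); i++) {
      Fib &f = w.fibs[w.t_fib[i]];
      int v = w.t_vtx[i];
      f.fx[v] += w.t_k[i] * (w.t_ax[i] - f.x[v]);
      f.fy[v] += w.t_k[i] * (w.t_ay[i] - f.y[v]);
    }
    // confinement (assembly phase only)
    if (confine_radius > 0.0) {
      for (size_t i = 0; i < w.fibs.size(); i++) {
        Fib &f = w.fibs[i];
        for (int j = 0; j < f.n(); j++) {
          double r = std::sqrt(f.x[j] * f.x[j] + f.y[j] * f.y[j]);
          if (r > confine_radius) {
            double fmag = confine_k * (r - confine_radius) / r;
            f.fx[j] -= fmag * f.x[j];
            f.fy[j] -= fmag * f.y[j];
          }
        }
      }
    }

    // -- motor stepping (linear force-velocity, detach at plus end) -------
    if (do_bind) {
      for (size_t ci = 0; ci < w.conns.size(); ci++) {
        Conn &c = w.conns[ci];
        if (c.species != 2) continue;
        const SpeciesPar &p = sp[2];
        for (int hi = 0; hi < 2; hi++) {
          if (c.h[hi].fib < 0) continue;
          double load = loadf[2 * ci + hi];
          double v = p.v0 * std::max(0.0, 1.0 - load / p.f_s);
          c.h[hi].abs += v * dt;
          double L = w.fibs[c.h[hi].fib].length();
          if (c.h[hi].abs >= L) {  // end detachment
            if (c.h[1 - hi].fib < 0)
              pos_at(w.fibs[c.h[hi].fib], L, c.ax, c.ay);
            c.h[hi].fib = -1;
          }
        }
      }
    }

    // -- Euler-Maruyama update --------------------------------------------
    {
      double gamma = mech.drag_per_length * 1.0;  // per-vertex, set below
      for (size_t i = 0; i < w.fibs.size(); i++) {
        Fib &f = w.fibs[i];
        double gv = mech.drag_per_length * f.seg_rest;
        double mob = dt / gv;
        double noise = mech.kT > 0.0 ? std::sqrt(2.0 * mech.kT * dt / gv) : 0.0;
        for (int j = 0; j < f.n(); j++) {
          f.x[j] += mob * f.fx[j] + (noise > 0.0 ? noise * rng.norm() : 0.0);
          f.y[j] += mob * f.fy[j] + (noise > 0.0 ? noise * rng.norm() : 0.0);
        }
      }
      (void)gamma;
    }
    w.time += dt;
  }

  List out = pack_state(w, state);
  List res = List::create(
      _["state"] = out,
      _["times"] = NumericVector(s_time.begin(), s_time.end()),
      _["radii"] = NumericVector(s_radius.begin(), s_radius.end()),
      _["max_strain"] = max_strain,
      _["pool"] = pool,
      _["arp_remaining"] = arp_remaining,
      _["strain_series"] = NumericVector(s_strain.begin(), s_strain.end()),
      _["branch_angles"] = NumericVector(branch_angles.begin(), branch_angles.end()));
  if (record_frames) {
    List fr(frame_list.size());
    for (size_t i = 0; i < frame_list.size(); i++) fr[i] = frame_list[i];
    res["frames"] = fr;
  }
  return res;
}

// ------------------------------------------------- exported force kernels --

// [[Rcpp::export]]
NumericMatrix cpp_bending_forces(NumericMatrix vertices, double rigidity,
                                 double seg_rest) {
  Fib f;
  f.x.resize(vertices.nrow()); f.y.resize(vertices.nrow());
  for (int i = 0; i < vertices.nrow(); i++) { f.x[i] = vertices(i, 0); f.y[i] = vertices(i, 1); }
  f.fx.assign(vertices.nrow(), 0.0); f.fy.assign(vertices.nrow(), 0.0);
  f.seg_rest = seg_rest; f.last_rest = seg_rest;
  f.rigidity = rigidity; f.frozen = true;
  add_bending(f, 0.0);
  NumericMatrix out(vertices.nrow(), 2);
  for (int i = 0; i < vertices.nrow(); i++) { out(i, 0) = f.fx[i]; out(i, 1) = f.fy[i]; }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_extension_forces(NumericMatrix vertices, NumericVector rests,
                                   double stiffness) {
  int n = vertices.nrow();
  Fib f;
  f.x.resize(n); f.y.resize(n);
  for (int i = 0; i < n; i++) { f.x[i] = vertices(i, 0); f.y[i] = vertices(i, 1); }
  f.fx.assign(n, 0.0); f.fy.assign(n, 0.0);
  f.seg_rest = rests[0];
  f.last_rest = rests[n - 2];
  f.rigidity = 0.0; f.frozen = true;
  // general rests: apply springs manually to honour per-segment rest lengths
  double ms = 0.0;
  for (int i = 0; i < n - 1; i++) {
    double sx = f.x[i + 1] - f.x[i], sy = f.y[i + 1] - f.y[i];
    double d = std::sqrt(sx * sx + sy * sy);
    if (d < 1e-12) continue;
    double fmag = stiffness * (d - rests[i]);
    f.fx[i] += fmag * sx / d;     f.fy[i] += fmag * sy / d;
    f.fx[i + 1] -= fmag * sx / d; f.fy[i + 1] -= fmag * sy / d;
  }
  (void)ms;
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; i++) { out(i, 0) = f.fx[i]; out(i, 1) = f.fy[i]; }
  return out;
}
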