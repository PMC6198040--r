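// Brownian-dynamics engine for dynamic microtubules and two-headed
// crosslinking motors in a thin box, periodic in x and y.
//
// Integration: explicit Euler-Maruyama for motor springs, steric repulsion,
// z-confinement and thermal noise; semi-implicit (banded per-filament solve)
// for bending so the bending stiffness does not bind the time step.
// Inextensibility: position-based projection + arc-length resampling from the
// static minus end.
//
// Randomness: a dedicated generator seeded once from R's RNG at entry, so a
// run is an exact deterministic function of (config, seed). Draws occur in a
// fixed order per step: nucleation, instability, attach, detach, noise.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <map>
using namespace Rcpp;

namespace {

// xoshiro256++ with Box-Muller normals: fast, and seeded once from R's
// generator so a run is an exact deterministic function of (config, seed)
struct Rng {
  uint64_t s[4];
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  void seedFromR() {
    uint64_t z = (uint64_t)(unif_rand() * 4294967296.0);
    z = (z << 32) ^ (uint64_t)(unif_rand() * 4294967296.0);
    for (int i = 0; i < 4; ++i) {       // splitmix64 expansion
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
      x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
      s[i] = x ^ (x >> 31);
    }
    if (!zig_ready) zigInit();
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  // Marsaglia-Tsang ziggurat for standard normals (128 layers)
  static uint32_t kn[128];
  static double wn[128], fn[128];
  static bool zig_ready;
  static void zigInit() {
    double dn = 3.442619855899, tn = dn;
    const double m1 = 2147483648.0, vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
    zig_ready = true;
  }
  double norm() {
    for (;;) {
      int32_t hz = (int32_t)(next() >> 32);
      uint32_t iz = (uint32_t)hz & 127u;
      if ((uint32_t)std::abs(hz) < kn[iz]) return hz * wn[iz];
      const double r = 3.442619855899;
      double x = hz * wn[iz];
      if (iz == 0) {
        double y;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -(r + x);
      }
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * x * x))
        return x;
      // otherwise resample from the top of the loop
    }
  }
};
uint32_t Rng::kn[128];
double Rng::wn[128];
double Rng::fn[128];
bool Rng::zig_ready = false;

struct Fil {
  int id;
  int nuc;          // nucleator index
  int state;        // 1 growing, 0 shrinking
  double L;
  double birth;
  double lrest;     // current segment rest length
  double ilrest;    // 1 / lrest
  double fa_tip;    // antagonistic force on the plus end (<= 0)
  std::vector<double> x, y, z;
  std::vector<double> fx, fy, fz;   // force accumulators, reused every step
  std::vector<double> kst;          // attached spring stiffness per vertex
  int nv() const { return (int)x.size(); }
};

struct Motor {
  int f[2];         // filament id or -1
  double a[2];      // abscissa from the minus end
  bool e[2];        // end-bound (plus end) flag
  // cached spring state for the current step (valid when doubly bound)
  double sfx, sfy, sfz;   // force vector on head 0 (head 1 gets the negative)
  double fmag;            // |kappa_m * (len - dm)|-signed magnitude
  bool hasSpring;
  Motor() {
    f[0] = f[1] = -1; a[0] = a[1] = 0.0; e[0] = e[1] = false;
    sfx = sfy = sfz = fmag = 0.0; hasSpring = false;
  }
  int nbound() const { return (f[0] >= 0) + (f[1] >= 0); }
};

struct P {
  double Lx, Ly, Lz, z_stiff;
  double vg, vs, kcat, fg, L0, rigidity, seg;
  double knuc; int n_nuc;
  double kappa_s, d0;
  int n_mot;
  double vm, f_stall, kon, rb, koff, kend, f_unbind, dm, kappa_m;
  int vsign;
  double visc, kT, dt, t_end, frame_interval;
  double gamma;     // per-vertex drag
};

inline double mi(double d, double Lbox) { return d - Lbox * std::nearbyint(d / Lbox); }

struct Vec3 { double x, y, z; };

inline Vec3 pointAt(const Fil& f, double s) {
  int k = (int)(s * f.ilrest);
  int ns = f.nv() - 1;
  if (k > ns - 1) k = ns - 1;
  if (k < 0) k = 0;
  double w = s * f.ilrest - k;
  if (w < 0) w = 0; if (w > 1) w = 1;
  return Vec3{ f.x[k] * (1 - w) + f.x[k + 1] * w,
               f.y[k] * (1 - w) + f.y[k + 1] * w,
               f.z[k] * (1 - w) + f.z[k + 1] * w };
}

// point and tangent at abscissa s with one segment lookup
inline void headGeom(const Fil& f, double s, Vec3& pt, Vec3& tg) {
  int k = (int)(s * f.ilrest);
  int ns = f.nv() - 1;
  if (k > ns - 1) k = ns - 1;
  if (k < 0) k = 0;
  double w = s * f.ilrest - k;
  if (w < 0) w = 0; if (w > 1) w = 1;
  double tx = f.x[k + 1] - f.x[k], ty = f.y[k + 1] - f.y[k], tz = f.z[k + 1] - f.z[k];
  pt.x = f.x[k] + w * tx; pt.y = f.y[k] + w * ty; pt.z = f.z[k] + w * tz;
  double n = std::sqrt(tx * tx + ty * ty + tz * tz);
  if (n < 1e-12) { tg = Vec3{1, 0, 0}; return; }
  tg.x = tx / n; tg.y = ty / n; tg.z = tz / n;
}

inline Vec3 tangentAt(const Fil& f, double s) {
  int k = (int)(s * f.ilrest);
  int ns = f.nv() - 1;
  if (k > ns - 1) k = ns - 1;
  if (k < 0) k = 0;
  double tx = f.x[k + 1] - f.x[k], ty = f.y[k + 1] - f.y[k], tz = f.z[k + 1] - f.z[k];
  double n = std::sqrt(tx * tx + ty * ty + tz * tz);
  if (n < 1e-12) return Vec3{1, 0, 0};
  return Vec3{ tx / n, ty / n, tz / n };
}

// resample the polyline to uniform spacing with total arc length L, anchored
// at the minus end; extrapolates along the final tangent when needed
void resample(Fil& f, double segnom) {
  static thread_local std::vector<double> cum, nx, ny, nz;
  int ns_new = std::max(1, (int)std::lround(f.L / segnom));
  int nv_old = f.nv();
  cum.resize(nv_old);
  cum[0] = 0.0;
  for (int i = 1; i < nv_old; ++i) {
    double dx = f.x[i] - f.x[i - 1], dy = f.y[i] - f.y[i - 1], dz = f.z[i] - f.z[i - 1];
    cum[i] = cum[i - 1] + std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  double arc = cum[nv_old - 1];
  double tx = 1, ty = 0, tz = 0;
  if (nv_old >= 2) {
    tx = f.x[nv_old - 1] - f.x[nv_old - 2];
    ty = f.y[nv_old - 1] - f.y[nv_old - 2];
    tz = f.z[nv_old - 1] - f.z[nv_old - 2];
    double n = std::sqrt(tx * tx + ty * ty + tz * tz);
    if (n > 1e-12) { tx /= n; ty /= n; tz /= n; } else { tx = 1; ty = 0; tz = 0; }
  }
  double lr = f.L / ns_new;
  nx.resize(ns_new + 1); ny.resize(ns_new + 1); nz.resize(ns_new + 1);
  int j = 0;
  for (int k = 0; k <= ns_new; ++k) {
    double s = lr * k;
    if (s <= arc + 1e-12) {
      while (j < nv_old - 2 && cum[j + 1] < s) ++j;
      double den = cum[j + 1] - cum[j];
      double w = den > 1e-12 ? (s - cum[j]) / den : 0.0;
      if (w < 0) w = 0; if (w > 1) w = 1;
      nx[k] = f.x[j] * (1 - w) + f.x[j + 1] * w;
      ny[k] = f.y[j] * (1 - w) + f.y[j + 1] * w;
      nz[k] = f.z[j] * (1 - w) + f.z[j + 1] * w;
    } else {
      double ex = s - arc;
      nx[k] = f.x[nv_old - 1] + tx * ex;
      ny[k] = f.y[nv_old - 1] + ty * ex;
      nz[k] = f.z[nv_old - 1] + tz * ex;
    }
  }
  f.x.assign(nx.begin(), nx.end());
  f.y.assign(ny.begin(), ny.end());
  f.z.assign(nz.begin(), nz.end());
  f.lrest = lr;
  f.ilrest = 1.0 / lr;
}

// solve (I + c * D4) u = b for the three coordinate right-hand sides, where
// D4 = D2^T D2 is the discrete bending operator: symmetric positive definite
// and pentadiagonal, solved by banded LDL^T (no pivoting needed)
void bendSolve(double c, int n, double* bx, double* by, double* bz) {
  static thread_local std::vector<double> d0, d1, d2;
  d0.assign(n, 1.0); d1.assign(n, 0.0); d2.assign(n, 0.0);
  for (int j = 1; j <= n - 2; ++j) {
    // D4 row contributions from the j-th second difference (1, -2, 1)
    d0[j - 1] += c; d0[j] += 4 * c; d0[j + 1] += c;
    d1[j - 1] += -2 * c; d1[j] += -2 * c;   // (j-1,j) and (j,j+1)
    d2[j - 1] += c;                          // (j-1,j+1)
  }
  // banded Cholesky-like factorization A = L D L^T, bandwidth 2
  static thread_local std::vector<double> D, L1, L2;
  D.assign(n, 0.0); L1.assign(n, 0.0); L2.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double di = d0[i];
    if (i >= 1) di -= L1[i - 1] * L1[i - 1] * D[i - 1];
    if (i >= 2) di -= L2[i - 2] * L2[i - 2] * D[i - 2];
    D[i] = di;
    if (i + 1 < n) {
      double v = d1[i];
      if (i >= 1) v -= L1[i - 1] * D[i - 1] * L2[i - 1];
      L1[i] = v / di;
    }
    if (i + 2 < n) L2[i] = d2[i] / di;
  }
  auto solve1 = [&](double* b) {
    for (int i = 0; i < n; ++i) {
      if (i >= 1) b[i] -= L1[i - 1] * b[i - 1];
      if (i >= 2) b[i] -= L2[i - 2] * b[i - 2];
    }
    for (int i = 0; i < n; ++i) b[i] /= D[i];
    for (int i = n - 1; i >= 0; --i) {
      if (i + 1 < n) b[i] -= L1[i] * b[i + 1];
      if (i + 2 < n) b[i] -= L2[i] * b[i + 2];
    }
  };
  solve1(bx); solve1(by); solve1(bz);
}

struct Grid {
  int nx = 0, ny = 0;
  double Lx = 0, Ly = 0;
  std::vector<int> head, nxt, vfil, vidx;
  void build(const std::vector<Fil>& fils, double cell, double Lx_, double Ly_) {
    Lx = Lx_; Ly = Ly_;
    nx = std::max(1, (int)(Lx / cell));
    ny = std::max(1, (int)(Ly / cell));
    head.assign((size_t)nx * ny, -1);
    int tot = 0;
    for (auto& f : fils) tot += f.nv();
    nxt.resize(tot); vfil.resize(tot); vidx.resize(tot);
    int vi = 0;
    for (int fi = 0; fi < (int)fils.size(); ++fi) {
      const Fil& f = fils[fi];
      for (int k = 0; k < f.nv(); ++k) {
        int c = cellOf(f.x[k], f.y[k]);
        vfil[vi] = fi; vidx[vi] = k;
        nxt[vi] = head[c]; head[c] = vi;
        ++vi;
      }
    }
  }
  inline int wrapi(int i, int n) const { i %= n; if (i < 0) i += n; return i; }
  inline int cellOf(double x, double y) const {
    int ix = wrapi((int)std::floor(x / Lx * nx), nx);
    int iy = wrapi((int)std::floor(y / Ly * ny), ny);
    return iy * nx + ix;
  }
};

} // namespace

// [[Rcpp::export]]
List sim_run_cpp(List cfg) {
  P p;
  p.Lx = cfg["Lx"]; p.Ly = cfg["Ly"]; p.Lz = cfg["Lz"]; p.z_stiff = cfg["z_stiff"];
  p.vg = cfg["vg"]; p.vs = cfg["vs"]; p.kcat = cfg["kcat"]; p.fg = cfg["fg"];
  p.L0 = cfg["L0"]; p.rigidity = cfg["rigidity"]; p.seg = cfg["seg"];
  p.knuc = cfg["knuc"]; p.n_nuc = cfg["n_nuc"];
  p.kappa_s = cfg["kappa_s"]; p.d0 = cfg["d0"];
  p.n_mot = cfg["n_mot"]; p.vm = cfg["vm"]; p.f_stall = cfg["f_stall"];
  p.kon = cfg["kon"]; p.rb = cfg["rb"]; p.koff = cfg["koff"]; p.kend = cfg["kend"];
  p.f_unbind = cfg["f_unbind"]; p.dm = cfg["dm"]; p.kappa_m = cfg["kappa_m"];
  p.vsign = as<bool>(cfg["plus_end_directed"]) ? 1 : -1;
  p.visc = cfg["viscosity"]; p.kT = cfg["kT"]; p.dt = cfg["dt"];
  p.t_end = cfg["t_end"]; p.frame_interval = cfg["frame_interval"];
  p.gamma = 3.0 * M_PI * p.visc * p.seg;

  Rng rng;
  rng.seedFromR();

  const double dt = p.dt;
  const double p_nuc = 1.0 - std::exp(-p.knuc * dt);
  const double p_cat = 1.0 - std::exp(-p.kcat * dt);
  const double p_on  = 1.0 - std::exp(-p.kon * dt);
  const double p_off0 = 1.0 - std::exp(-p.koff * dt);
  const double p_end0 = 1.0 - std::exp(-p.kend * dt);
  const double Lmin = 1e-3;

  std::vector<double> nucx(p.n_nuc), nucy(p.n_nuc), nucz(p.n_nuc);
  std::vector<int> nucBusy(p.n_nuc, 0);
  if (cfg.containsElementNamed("nucleator_positions") &&
      !Rf_isNull(cfg["nucleator_positions"])) {
    NumericMatrix np = cfg["nucleator_positions"];
    if (np.nrow() != p.n_nuc) stop("nucleator_positions must have n_nuc rows");
    for (int i = 0; i < p.n_nuc; ++i) { nucx[i] = np(i, 0); nucy[i] = np(i, 1); nucz[i] = np(i, 2); }
  } else {
    for (int i = 0; i < p.n_nuc; ++i) {
      nucx[i] = rng.unif() * p.Lx;
      nucy[i] = rng.unif() * p.Ly;
      nucz[i] = (rng.unif() - 0.5) * p.Lz;
    }
  }

  std::vector<Fil> fils;
  std::vector<Motor> motors(p.n_mot);
  int nextId = 0;

  auto makeFil = [&](int nuc, double x0, double y0, double z0,
                     double ux, double uy, double uz, double L, int state, double t) {
    Fil f;
    f.id = nextId++; f.nuc = nuc; f.state = state; f.L = L; f.birth = t;
    f.fa_tip = 0.0;
    int ns = std::max(1, (int)std::lround(L / p.seg));
    f.lrest = L / ns;
    f.ilrest = ns / L;
    f.x.resize(ns + 1); f.y.resize(ns + 1); f.z.resize(ns + 1);
    for (int k = 0; k <= ns; ++k) {
      f.x[k] = x0 + ux * f.lrest * k;
      f.y[k] = y0 + uy * f.lrest * k;
      f.z[k] = z0 + uz * f.lrest * k;
    }
    if (nuc >= 0) nucBusy[nuc] = 1;
    fils.push_back(std::move(f));
  };

  if (cfg.containsElementNamed("init_filaments") && !Rf_isNull(cfg["init_filaments"])) {
    DataFrame init = cfg["init_filaments"];
    NumericVector ix = init["x"], iy = init["y"], iz = init["z"],
                  iux = init["ux"], iuy = init["uy"], iuz = init["uz"], il = init["length"];
    if ((int)ix.size() > p.n_nuc) stop("more init_filaments than nucleators");
    for (int i = 0; i < ix.size(); ++i) {
      double n = std::sqrt(iux[i] * iux[i] + iuy[i] * iuy[i] + iuz[i] * iuz[i]);
      makeFil(i, ix[i], iy[i], iz[i], iux[i] / n, iuy[i] / n, iuz[i] / n, il[i], 1, 0.0);
      nucx[i] = ix[i]; nucy[i] = iy[i]; nucz[i] = iz[i];
    }
  }
  if (cfg.containsElementNamed("init_motors") && !Rf_isNull(cfg["init_motors"])) {
    DataFrame im = cfg["init_motors"];
    IntegerVector fa = im["fil_a"], fb = im["fil_b"];
    NumericVector aa = im["abs_a"], ab = im["abs_b"];
    if (fa.size() > (int)motors.size()) stop("more init_motors than motors");
    for (int i = 0; i < fa.size(); ++i) {
      if (!IntegerVector::is_na(fa[i])) { motors[i].f[0] = fils[fa[i] - 1].id; motors[i].a[0] = aa[i]; }
      if (!IntegerVector::is_na(fb[i])) { motors[i].f[1] = fils[fb[i] - 1].id; motors[i].a[1] = ab[i]; }
    }
  }

  std::vector<int> slotOf;
  auto rebuildSlots = [&]() {
    slotOf.assign(nextId, -1);
    for (int i = 0; i < (int)fils.size(); ++i) slotOf[fils[i].id] = i;
  };
  rebuildSlots();

  Grid grid;
  const double cellSize = std::max(p.d0, p.rb);

  long n_nucleated = 0, n_cat = 0, n_deleted = 0, n_att1 = 0, n_att2 = 0,
       n_det_side = 0, n_det_end = 0;

  std::vector<int> F_frame, F_id, F_nuc, F_state, F_vi;
  std::vector<double> F_time, F_len, F_birth, F_x, F_y, F_z;
  std::vector<int> M_frame, M_id, M_fa, M_fb, M_ea, M_eb;
  std::vector<double> M_time, M_aa, M_ab;
  int frameNo = 0;

  auto emitFrame = [&](double t) {
    for (auto& f : fils) {
      for (int k = 0; k < f.nv(); ++k) {
        F_frame.push_back(frameNo); F_time.push_back(t);
        F_id.push_back(f.id); F_nuc.push_back(f.nuc); F_state.push_back(f.state);
        F_len.push_back(f.L); F_birth.push_back(f.birth); F_vi.push_back(k);
        F_x.push_back(f.x[k]); F_y.push_back(f.y[k]); F_z.push_back(f.z[k]);
      }
    }
    for (int m = 0; m < (int)motors.size(); ++m) {
      if (motors[m].nbound() == 0) continue;
      M_frame.push_back(frameNo); M_time.push_back(t); M_id.push_back(m);
      M_fa.push_back(motors[m].f[0]); M_aa.push_back(motors[m].a[0]); M_ea.push_back(motors[m].e[0]);
      M_fb.push_back(motors[m].f[1]); M_ab.push_back(motors[m].a[1]); M_eb.push_back(motors[m].e[1]);
    }
    ++frameNo;
  };

  long nsteps = (long)std::ceil(p.t_end / dt);
  long framesEvery = std::max(1L, (long)std::lround(p.frame_interval / dt));
  emitFrame(0.0);

  std::vector<char> seen;
  std::vector<double> bx, by, bz;
  std::vector<int> kill;

  for (long step = 0; step < nsteps; ++step) {
    double t = step * dt;
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();

    // ---- 1. nucleation -------------------------------------------------
    bool newFil = false;
    for (int i = 0; i < p.n_nuc; ++i) {
      if (nucBusy[i]) continue;
      if (rng.unif() < p_nuc) {
        double phi = rng.unif() * 2.0 * M_PI;
        double alpha = (rng.unif() - 0.5) * 0.2;
        makeFil(i, nucx[i], nucy[i], nucz[i],
                std::cos(phi) * std::cos(alpha), std::sin(phi) * std::cos(alpha),
                std::sin(alpha), p.L0, 1, t);
        ++n_nucleated;
        newFil = true;
      }
    }
    if (newFil) rebuildSlots();

    // ---- 2. dynamic instability ----------------------------------------
    kill.clear();
    for (auto& f : fils) {
      if (f.state == 1) {
        double dL = p.vg * std::exp(std::min(0.0, f.fa_tip) / p.fg) * dt;
        // extend the tip, then re-sample to uniform spacing anchored at the
        // minus end, so growth never stretches segments into the constraint
        // projection (which would leak tip displacement down the chain)
        int n = f.nv();
        Vec3 tt = tangentAt(f, f.L);
        f.x[n - 1] += tt.x * dL; f.y[n - 1] += tt.y * dL; f.z[n - 1] += tt.z * dL;
        f.L += dL;
        resample(f, p.seg);
        if (p.kcat > 0 && rng.unif() < p_cat) { f.state = 0; ++n_cat; }
      } else {
        f.L -= p.vs * dt;
        if (f.L <= Lmin) { kill.push_back(f.id); continue; }
        resample(f, p.seg);
      }
    }
    if (!kill.empty()) {
      for (int id : kill) {
        int s = slotOf[id];
        nucBusy[fils[s].nuc] = 0;
        fils.erase(fils.begin() + s);
        rebuildSlots();
        ++n_deleted;
      }
      for (auto& m : motors)
        for (int h = 0; h < 2; ++h)
          if (m.f[h] >= 0 && slotOf[m.f[h]] < 0) { m.f[h] = -1; m.e[h] = false; }
    }
    for (auto& m : motors) {
      for (int h = 0; h < 2; ++h) {
        if (m.f[h] < 0) continue;
        Fil& f = fils[slotOf[m.f[h]]];
        if (m.a[h] > f.L) {
          if (f.state == 0) {   // lattice under the head depolymerized
            m.f[h] = -1; m.e[h] = false;
            ++n_det_side;
          } else m.a[h] = f.L;
        }
        if (m.f[h] >= 0 && m.e[h] && m.a[h] < f.L - 1e-9) m.e[h] = false;
      }
    }

    if (fils.empty()) {
      if ((step + 1) % framesEvery == 0 || step == nsteps - 1) emitFrame((step + 1) * dt);
      continue;
    }

    grid.build(fils, cellSize, p.Lx, p.Ly);

    // ---- 3. attachment --------------------------------------------------
    double totL = 0.0;
    for (auto& f : fils) totL += f.L;
    for (auto& m : motors) {
      int nb = m.nbound();
      if (nb == 2) continue;
      if (nb == 0) {
        if (rng.unif() < p_on && totL > 0) {
          double u = rng.unif() * totL;
          int fi = 0;
          while (fi < (int)fils.size() - 1 && u > fils[fi].L) { u -= fils[fi].L; ++fi; }
          m.f[0] = fils[fi].id; m.a[0] = std::min(u, fils[fi].L); m.e[0] = false;
          ++n_att1;
        }
        continue;
      }
      if (rng.unif() >= p_on) continue;
      int hb = (m.f[0] >= 0) ? 0 : 1, hf = 1 - hb;
      const Fil& A = fils[slotOf[m.f[hb]]];
      Vec3 pos = pointAt(A, m.a[hb]);
      double reach = p.rb + 0.8 * p.seg;
      int kcx = (int)std::ceil(reach / (p.Lx / grid.nx)) + 1;
      int kcy = (int)std::ceil(reach / (p.Ly / grid.ny)) + 1;
      int ix0 = (int)std::floor(pos.x / p.Lx * grid.nx);
      int iy0 = (int)std::floor(pos.y / p.Ly * grid.ny);
      int nCand = 0;
      int candF[32]; double candA[32];
      seen.assign(fils.size(), 0);
      for (int dy2 = -kcy; dy2 <= kcy; ++dy2) {
        for (int dx2 = -kcx; dx2 <= kcx; ++dx2) {
          int c = grid.wrapi(iy0 + dy2, grid.ny) * grid.nx + grid.wrapi(ix0 + dx2, grid.nx);
          for (int vi = grid.head[c]; vi >= 0; vi = grid.nxt[vi]) {
            int fi = grid.vfil[vi];
            if (seen[fi]) continue;
            const Fil& B = fils[fi];
            if (B.id == m.f[hb]) { seen[fi] = 1; continue; }
            double vx = mi(pos.x - B.x[grid.vidx[vi]], p.Lx);
            double vy = mi(pos.y - B.y[grid.vidx[vi]], p.Ly);
            double vz = pos.z - B.z[grid.vidx[vi]];
            if (vx * vx + vy * vy + vz * vz > reach * reach) continue;
            seen[fi] = 1;
            double bestD2 = 1e30, bestS = 0.0;
            for (int k = 0; k < B.nv() - 1; ++k) {
              double ax = mi(pos.x - B.x[k], p.Lx), ay = mi(pos.y - B.y[k], p.Ly), az = pos.z - B.z[k];
              double ex = B.x[k + 1] - B.x[k], ey = B.y[k + 1] - B.y[k], ez = B.z[k + 1] - B.z[k];
              double ee = ex * ex + ey * ey + ez * ez;
              double w = ee > 1e-12 ? (ax * ex + ay * ey + az * ez) / ee : 0.0;
              if (w < 0) w = 0; if (w > 1) w = 1;
              double qx = ax - w * ex, qy = ay - w * ey, qz = az - w * ez;
              double d2 = qx * qx + qy * qy + qz * qz;
              if (d2 < bestD2) { bestD2 = d2; bestS = (k + w) * B.lrest; }
            }
            if (bestD2 <= p.rb * p.rb && nCand < 32) {
              candF[nCand] = fi;
              candA[nCand] = std::min(bestS, B.L);
              ++nCand;
            }
          }
        }
      }
      if (nCand > 0) {
        int pick = std::min((int)(rng.unif() * nCand), nCand - 1);
        m.f[hf] = fils[candF[pick]].id;
        m.a[hf] = candA[pick];
        m.e[hf] = false;
        ++n_att2;
      }
    }

    // ---- 4. motor walking (spring cached for detach + integration) ------
    for (auto& m : motors) {
      int nb = m.nbound();
      if (nb == 0) { m.hasSpring = false; continue; }
      m.hasSpring = false;
      Vec3 pt[2], tg[2];
      for (int h = 0; h < 2; ++h)
        if (m.f[h] >= 0) headGeom(fils[slotOf[m.f[h]]], m.a[h], pt[h], tg[h]);
      if (nb == 2) {
        double dx = mi(pt[1].x - pt[0].x, p.Lx), dy = mi(pt[1].y - pt[0].y, p.Ly),
               dz = pt[1].z - pt[0].z;
        double len = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (len >= 1e-9) {
          m.fmag = p.kappa_m * (len - p.dm);
          double s = m.fmag / len;
          m.sfx = s * dx; m.sfy = s * dy; m.sfz = s * dz;
          m.hasSpring = true;
        }
      }
      for (int h = 0; h < 2; ++h) {
        if (m.f[h] < 0) continue;
        Fil& f = fils[slotOf[m.f[h]]];
        double v = p.vm;
        if (m.hasSpring) {
          double sgn = (h == 0) ? 1.0 : -1.0;
          double fpar = sgn * (m.sfx * tg[h].x + m.sfy * tg[h].y + m.sfz * tg[h].z);
          v = p.vm * (1.0 + (p.vsign > 0 ? fpar : -fpar) / p.f_stall);
          if (v < 0) v = 0;
        }
        m.a[h] += p.vsign * v * dt;
        if (m.a[h] >= f.L) { m.a[h] = f.L; if (p.vsign > 0) m.e[h] = true; }
        if (m.a[h] <= 0) m.a[h] = 0;
      }
    }

    // ---- 5. detachment --------------------------------------------------
    for (auto& m : motors) {
      int nb = m.nbound();
      if (nb == 0) continue;
      double fload = m.hasSpring ? std::fabs(m.fmag) : 0.0;
      bool loaded = fload > 1e-12;
      double kram = loaded ? std::exp(fload / p.f_unbind) : 1.0;
      for (int h = 0; h < 2; ++h) {
        if (m.f[h] < 0) continue;
        double prob;
        if (!loaded) prob = m.e[h] ? p_end0 : p_off0;
        else {
          double x = (m.e[h] ? p.kend : p.koff) * kram * dt;
          // 1 - exp(-x): series for small x (|error| < 2e-7), exact otherwise
          prob = x < 0.05 ? x * (1.0 - 0.5 * x * (1.0 - x / 3.0)) : -std::expm1(-x);
        }
        if (rng.unif() < prob) {
          if (m.e[h]) ++n_det_end; else ++n_det_side;
          m.f[h] = -1; m.e[h] = false;
          m.hasSpring = false;
        }
      }
    }

    // ---- 6. Langevin integration ----------------------------------------
    int nf = fils.size();
    for (auto& f : fils) {
      f.fx.assign(f.nv(), 0.0);
      f.fy.assign(f.nv(), 0.0);
      f.fz.assign(f.nv(), 0.0);
      f.kst.assign(f.nv(), 0.0);
    }
    auto addAt = [&](int fi, double s, double fx, double fy, double fz, double kk) {
      Fil& f = fils[fi];
      int k = (int)(s * f.ilrest);
      if (k > f.nv() - 2) k = f.nv() - 2;
      if (k < 0) k = 0;
      double w = s * f.ilrest - k;
      if (w < 0) w = 0; if (w > 1) w = 1;
      f.fx[k] += fx * (1 - w); f.fx[k + 1] += fx * w;
      f.fy[k] += fy * (1 - w); f.fy[k + 1] += fy * w;
      f.fz[k] += fz * (1 - w); f.fz[k + 1] += fz * w;
      f.kst[k] += kk * (1 - w); f.kst[k + 1] += kk * w;
    };

    for (auto& m : motors) {
      if (!m.hasSpring || m.nbound() != 2) continue;
      int ia = slotOf[m.f[0]], ib = slotOf[m.f[1]];
      addAt(ia, m.a[0],  m.sfx,  m.sfy,  m.sfz, p.kappa_m);
      addAt(ib, m.a[1], -m.sfx, -m.sfy, -m.sfz, p.kappa_m);
    }

    if (p.kappa_s > 0) {
      int tot = grid.vfil.size();
      for (int vi = 0; vi < tot; ++vi) {
        int fi = grid.vfil[vi], ki = grid.vidx[vi];
        Fil& A = fils[fi];
        double axp = A.x[ki], ayp = A.y[ki], azp = A.z[ki];
        int ix0 = (int)std::floor(axp / p.Lx * grid.nx);
        int iy0 = (int)std::floor(ayp / p.Ly * grid.ny);
        for (int dy2 = -1; dy2 <= 1; ++dy2) {
          for (int dx2 = -1; dx2 <= 1; ++dx2) {
            int c = grid.wrapi(iy0 + dy2, grid.ny) * grid.nx + grid.wrapi(ix0 + dx2, grid.nx);
            for (int vj = grid.head[c]; vj >= 0; vj = grid.nxt[vj]) {
              if (vj <= vi) continue;
              int fj = grid.vfil[vj];
              if (fj == fi) continue;
              Fil& B = fils[fj];
              int kj = grid.vidx[vj];
              double dx = mi(B.x[kj] - axp, p.Lx), dy = mi(B.y[kj] - ayp, p.Ly),
                     dz = B.z[kj] - azp;
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 >= p.d0 * p.d0) continue;
              double d = std::sqrt(d2);
              double ux, uy, uz;
              if (d < 1e-9) {
                double phi = rng.unif() * 2 * M_PI;
                ux = std::cos(phi); uy = std::sin(phi); uz = 0;
                d = 0;
              } else { ux = dx / d; uy = dy / d; uz = dz / d; }
              // shared normal: separation vector minus its component along
              // the mean filament axis (exact Newton pair; perpendicular to
              // both axes for parallel/anti-parallel contacts)
              Vec3 ta = tangentAt(A, std::min(ki * A.lrest, A.L));
              Vec3 tb = tangentAt(B, std::min(kj * B.lrest, B.L));
              double sgn = (ta.x * tb.x + ta.y * tb.y + ta.z * tb.z) >= 0 ? 1.0 : -1.0;
              double mx = ta.x + sgn * tb.x, my = ta.y + sgn * tb.y, mz = ta.z + sgn * tb.z;
              double mn = std::sqrt(mx * mx + my * my + mz * mz);
              if (mn > 1e-9) {
                mx /= mn; my /= mn; mz /= mn;
                double proj = ux * mx + uy * my + uz * mz;
                ux -= proj * mx; uy -= proj * my; uz -= proj * mz;
                double un = std::sqrt(ux * ux + uy * uy + uz * uz);
                if (un < 1e-9) {
                  // separation parallel to the common axis: pick a random
                  // direction perpendicular to it
                  double rx = rng.norm(), ry = rng.norm(), rz = rng.norm();
                  double pr = rx * mx + ry * my + rz * mz;
                  rx -= pr * mx; ry -= pr * my; rz -= pr * mz;
                  double rn = std::sqrt(rx * rx + ry * ry + rz * rz);
                  if (rn < 1e-9) { rx = -my; ry = mx; rz = 0; rn = std::sqrt(rx * rx + ry * ry); }
                  ux = rx / rn; uy = ry / rn; uz = rz / rn;
                } else { ux /= un; uy /= un; uz /= un; }
              }
              double fm = p.kappa_s * (p.d0 - d);
              A.fx[ki] -= fm * ux; A.fy[ki] -= fm * uy; A.fz[ki] -= fm * uz;
              B.fx[kj] += fm * ux; B.fy[kj] += fm * uy; B.fz[kj] += fm * uz;
              A.kst[ki] += p.kappa_s; B.kst[kj] += p.kappa_s;
            }
          }
        }
      }
    }

    for (auto& f : fils) {
      double zh = p.Lz / 2;
      for (int k = 0; k < f.nv(); ++k) {
        if (f.z[k] > zh) { f.fz[k] -= p.z_stiff * (f.z[k] - zh); f.kst[k] += p.z_stiff; }
        else if (f.z[k] < -zh) { f.fz[k] -= p.z_stiff * (f.z[k] + zh); f.kst[k] += p.z_stiff; }
      }
    }

    // antagonistic tip load for the next growth update (deterministic forces)
    for (auto& f : fils) {
      int ke = f.nv() - 1;
      Vec3 tt = tangentAt(f, f.L);
      f.fa_tip = std::min(0.0, f.fx[ke] * tt.x + f.fy[ke] * tt.y + f.fz[ke] * tt.z);
    }

    double noiseAmp = std::sqrt(2.0 * p.kT * dt / p.gamma);
    double maxDisp2 = 0.0;
    for (int i = 0; i < nf; ++i) {
      Fil& f = fils[i];
      int n = f.nv();
      bx.resize(n); by.resize(n); bz.resize(n);
      for (int k = 0; k < n; ++k) {
        double nxr = 0, nyr = 0, nzr = 0;
        if (p.kT > 0) { nxr = rng.norm(); nyr = rng.norm(); nzr = rng.norm(); }
        // diagonally-implicit stabilization: the response to the attached
        // spring forces is damped by the local stiffness so that arbitrarily
        // many crosslinks on one vertex cannot destabilize the step
        double damp = dt / (p.gamma + dt * f.kst[k]);
        bx[k] = f.x[k] + damp * f.fx[k] + noiseAmp * nxr;
        by[k] = f.y[k] + damp * f.fy[k] + noiseAmp * nyr;
        bz[k] = f.z[k] + damp * f.fz[k] + noiseAmp * nzr;
      }
      if (n >= 3 && p.rigidity > 0) {
        double kb = p.rigidity / (f.lrest * f.lrest * f.lrest);
        bendSolve(dt * kb / p.gamma, n, bx.data(), by.data(), bz.data());
      }
      for (int it = 0; it < 2; ++it) {
        for (int k = 0; k < n - 1; ++k) {
          double ex = bx[k + 1] - bx[k], ey = by[k + 1] - by[k], ez = bz[k + 1] - bz[k];
          double el = std::sqrt(ex * ex + ey * ey + ez * ez);
          if (el < 1e-12) continue;
          double corr = 0.5 * (el - f.lrest) / el;
          bx[k] += corr * ex; by[k] += corr * ey; bz[k] += corr * ez;
          bx[k + 1] -= corr * ex; by[k + 1] -= corr * ey; bz[k + 1] -= corr * ez;
        }
      }
      for (int k = 0; k < n; ++k) {
        double ddx = bx[k] - f.x[k], ddy = by[k] - f.y[k], ddz = bz[k] - f.z[k];
        double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
        if (d2 > maxDisp2) maxDisp2 = d2;
        f.x[k] = bx[k]; f.y[k] = by[k]; f.z[k] = bz[k];
      }
      resample(f, p.seg);   // re-anchors the minus end every step
    }
    if (maxDisp2 > p.seg * p.seg) {
      // diagnostic: largest per-vertex force and heaviest filament-pair bridge
      double fmax = 0; int fmaxFil = -1;
      for (auto& f : fils)
        for (int k = 0; k < f.nv(); ++k) {
          double fm2 = f.fx[k]*f.fx[k] + f.fy[k]*f.fy[k] + f.fz[k]*f.fz[k];
          if (fm2 > fmax) { fmax = fm2; fmaxFil = f.id; }
        }
      std::map<std::pair<int,int>, int> bridges;
      for (auto& m : motors)
        if (m.nbound() == 2) {
          auto key = std::minmax(m.f[0], m.f[1]);
          bridges[{key.first, key.second}]++;
        }
      int bmax = 0;
      for (auto& kv : bridges) bmax = std::max(bmax, kv.second);
      stop("integration unstable at t=%.3f s: vertex displacement %.3g um exceeds the segment length (max |F| %.3g pN on filament %d; max bridges per pair %d); reduce dt", t, std::sqrt(maxDisp2), std::sqrt(fmax), fmaxFil, bmax);
    }

    if ((step + 1) % framesEvery == 0 || step == nsteps - 1) emitFrame((step + 1) * dt);
  }

  DataFrame fdf = DataFrame::create(
    _["frame"] = F_frame, _["time"] = F_time, _["fil_id"] = F_id, _["nuc_id"] = F_nuc,
    _["state"] = F_state, _["length"] = F_len, _["birth"] = F_birth,
    _["vertex"] = F_vi, _["x"] = F_x, _["y"] = F_y, _["z"] = F_z);
  DataFrame mdf = DataFrame::create(
    _["frame"] = M_frame, _["time"] = M_time, _["motor_id"] = M_id,
    _["fil_a"] = M_fa, _["abs_a"] = M_aa, _["end_a"] = M_ea,
    _["fil_b"] = M_fb, _["abs_b"] = M_ab, _["end_b"] = M_eb);
  List log = List::create(
    _["steps"] = (double)nsteps, _["nucleations"] = (double)n_nucleated,
    _["catastrophes"] = (double)n_cat, _["deletions"] = (double)n_deleted,
    _["first_attachments"] = (double)n_att1, _["crosslink_attachments"] = (double)n_att2,
    _["side_detachments"] = (double)n_det_side, _["end_detachments"] = (double)n_det_end);
  return List::create(_["filaments"] = fdf, _["motors"] = mdf, _["log"] = log,
                      _["n_frames"] = frameNo);
}
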