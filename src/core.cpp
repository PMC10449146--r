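// Core numerical engine: Sobol' sequence generation, voxel traversal,
// photon physics kernels, the forced-fixed-detection transport loop,
// an analog Monte Carlo oracle and the deterministic primary projector.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static const double MEC2 = 510.99895;   // electron rest energy, keV

// ---------------------------------------------------------------- vectors
struct V3 { double x, y, z; };
static inline V3 v3(double x, double y, double z) { return {x, y, z}; }
static inline double dot3(const V3 &a, const V3 &b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline V3 add3(const V3 &a, const V3 &b) { return {a.x+b.x, a.y+b.y, a.z+b.z}; }
static inline V3 sub3(const V3 &a, const V3 &b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
static inline V3 scl3(const V3 &a, double s) { return {a.x*s, a.y*s, a.z*s}; }
static inline V3 cross3(const V3 &a, const V3 &b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
static inline V3 unit3(const V3 &a) {
  double n = std::sqrt(dot3(a, a));
  return {a.x/n, a.y/n, a.z/n};
}
static inline V3 getv3(const NumericVector &v) { return {v[0], v[1], v[2]}; }

// ---------------------------------------------------------------- grid
// id type is templated: the transport engine uses uint8 voxel ids (4x less
// memory traffic), the exported traversal API works on R integer arrays.
template <typename IdT>
struct GridT {
  const IdT *ids;           // material index per voxel, x fastest (R array order)
  int nx, ny, nz;
  double hx, hy, hz;        // voxel size, mm
  double ox, oy, oz;        // world position of the low corner of voxel (0,0,0)
  double ex, ey, ez;        // high corner
  inline int id(int ix, int iy, int iz) const {
    return (int)ids[(size_t)ix + (size_t)nx*((size_t)iy + (size_t)ny*iz)];
  }
};
typedef GridT<int> Grid;
typedef GridT<uint8_t> Grid8;

struct Bricks {
  const int *ids;           // material id if the brick is uniform, else -1
  int B;                    // brick edge in voxels
  int nx, ny, nz;
  inline int id(int ix, int iy, int iz) const {
    return ids[(size_t)ix + (size_t)nx*((size_t)iy + (size_t)ny*iz)];
  }
};

// slab intersection of a ray with the phantom bounding box, clamped to t >= 0
template <typename G>
static inline bool box_hit(const G &g, const V3 &p, const V3 &d,
                           double &t0, double &t1) {
  t0 = 0.0; t1 = 1e300;
  const double lo[3] = {g.ox, g.oy, g.oz}, hi[3] = {g.ex, g.ey, g.ez};
  const double pp[3] = {p.x, p.y, p.z},   dd[3] = {d.x, d.y, d.z};
  for (int a = 0; a < 3; a++) {
    if (std::fabs(dd[a]) < 1e-12) {
      if (pp[a] < lo[a] || pp[a] > hi[a]) return false;
    } else {
      double ta = (lo[a] - pp[a]) / dd[a], tb = (hi[a] - pp[a]) / dd[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  return t1 > t0;
}

// componentwise safe inverse of a unit direction (sentinel for tiny entries)
static inline V3 inv_dir(const V3 &d) {
  return {std::fabs(d.x) < 1e-12 ? 0.0 : 1.0 / d.x,
          std::fabs(d.y) < 1e-12 ? 0.0 : 1.0 / d.y,
          std::fabs(d.z) < 1e-12 ? 0.0 : 1.0 / d.z};
}

// exact incremental traversal over fine voxels of the segment [t0,t1] of the
// ray p + t*d; emit(material, chord) per traversed voxel.  `iv` is the
// precomputed safe inverse direction (0 marks a degenerate component).
template <class G, class F>
static inline void march_fine(const G &g, const V3 &p, const V3 &d, const V3 &iv,
                              double t0, double t1, F &&emit) {
  if (t1 <= t0) return;
  const double eps = 1e-9 * (t1 - t0) + 1e-12;
  double ts = t0 + eps;
  int ix = (int)std::floor((p.x + d.x*ts - g.ox) / g.hx);
  int iy = (int)std::floor((p.y + d.y*ts - g.oy) / g.hy);
  int iz = (int)std::floor((p.z + d.z*ts - g.oz) / g.hz);
  if (ix < 0) ix = 0; if (ix >= g.nx) ix = g.nx - 1;
  if (iy < 0) iy = 0; if (iy >= g.ny) iy = g.ny - 1;
  if (iz < 0) iz = 0; if (iz >= g.nz) iz = g.nz - 1;
  const double INF = 1e300;
  double tmx, tmy, tmz, tdx, tdy, tdz;
  int sx, sy, sz;
  if (iv.x == 0.0) { tmx = INF; tdx = 0.0; sx = 0; }
  else {
    sx = d.x > 0 ? 1 : -1; tdx = g.hx * std::fabs(iv.x);
    tmx = (g.ox + (ix + (d.x > 0 ? 1 : 0)) * g.hx - p.x) * iv.x;
  }
  if (iv.y == 0.0) { tmy = INF; tdy = 0.0; sy = 0; }
  else {
    sy = d.y > 0 ? 1 : -1; tdy = g.hy * std::fabs(iv.y);
    tmy = (g.oy + (iy + (d.y > 0 ? 1 : 0)) * g.hy - p.y) * iv.y;
  }
  if (iv.z == 0.0) { tmz = INF; tdz = 0.0; sz = 0; }
  else {
    sz = d.z > 0 ? 1 : -1; tdz = g.hz * std::fabs(iv.z);
    tmz = (g.oz + (iz + (d.z > 0 ? 1 : 0)) * g.hz - p.z) * iv.z;
  }
  double tc = t0;
  while (true) {
    double tn = tmx < tmy ? (tmx < tmz ? tmx : tmz) : (tmy < tmz ? tmy : tmz);
    if (tn >= t1) {
      if (t1 > tc) emit(g.id(ix, iy, iz), t1 - tc);
      break;
    }
    if (tn > tc) { emit(g.id(ix, iy, iz), tn - tc); tc = tn; }
    // branchless axis advance
    int mx = (tmx <= tmy) & (tmx <= tmz);
    int my = (1 - mx) & (tmy <= tmz);
    int mz = 1 - mx - my;
    ix += sx & -mx; iy += sy & -my; iz += sz & -mz;
    tmx += tdx * mx; tmy += tdy * my; tmz += tdz * mz;
    if (((unsigned)ix >= (unsigned)g.nx) | ((unsigned)iy >= (unsigned)g.ny) |
        ((unsigned)iz >= (unsigned)g.nz)) break;
  }
}

template <typename G>
static inline Grid level_grid(const G &g, const Bricks &bg) {
  Grid cg;
  cg.ids = bg.ids; cg.nx = bg.nx; cg.ny = bg.ny; cg.nz = bg.nz;
  cg.hx = g.hx * bg.B; cg.hy = g.hy * bg.B; cg.hz = g.hz * bg.B;
  cg.ox = g.ox; cg.oy = g.oy; cg.oz = g.oz;
  cg.ex = g.ex; cg.ey = g.ey; cg.ez = g.ez;
  return cg;
}

// two-level traversal: bricks that hold a single material are consumed in
// one step, mixed bricks descend to exact fine-voxel stepping.
template <class G, class F>
static inline void march(const G &g, const Bricks &bg,
                         const V3 &p, const V3 &d, double t0, double t1, F &&emit) {
  if (t1 <= t0) return;
  Grid cg = level_grid(g, bg);
  V3 iv = inv_dir(d);
  double tc = t0;
  march_fine(cg, p, d, iv, t0, t1, [&](int cid, double len) {
    double ta = tc, tb = tc + len; tc = tb;
    if (cid >= 0) emit(cid, len);
    else march_fine(g, p, d, iv, ta, tb, emit);
  });
}

// optical depth of [t0,t1] given per-material attenuation coefficients
template <typename G>
static inline double seg_tau(const G &g, const Bricks &bg, const V3 &p, const V3 &d,
                             double t0, double t1, const double *mu) {
  double tau = 0.0;
  march(g, bg, p, d, t0, t1, [&](int m, double len) { tau += mu[m] * len; });
  return tau;
}

// invert the cumulative optical depth: smallest t with tau(t0 -> t) = target.
// returns -1 if the total depth of the segment is below the target.
template <typename G>
static inline double invert_tau(const G &g, const Bricks &bg, const V3 &p, const V3 &d,
                                double t0, double t1, const double *mu, double target) {
  double cum = 0.0, hit = -1.0, tc = t0;
  if (target <= 0.0) return t0;
  march(g, bg, p, d, t0, t1, [&](int m, double len) {
    if (hit >= 0.0) { tc += len; return; }
    double seg = mu[m] * len;
    if (cum + seg >= target && seg > 0.0) hit = tc + (target - cum) / mu[m];
    cum += seg; tc += len;
  });
  return hit;
}

// ---------------------------------------------------------------- physics
// unnormalised Klein-Nishina angular distribution (per steradian shape)
static inline double kn_unnorm(double E, double c) {
  double k = E / MEC2;
  double ik = 1.0 + k * (1.0 - c);
  double r = 1.0 / ik;
  return r * r * (ik + r - (1.0 - c * c));
}

// Moliere/Thomas-Fermi analytic atomic form factor, q in units of 1/a_bohr
static inline double form_factor(double qa0, double Z) {
  double z3 = std::cbrt(Z) / 0.88534;
  double b1 = 6.0 * z3, b2 = 1.2 * z3, b3 = 0.30 * z3;
  double q2 = qa0 * qa0;
  return Z * (0.10 * b1*b1 / (b1*b1 + q2) +
              0.55 * b2*b2 / (b2*b2 + q2) +
              0.35 * b3*b3 / (b3*b3 + q2));
}

// unnormalised Rayleigh (Thomson x form factor^2) angular distribution
static inline double ray_unnorm(double E, double c, double Z) {
  double s = (1.0 - c) * 0.5;
  double q = 0.536367 * E * std::sqrt(s > 0.0 ? s : 0.0);
  double F = form_factor(q, Z);
  return (1.0 + c * c) * F * F;
}

static inline double compton_E(double E, double c) {
  return E / (1.0 + (E / MEC2) * (1.0 - c));
}

// fast e^x for x <= 0 (relative error ~1e-7), used only in the splat hot loop
static inline double fexp(double x) {
  if (x < -700.0) return 0.0;
  double y = x * 1.4426950408889634;
  double n = std::floor(y);
  double t = (y - n) * 0.6931471805599453;
  double p = 1.0 + t * (1.0 + t * (0.5 + t * (1.0/6.0 + t * (1.0/24.0 +
             t * (1.0/120.0 + t * (1.0/720.0 + t / 5040.0))))));
  union { double d; uint64_t u; } s;
  s.u = (uint64_t)((int64_t)n + 1023) << 52;
  return p * s.d;
}

// [[Rcpp::export]]
NumericVector cpp_dcs(int kind, double E, double zeff, NumericVector cos_theta) {
  int n = cos_theta.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++)
    out[i] = kind == 0 ? kn_unnorm(E, cos_theta[i]) : ray_unnorm(E, cos_theta[i], zeff);
  return out;
}

// ---------------------------------------------------------------- samplers
static inline int alias_draw(const double *cut, const int *ali, int K, double u) {
  double s = u * K;
  int j = (int)s;
  if (j >= K) j = K - 1;
  return (s - j) < cut[j] ? j : ali[j];
}

static inline double rita_draw(const double *x, const double *xi, const double *a,
                               const double *b, int n, double u) {
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int mid = (lo + hi) >> 1; if (xi[mid] <= u) lo = mid; else hi = mid; }
  double nu = u - xi[lo], dd = xi[lo + 1] - xi[lo];
  if (dd <= 0.0) return x[lo];
  double t = (1.0 + a[lo] + b[lo]) * dd * nu / (dd * dd + a[lo] * dd * nu + b[lo] * nu * nu);
  if (t < 0.0) t = 0.0; if (t > 1.0) t = 1.0;
  return x[lo] + t * (x[lo + 1] - x[lo]);
}

// [[Rcpp::export]]
NumericVector cpp_rita_sample(NumericVector x, NumericVector xi, NumericVector a,
                              NumericVector b, NumericVector u) {
  int n = u.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++)
    out[i] = rita_draw(x.begin(), xi.begin(), a.begin(), b.begin(), x.size(), u[i]);
  return out;
}

static inline V3 rotate_dir(const V3 &w, double ct, double phi) {
  double st2 = 1.0 - ct * ct;
  double st = st2 > 0.0 ? std::sqrt(st2) : 0.0;
  double ax = std::fabs(w.x), ay = std::fabs(w.y), az = std::fabs(w.z);
  V3 a = (ax <= ay && ax <= az) ? v3(1, 0, 0) : ((ay <= az) ? v3(0, 1, 0) : v3(0, 0, 1));
  V3 t1 = unit3(cross3(a, w));
  V3 t2 = cross3(w, t1);
  return unit3(add3(scl3(w, ct), add3(scl3(t1, st * std::cos(phi)),
                                      scl3(t2, st * std::sin(phi)))));
}

// ---------------------------------------------------------------- scene pack
struct Scene {
  Grid8 g; Bricks bg;
  int M, ne;
  double e0, de;
  const double *mu_pe, *mu_co, *mu_ra, *mu_tot;   // [m*ne + e]
  const double *kn_norm;                          // [ne]
  const double *ray_norm;                         // [m*ne + e]
  const double *zeff;                             // [M]
  const double *sp_e, *sp_cut; const int *sp_alias; int sp_K;
  V3 src, cw, cu, cv;
  double a0, a1, b0, b1;                          // source cone rectangle
  const double *pixc; int npix, nu, nv;
  V3 nto;                                         // detector normal, phantom -> detector
  double pix_area;
  V3 det_c, det_u, det_v; double pitch;
  const double *rx, *rxi, *ra, *rb; const int *roff;
  int ner; double rle0, rld;
  int n_order, kernel_mode, kill_floor;
  int uniform_id;                                 // >= 0: whole phantom one material
  double W0;

  inline double lk(const double *tab, int m, double E) const {
    double f = (E - e0) / de;
    if (f < 0.0) f = 0.0;
    if (f > ne - 1.000001) f = ne - 1.000001;
    int i = (int)f; double w = f - i;
    const double *t = tab + (size_t)m * ne;
    return t[i] + w * (t[i + 1] - t[i]);
  }
  inline int rita_eidx(double E) const {
    double f = (std::log(E) - rle0) / rld;
    int i = (int)std::lround(f);
    if (i < 0) i = 0; if (i >= ner) i = ner - 1;
    return i;
  }
  // table index: Compton tables first (per energy), then Rayleigh per material
  inline double rita_cos(int kind, int mat, double E, double u) const {
    int t = kind == 0 ? rita_eidx(E) : ner * (1 + mat) + rita_eidx(E);
    int o = roff[t], len = roff[t + 1] - o;
    return rita_draw(rx + o, rxi + o, ra + o, rb + o, len, u);
  }
  inline int vox_id(const V3 &p) const {
    int ix = (int)std::floor((p.x - g.ox) / g.hx);
    int iy = (int)std::floor((p.y - g.oy) / g.hy);
    int iz = (int)std::floor((p.z - g.oz) / g.hz);
    if (ix < 0) ix = 0; if (ix >= g.nx) ix = g.nx - 1;
    if (iy < 0) iy = 0; if (iy >= g.ny) iy = g.ny - 1;
    if (iz < 0) iz = 0; if (iz >= g.nz) iz = g.nz - 1;
    return g.id(ix, iy, iz);
  }
};

static Scene unpack(const List &pk) {
  Scene s;
  RawVector ids = pk["ids"];
  IntegerVector bricks = pk["bricks"], dims = pk["dims"], bdims = pk["bdims"];
  s.g.ids = (const uint8_t *)ids.begin();
  s.g.nx = dims[0]; s.g.ny = dims[1]; s.g.nz = dims[2];
  NumericVector h = pk["h"], orig = pk["origin"];
  s.g.hx = h[0]; s.g.hy = h[1]; s.g.hz = h[2];
  s.g.ox = orig[0]; s.g.oy = orig[1]; s.g.oz = orig[2];
  s.g.ex = s.g.ox + s.g.nx * s.g.hx;
  s.g.ey = s.g.oy + s.g.ny * s.g.hy;
  s.g.ez = s.g.oz + s.g.nz * s.g.hz;
  s.bg.ids = bricks.begin(); s.bg.B = as<int>(pk["B"]);
  s.bg.nx = bdims[0]; s.bg.ny = bdims[1]; s.bg.nz = bdims[2];
  s.M = as<int>(pk["M"]); s.ne = as<int>(pk["ne"]);
  s.e0 = as<double>(pk["e_lo"]); s.de = as<double>(pk["e_step"]);
  NumericVector mp = pk["mu_pe"], mc = pk["mu_co"], mr = pk["mu_ra"], mt = pk["mu_tot"],
                kn = pk["kn_norm"], rn = pk["ray_norm"], zf = pk["zeff"],
                se = pk["sp_e"], sc = pk["sp_cut"];
  s.mu_pe = mp.begin(); s.mu_co = mc.begin(); s.mu_ra = mr.begin(); s.mu_tot = mt.begin();
  s.kn_norm = kn.begin(); s.ray_norm = rn.begin(); s.zeff = zf.begin();
  s.sp_e = se.begin(); s.sp_cut = sc.begin();
  IntegerVector sa = pk["sp_alias"];
  s.sp_alias = sa.begin(); s.sp_K = se.size();
  s.src = getv3(pk["src"]); s.cw = getv3(pk["cone_w"]);
  s.cu = getv3(pk["cone_u"]); s.cv = getv3(pk["cone_v"]);
  NumericVector rect = pk["cone_rect"];
  s.a0 = rect[0]; s.a1 = rect[1]; s.b0 = rect[2]; s.b1 = rect[3];
  NumericVector pixc = pk["pixc"];
  s.pixc = pixc.begin(); s.npix = pixc.size() / 3;
  s.nu = as<int>(pk["ndet_u"]); s.nv = as<int>(pk["ndet_v"]);
  s.nto = getv3(pk["det_normal"]);
  s.pix_area = as<double>(pk["pix_area"]);
  s.det_c = getv3(pk["det_center"]); s.det_u = getv3(pk["det_uaxis"]);
  s.det_v = getv3(pk["det_vaxis"]); s.pitch = as<double>(pk["det_pitch"]);
  NumericVector rx = pk["rita_x"], rxi = pk["rita_xi"], ra = pk["rita_a"], rb = pk["rita_b"];
  IntegerVector roff = pk["rita_off"];
  s.rx = rx.begin(); s.rxi = rxi.begin(); s.ra = ra.begin(); s.rb = rb.begin();
  s.roff = roff.begin();
  s.ner = as<int>(pk["rita_ne"]); s.rle0 = as<double>(pk["rita_loge0"]);
  s.rld = as<double>(pk["rita_dloge"]);
  s.n_order = as<int>(pk["n_order"]);
  s.uniform_id = as<int>(pk["uniform_id"]);
  s.kernel_mode = as<int>(pk["kernel_mode"]);
  s.kill_floor = as<int>(pk["kill_floor"]);
  s.W0 = as<double>(pk["w0"]);
  return s;
}

// forced-fixed-detection splat: per-pixel probability P_i(A_i -> D_j) for a
// photon at `pos` with incoming direction `win` and pre-collision energy E.
// acc/macc accumulate weight*P and its square; if `raw` is non-null the
// unweighted P is stored instead.
static void ffd_splat_core(const Scene &s, const V3 &pos, const V3 &win, double E,
                           double W, double *acc, double *macc, double *raw) {
  int mat = s.vox_id(pos);
  double pT0 = 0.0, pT1 = 0.0, ikn = 1.0, irn = 1.0;
  double mu_ray[64];
  for (int m = 0; m < s.M; m++) mu_ray[m] = s.lk(s.mu_tot, m, E);
  if (s.kernel_mode == 0) {
    double pe = s.lk(s.mu_pe, mat, E), co = s.lk(s.mu_co, mat, E),
           ra = s.lk(s.mu_ra, mat, E);
    double tot = pe + co + ra;
    if (tot <= 0.0) return;            // no interaction possible here
    pT0 = co / tot; pT1 = ra / tot;
    ikn = 1.0 / s.lk(s.kn_norm, 0, E);
    irn = 1.0 / s.lk(s.ray_norm, mat, E);
  }
  // per-interaction constants hoisted out of the pixel loop
  double Z = s.zeff[mat];
  double z3 = std::cbrt(Z) / 0.88534;
  double b1s = 36.0 * z3 * z3, b2s = 1.44 * z3 * z3, b3s = 0.09 * z3 * z3;
  double qf = 0.536367 * E;            // q*a0 = qf * sin(theta/2)
  double kk = E / MEC2;
  double inv_de = 1.0 / s.de;
  // brick-level grid for the traversal, built once
  Grid cg = level_grid(s.g, s.bg);
  double L[64];
  for (int j = 0; j < s.npix; j++) {
    V3 pc = v3(s.pixc[3*j], s.pixc[3*j+1], s.pixc[3*j+2]);
    V3 dvec = sub3(pc, pos);
    double r2 = dot3(dvec, dvec), rinv = 1.0 / std::sqrt(r2);
    V3 dirn = scl3(dvec, rinv);
    double cosal = dot3(dirn, s.nto);
    if (cosal <= 0.0) { if (raw) raw[j] = 0.0; continue; }
    double omega = cosal * s.pix_area * (rinv * rinv);
    // exit parameter only: the interaction point is inside the box
    double t0 = 0.0, t1 = 1e300;
    {
      double tx = dirn.x > 1e-12 ? (s.g.ex - pos.x) / dirn.x :
                  (dirn.x < -1e-12 ? (s.g.ox - pos.x) / dirn.x : 1e300);
      double ty = dirn.y > 1e-12 ? (s.g.ey - pos.y) / dirn.y :
                  (dirn.y < -1e-12 ? (s.g.oy - pos.y) / dirn.y : 1e300);
      double tz = dirn.z > 1e-12 ? (s.g.ez - pos.z) / dirn.z :
                  (dirn.z < -1e-12 ? (s.g.oz - pos.z) / dirn.z : 1e300);
      t1 = tx < ty ? (tx < tz ? tx : tz) : (ty < tz ? ty : tz);
      if (t1 < 0.0) t1 = 0.0;
    }
    for (int m = 0; m < s.M; m++) L[m] = 0.0;
    if (s.uniform_id >= 0) {
      L[s.uniform_id] = t1 - t0;
    } else {  // two-level traversal, inlined
      V3 ivd = inv_dir(dirn);
      double tc = t0;
      march_fine(cg, pos, dirn, ivd, t0, t1, [&](int cid, double len) {
        double ta = tc, tb = tc + len; tc = tb;
        if (cid >= 0) L[cid] += len;
        else march_fine(s.g, pos, dirn, ivd, ta, tb,
                        [&](int m2, double l2) { L[m2] += l2; });
      });
    }
    double contrib;
    if (s.kernel_mode == 1) {           // isotropic stub kernel, no type split
      double tau = 0.0;
      for (int m = 0; m < s.M; m++) tau += L[m] * mu_ray[m];
      contrib = fexp(-tau) / (4.0 * M_PI);
    } else {
      double ct = dot3(win, dirn);
      double ikc = 1.0 + kk * (1.0 - ct);
      double Ec = E / ikc;
      if (Ec < s.e0) Ec = s.e0;         // transport floor of the tables
      // Compton-energy table lookups on the uniform grid
      double fidx = (Ec - s.e0) * inv_de;
      if (fidx < 0.0) fidx = 0.0;
      double fmax = s.ne - 1.000001;
      if (fidx > fmax) fidx = fmax;
      int ei = (int)fidx; double ew = fidx - ei;
      double tau_c = 0.0, tau_r = 0.0;
      for (int m = 0; m < s.M; m++) {
        const double *t = s.mu_tot + (size_t)m * s.ne;
        tau_c += L[m] * (t[ei] + ew * (t[ei + 1] - t[ei]));
        tau_r += L[m] * mu_ray[m];
      }
      // Klein-Nishina shape
      double rr = 1.0 / ikc;
      double fkn = rr * rr * (ikc + rr - (1.0 - ct * ct));
      // Rayleigh: Thomson x Moliere form factor squared
      double q2 = qf * qf * 0.5 * (1.0 - ct);
      double F = Z * (0.10 * b1s / (b1s + q2) + 0.55 * b2s / (b2s + q2) +
                      0.35 * b3s / (b3s + q2));
      double fray = (1.0 + ct * ct) * F * F;
      contrib = pT0 * fkn * ikn * fexp(-tau_c) + pT1 * fray * irn * fexp(-tau_r);
    }
    double P = contrib * omega;
    if (raw) raw[j] = P;
    if (acc) {
      double v = W * P;
      acc[j] += v;
      if (macc) macc[j] += v * v;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_ffd_splat(List pack, NumericVector pos, NumericVector win, double E) {
  Scene s = unpack(pack);
  NumericVector out(s.npix);
  ffd_splat_core(s, getv3(pos), getv3(win), E, 1.0, nullptr, nullptr, out.begin());
  return out;
}

// full forced-fixed-detection history loop over the rows of U (N x 4n)
// [[Rcpp::export]]
List cpp_transport(List pack, NumericMatrix U, bool moments, bool trace) {
  Scene s = unpack(pack);
  const int N = U.nrow(), n = s.n_order;
  if (U.ncol() < 4 * n) stop("sample matrix has fewer than 4n columns");
  NumericVector acc(n * (size_t)s.npix), macc(moments ? n * (size_t)s.npix : 0);
  std::vector<double> tr_w, tr_E, tr_p, tr_s, tr_ct, tr_x, tr_y, tr_z;
  std::vector<int> tr_hist, tr_ord, tr_kind;
  double muv[64];
  const double *u = U.begin();
  for (int i = 0; i < N; i++) {
    double E = s.sp_e[alias_draw(s.sp_cut, s.sp_alias, s.sp_K, u[i])];
    double al = s.a0 + u[i + (size_t)N] * (s.a1 - s.a0);
    double be = s.b0 + u[i + 2 * (size_t)N] * (s.b1 - s.b0);
    V3 dir = unit3(add3(s.cw, add3(scl3(s.cu, al), scl3(s.cv, be))));
    double t0, t1;
    if (!box_hit(s.g, s.src, dir, t0, t1)) continue;
    V3 anchor = s.src;
    double W = s.W0;
    int lastkind = -1;
    for (int ord = 1; ord <= n; ord++) {
      for (int m = 0; m < s.M; m++) muv[m] = s.lk(s.mu_tot, m, E);
      double tau = seg_tau(s.g, s.bg, anchor, dir, t0, t1, muv);
      if (tau <= 0.0) break;
      double pesc = std::exp(-tau);
      W *= (1.0 - pesc);
      double ud = u[i + (size_t)N * (4 * (ord - 1) + 3)];
      double target = -std::log1p(-(1.0 - pesc) * ud);
      double th = invert_tau(s.g, s.bg, anchor, dir, t0, t1, muv, target);
      if (th < 0.0) th = t1;            // numerical guard: clamp to the boundary
      V3 pos = add3(anchor, scl3(dir, th));
      ffd_splat_core(s, pos, dir, E, W,
                     acc.begin() + (size_t)(ord - 1) * s.npix,
                     moments ? macc.begin() + (size_t)(ord - 1) * s.npix : nullptr,
                     nullptr);
      if (trace) {
        tr_hist.push_back(i + 1); tr_ord.push_back(ord); tr_w.push_back(W);
        tr_E.push_back(E); tr_p.push_back(pesc); tr_ct.push_back(NA_REAL);
        tr_s.push_back(NA_REAL); tr_kind.push_back(lastkind);
        tr_x.push_back(pos.x); tr_y.push_back(pos.y); tr_z.push_back(pos.z);
      }
      if (ord == n) break;
      int mat = s.vox_id(pos);
      double co = s.lk(s.mu_co, mat, E), ra = s.lk(s.mu_ra, mat, E),
             pe = s.lk(s.mu_pe, mat, E);
      double tot = pe + co + ra;
      double sc = (co + ra) / tot;
      if (!(sc > 0.0)) break;
      double ut = u[i + (size_t)N * (4 * ord)];
      int kind = (ut * (co + ra) < co) ? 0 : 1;
      W *= sc;
      double ct = s.rita_cos(kind, mat, E, u[i + (size_t)N * (4 * ord + 1)]);
      double phi = 2.0 * M_PI * u[i + (size_t)N * (4 * ord + 2)];
      dir = rotate_dir(dir, ct, phi);
      if (kind == 0) {
        E = compton_E(E, ct);
        if (E < s.e0) { if (s.kill_floor) { W = 0.0; break; } E = s.e0; }
      }
      lastkind = kind;
      if (trace) { tr_ct.back() = ct; tr_s.back() = sc; }
      anchor = pos;
      t0 = 0.0;
      double tt0, tt1;
      if (!box_hit(s.g, anchor, dir, tt0, tt1)) break;
      t1 = tt1;
    }
    if ((i & 0x3ff) == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(_["acc"] = acc, _["N"] = N);
  if (moments) out["sumsq"] = macc;
  if (trace)
    out["trace"] = DataFrame::create(
        _["history"] = tr_hist, _["order"] = tr_ord, _["weight"] = tr_w,
        _["energy"] = tr_E, _["p_escape"] = tr_p, _["survival"] = tr_s,
        _["cos_theta"] = tr_ct, _["kind"] = tr_kind,
        _["x"] = tr_x, _["y"] = tr_y, _["z"] = tr_z);
  return out;
}

// ---------------------------------------------------------------- analog MC
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  inline uint64_t nxt() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  inline double unif() { return (nxt() >> 11) * 0x1.0p-53; }
};

// unbiased analog transport scoring binary detector hits per scatter order
// [[Rcpp::export]]
List cpp_analog(List pack, int N, double seed) {
  Scene s = unpack(pack);
  const int n = s.n_order;
  IntegerVector counts(n * (size_t)s.npix);
  long absorbed = 0, primary = 0, lost = 0;
  SplitMix rng((uint64_t)seed * 2654435761ULL + 88172645463325252ULL);
  double muv[64];
  for (int i = 0; i < N; i++) {
    double E = s.sp_e[alias_draw(s.sp_cut, s.sp_alias, s.sp_K, rng.unif())];
    double al = s.a0 + rng.unif() * (s.a1 - s.a0);
    double be = s.b0 + rng.unif() * (s.b1 - s.b0);
    V3 dir = unit3(add3(s.cw, add3(scl3(s.cu, al), scl3(s.cv, be))));
    V3 pos = s.src;
    int order = 0;
    bool alive = true;
    while (alive) {
      double t0, t1;
      bool inph = box_hit(s.g, pos, dir, t0, t1);
      double th = -1.0;
      if (inph) {
        for (int m = 0; m < s.M; m++) muv[m] = s.lk(s.mu_tot, m, E);
        double target = -std::log(1.0 - rng.unif());
        th = invert_tau(s.g, s.bg, pos, dir, t0, t1, muv, target);
      }
      if (th < 0.0) {
        // escaped: score a detector-plane crossing for scattered photons
        double den = dot3(dir, s.nto);
        if (order == 0) primary++;
        else if (den > 0.0 && order <= n) {
          double tp = dot3(sub3(s.det_c, pos), s.nto) / den;
          if (tp > 0.0) {
            V3 q = sub3(add3(pos, scl3(dir, tp)), s.det_c);
            double a = dot3(q, s.det_u), b = dot3(q, s.det_v);
            int iu = (int)std::floor(a / s.pitch + 0.5 * s.nu);
            int iv = (int)std::floor(b / s.pitch + 0.5 * s.nv);
            if (iu >= 0 && iu < s.nu && iv >= 0 && iv < s.nv)
              counts[(size_t)(order - 1) * s.npix + iu + (size_t)s.nu * iv]++;
          }
        } else if (order > n) lost++;
        break;
      }
      pos = add3(pos, scl3(dir, th));
      int mat = s.vox_id(pos);
      double pe = s.lk(s.mu_pe, mat, E), co = s.lk(s.mu_co, mat, E),
             ra = s.lk(s.mu_ra, mat, E);
      double tot = pe + co + ra;
      double xi = rng.unif() * tot;
      if (xi < pe) { absorbed++; break; }
      int kind = xi < pe + co ? 0 : 1;
      // rejection sampling of the polar angle from the exact distribution
      double Z = s.zeff[mat];
      double fmax = (kind == 0 ? kn_unnorm(E, 1.0) : ray_unnorm(E, 1.0, Z)) * 1.000001;
      double ct;
      for (int it = 0;; it++) {
        ct = 2.0 * rng.unif() - 1.0;
        double f = kind == 0 ? kn_unnorm(E, ct) : ray_unnorm(E, ct, Z);
        if (rng.unif() * fmax <= f) break;
        if (it > 100000) break;
      }
      double phi = 2.0 * M_PI * rng.unif();
      dir = rotate_dir(dir, ct, phi);
      if (kind == 0) {
        E = compton_E(E, ct);
        if (E < s.e0) { if (s.kill_floor) { absorbed++; break; } E = s.e0; }
      }
      order++;
      if (order > n + 1) break;  // beyond tracked orders; cannot score anyway
    }
    if ((i & 0xfff) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["counts"] = counts, _["N"] = N, _["absorbed"] = (double)absorbed,
                      _["primary_escapes"] = (double)primary);
}

// ---------------------------------------------------------------- primary
// deterministic Beer-Lambert projection: pixels x spectrum-bin quadrature
// [[Rcpp::export]]
NumericVector cpp_primary(List pack, NumericVector pixc, NumericVector sp_w,
                          NumericMatrix mu_bins) {
  Scene s = unpack(pack);
  int npix = pixc.size() / 3, nb = sp_w.size(), M = mu_bins.ncol();
  NumericVector out(npix);
  std::vector<double> L(M);
  for (int j = 0; j < npix; j++) {
    V3 pc = v3(pixc[3*j], pixc[3*j+1], pixc[3*j+2]);
    V3 dir = unit3(sub3(pc, s.src));
    double t0, t1;
    std::fill(L.begin(), L.end(), 0.0);
    if (box_hit(s.g, s.src, dir, t0, t1))
      march(s.g, s.bg, s.src, dir, t0, t1, [&](int m, double len) { L[m] += len; });
    double val = 0.0;
    for (int b = 0; b < nb; b++) {
      double tau = 0.0;
      for (int m = 0; m < M; m++) tau += L[m] * mu_bins(b, m);
      val += sp_w[b] * std::exp(-tau);
    }
    out[j] = val;
    if ((j & 0xfff) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------- traversal API
// [[Rcpp::export]]
IntegerVector cpp_build_bricks(IntegerVector ids, IntegerVector dims, int B) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int bx = (nx + B - 1) / B, by = (ny + B - 1) / B, bz = (nz + B - 1) / B;
  IntegerVector out((size_t)bx * by * bz);
  for (int cz = 0; cz < bz; cz++)
    for (int cy = 0; cy < by; cy++)
      for (int cx = 0; cx < bx; cx++) {
        int first = ids[(size_t)cx * B + (size_t)nx * ((size_t)cy * B + (size_t)ny * (cz * B))];
        int uni = first;
        for (int z = cz * B; z < std::min(nz, (cz + 1) * B) && uni >= 0; z++)
          for (int y = cy * B; y < std::min(ny, (cy + 1) * B) && uni >= 0; y++)
            for (int x = cx * B; x < std::min(nx, (cx + 1) * B); x++)
              if (ids[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)] != first) {
                uni = -1; break;
              }
        out[(size_t)cx + (size_t)bx * ((size_t)cy + (size_t)by * cz)] = uni;
      }
  return out;
}

static Grid grid_from(IntegerVector &ids, IntegerVector &dims, NumericVector &h,
                      NumericVector &orig) {
  Grid g;
  g.ids = ids.begin(); g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.hx = h[0]; g.hy = h[1]; g.hz = h[2];
  g.ox = orig[0]; g.oy = orig[1]; g.oz = orig[2];
  g.ex = g.ox + g.nx * g.hx; g.ey = g.oy + g.ny * g.hy; g.ez = g.oz + g.nz * g.hz;
  return g;
}

// per-material chord lengths of the in-box segment [t0,t1]
// [[Rcpp::export]]
NumericVector cpp_chords(IntegerVector ids, IntegerVector bricks, int B,
                         IntegerVector dims, NumericVector h, NumericVector orig,
                         int M, NumericVector p, NumericVector d, double t0, double t1) {
  Grid g = grid_from(ids, dims, h, orig);
  Bricks bg;
  bg.ids = bricks.begin(); bg.B = B;
  bg.nx = (g.nx + B - 1) / B; bg.ny = (g.ny + B - 1) / B; bg.nz = (g.nz + B - 1) / B;
  NumericVector L(M);
  V3 pp = getv3(p), dd = getv3(d), iv = inv_dir(dd);
  double tc = t0;
  march_fine(level_grid(g, bg), pp, dd, iv, t0, t1, [&](int cid, double len) {
    double ta = tc, tb = tc + len; tc = tb;
    if (cid >= 0) L[cid] += len;
    else march_fine(g, pp, dd, iv, ta, tb, [&](int m, double l) { L[m] += l; });
  });
  return L;
}

// invert cumulative optical depth along a segment; -1 when unreachable
// [[Rcpp::export]]
double cpp_invert_tau(IntegerVector ids, IntegerVector bricks, int B,
                      IntegerVector dims, NumericVector h, NumericVector orig,
                      NumericVector mu, NumericVector p, NumericVector d,
                      double t0, double t1, double target) {
  Grid g = grid_from(ids, dims, h, orig);
  Bricks bg;
  bg.ids = bricks.begin(); bg.B = B;
  bg.nx = (g.nx + B - 1) / B; bg.ny = (g.ny + B - 1) / B; bg.nz = (g.nz + B - 1) / B;
  return invert_tau(g, bg, getv3(p), getv3(d), t0, t1, mu.begin(), target);
}

// [[Rcpp::export]]
NumericVector cpp_box_intersect(NumericVector lo, NumericVector hi,
                                NumericVector p, NumericVector d) {
  Grid g;
  g.ox = lo[0]; g.oy = lo[1]; g.oz = lo[2];
  g.ex = hi[0]; g.ey = hi[1]; g.ez = hi[2];
  double t0, t1;
  bool hit = box_hit(g, getv3(p), getv3(d), t0, t1);
  return NumericVector::create(hit ? 1.0 : 0.0, t0, t1);
}

// ---------------------------------------------------------------- Sobol'
// Gray-code Sobol' generator with Joe-Kuo direction numbers, optional
// Matousek linear matrix scramble and digital shift.
// [[Rcpp::export]]
NumericMatrix cpp_sobol(int n, int skip, int dim, IntegerVector poly,
                        IntegerMatrix minit, double scramble_seed) {
  const int BITS = 32;
  if (dim > poly.size()) stop("Sobol' dimension exceeds the direction-number table");
  std::vector<uint32_t> V((size_t)dim * BITS);
  for (int j = 0; j < dim; j++) {
    uint32_t *v = &V[(size_t)j * BITS];
    if (j == 0) {
      for (int k = 0; k < BITS; k++) v[k] = 1u << (31 - k);
    } else {
      uint32_t p = (uint32_t)poly[j];
      int sdeg = 0;
      for (uint32_t q = p; q > 1; q >>= 1) sdeg++;
      uint32_t a = (p ^ (1u << sdeg)) >> 1;   // interior coefficient bits
      for (int k = 0; k < BITS; k++) {
        if (k < sdeg) {
          v[k] = ((uint32_t)minit(j, k)) << (31 - k);
        } else {
          uint32_t val = v[k - sdeg] ^ (v[k - sdeg] >> sdeg);
          for (int l = 1; l < sdeg; l++)
            if ((a >> (sdeg - 1 - l)) & 1u) val ^= v[k - l];
          v[k] = val;
        }
      }
    }
  }
  std::vector<uint32_t> shift(dim, 0u);
  if (scramble_seed != 0) {
    SplitMix rng((uint64_t)scramble_seed * 6364136223846793005ULL + 1442695040888963407ULL);
    for (int j = 0; j < dim; j++) {
      // lower-triangular random matrix over GF(2), unit diagonal (digit 0 = MSB)
      uint32_t rows[BITS];
      for (int k = 0; k < BITS; k++) {
        uint32_t msk = k == 0 ? 0u : ((uint32_t)(rng.nxt() >> 32) & (0xffffffffu << (32 - k)));
        rows[k] = msk | (1u << (31 - k));
      }
      uint32_t *v = &V[(size_t)j * BITS];
      for (int k = 0; k < BITS; k++) {
        uint32_t x = v[k], y = 0u;
        for (int r = 0; r < BITS; r++) {
          uint32_t t = rows[r] & x;
          t ^= t >> 16; t ^= t >> 8; t ^= t >> 4; t ^= t >> 2; t ^= t >> 1;
          y |= (t & 1u) << (31 - r);
        }
        v[k] = y;
      }
      shift[j] = (uint32_t)(rng.nxt() >> 32);
    }
  }
  NumericMatrix out(n, dim);
  std::vector<uint32_t> X(dim, 0u);
  // iterate the gray-code recursion up to skip + n points
  for (long i = 0; i < (long)skip + n; i++) {
    if (i > 0) {
      unsigned long im1 = (unsigned long)(i - 1);
      int c = 0;
      while (im1 & 1ul) { im1 >>= 1; c++; }
      for (int j = 0; j < dim; j++) X[j] ^= V[(size_t)j * BITS + c];
    }
    if (i >= skip)
      for (int j = 0; j < dim; j++)
        out(i - skip, j) = (double)(X[j] ^ shift[j]) * 0x1.0p-32;
  }
  return out;
}
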