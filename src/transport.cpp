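// Monte Carlo transport core: analog photon transport with primary/scatter
// tagging, Woodcock tracking through the focused-hole grid collimator, and
// straight-ahead CSDA electron transport in water.  All hot loops live here;
// the R layer owns geometry construction, batching and analysis.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double MEC2 = 0.51099895;
static const double SQRT3 = 1.7320508075688772;

// ---- counter-seeded PCG32: per-batch streams are independent --------------
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq) {
    state = 0u; inc = (seq << 1u) | 1u;
    next(); state += seed + 0x9E3779B97F4A7C15ULL; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double u() { // uniform in (0,1)
    return (next() + 1.0) * 2.3283064359965952e-10;
  }
};

// ---- uniform-log-grid material table --------------------------------------
struct MatTable {
  double logE0, dlogE; int n;
  std::vector<double> tot, pe, inc, coh, pair, mutr;
  double zeff;
  void load(const List& L) {
    logE0 = as<double>(L["logE0"]); dlogE = as<double>(L["dlogE"]);
    tot  = as<std::vector<double>>(L["tot"]);
    pe   = as<std::vector<double>>(L["pe"]);
    inc  = as<std::vector<double>>(L["inc"]);
    coh  = as<std::vector<double>>(L["coh"]);
    pair = as<std::vector<double>>(L["pair"]);
    if (L.containsElementNamed("mutr"))
      mutr = as<std::vector<double>>(L["mutr"]);
    zeff = L.containsElementNamed("zeff") ? as<double>(L["zeff"]) : 8.0;
    n = (int)tot.size();
  }
  inline double look(const std::vector<double>& v, double E) const {
    double x = (std::log(E) - logE0) / dlogE;
    if (x <= 0) return v[0];
    if (x >= n - 1) return v[n - 1];
    int i = (int)x; double f = x - i;
    return v[i] * (1 - f) + v[i + 1] * f;
  }
  inline double mu_tot(double E)  const { return look(tot, E); }
  inline double mu_tr(double E)   const { return look(mutr, E); }
};

// electron stopping power table, MeV/cm (water)
struct ETable {
  double logE0, dlogE; int n; std::vector<double> S;
  void load(const List& L) {
    logE0 = as<double>(L["logE0"]); dlogE = as<double>(L["dlogE"]);
    S = as<std::vector<double>>(L["S"]); n = (int)S.size();
  }
  inline double s(double E) const {
    double x = (std::log(E) - logE0) / dlogE;
    if (x <= 0) return S[0];
    if (x >= n - 1) return S[n - 1];
    int i = (int)x; double f = x - i;
    return S[i] * (1 - f) + S[i + 1] * f;
  }
};

struct Photon {
  double x, y, z, ux, uy, uz, E, w;
  int tag; // 0 primary, 1 scattered
  uint64_t id; // stable history id: keys the per-history RNG stream
};

// rotate direction u by polar angle (cth,sth) about itself with azimuth phi
static inline void rotate_dir(double& ux, double& uy, double& uz,
                              double cth, double phi) {
  double sth = std::sqrt(std::max(0.0, 1.0 - cth * cth));
  double cph = std::cos(phi), sph = std::sin(phi);
  double uz2 = uz * uz;
  if (uz2 > 1.0 - 1e-10) {
    double sgn = uz > 0 ? 1.0 : -1.0;
    ux = sth * cph; uy = sgn * sth * sph; uz = sgn * cth;
  } else {
    double st = std::sqrt(1.0 - uz2);
    double nx = ux * cth + sth * (ux * uz * cph - uy * sph) / st;
    double ny = uy * cth + sth * (uy * uz * cph + ux * sph) / st;
    double nz = uz * cth - sth * st * cph;
    double nn = 1.0 / std::sqrt(nx * nx + ny * ny + nz * nz);
    ux = nx * nn; uy = ny * nn; uz = nz * nn;
  }
}

// Klein-Nishina sampling (composition-rejection), returns eps = E'/E and cos
static inline void kn_sample(double E, Pcg32& rng, double& eps, double& cth) {
  double k = E / MEC2;
  double eps0 = 1.0 / (1.0 + 2.0 * k);
  double a1 = -std::log(eps0), a2 = 0.5 * (1.0 - eps0 * eps0);
  double t, sin2;
  for (;;) {
    if (rng.u() * (a1 + a2) < a1) eps = std::exp(-a1 * rng.u());
    else eps = std::sqrt(eps0 * eps0 + (1.0 - eps0 * eps0) * rng.u());
    t = (1.0 - eps) / (k * eps);
    sin2 = t * (2.0 - t);
    double g = 1.0 - eps * sin2 / (1.0 + eps * eps);
    if (rng.u() < g) break;
  }
  cth = 1.0 - t;
}

// forward-restricted Thomson-like Rayleigh angle
static inline double rayleigh_costheta(double E, double zeff, Pcg32& rng) {
  double thmax = 0.10 * std::cbrt(zeff) / std::max(E, 0.01);
  if (thmax > M_PI) thmax = M_PI;
  double cmin = std::cos(thmax);
  for (;;) {
    double c = cmin + (1.0 - cmin) * rng.u();
    if (rng.u() * 2.0 < 1.0 + c * c) return c;
  }
}

// ---- hexagonal focused-hole membership ------------------------------------
// point (x,y,z) is inside a hole cone iff its projection through the focus
// (source at origin) onto the isocenter plane falls inside one of the 127
// disks of the hexagonal lattice.
struct HexGrid {
  double pitch, hole_r, sad; int max_ring;
  inline bool in_hole(double x, double y, double z) const {
    double s = sad / z;
    double sx = x * s, sy = y * s;
    double rr = sy * 2.0 / (SQRT3 * pitch);
    double qq = sx / pitch - 0.5 * rr;
    int q0 = (int)std::floor(qq), r0 = (int)std::floor(rr);
    for (int dq = 0; dq <= 1; ++dq) for (int dr = 0; dr <= 1; ++dr) {
      int qi = q0 + dq, ri = r0 + dr;
      int ring = (std::abs(qi) + std::abs(ri) + std::abs(qi + ri)) / 2;
      if (ring > max_ring) continue;
      double cx = pitch * (qi + 0.5 * ri);
      double cy = pitch * (SQRT3 * 0.5) * ri;
      double ddx = sx - cx, ddy = sy - cy;
      if (ddx * ddx + ddy * ddy < hole_r * hole_r) return true;
    }
    return false;
  }
};

// [[Rcpp::export]]
NumericMatrix cpp_kn_sample(double E, int n, int seed) {
  Pcg32 rng((uint64_t)seed, 7u);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double eps, cth; kn_sample(E, rng, eps, cth);
    out(i, 0) = E * eps;
    out(i, 1) = std::acos(std::min(1.0, std::max(-1.0, cth)));
  }
  colnames(out) = CharacterVector::create("energy", "theta");
  return out;
}

// ---------------------------------------------------------------------------
// Grid + tray pass.  Woodcock (delta) tracking between tray_z0 and block_z1;
// analog interactions; any interaction flips the tag to scattered.  Photons
// exiting downstream are returned; upstream-going or absorbed photons die.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_grid_pass(NumericMatrix st, List geom, List mats, int seed,
                   bool scatter) {
  double tray_z0 = as<double>(geom["tray_z0"]);
  double tray_z1 = as<double>(geom["tray_z1"]);
  double block_z0 = as<double>(geom["block_z0"]);
  double block_z1 = as<double>(geom["block_z1"]);
  bool has_block = as<bool>(geom["has_block"]);
  HexGrid hex;
  hex.pitch = as<double>(geom["pitch"]); hex.hole_r = as<double>(geom["hole_r"]);
  hex.sad = as<double>(geom["sad"]); hex.max_ring = as<int>(geom["max_ring"]);

  MatTable blk, tray;
  if (has_block) blk.load(mats["block"]);
  tray.load(mats["tray"]);
  double pcut = as<double>(geom["pcut"]);
  double r_blk2 = as<double>(geom["r_block"]); r_blk2 *= r_blk2;

  std::vector<Photon> out;
  std::vector<Photon> stack;
  out.reserve(st.nrow());
  double e_absorbed = 0, e_upstream = 0, n_killed = 0;
  bool has_id = st.ncol() > 9;

  for (int i = 0; i < st.nrow(); ++i) {
    uint64_t hid = has_id ? (uint64_t)st(i, 9) : (uint64_t)(i + 1);
    Pcg32 rng((uint64_t)seed, 2u * hid + 11u);
    Photon p { st(i,0), st(i,1), st(i,2), st(i,3), st(i,4), st(i,5),
               st(i,6), st(i,7), (int)st(i,8), hid };
    stack.push_back(p);
    while (!stack.empty()) {
      Photon ph = stack.back(); stack.pop_back();
      bool alive = true;
      while (alive) {
        if (ph.uz <= 1e-8) { e_upstream += ph.E * ph.w; n_killed++; break; }
        if (ph.z < tray_z0) { // vacuum gap above tray
          double t = (tray_z0 - ph.z) / ph.uz + 1e-9;
          ph.x += t * ph.ux; ph.y += t * ph.uy; ph.z += t * ph.uz;
        }
        if (ph.z >= block_z1 - 1e-12) { out.push_back(ph); break; }
        double mu_t = tray.mu_tot(ph.E);
        double mu_b = has_block ? blk.mu_tot(ph.E) : 0.0;
        double mu_maj = std::max(mu_t, mu_b);
        double s = -std::log(1.0 - rng.u()) / mu_maj;
        double t_bound = (block_z1 - ph.z) / ph.uz;
        if (s >= t_bound) {
          double t = t_bound + 1e-9;
          ph.x += t * ph.ux; ph.y += t * ph.uy; ph.z += t * ph.uz;
          out.push_back(ph); break;
        }
        ph.x += s * ph.ux; ph.y += s * ph.uy; ph.z += s * ph.uz;
        // local medium at collision point (block and tray are finite disks)
        const MatTable* loc = nullptr;
        if (ph.x * ph.x + ph.y * ph.y < r_blk2) {
          if (ph.z >= tray_z0 && ph.z < tray_z1) loc = &tray;
          else if (has_block && ph.z >= block_z0 && ph.z < block_z1 &&
                   !hex.in_hole(ph.x, ph.y, ph.z)) loc = &blk;
        }
        double mu_loc = loc ? loc->mu_tot(ph.E) : 0.0;
        if (rng.u() * mu_maj >= mu_loc) continue; // virtual collision
        if (!scatter) { // attenuate-only: kill on any real collision
          e_absorbed += ph.E * ph.w; break;
        }
        // real collision: sample the process
        double xi = rng.u() * mu_loc;
        double m_pe = loc->look(loc->pe, ph.E);
        double m_in = loc->look(loc->inc, ph.E);
        double m_co = loc->look(loc->coh, ph.E);
        if (xi < m_pe) { e_absorbed += ph.E * ph.w; break; }
        else if (xi < m_pe + m_in) {
          double eps, cth; kn_sample(ph.E, rng, eps, cth);
          e_absorbed += ph.E * (1.0 - eps) * ph.w; // electron stays in block
          ph.E *= eps; ph.tag = 1;
          rotate_dir(ph.ux, ph.uy, ph.uz, cth, 2.0 * M_PI * rng.u());
          if (ph.E < pcut) { e_absorbed += ph.E * ph.w; break; }
        } else if (xi < m_pe + m_in + m_co) {
          double cth = rayleigh_costheta(ph.E, loc->zeff, rng);
          ph.tag = 1;
          rotate_dir(ph.ux, ph.uy, ph.uz, cth, 2.0 * M_PI * rng.u());
        } else { // pair: e+/e- absorbed locally, annihilation photons emitted
          e_absorbed += (ph.E - 2.0 * MEC2) * ph.w;
          double c = 2.0 * rng.u() - 1.0, phi = 2.0 * M_PI * rng.u();
          double sth = std::sqrt(1.0 - c * c);
          Photon a { ph.x, ph.y, ph.z, sth * std::cos(phi),
                     sth * std::sin(phi), c, MEC2, ph.w, 1, ph.id };
          Photon b = a; b.ux = -a.ux; b.uy = -a.uy; b.uz = -a.uz;
          stack.push_back(a); stack.push_back(b);
          break;
        }
      }
    }
  }
  NumericMatrix om(out.size(), 10);
  for (size_t i = 0; i < out.size(); ++i) {
    om(i,0)=out[i].x;  om(i,1)=out[i].y;  om(i,2)=out[i].z;
    om(i,3)=out[i].ux; om(i,4)=out[i].uy; om(i,5)=out[i].uz;
    om(i,6)=out[i].E;  om(i,7)=out[i].w;  om(i,8)=out[i].tag;
    om(i,9)=(double)out[i].id;
  }
  return List::create(_["batch"] = om, _["e_absorbed"] = e_absorbed,
                      _["e_upstream"] = e_upstream, _["n_killed"] = n_killed);
}

// ---------------------------------------------------------------------------
// Water phantom transport with full tallies.
// ---------------------------------------------------------------------------
struct Tallies {
  // cylindrical CAX mesh: 2 mm depth bins over 0-30 cm, r < 0.4
  int n_cyl; double cyl_dz, cyl_r2, cyl_vol, force_r2;
  std::vector<double> cyl_kerma, cyl_edep_pre, cyl_edep_post; // [bin*2+tag]
  std::vector<double> cyl_fdose_pre, cyl_fdose_post; // forced-collision dose
  // rectangular profile mesh at fixed depth
  double rect_zlo, rect_zhi, rect_xlo, rect_dx, rect_yhw, rect_vol;
  int n_rect;
  std::vector<double> rect_kerma, rect_edep;
  // fluence spectra in small cylinders
  std::vector<double> spec_depth; double spec_r2, spec_hh, spec_vol;
  int np_bins; double p_e0, p_de;
  int ne_bins; double e_e0, e_de;
  std::vector<double> pspec, espec; // [depth][bin][tag]
  double out_of_mesh;
};

struct Phantom {
  double ssd, half, depth;
};

static inline void seg_zbins(double z0, double z1, double zoff, double dz,
                             int nb, double len_per_dz,
                             std::vector<double>& acc, int tag, double val) {
  // distribute val*length over depth bins between absolute z0<z1
  double d0 = (z0 - zoff) / dz, d1 = (z1 - zoff) / dz;
  if (d1 <= 0 || d0 >= nb) return;
  if (d0 < 0) d0 = 0; if (d1 > nb) d1 = nb;
  int i0 = (int)d0, i1 = (int)d1; if (i1 >= nb) i1 = nb - 1;
  for (int i = i0; i <= i1; ++i) {
    double lo = std::max(d0, (double)i), hi = std::min(d1, (double)(i + 1));
    if (hi > lo) acc[i * 2 + tag] += val * (hi - lo) * dz * len_per_dz;
  }
}

// chord of segment [p, p+t*d] with cylinder x^2+y^2<r2, z in [zlo,zhi]
static inline bool cyl_chord(double x, double y, double z, double ux,
                             double uy, double uz, double tmax, double r2,
                             double zlo, double zhi, double& t0, double& t1) {
  t0 = 0; t1 = tmax;
  if (std::abs(uz) > 1e-12) {
    double ta = (zlo - z) / uz, tb = (zhi - z) / uz;
    if (ta > tb) std::swap(ta, tb);
    if (ta > t0) t0 = ta; if (tb < t1) t1 = tb;
  } else if (z < zlo || z > zhi) return false;
  if (t0 >= t1) return false;
  double a = ux * ux + uy * uy;
  double b = x * ux + y * uy;
  double c = x * x + y * y - r2;
  if (a < 1e-14) { if (c > 0) return false; }
  else {
    double disc = b * b - a * c;
    if (disc <= 0) return false;
    double sq = std::sqrt(disc);
    double ra = (-b - sq) / a, rb = (-b + sq) / a;
    if (ra > t0) t0 = ra; if (rb < t1) t1 = rb;
    if (t0 >= t1) return false;
  }
  return true;
}

struct Ctx {
  MatTable water; ETable esp; Tallies tal; Phantom ph;
  double pcut, ecut, estep, rr_thresh, rr_factor;
  double e_dep, e_escape, rr_loss, rr_gain;
};

static void transport_electron(Ctx& C, Pcg32& rng, double x, double y,
                               double z, double ux, double uy, double uz,
                               double E, double w, int tag_pre, int tag_post,
                               double& xe, double& ye, double& ze, int mode);
static inline void deposit_point(Ctx& C, double x, double y, double z,
                                 double edep, int tag_pre, int tag_post,
                                 int mode);

// electron direction for a Compton event with photon scatter angle cth
static inline void compton_electron_dir(double ux, double uy, double uz,
                                        double k, double cth, double azim,
                                        double& ex, double& ey, double& ez) {
  double half_th = 0.5 * std::acos(std::min(1.0, std::max(-1.0, cth)));
  double tphi = (std::tan(half_th) > 1e-12)
    ? 1.0 / ((1.0 + k) * std::tan(half_th)) : 1e12;
  double phi_e = std::atan(tphi);
  ex = ux; ey = uy; ez = uz;
  rotate_dir(ex, ey, ez, std::cos(phi_e), azim + M_PI);
}

// spawn the CSDA electron(s) of a sampled interaction with statistical
// weight wf; used by the forced-collision track-length dose estimator
static void forced_electron(Ctx& C, Pcg32& rng, double fx, double fy,
                            double fz, double ux, double uy, double uz,
                            double E, double wf, int tag) {
  double m_pe = C.water.look(C.water.pe, E);
  double m_in = C.water.look(C.water.inc, E);
  double m_pr = C.water.look(C.water.pair, E);
  double xi = rng.u() * (m_pe + m_in + m_pr);
  double xe, ye, ze;
  auto run_e = [&](double Ee, double ex, double ey, double ez, int post) {
    if (Ee >= C.ecut)
      transport_electron(C, rng, fx, fy, fz, ex, ey, ez, Ee, wf, tag, post,
                         xe, ye, ze, 1);
    else if (Ee > 0) deposit_point(C, fx, fy, fz, Ee * wf, tag, post, 1);
  };
  if (xi < m_pe) run_e(E, ux, uy, uz, tag);
  else if (xi < m_pe + m_in) {
    double eps, cth; kn_sample(E, rng, eps, cth);
    double ex, ey, ez;
    compton_electron_dir(ux, uy, uz, E / MEC2, cth, 2.0 * M_PI * rng.u(),
                         ex, ey, ez);
    run_e(E * (1.0 - eps), ex, ey, ez, 1);
  } else {
    double avail = E - 2.0 * MEC2, f = rng.u();
    run_e(f * avail, ux, uy, uz, tag);
    run_e((1.0 - f) * avail, ux, uy, uz, tag);
  }
}

static void score_photon_segment(Ctx& C, Pcg32& rng, double x, double y,
                                 double z, double ux, double uy, double uz,
                                 double seg, double E, double w, int tag) {
  Tallies& T = C.tal;
  double kfac = C.water.mu_tr(E) * E * w; // MeV per cm path, per cm^3 after /V
  // cylindrical CAX mesh (kerma, track length)
  double t0, t1;
  if (cyl_chord(x, y, z, ux, uy, uz, seg, T.cyl_r2,
                C.ph.ssd, C.ph.ssd + T.n_cyl * T.cyl_dz, t0, t1)) {
    double za = z + t0 * uz, zb = z + t1 * uz;
    if (za > zb) std::swap(za, zb);
    double len_per_dz = (t1 - t0) / std::max(1e-12, zb - za);
    seg_zbins(za, zb, C.ph.ssd, T.cyl_dz, T.n_cyl, len_per_dz,
              T.cyl_kerma, tag, kfac / T.cyl_vol);
  }
  // forced-collision dose estimator: sample one interaction per chord
  // through a wider cylinder (weight w * chord * mu) so that electron
  // in-scatter into the scoring column is represented; deposits are only
  // scored inside the CAX mesh
  if (cyl_chord(x, y, z, ux, uy, uz, seg, T.force_r2,
                C.ph.ssd, C.ph.ssd + T.n_cyl * T.cyl_dz, t0, t1)) {
    double len = t1 - t0;
    double m_nc = C.water.look(C.water.pe, E) +
      C.water.look(C.water.inc, E) + C.water.look(C.water.pair, E);
    // stratified sampling: one interaction per <= 1 cm of chord
    int nsub = 1 + (int)(len);
    double dl = len / nsub, wf = w * dl * m_nc;
    for (int ksub = 0; ksub < nsub; ++ksub) {
      double tf = t0 + (ksub + rng.u()) * dl;
      forced_electron(C, rng, x + tf * ux, y + tf * uy, z + tf * uz,
                      ux, uy, uz, E, wf, tag);
    }
  }
  // rectangular profile mesh (kerma)
  if (std::abs(uz) > 1e-12) {
    double ta = (T.rect_zlo - z) / uz, tb = (T.rect_zhi - z) / uz;
    if (ta > tb) std::swap(ta, tb);
    if (tb > 0 && ta < seg) {
      ta = std::max(ta, 0.0); tb = std::min(tb, seg);
      // walk x bins over [ta,tb]
      int nsub = 1 + (int)(std::abs((tb - ta) * ux) / T.rect_dx * 2.0);
      double dt = (tb - ta) / nsub;
      for (int ksub = 0; ksub < nsub; ++ksub) {
        double tm = ta + (ksub + 0.5) * dt;
        double xm = x + tm * ux, ym = y + tm * uy;
        if (std::abs(ym) > T.rect_yhw) continue;
        int ib = (int)((xm - T.rect_xlo) / T.rect_dx);
        if (ib < 0 || ib >= T.n_rect) continue;
        T.rect_kerma[ib * 2 + tag] += kfac * dt / T.rect_vol;
      }
    }
  }
  // spectrum cylinders
  for (size_t kdi = 0; kdi < T.spec_depth.size(); ++kdi) {
    double zc = C.ph.ssd + T.spec_depth[kdi];
    double s0, s1;
    if (!cyl_chord(x, y, z, ux, uy, uz, seg, T.spec_r2,
                   zc - T.spec_hh, zc + T.spec_hh, s0, s1)) continue;
    int ib = (int)((E - T.p_e0) / T.p_de);
    if (ib < 0 || ib >= T.np_bins) continue; // under/overflow excluded
    T.pspec[(kdi * T.np_bins + ib) * 2 + tag] += w * (s1 - s0) / T.spec_vol;
  }
}

// mode 0: analog scoring (edep meshes, electron spectra, energy ledger);
// mode 1: forced-collision dose estimator (CAX fdose mesh only)
static inline void deposit_point(Ctx& C, double x, double y, double z,
                                 double edep, int tag_pre, int tag_post,
                                 int mode) {
  Tallies& T = C.tal;
  double d = z - C.ph.ssd;
  bool in_cyl = x * x + y * y < T.cyl_r2 && d >= 0 && d < T.n_cyl * T.cyl_dz;
  if (mode == 1) {
    if (in_cyl) {
      int ib = (int)(d / T.cyl_dz);
      T.cyl_fdose_pre[ib * 2 + tag_pre] += edep / T.cyl_vol;
      T.cyl_fdose_post[ib * 2 + tag_post] += edep / T.cyl_vol;
    }
    return;
  }
  C.e_dep += edep;
  bool scored = false;
  if (in_cyl) {
    int ib = (int)(d / T.cyl_dz);
    T.cyl_edep_pre[ib * 2 + tag_pre] += edep / T.cyl_vol;
    T.cyl_edep_post[ib * 2 + tag_post] += edep / T.cyl_vol;
    scored = true;
  }
  if (z >= T.rect_zlo && z < T.rect_zhi && std::abs(y) <= T.rect_yhw) {
    int ib = (int)((x - T.rect_xlo) / T.rect_dx);
    if (ib >= 0 && ib < T.n_rect) {
      T.rect_edep[ib * 2 + tag_pre] += edep / T.rect_vol;
      scored = true;
    }
  }
  if (!scored) T.out_of_mesh += edep;
}

// CSDA electron with Gaussian (Highland) multiple-scattering deflection
// per sub-step; returns end position (for positrons)
static const double WATER_X0 = 36.08; // radiation length of water, cm
static void transport_electron(Ctx& C, Pcg32& rng, double x, double y,
                               double z, double ux, double uy, double uz,
                               double E, double w, int tag_pre, int tag_post,
                               double& xe, double& ye, double& ze, int mode) {
  Tallies& T = C.tal;
  double half = C.ph.half;
  double sx0 = std::sqrt(C.estep / WATER_X0) *
    (1.0 + 0.038 * std::log(C.estep / WATER_X0));
  for (;;) {
    if (std::abs(x) > half || std::abs(y) > half || z < C.ph.ssd ||
        z > C.ph.ssd + C.ph.depth) { if (mode == 0) C.e_escape += E * w; break; }
    double S = C.esp.s(std::max(E, C.ecut));
    double de = S * C.estep;
    if (E - de <= C.ecut) { // terminal: deposit everything here
      deposit_point(C, x, y, z, E * w, tag_pre, tag_post, mode);
      break;
    }
    // random-hinge multiple scattering: advance to a uniform point inside
    // the step, apply the full Highland deflection there, then complete
    // the step along the new direction
    double hinge = C.estep * rng.u();
    double xm = x + 0.5 * hinge * ux, ym = y + 0.5 * hinge * uy,
           zm = z + 0.5 * hinge * uz;  // rough midpoint for scoring
    deposit_point(C, xm, ym, zm, de * w, tag_pre, tag_post, mode);
    // electron track-length fluence in the spectrum cylinders
    double Emid = E - 0.5 * de;
    if (mode == 0 &&
        Emid >= T.e_e0 && Emid < T.e_e0 + T.ne_bins * T.e_de) {
      for (size_t kdi = 0; kdi < T.spec_depth.size(); ++kdi) {
        double zc = C.ph.ssd + T.spec_depth[kdi];
        if (std::abs(zm - zc) > T.spec_hh) continue;
        if (xm * xm + ym * ym >= T.spec_r2) continue;
        int ib = (int)((Emid - T.e_e0) / T.e_de);
        T.espec[(kdi * T.ne_bins + ib) * 2 + tag_pre] +=
          w * C.estep / T.spec_vol;
      }
    }
    x += hinge * ux; y += hinge * uy; z += hinge * uz;
    double pc2 = E * (E + 2.0 * MEC2);
    double beta_pc = pc2 / (E + MEC2);
    double th0 = 13.6 / beta_pc * sx0;
    if (th0 > 1.2) th0 = 1.2;
    double th = th0 * std::sqrt(-2.0 * std::log(1.0 - rng.u()));
    rotate_dir(ux, uy, uz, std::cos(th), 2.0 * M_PI * rng.u());
    double rest = C.estep - hinge;
    x += rest * ux; y += rest * uy; z += rest * uz;
    E -= de;
  }
  xe = x; ye = y; ze = z;
}

// [[Rcpp::export]]
List cpp_phantom_run(NumericMatrix st, List geom, List mats, List tcfg,
                     int seed) {
  Ctx C;
  C.water.load(mats["water"]);
  C.esp.load(mats["electron"]);
  C.ph.ssd = as<double>(geom["ssd"]);
  C.ph.half = as<double>(geom["half"]);
  C.ph.depth = as<double>(geom["depth"]);
  C.pcut = as<double>(geom["pcut"]); C.ecut = as<double>(geom["ecut"]);
  C.estep = as<double>(geom["estep"]);
  C.rr_thresh = as<double>(geom["rr_thresh"]);
  C.rr_factor = as<double>(geom["rr_factor"]);
  C.e_dep = C.e_escape = C.rr_loss = C.rr_gain = 0;

  Tallies& T = C.tal;
  T.n_cyl = as<int>(tcfg["n_cyl"]); T.cyl_dz = as<double>(tcfg["cyl_dz"]);
  double cyl_r = as<double>(tcfg["cyl_r"]);
  T.cyl_r2 = cyl_r * cyl_r;
  double force_r = tcfg.containsElementNamed("force_r")
    ? as<double>(tcfg["force_r"]) : 2.4;
  T.force_r2 = force_r * force_r;
  T.cyl_vol = M_PI * T.cyl_r2 * T.cyl_dz;
  T.cyl_kerma.assign(T.n_cyl * 2, 0.0);
  T.cyl_edep_pre.assign(T.n_cyl * 2, 0.0);
  T.cyl_edep_post.assign(T.n_cyl * 2, 0.0);
  T.cyl_fdose_pre.assign(T.n_cyl * 2, 0.0);
  T.cyl_fdose_post.assign(T.n_cyl * 2, 0.0);
  double rect_depth = as<double>(tcfg["rect_depth"]);
  double rect_dz = as<double>(tcfg["rect_dz"]);
  T.rect_zlo = C.ph.ssd + rect_depth - 0.5 * rect_dz;
  T.rect_zhi = C.ph.ssd + rect_depth + 0.5 * rect_dz;
  T.rect_dx = as<double>(tcfg["rect_dx"]);
  double rect_half = as<double>(tcfg["rect_half"]);
  T.rect_xlo = -rect_half;
  T.n_rect = (int)std::lround(2.0 * rect_half / T.rect_dx);
  T.rect_yhw = as<double>(tcfg["rect_yhw"]);
  T.rect_vol = T.rect_dx * 2.0 * T.rect_yhw * rect_dz;
  T.rect_kerma.assign(T.n_rect * 2, 0.0);
  T.rect_edep.assign(T.n_rect * 2, 0.0);
  T.spec_depth = as<std::vector<double>>(tcfg["spec_depths"]);
  double spec_r = as<double>(tcfg["spec_r"]);
  T.spec_r2 = spec_r * spec_r;
  T.spec_hh = 0.5 * as<double>(tcfg["spec_h"]);
  T.spec_vol = M_PI * T.spec_r2 * 2.0 * T.spec_hh;
  T.np_bins = as<int>(tcfg["np_bins"]);
  T.p_e0 = as<double>(tcfg["p_e0"]); T.p_de = as<double>(tcfg["p_de"]);
  T.ne_bins = as<int>(tcfg["ne_bins"]);
  T.e_e0 = as<double>(tcfg["e_e0"]); T.e_de = as<double>(tcfg["e_de"]);
  T.pspec.assign(T.spec_depth.size() * T.np_bins * 2, 0.0);
  T.espec.assign(T.spec_depth.size() * T.ne_bins * 2, 0.0);
  T.out_of_mesh = 0;

  double e_in = 0, n_missed = 0;
  std::vector<Photon> stack;
  bool has_id = st.ncol() > 9;

  for (int i = 0; i < st.nrow(); ++i) {
    uint64_t hid = has_id ? (uint64_t)st(i, 9) : (uint64_t)(i + 1);
    Pcg32 rng((uint64_t)seed, 2u * hid + 23u);
    Photon p { st(i,0), st(i,1), st(i,2), st(i,3), st(i,4), st(i,5),
               st(i,6), st(i,7), (int)st(i,8), hid };
    e_in += p.E * p.w;
    // vacuum propagation to the phantom surface
    if (p.uz <= 1e-8) { C.e_escape += p.E * p.w; n_missed++; continue; }
    double t = (C.ph.ssd - p.z) / p.uz;
    if (t > 0) { p.x += t * p.ux; p.y += t * p.uy; p.z = C.ph.ssd; }
    if (std::abs(p.x) > C.ph.half || std::abs(p.y) > C.ph.half) {
      C.e_escape += p.E * p.w; n_missed++; continue;
    }
    stack.push_back(p);
    while (!stack.empty()) {
      Photon ph = stack.back(); stack.pop_back();
      bool alive = true;
      while (alive) {
        double mu = C.water.mu_tot(ph.E);
        double s = -std::log(1.0 - rng.u()) / mu;
        // distance to box exit
        double t_exit = 1e30;
        if (ph.uz > 1e-12) t_exit = (C.ph.ssd + C.ph.depth - ph.z) / ph.uz;
        else if (ph.uz < -1e-12) t_exit = (C.ph.ssd - ph.z) / ph.uz;
        if (ph.ux > 1e-12) t_exit = std::min(t_exit, (C.ph.half - ph.x) / ph.ux);
        else if (ph.ux < -1e-12) t_exit = std::min(t_exit, (-C.ph.half - ph.x) / ph.ux);
        if (ph.uy > 1e-12) t_exit = std::min(t_exit, (C.ph.half - ph.y) / ph.uy);
        else if (ph.uy < -1e-12) t_exit = std::min(t_exit, (-C.ph.half - ph.y) / ph.uy);
        double seg = std::min(s, t_exit);
        score_photon_segment(C, rng, ph.x, ph.y, ph.z, ph.ux, ph.uy,
                             ph.uz, seg, ph.E, ph.w, ph.tag);
        ph.x += seg * ph.ux; ph.y += seg * ph.uy; ph.z += seg * ph.uz;
        if (s >= t_exit) { C.e_escape += ph.E * ph.w; break; }
        // collision
        int tag_pre = ph.tag;
        double m_pe = C.water.look(C.water.pe, ph.E);
        double m_in = C.water.look(C.water.inc, ph.E);
        double m_co = C.water.look(C.water.coh, ph.E);
        double m_pr = C.water.look(C.water.pair, ph.E);
        double xi = rng.u() * (m_pe + m_in + m_co + m_pr);
        double xe, ye, ze;
        if (xi < m_pe) { // photoelectric: photon terminates
          if (ph.E >= C.ecut)
            transport_electron(C, rng, ph.x, ph.y, ph.z, ph.ux, ph.uy,
                               ph.uz, ph.E, ph.w, tag_pre, tag_pre,
                               xe, ye, ze, 0);
          else deposit_point(C, ph.x, ph.y, ph.z, ph.E * ph.w, tag_pre,
                             tag_pre, 0);
          break;
        } else if (xi < m_pe + m_in) { // Compton
          double eps, cth; kn_sample(ph.E, rng, eps, cth);
          double Ee = ph.E * (1.0 - eps);
          double azim = 2.0 * M_PI * rng.u();
          double ex, ey, ez;
          compton_electron_dir(ph.ux, ph.uy, ph.uz, ph.E / MEC2, cth, azim,
                               ex, ey, ez);
          if (Ee >= C.ecut)
            transport_electron(C, rng, ph.x, ph.y, ph.z, ex, ey, ez, Ee,
                               ph.w, tag_pre, 1, xe, ye, ze, 0);
          else if (Ee > 0)
            deposit_point(C, ph.x, ph.y, ph.z, Ee * ph.w, tag_pre, 1, 0);
          ph.E *= eps; ph.tag = 1;
          rotate_dir(ph.ux, ph.uy, ph.uz, cth, azim);
          if (ph.E < C.pcut) {
            deposit_point(C, ph.x, ph.y, ph.z, ph.E * ph.w, tag_pre, 1, 0);
            break;
          }
        } else if (xi < m_pe + m_in + m_co) { // Rayleigh
          double cth = rayleigh_costheta(ph.E, C.water.zeff, rng);
          ph.tag = 1;
          rotate_dir(ph.ux, ph.uy, ph.uz, cth, 2.0 * M_PI * rng.u());
        } else { // pair production
          double avail = ph.E - 2.0 * MEC2;
          double f = rng.u();
          double Eel = f * avail, Epo = (1.0 - f) * avail;
          if (Eel >= C.ecut)
            transport_electron(C, rng, ph.x, ph.y, ph.z, ph.ux, ph.uy,
                               ph.uz, Eel, ph.w, tag_pre, tag_pre,
                               xe, ye, ze, 0);
          else deposit_point(C, ph.x, ph.y, ph.z, Eel * ph.w, tag_pre,
                             tag_pre, 0);
          xe = ph.x; ye = ph.y; ze = ph.z;
          if (Epo >= C.ecut)
            transport_electron(C, rng, ph.x, ph.y, ph.z, ph.ux, ph.uy,
                               ph.uz, Epo, ph.w, tag_pre, tag_pre,
                               xe, ye, ze, 0);
          else deposit_point(C, ph.x, ph.y, ph.z, Epo * ph.w, tag_pre,
                             tag_pre, 0);
          // annihilation at the positron track end
          double c = 2.0 * rng.u() - 1.0, phi = 2.0 * M_PI * rng.u();
          double sth = std::sqrt(1.0 - c * c);
          if (std::abs(xe) < C.ph.half && std::abs(ye) < C.ph.half &&
              ze > C.ph.ssd && ze < C.ph.ssd + C.ph.depth) {
            Photon a { xe, ye, ze, sth * std::cos(phi), sth * std::sin(phi),
                       c, MEC2, ph.w, 1, ph.id };
            Photon b = a; b.ux = -a.ux; b.uy = -a.uy; b.uz = -a.uz;
            stack.push_back(a); stack.push_back(b);
          } else C.e_escape += 2.0 * MEC2 * ph.w;
          break;
        }
        if (!std::isfinite(ph.E) || !std::isfinite(ph.ux))
          stop("non-finite photon state");
        if (ph.w < C.rr_thresh) { // Russian roulette
          if (rng.u() < 1.0 / C.rr_factor) {
            C.rr_gain += ph.E * ph.w * (C.rr_factor - 1.0);
            ph.w *= C.rr_factor;
          } else { C.rr_loss += ph.E * ph.w; break; }
        }
      }
    }
  }

  auto vec2mat = [](std::vector<double>& v, int nb) {
    NumericMatrix m(nb, 2);
    for (int i = 0; i < nb; ++i) { m(i,0) = v[i*2]; m(i,1) = v[i*2+1]; }
    return m;
  };
  int nd = (int)T.spec_depth.size();
  NumericVector pspec(nd * T.np_bins * 2), espec(nd * T.ne_bins * 2);
  for (int i = 0; i < (int)T.pspec.size(); ++i) pspec[i] = T.pspec[i];
  for (int i = 0; i < (int)T.espec.size(); ++i) espec[i] = T.espec[i];
  pspec.attr("dim") = IntegerVector::create(2, T.np_bins, nd);
  espec.attr("dim") = IntegerVector::create(2, T.ne_bins, nd);

  return List::create(
    _["cyl_kerma"] = vec2mat(T.cyl_kerma, T.n_cyl),
    _["cyl_edep_pre"] = vec2mat(T.cyl_edep_pre, T.n_cyl),
    _["cyl_edep_post"] = vec2mat(T.cyl_edep_post, T.n_cyl),
    _["cyl_fdose_pre"] = vec2mat(T.cyl_fdose_pre, T.n_cyl),
    _["cyl_fdose_post"] = vec2mat(T.cyl_fdose_post, T.n_cyl),
    _["rect_kerma"] = vec2mat(T.rect_kerma, T.n_rect),
    _["rect_edep"] = vec2mat(T.rect_edep, T.n_rect),
    _["pspec"] = pspec, _["espec"] = espec,
    _["e_in"] = e_in, _["e_dep"] = C.e_dep, _["e_escape"] = C.e_escape,
    _["rr_gain"] = C.rr_gain, _["rr_loss"] = C.rr_loss,
    _["out_of_mesh"] = T.out_of_mesh, _["n_missed"] = n_missed);
}
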