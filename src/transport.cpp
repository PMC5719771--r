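// Analog Monte Carlo photon/electron transport in layered slab geometry
// with cylindrical central-axis scoring. Photons: Compton (Klein-Nishina),
// pair production, photoelectric. Secondary electrons: straight-line
// density-scaled CSDA kernel with distance-proportional lateral Gaussian
// spread, or local deposition.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const double MC2 = 0.51099895;   // MeV
static const double RE = 2.8179403e-13; // cm
static const double ALPHA_FS = 1.0 / 137.035999;

// ---- xoshiro256++ RNG (deterministic across platforms) --------------------
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    // splitmix64 expansion
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_norm = false;
  double cached_norm = 0.0;
  inline double norm() {
    if (have_norm) { have_norm = false; return cached_norm; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    cached_norm = r * std::sin(2.0 * M_PI * u2);
    have_norm = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

// ---- cross sections -------------------------------------------------------
static inline double kn_sigma_total(double E) { // cm^2 per electron
  double a = E / MC2;
  return 2.0 * M_PI * RE * RE * (
    (1 + a) / (a * a) * (2 * (1 + a) / (1 + 2 * a) - std::log(1 + 2 * a) / a)
    + std::log(1 + 2 * a) / (2 * a) - (1 + 3 * a) / ((1 + 2 * a) * (1 + 2 * a)));
}

static inline double pair_P(double E) {
  double k = E / MC2;
  if (k < 2.0) return 0.0;
  double base = 28.0 / 9.0 * std::log(2.0 * k) - 218.0 / 27.0;
  return base > 0.0 ? base : 0.0;
}

struct MatXS {
  double rho;        // transport density g/cm^3
  double ne_per_g;   // electrons per gram
  double spair_per_g; // sum w_i NA/A_i * Z_i(Z_i+1)
  double spe_per_g;  // sum w_i NA/A_i * Z_i^4.5
  double rel_edens;  // electron density relative to unit-density water
};

// linear attenuation components (1/cm)
static inline void mu_parts(const MatXS& m, double E, double& mu_c,
                            double& mu_pe, double& mu_pp) {
  mu_c = m.rho * m.ne_per_g * kn_sigma_total(E);
  mu_pe = m.rho * m.spe_per_g * 9.36e-34 / (E * E * E);
  mu_pp = m.rho * m.spair_per_g * ALPHA_FS * RE * RE * pair_P(E);
}

// CSDA range in water, g/cm^2 (Katz-Penfold below 2.5 MeV, linear above)
static inline double csda_range(double T) {
  if (T <= 0) return 0.0;
  if (T < 2.5) return 0.412 * std::pow(T, 1.265 - 0.0954 * std::log(T));
  return 0.530 * T - 0.106;
}

// ---- geometry -------------------------------------------------------------
struct Geom {
  std::vector<double> zb;      // interval boundaries, ascending, zb[0]=0
  std::vector<int> mat;        // base material per interval
  std::vector<int> ins_active; // 1 if insert overlaps this interval
  int ins_mat = -1;
  double ins_r = 0.0;
  double zmax = 0.0;
  int find_interval(double z) const {
    int n = (int)mat.size();
    int lo = 0, hi = n - 1;
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (z >= zb[mid]) lo = mid; else hi = mid - 1;
    }
    return lo;
  }
  inline int material_at(double z, double r2) const {
    int iv = find_interval(z);
    if (ins_mat >= 0 && ins_active[iv] && r2 < ins_r * ins_r) return ins_mat;
    return mat[iv];
  }
};

struct Tally {
  int nbins, nbatch;
  double bin_w, r_score2;
  int mode = 0;          // 0: fixed scoring cylinder; 1: reciprocity
  double rfield = 0.0, ssd = 100.0; // mode 1: field radius projected with depth
  std::vector<double> edep; // nbins x nbatch, column-major per batch
  double e_total_inside = 0.0;
  inline void deposit(double x, double y, double z, double e, int batch) {
    if (z < 0) return;
    int b = (int)(z / bin_w);
    if (b < 0 || b >= nbins) return;
    e_total_inside += e;
    double r2lim = r_score2;
    if (mode == 1) {
      double rp = rfield * (ssd + z) / ssd;
      r2lim = rp * rp;
    }
    if (x * x + y * y >= r2lim) return;
    edep[(size_t)batch * nbins + b] += e;
  }
};

// rotate: given direction d (unit), return direction at polar angle
// (cost relative to d) and azimuth phi
static inline void rotate_dir(const double d[3], double cost, double phi,
                              double out[3]) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cphi = std::cos(phi), sphi = std::sin(phi);
  double dz = d[2];
  if (std::fabs(dz) > 0.99999999) {
    double sign = dz > 0 ? 1.0 : -1.0;
    out[0] = sint * cphi;
    out[1] = sign * sint * sphi;
    out[2] = sign * cost;
    return;
  }
  double st = std::sqrt(1.0 - dz * dz);
  // orthonormal basis e1, e2 perpendicular to d
  double e1[3] = { d[0] * dz / st, d[1] * dz / st, -st };
  double e2[3] = { -d[1] / st, d[0] / st, 0.0 };
  for (int i = 0; i < 3; ++i)
    out[i] = d[i] * cost + sint * (cphi * e1[i] + sphi * e2[i]);
  double n = std::sqrt(out[0]*out[0] + out[1]*out[1] + out[2]*out[2]);
  out[0] /= n; out[1] /= n; out[2] /= n;
}

struct Opts {
  double photon_cutoff, electron_cutoff;
  int electron_mode; // 0 local, 1 kernel
  bool primary_only;
  double ffwd, klat;
  int nsub;
};

struct Engine {
  const Geom& g;
  const std::vector<MatXS>& mats;
  Tally& tally;
  const Opts& o;
  Rng& rng;
  double e_emitted = 0.0;

  Engine(const Geom& g_, const std::vector<MatXS>& m_, Tally& t_,
         const Opts& o_, Rng& r_) : g(g_), mats(m_), tally(t_), o(o_),
                                    rng(r_) {}

  // straight-line CSDA kernel: energy deposited uniformly per unit *mass*
  // path, with substeps clipped at slab boundaries so that dose stays
  // continuous across density interfaces
  void electron(double p[3], const double d[3], double T, int batch) {
    if (T <= 0) return;
    if (o.electron_mode == 0 || T < o.electron_cutoff) {
      tally.deposit(p[0], p[1], p[2], T, batch);
      return;
    }
    double Rm = o.ffwd * csda_range(T); // effective forward mass path g/cm^2
    double dm_nom = Rm / o.nsub;
    // lateral spread: tilt the track direction once by a transverse Gaussian
    // (models angular spread / multiple scattering; gives sigma(s)=klat*s);
    // the deposit positions and the material lookups share the same track
    double dd[3];
    {
      double tmp[3];
      rotate_dir(d, 0.0, 2.0 * M_PI * rng.unif(), tmp);
      double e2[3] = { d[1] * tmp[2] - d[2] * tmp[1],
                       d[2] * tmp[0] - d[0] * tmp[2],
                       d[0] * tmp[1] - d[1] * tmp[0] };
      double g1 = rng.norm() * o.klat, g2 = rng.norm() * o.klat;
      for (int i = 0; i < 3; ++i) dd[i] = d[i] + g1 * tmp[i] + g2 * e2[i];
      double n = std::sqrt(dd[0]*dd[0] + dd[1]*dd[1] + dd[2]*dd[2]);
      for (int i = 0; i < 3; ++i) dd[i] /= n;
    }
    double x = p[0], y = p[1], z = p[2], s = 0.0, rem = Rm;
    int guard = 0;
    while (rem > 1e-12 && guard++ < 20 * o.nsub) {
      if (z < -5.0 || z > g.zmax + 5.0) break; // escaped far from phantom
      double r2 = x * x + y * y;
      bool inside = (z >= 0 && z <= g.zmax);
      int mi = inside ? g.material_at(z, r2) : -1;
      double red = (mi >= 0) ? mats[mi].rel_edens : 1e-3; // near-vacuum outside
      double ds = std::min(rem, dm_nom) / red;
      // clip at the next z-boundary so deposits never straddle an interface
      double dist = 1e30;
      if (inside) {
        int iv = g.find_interval(z);
        if (dd[2] > 1e-12) dist = (g.zb[iv + 1] - z) / dd[2];
        else if (dd[2] < -1e-12) dist = (g.zb[iv] - z) / dd[2];
      } else if (z < 0 && dd[2] > 1e-12) {
        dist = (0.0 - z) / dd[2];
      } else if (z > g.zmax && dd[2] < -1e-12) {
        dist = (g.zmax - z) / dd[2];
      }
      bool hit = dist < ds;
      if (hit) ds = std::max(dist, 1e-9);
      double dm_used = ds * red;
      double de = T * dm_used / Rm;
      tally.deposit(x + 0.5 * ds * dd[0], y + 0.5 * ds * dd[1],
                    z + 0.5 * ds * dd[2], de, batch);
      double adv = hit ? ds + 1e-9 : ds;
      x += adv * dd[0]; y += adv * dd[1]; z += adv * dd[2];
      s += adv;
      rem -= dm_used;
    }
  }

  // returns end-of-track position of a (positron) kernel for annihilation
  void electron_endpoint(const double p[3], const double d[3], double T,
                         double out[3]) {
    double Rm = o.ffwd * csda_range(T);
    double x = p[0], y = p[1], z = p[2], rem = Rm;
    for (int i = 0; i < 64 && rem > 0; ++i) {
      double r2 = x * x + y * y;
      int mi = (z >= 0 && z <= g.zmax) ? g.material_at(z, r2) : -1;
      double red = (mi >= 0) ? mats[mi].rel_edens : 1e-3;
      double step = std::min(rem, 0.1 * Rm);
      double ds = step / red;
      x += ds * d[0]; y += ds * d[1]; z += ds * d[2];
      rem -= step;
      if (z < -5 || z > g.zmax + 5) break;
    }
    out[0] = x; out[1] = y; out[2] = z;
  }

  struct Photon { double p[3], d[3], E; };

  void history(double E0, double x0, double y0, double ssd, int batch) {
    e_emitted += E0;
    std::vector<Photon> stack;
    Photon ph;
    ph.p[0] = x0; ph.p[1] = y0; ph.p[2] = 0.0;
    double norm = std::sqrt(x0 * x0 + y0 * y0 + ssd * ssd);
    ph.d[0] = x0 / norm; ph.d[1] = y0 / norm; ph.d[2] = ssd / norm;
    ph.E = E0;
    stack.push_back(ph);
    bool first_interaction = true;
    while (!stack.empty()) {
      Photon cur = stack.back(); stack.pop_back();
      while (true) {
        if (cur.E < o.photon_cutoff) {
          tally.deposit(cur.p[0], cur.p[1], cur.p[2], cur.E, batch);
          break;
        }
        double tau = -std::log(rng.unif());
        // march to interaction or escape
        double x = cur.p[0], y = cur.p[1], z = cur.p[2];
        bool interacted = false;
        int guard = 0;
        while (guard++ < 10000) {
          if (z < 0 && cur.d[2] <= 0) break;
          if (z > g.zmax && cur.d[2] >= 0) break;
          if (z < 0) { // re-enter from above
            double t = (0.0 - z) / cur.d[2];
            x += t * cur.d[0]; y += t * cur.d[1]; z = 1e-9;
            continue;
          }
          if (z > g.zmax) break;
          int iv = g.find_interval(z);
          double r2 = x * x + y * y;
          bool in_ins = g.ins_mat >= 0 && g.ins_active[iv] &&
                        r2 < g.ins_r * g.ins_r;
          int mi = in_ins ? g.ins_mat : g.mat[iv];
          double mu_c, mu_pe, mu_pp;
          mu_parts(mats[mi], cur.E, mu_c, mu_pe, mu_pp);
          double mu = mu_c + mu_pe + mu_pp;
          // distance to interval z-boundary
          double tb = 1e30;
          if (cur.d[2] > 1e-12) tb = (g.zb[iv + 1] - z) / cur.d[2];
          else if (cur.d[2] < -1e-12) tb = (g.zb[iv] - z) / cur.d[2];
          // distance to insert cylinder wall if insert overlaps interval
          if (g.ins_mat >= 0 && g.ins_active[iv]) {
            double A = cur.d[0] * cur.d[0] + cur.d[1] * cur.d[1];
            if (A > 1e-14) {
              double B = 2.0 * (x * cur.d[0] + y * cur.d[1]);
              double C = r2 - g.ins_r * g.ins_r;
              double disc = B * B - 4 * A * C;
              if (disc > 0) {
                double sq = std::sqrt(disc);
                double t1 = (-B - sq) / (2 * A), t2 = (-B + sq) / (2 * A);
                if (t1 > 1e-9 && t1 < tb) tb = t1;
                else if (t2 > 1e-9 && t2 < tb) tb = t2;
              }
            }
          }
          double tint = (mu > 0) ? tau / mu : 1e30;
          if (tint < tb) {
            x += tint * cur.d[0]; y += tint * cur.d[1]; z += tint * cur.d[2];
            cur.p[0] = x; cur.p[1] = y; cur.p[2] = z;
            interacted = true;
            // choose interaction type
            double u = rng.unif() * mu;
            if (o.primary_only && first_interaction) {
              tally.deposit(x, y, z, cur.E, batch);
              cur.E = 0;
            } else if (u < mu_c) {
              compton(cur, batch, stack);
            } else if (u < mu_c + mu_pe) {
              // photoelectric: electron carries full photon energy
              electron(cur.p, cur.d, cur.E, batch);
              cur.E = 0;
            } else {
              pairprod(cur, batch, stack);
            }
            first_interaction = false;
            break;
          } else {
            tau -= mu * tb;
            double eps = tb + 1e-9;
            x += eps * cur.d[0]; y += eps * cur.d[1]; z += eps * cur.d[2];
          }
        }
        if (!interacted || cur.E <= 0) break;
      }
      if (o.primary_only) break;
    }
  }

  void compton(Photon& ph, int batch, std::vector<Photon>& stack) {
    double a = ph.E / MC2;
    double e0 = 1.0 / (1.0 + 2.0 * a);
    double a1 = -std::log(e0), a2 = 0.5 * (1.0 - e0 * e0);
    double eps, t, sin2;
    for (int k = 0; k < 1000; ++k) {
      if (rng.unif() * (a1 + a2) < a1) eps = e0 * std::exp(a1 * rng.unif());
      else eps = std::sqrt(e0 * e0 + (1.0 - e0 * e0) * rng.unif());
      t = (1.0 - eps) / (a * eps);
      sin2 = t * (2.0 - t);
      if (rng.unif() <= 1.0 - eps * sin2 / (1.0 + eps * eps)) break;
    }
    double cost = 1.0 - t;
    double phi = 2.0 * M_PI * rng.unif();
    double T = ph.E * (1.0 - eps);
    // electron direction from kinematics
    double tan_half = std::sqrt(std::max(0.0, (1 - cost) / (1 + cost + 1e-30)));
    double cot_e = (1.0 + a) * tan_half;
    double theta_e = std::atan2(1.0, cot_e);
    double ed[3];
    rotate_dir(ph.d, std::cos(theta_e), phi + M_PI, ed);
    double ep[3] = { ph.p[0], ph.p[1], ph.p[2] };
    electron(ep, ed, T, batch);
    double nd[3];
    rotate_dir(ph.d, cost, phi, nd);
    ph.d[0] = nd[0]; ph.d[1] = nd[1]; ph.d[2] = nd[2];
    ph.E *= eps;
  }

  void pairprod(Photon& ph, int batch, std::vector<Photon>& stack) {
    double T = ph.E - 2.0 * MC2;
    double u = rng.unif();
    double Tm = u * T, Tp = (1.0 - u) * T; // electron / positron kinetic
    double ep[3] = { ph.p[0], ph.p[1], ph.p[2] };
    electron(ep, ph.d, Tm, batch);
    double endp[3];
    electron_endpoint(ph.p, ph.d, Tp, endp);
    electron(ep, ph.d, Tp, batch);
    // annihilation: two back-to-back 511 keV photons, isotropic
    double cost = 2.0 * rng.unif() - 1.0;
    double phi = 2.0 * M_PI * rng.unif();
    double sint = std::sqrt(1.0 - cost * cost);
    Photon g1, g2;
    for (int i = 0; i < 3; ++i) { g1.p[i] = endp[i]; g2.p[i] = endp[i]; }
    g1.d[0] = sint * std::cos(phi); g1.d[1] = sint * std::sin(phi);
    g1.d[2] = cost;
    g2.d[0] = -g1.d[0]; g2.d[1] = -g1.d[1]; g2.d[2] = -g1.d[2];
    g1.E = MC2; g2.E = MC2;
    if (endp[2] > -2 && endp[2] < g.zmax + 2) {
      stack.push_back(g1); stack.push_back(g2);
    }
    ph.E = 0;
  }
};

// [[Rcpp::export(name = ".cpp_run_transport")]]
List cpp_run_transport(int n_hist, double seed, int n_batches,
                       NumericVector zb, IntegerVector mat,
                       IntegerVector ins_active,
                       NumericMatrix mat_props, // rows: materials; cols: rho, ne_per_g, spair, spe, rel_edens
                       int ins_mat, double ins_r,
                       NumericVector spec_E, NumericVector spec_cum,
                       double ssd, double field_radius,
                       double r_score, int nbins, double bin_w,
                       double photon_cutoff, double electron_cutoff,
                       int electron_mode, bool primary_only,
                       double ffwd, double klat, int nsub, int score_mode) {
  Geom g;
  g.zb = as<std::vector<double>>(zb);
  g.mat = as<std::vector<int>>(mat);
  g.ins_active = as<std::vector<int>>(ins_active);
  g.ins_mat = ins_mat; g.ins_r = ins_r;
  g.zmax = g.zb.back();
  std::vector<MatXS> mats(mat_props.nrow());
  for (int i = 0; i < mat_props.nrow(); ++i) {
    mats[i].rho = mat_props(i, 0);
    mats[i].ne_per_g = mat_props(i, 1);
    mats[i].spair_per_g = mat_props(i, 2);
    mats[i].spe_per_g = mat_props(i, 3);
    mats[i].rel_edens = mat_props(i, 4);
  }
  Tally tally;
  tally.nbins = nbins; tally.nbatch = n_batches; tally.bin_w = bin_w;
  tally.r_score2 = r_score * r_score;
  tally.mode = score_mode; tally.rfield = field_radius; tally.ssd = ssd;
  tally.edep.assign((size_t)nbins * n_batches, 0.0);
  Opts o;
  o.photon_cutoff = photon_cutoff; o.electron_cutoff = electron_cutoff;
  o.electron_mode = electron_mode; o.primary_only = primary_only;
  o.ffwd = ffwd; o.klat = klat; o.nsub = nsub;
  Rng rng((uint64_t)seed);
  Engine eng(g, mats, tally, o, rng);
  int nspec = spec_E.size();
  for (int h = 0; h < n_hist; ++h) {
    // sample energy from discrete spectrum
    double u = rng.unif();
    int lo = 0, hi = nspec - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (spec_cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    double E = spec_E[lo];
    if (score_mode == 1) {
      // reciprocity estimator: central-axis pencil
      eng.history(E, 0.0, 0.0, ssd, h % n_batches);
    } else {
      // sample entrance point uniformly on the field disk at the surface
      double r = field_radius * std::sqrt(rng.unif());
      double phi = 2.0 * M_PI * rng.unif();
      eng.history(E, r * std::cos(phi), r * std::sin(phi), ssd,
                  h % n_batches);
    }
  }
  NumericMatrix edep(nbins, n_batches);
  for (int b = 0; b < n_batches; ++b)
    for (int i = 0; i < nbins; ++i)
      edep(i, b) = tally.edep[(size_t)b * nbins + i];
  return List::create(_["edep"] = edep,
                      _["e_emitted"] = eng.e_emitted,
                      _["e_deposited"] = tally.e_total_inside);
}
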