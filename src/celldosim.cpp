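// Monte Carlo electron transport in liquid water with cellular-scale scoring.
//
// Two-tier physics:
//   tier 1 (E <= 10 keV): event-by-event. Binary-encounter-Bethe (BEB)
//     ionization for the five water orbitals, five discrete excitation
//     channels with a Born-like shape, screened-Rutherford elastic scattering.
//   tier 2 (E > 10 keV): condensed history between discrete events.
//     Restricted Bethe collision stopping (Moller losses above 1 keV removed),
//     explicit Moller delta-ray production above 1 keV, and the same discrete
//     screened-Rutherford elastic scattering as tier 1.
// Sub-excitation electrons (below the lowest excitation channel or below the
// user cutoff, default 7.4 eV) deposit their residual energy locally.
//
// Units: energy eV, length micron (cross sections internally in cm^2).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

const double MC2    = 510998.95;     // electron rest energy, eV
const double RE2    = 7.9407877e-26; // classical electron radius squared, cm^2
const double A0CM   = 0.529177e-8;   // Bohr radius, cm
const double RYD    = 13.6057;       // Rydberg, eV
const double NMOL   = 3.3428e22;     // water molecules per cm^3 at 1 g/cm^3
const double NELE   = 3.3428e23;     // electrons per cm^3
const double IWATER = 78.0;          // mean excitation energy, eV
const double CM2UM  = 1e4;

const double TIER_EV  = 10000.0;     // tier boundary
const double DELTA_EV = 1000.0;      // delta-ray production threshold
const double EMAX_EV  = 1.2e6;       // table upper bound

// BEB orbital parameters for water (binding B, mean kinetic U, occupancy 2)
const int    NSH = 5;
const double BSH[NSH] = {12.62, 14.75, 18.51, 32.40, 539.7};
const double USH[NSH] = {61.91, 59.52, 48.36, 70.71, 793.9};

// discrete excitation channels (eV) with relative strengths; CEXC fixes the
// absolute scale (calibrated once against the ~6.4 nm penetration of the
// 119 eV Auger group).
const int    NXC = 5;
const double EXC[NXC] = {8.22, 10.00, 11.24, 12.61, 13.77};
const double FXC[NXC] = {1.00, 1.20, 1.40, 2.00, 1.60};
const double CEXC     = 0.10;

// ---------------------------------------------------------------- RNG ------
// splitmix64; one independent stream per (seed, source index, history).
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  static uint64_t mix(uint64_t z) {
    z += 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  static uint64_t key(uint64_t seed, uint64_t a, uint64_t b) {
    uint64_t k = mix(seed + 0x632BE59BD9B4E019ULL);
    k = mix(k ^ mix(a + 0x9E3779B97F4A7C15ULL));
    k = mix(k ^ mix(b + 0xD1B54A32D192ED03ULL));
    return k;
  }
  uint64_t nextu() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { // in (0,1)
    double u = (nextu() >> 11) * (1.0 / 9007199254740992.0);
    return u > 0.0 ? u : 5e-324;
  }
};

struct Vec3 { double x, y, z; };

inline void isotropic(Rng& r, Vec3& d) {
  d.z = 2.0 * r.unif() - 1.0;
  double ph = 6.283185307179586 * r.unif();
  double s = std::sqrt(std::max(0.0, 1.0 - d.z * d.z));
  d.x = s * std::cos(ph);
  d.y = s * std::sin(ph);
}

// rotate direction d by polar angle (cost) and random azimuth
inline void deflect(Rng& r, Vec3& d, double cost) {
  cost = std::max(-1.0, std::min(1.0, cost));
  double sint = std::sqrt(1.0 - cost * cost);
  double ph = 6.283185307179586 * r.unif();
  double cph = std::cos(ph), sph = std::sin(ph);
  double sq = std::sqrt(std::max(0.0, 1.0 - d.z * d.z));
  if (sq < 1e-12) {
    double sgn = d.z >= 0 ? 1.0 : -1.0;
    d.x = sint * cph;
    d.y = sint * sph;
    d.z = cost * sgn;
  } else {
    double nx = sint * (d.x * d.z * cph - d.y * sph) / sq + d.x * cost;
    double ny = sint * (d.y * d.z * cph + d.x * sph) / sq + d.y * cost;
    double nz = -sint * sq * cph + d.z * cost;
    d.x = nx; d.y = ny; d.z = nz;
  }
  double n = std::sqrt(d.x * d.x + d.y * d.y + d.z * d.z);
  d.x /= n; d.y /= n; d.z /= n;
}

// ------------------------------------------------------------ physics ------

inline double beta2(double T) {
  double tau = T / MC2;
  return tau * (tau + 2.0) / ((tau + 1.0) * (tau + 1.0));
}

// BEB total ionization cross section for shell j (cm^2)
inline double sigBEB(double T, int j) {
  double B = BSH[j], t = T / B;
  if (t <= 1.0) return 0.0;
  double u = USH[j] / B;
  double S = 4.0 * M_PI * A0CM * A0CM * 2.0 * (RYD / B) * (RYD / B);
  double lt = std::log(t);
  return S / (t + u + 1.0) *
         (0.5 * lt * (1.0 - 1.0 / (t * t)) + 1.0 - 1.0 / t - lt / (t + 1.0));
}

// BEB singly differential cross section in w = W/B (relative shape is all
// that matters for sampling; absolute scale kept for the mean-loss integral)
inline double bebSDCS(double t, double u, double w, double S) {
  double a = 1.0 / (w + 1.0), b = 1.0 / (t - w);
  double lt = std::log(t);
  double f = (a * a + b * b) - (a + b) / (t + 1.0) + lt * (a * a * a + b * b * b);
  return S / (t + u + 1.0) * f;
}

// sample secondary energy W (eV) from the BEB SDCS for shell j at energy T
inline double sampleBEB(Rng& r, double T, int j) {
  double B = BSH[j], t = T / B, u = USH[j] / B;
  double wmax = 0.5 * (t - 1.0);
  double lt = std::log(t);
  // envelope: (1 + ln t) * (1/(w+1)^2 + 1/(t-w)^2)
  double I1 = 1.0 - 2.0 / (t + 1.0);
  double I2 = 2.0 / (t + 1.0) - 1.0 / t;
  for (int it = 0; it < 1000; ++it) {
    double w;
    if (r.unif() * (I1 + I2) < I1) {
      w = 1.0 / (1.0 - r.unif() * I1) - 1.0;
    } else {
      double y = 1.0 / t + r.unif() * (2.0 / (t + 1.0) - 1.0 / t);
      w = t - 1.0 / y;
    }
    if (w < 0.0) w = 0.0;
    if (w > wmax) w = wmax;
    double a = 1.0 / (w + 1.0), b = 1.0 / (t - w);
    double env = (1.0 + lt) * (a * a + b * b);
    double f = (a * a + b * b) - (a + b) / (t + 1.0) + lt * (a * a * a + b * b * b);
    if (r.unif() * env <= f) return w * B;
  }
  return 0.0;
}

// excitation cross section, channel k (cm^2)
inline double sigEXC(double T, int k) {
  double E = EXC[k];
  if (T <= E) return 0.0;
  return CEXC * FXC[k] * 4.0 * M_PI * A0CM * A0CM * RYD * RYD / (T * E) *
         std::log(M_E + 4.0 * T / E);
}

// screened-Rutherford elastic scattering; Moliere screening per atom
inline double etaAtom(double T, double Z23) {
  double tau = T / MC2;
  return 1.7e-5 * Z23 / (tau * (tau + 2.0));
}
inline double sigElAtom(double T, double Z, double Z23) {
  double b2 = beta2(T);
  double eta = etaAtom(T, Z23);
  double g = (1.0 - b2) / (b2 * b2);
  return M_PI * Z * Z * RE2 * g / (eta * (1.0 + eta));
}
// per molecule (2 H + 1 O); also returns the oxygen share
inline double sigElMol(double T, double& fracO) {
  double sO = sigElAtom(T, 8.0, 4.0);          // 8^(2/3) = 4
  double sH = sigElAtom(T, 1.0, 1.0);
  fracO = sO / (sO + 2.0 * sH);
  return sO + 2.0 * sH;
}
inline double sampleElastic(Rng& r, double T) {
  double fracO;
  sigElMol(T, fracO);
  double Z23 = (r.unif() < fracO) ? 4.0 : 1.0;
  double eta = etaAtom(T, Z23);
  double mu = r.unif();
  double omc = 2.0 * eta * mu / (1.0 + eta - mu); // 1 - cos(theta)
  return 1.0 - omc;
}

// unrestricted Bethe collision stopping power (eV/um)
inline double spBethe(double T) {
  double tau = T / MC2, b2 = beta2(T);
  double k = 2.0 * M_PI * RE2 * MC2 * NELE / b2; // eV/cm
  double arg = tau * tau * (tau + 2.0) / 2.0 * (MC2 / IWATER) * (MC2 / IWATER);
  double F = 1.0 - b2 +
             (tau * tau / 8.0 - (2.0 * tau + 1.0) * std::log(2.0)) /
                 ((tau + 1.0) * (tau + 1.0));
  double s = k * (std::log(arg) + F);
  return s / CM2UM;
}

// Moller cross section integrals between eps1 and eps2 (eps = W/T):
// number (cm^2 per electron) and energy-loss moment (eV cm^2 per electron)
inline void mollerInt(double T, double eps1, double eps2, double& num, double& loss) {
  double tau = T / MC2, g = tau + 1.0, b2 = beta2(T);
  double C = 2.0 * M_PI * RE2 * MC2 / (b2 * T); // cm^2 (per unit eps)
  double tg2 = (tau / g) * (tau / g);
  double c2 = (2.0 * tau + 1.0) / (g * g);
  auto Fn = [&](double e) {
    return -1.0 / e - 1.0 / (1.0 - e) * (-1.0) + tg2 * e - c2 * std::log(e / (1.0 - e));
  };
  // note: integral of 1/(1-e)^2 de = 1/(1-e)
  auto Fnum = [&](double e) {
    return -1.0 / e + 1.0 / (1.0 - e) + tg2 * e - c2 * std::log(e / (1.0 - e));
  };
  auto Floss = [&](double e) {
    return std::log(e) + 1.0 / (1.0 - e) + std::log(1.0 - e) + 0.5 * tg2 * e * e +
           c2 * std::log(1.0 - e);
  };
  (void)Fn;
  num = C * (Fnum(eps2) - Fnum(eps1));
  loss = C * T * (Floss(eps2) - Floss(eps1));
}

inline double sampleMoller(Rng& r, double T) {
  double eps1 = DELTA_EV / T;
  double tau = T / MC2, g = tau + 1.0;
  double tg2 = (tau / g) * (tau / g);
  double c2 = (2.0 * tau + 1.0) / (g * g);
  for (int it = 0; it < 1000; ++it) {
    // envelope ~ 1/eps^2 on [eps1, 1/2]
    double u = r.unif();
    double inv = 1.0 / eps1 - u * (1.0 / eps1 - 2.0);
    double e = 1.0 / inv;
    double f = 1.0 / (e * e) + 1.0 / ((1.0 - e) * (1.0 - e)) + tg2 -
               c2 / (e * (1.0 - e));
    if (r.unif() * (2.2 / (e * e)) <= f) return e * T;
  }
  return DELTA_EV;
}

// --------------------------------------------------------- energy grid -----
struct Tables {
  int n;
  std::vector<double> lE;          // log energy grid
  double lmin, dl;
  std::vector<double> ion[NSH];    // per-shell ionization xs
  std::vector<double> iontot;
  std::vector<double> exctot;
  std::vector<double> el;          // elastic xs per molecule
  std::vector<double> spmod;       // model stopping power eV/um
  std::vector<double> lrest;       // restricted stopping eV/um (tier 2)
  std::vector<double> smoller;     // moller xs per molecule-equivalent cm^2*NELE -> 1/um
  std::vector<double> csda;        // cumulative csda range, um

  Tables() {
    n = 600;
    lmin = std::log(7.4);
    double lmax = std::log(EMAX_EV);
    dl = (lmax - lmin) / (n - 1);
    lE.resize(n);
    for (int s = 0; s < NSH; ++s) ion[s].resize(n);
    iontot.resize(n); exctot.resize(n); el.resize(n);
    spmod.resize(n); lrest.resize(n); smoller.resize(n); csda.resize(n);

    for (int i = 0; i < n; ++i) {
      double T = std::exp(lmin + i * dl);
      lE[i] = std::log(T);
      double stot = 0.0;
      for (int s = 0; s < NSH; ++s) {
        ion[s][i] = sigBEB(T, s);
        stot += ion[s][i];
      }
      iontot[i] = stot;
      double xtot = 0.0;
      for (int k = 0; k < NXC; ++k) xtot += sigEXC(T, k);
      exctot[i] = xtot;
      double fo;
      el[i] = sigElMol(T, fo);

      // tier-1 stopping: sum over channels of xs * mean energy loss
      double sp1 = 0.0;
      for (int s = 0; s < NSH; ++s) {
        if (ion[s][i] <= 0.0) continue;
        double B = BSH[s], t = T / B, u = USH[s] / B;
        // mean W over the SDCS, integrated in x = log(w+1)
        double xmax = std::log((t + 1.0) / 2.0);
        int m = 120;
        double dx = xmax / m, s0 = 0.0, s1 = 0.0;
        for (int q = 0; q <= m; ++q) {
          double x = q * dx;
          double w = std::exp(x) - 1.0;
          if (w > 0.5 * (t - 1.0)) w = 0.5 * (t - 1.0);
          double f = bebSDCS(t, u, w, 1.0) * std::exp(x); // jacobian
          double wgt = (q == 0 || q == m) ? 0.5 : 1.0;
          s0 += wgt * f;
          s1 += wgt * f * w;
        }
        double wmean = (s0 > 0.0) ? (s1 / s0) * B : 0.0;
        sp1 += ion[s][i] * (B + wmean);
      }
      for (int k = 0; k < NXC; ++k) sp1 += sigEXC(T, k) * EXC[k];
      sp1 *= NMOL / CM2UM; // eV/um

      double spb = spBethe(T);
      spmod[i] = (T <= TIER_EV) ? sp1 : spb;

      // restricted stopping and delta production for tier 2
      if (T > 2.0 * DELTA_EV) {
        double num, loss;
        mollerInt(T, DELTA_EV / T, 0.5, num, loss);
        lrest[i] = spb - loss * NELE / CM2UM;
        smoller[i] = num * NELE / CM2UM; // 1/um
      } else {
        lrest[i] = spb;
        smoller[i] = 0.0;
      }
      if (lrest[i] < 0.1 * spb) lrest[i] = 0.1 * spb; // numerical guard
    }
    // cumulative CSDA range; below the first excitation channel the model
    // has no inelastic channel (sub-excitation electrons stop locally)
    csda[0] = 0.0;
    for (int i = 1; i < n; ++i) {
      double E0 = std::exp(lE[i - 1]), E1 = std::exp(lE[i]);
      if (spmod[i - 1] <= 0.0 || spmod[i] <= 0.0) {
        csda[i] = csda[i - 1];
        continue;
      }
      double f0 = 1.0 / spmod[i - 1], f1 = 1.0 / spmod[i];
      csda[i] = csda[i - 1] + 0.5 * (f0 + f1) * (E1 - E0);
    }
  }

  inline double interp(const std::vector<double>& v, double T) const {
    double l = std::log(T);
    double x = (l - lmin) / dl;
    if (x <= 0.0) return v[0];
    if (x >= n - 1) return v[n - 1];
    int i = (int)x;
    double f = x - i;
    return v[i] * (1.0 - f) + v[i + 1] * f;
  }
};

const Tables& tables() {
  static Tables tb;
  return tb;
}

// ------------------------------------------------------------ geometry -----
// cell constants (um)
const double RCELL = 7.0, RMEM = 6.99, RNUC = 5.0;
const double RC2 = (RCELL + 1e-9) * (RCELL + 1e-9);

struct Geom {
  int kind;                 // 0 none, 1 sphere, 2 cells
  double R;                 // sphere radius
  std::vector<double> cx, cy, cz;
  mutable int last;
  Geom() : kind(0), R(0.0), last(-1) {}

  // bin: 0 outside; sphere: 1 inside; cells: 1 + 3*cell + comp
  // comp: 0 nucleus, 1 cytoplasm, 2 membrane
  inline int bin(const Vec3& p) const {
    if (kind == 1) {
      double r2 = p.x * p.x + p.y * p.y + p.z * p.z;
      return (r2 <= R * R * (1.0 + 1e-12)) ? 1 : 0;
    }
    if (kind == 2) {
      int nc = (int)cx.size();
      if (last >= 0) {
        double dx = p.x - cx[last], dy = p.y - cy[last], dz = p.z - cz[last];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 <= RC2) return 1 + 3 * last + comp(r2);
      }
      for (int i = 0; i < nc; ++i) {
        double dx = p.x - cx[i];
        if (dx > RCELL + 1e-6 || dx < -RCELL - 1e-6) continue;
        double dy = p.y - cy[i];
        if (dy > RCELL + 1e-6 || dy < -RCELL - 1e-6) continue;
        double dz = p.z - cz[i];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 <= RC2) {
          last = i;
          return 1 + 3 * i + comp(r2);
        }
      }
      return 0;
    }
    return 0;
  }
  static inline int comp(double r2) {
    if (r2 <= RNUC * RNUC) return 0;
    if (r2 <= RMEM * RMEM) return 1;
    return 2;
  }
};

// ------------------------------------------------------------- scorer ------
struct Scorer {
  int mode; // 0 events, 1 radial, 2 geom
  // events
  std::vector<double>* evx = nullptr;
  std::vector<double>* evy = nullptr;
  std::vector<double>* evz = nullptr;
  std::vector<double>* eve = nullptr;
  // radial
  double inv_shell = 0.0;
  int nshell = 0;
  double* rbins = nullptr; // length nshell + 1 (overflow)
  // geometry
  const Geom* geom = nullptr;
  double* tally = nullptr; // [nbins x 3cat x 2part] for current batch
  int nbins = 0, cat = 0, part = 0;
  double weight = 1.0;

  inline void deposit(const Vec3& p, double e) {
    if (e <= 0.0) return;
    if (mode == 2) {
      int b = geom->bin(p);
      tally[b + nbins * (cat + 3 * part)] += e * weight;
    } else if (mode == 1) {
      double r = std::sqrt(p.x * p.x + p.y * p.y + p.z * p.z);
      int i = (int)(r * inv_shell);
      if (i >= nshell) i = nshell;
      rbins[i] += e * weight;
    } else {
      evx->push_back(p.x);
      evy->push_back(p.y);
      evz->push_back(p.z);
      eve->push_back(e);
    }
  }
};

// ----------------------------------------------------------- transport -----
struct Part {
  double E;
  Vec3 pos, dir;
};

// transport one electron and all its secondaries; returns energy deposited
double transportCascade(Rng& rng, Scorer& sc, double E0, Vec3 pos0, Vec3 dir0,
                        double cutoff) {
  const Tables& tb = tables();
  double killE = std::max(cutoff, 0.0);
  std::vector<Part> stack;
  stack.push_back({E0, pos0, dir0});
  double edep = 0.0;

  while (!stack.empty()) {
    Part p = stack.back();
    stack.pop_back();
    double E = p.E;
    Vec3 pos = p.pos, dir = p.dir;

    for (;;) {
      if (E <= killE || E <= EXC[0]) { // sub-excitation: absorb locally
        sc.deposit(pos, E);
        edep += E;
        break;
      }
      if (E > TIER_EV) {
        // ---- tier 2: condensed history segment
        double lam_el = CM2UM / (NMOL * tb.interp(tb.el, E));
        double sm = tb.interp(tb.smoller, E);
        double L = tb.interp(tb.lrest, E);
        double s_el = -lam_el * std::log(rng.unif());
        double s_d = (sm > 0.0) ? -std::log(rng.unif()) / sm : 1e300;
        double s_cap = 0.03 * E / L;
        if (s_cap > 5.0) s_cap = 5.0;
        double s = s_el;
        int ev = 0; // 0 elastic, 1 delta, 2 cap
        if (s_d < s) { s = s_d; ev = 1; }
        if (s_cap < s) { s = s_cap; ev = 2; }
        double dE = L * s;
        // midpoint correction
        double Lm = tb.interp(tb.lrest, std::max(TIER_EV, E - 0.5 * dE));
        dE = Lm * s;
        if (E - dE <= TIER_EV) {
          // shorten the step so the electron lands on the tier boundary
          double frac = (E - TIER_EV) / dE;
          s *= frac;
          dE = E - TIER_EV;
          ev = 3;
        }
        double u = rng.unif();
        Vec3 dpos = {pos.x + u * s * dir.x, pos.y + u * s * dir.y,
                     pos.z + u * s * dir.z};
        sc.deposit(dpos, dE);
        edep += dE;
        E -= dE;
        pos.x += s * dir.x; pos.y += s * dir.y; pos.z += s * dir.z;
        if (ev == 0) {
          deflect(rng, dir, sampleElastic(rng, E));
        } else if (ev == 1) {
          double W = sampleMoller(rng, E);
          double Ep = E - W;
          // secondary
          double cd = std::sqrt((W / E) * (E + 2.0 * MC2) / (W + 2.0 * MC2));
          Vec3 sd = dir;
          deflect(rng, sd, cd);
          stack.push_back({W, pos, sd});
          // primary
          double cp = std::sqrt((Ep / E) * (E + 2.0 * MC2) / (Ep + 2.0 * MC2));
          deflect(rng, dir, cp);
          E = Ep;
        } else if (ev == 3) {
          E = TIER_EV; // continue in tier 1
        }
      } else {
        // ---- tier 1: event by event
        double si = tb.interp(tb.iontot, E);
        double sx = tb.interp(tb.exctot, E);
        double se = tb.interp(tb.el, E);
        double stot = si + sx + se;
        double lam = CM2UM / (NMOL * stot);
        double s = -lam * std::log(rng.unif());
        pos.x += s * dir.x; pos.y += s * dir.y; pos.z += s * dir.z;
        double u = rng.unif() * stot;
        if (u < se) {
          deflect(rng, dir, sampleElastic(rng, E));
        } else if (u < se + sx) {
          // pick excitation channel
          double v = rng.unif();
          double acc = 0.0, tot = 0.0;
          double sig[NXC];
          for (int k = 0; k < NXC; ++k) { sig[k] = sigEXC(E, k); tot += sig[k]; }
          int k = 0;
          if (tot > 0.0) {
            k = NXC - 1;
            for (int q = 0; q < NXC; ++q) {
              acc += sig[q] / tot;
              if (v <= acc) { k = q; break; }
            }
          }
          double de = std::min(EXC[k], E);
          sc.deposit(pos, de);
          edep += de;
          E -= de;
        } else {
          // ionization: pick shell
          double v = rng.unif() * si;
          double acc = 0.0;
          int j = 0;
          for (int q = 0; q < NSH; ++q) {
            acc += tb.interp(tb.ion[q], E);
            if (v <= acc) { j = q; break; }
            j = q;
          }
          if (E <= BSH[j]) { // interpolation edge: treat as excitation-like
            sc.deposit(pos, E);
            edep += E;
            E = 0.0;
            break;
          }
          double W = sampleBEB(rng, E, j);
          double B = BSH[j];
          if (W + B > E) W = E - B;
          sc.deposit(pos, B);
          edep += B;
          E -= (W + B);
          if (W > killE && W >= EXC[0]) {
            double cd = std::sqrt((W / (E + W + B)) *
                                  ((E + W + B) + 2.0 * MC2) / (W + 2.0 * MC2));
            Vec3 sd = dir;
            deflect(rng, sd, cd);
            stack.push_back({W, pos, sd});
          } else {
            sc.deposit(pos, W);
            edep += W;
          }
        }
      }
    }
  }
  return edep;
}

// --------------------------------------------------------- decay source ----
struct Scheme {
  std::vector<double> lineE;   // eV
  std::vector<double> lineY;
  std::vector<int> lineCat;    // 0 AE, 1 CE
  std::vector<int> linePart;   // 0 first part (e.g. Pd103), 1 second (Rh103m)
  // betas: inverse-CDF tables (eV), one column per beta branch
  std::vector<std::vector<double>> betaQ;
  std::vector<double> betaY;
  std::vector<int> betaPart;
};

inline int rpoisKnuth(Rng& r, double lam) {
  double L = std::exp(-lam), p = 1.0;
  int k = 0;
  do { ++k; p *= r.unif(); } while (p > L);
  return k - 1;
}

// emit one decay's worth of electrons into the transport; returns released energy
double simulateDecay(Rng& rng, Scorer& sc, const Scheme& sch, const Vec3& src,
                     double cutoff, int expected) {
  double released = 0.0;
  size_t nl = sch.lineE.size();
  for (size_t i = 0; i < nl; ++i) {
    int k;
    double w;
    if (expected) { k = 1; w = sch.lineY[i]; }
    else { k = rpoisKnuth(rng, sch.lineY[i]); w = 1.0; }
    for (int q = 0; q < k; ++q) {
      Vec3 d;
      isotropic(rng, d);
      sc.cat = sch.lineCat[i];
      sc.part = sch.linePart[i];
      sc.weight = w;
      transportCascade(rng, sc, sch.lineE[i], src, d, cutoff);
      released += sch.lineE[i] * w;
    }
  }
  for (size_t b = 0; b < sch.betaY.size(); ++b) {
    int k;
    double w;
    if (expected) { k = 1; w = sch.betaY[b]; }
    else { k = rpoisKnuth(rng, sch.betaY[b]); w = 1.0; }
    for (int q = 0; q < k; ++q) {
      const std::vector<double>& Q = sch.betaQ[b];
      double u = rng.unif() * (Q.size() - 1);
      int i0 = (int)u;
      if (i0 >= (int)Q.size() - 1) i0 = Q.size() - 2;
      double E = Q[i0] + (u - i0) * (Q[i0 + 1] - Q[i0]);
      if (E <= 0.0) continue;
      Vec3 d;
      isotropic(rng, d);
      sc.cat = 2;
      sc.part = sch.betaPart[b];
      sc.weight = w;
      transportCascade(rng, sc, E, src, d, cutoff);
      released += E * w;
    }
  }
  return released;
}

Scheme schemeFromR(const List& sch) {
  Scheme s;
  NumericVector E = sch["line_energy_ev"];
  NumericVector Y = sch["line_yield"];
  IntegerVector C = sch["line_cat"];
  IntegerVector P = sch["line_part"];
  s.lineE = std::vector<double>(E.begin(), E.end());
  s.lineY = std::vector<double>(Y.begin(), Y.end());
  s.lineCat = std::vector<int>(C.begin(), C.end());
  s.linePart = std::vector<int>(P.begin(), P.end());
  if (sch.containsElementNamed("beta_yield")) {
    NumericVector by = sch["beta_yield"];
    IntegerVector bp = sch["beta_part"];
    NumericMatrix bq = sch["beta_quantiles_ev"]; // nq x nbeta
    for (int b = 0; b < by.size(); ++b) {
      s.betaY.push_back(by[b]);
      s.betaPart.push_back(bp[b]);
      std::vector<double> col(bq.nrow());
      for (int i = 0; i < bq.nrow(); ++i) col[i] = bq(i, b);
      s.betaQ.push_back(col);
    }
  }
  return s;
}

// source position sampling
// dist: 0 point at origin, 1 uniform sphere(R), 2 cell surface, 3 cytoplasm,
//       4 nucleus (cell-relative draws are offset by the source cell center)
Vec3 samplePosition(Rng& rng, int dist, double R, const Geom& g, int cell) {
  Vec3 p = {0, 0, 0};
  if (dist == 0) return p;
  if (dist == 1) {
    double r = R * std::cbrt(rng.unif());
    Vec3 d; isotropic(rng, d);
    return {r * d.x, r * d.y, r * d.z};
  }
  double cx = g.cx[cell], cy = g.cy[cell], cz = g.cz[cell];
  Vec3 d; isotropic(rng, d);
  double r;
  if (dist == 2) r = RCELL;
  else if (dist == 3) {
    double a3 = RNUC * RNUC * RNUC, b3 = RMEM * RMEM * RMEM;
    r = std::cbrt(a3 + rng.unif() * (b3 - a3));
  } else {
    r = RNUC * std::cbrt(rng.unif());
  }
  return {cx + r * d.x, cy + r * d.y, cz + r * d.z};
}

} // namespace

// ============================================================ exports ======

// [[Rcpp::export]]
NumericVector cpp_stopping_power(NumericVector energy_keV) {
  const Tables& tb = tables();
  NumericVector out(energy_keV.size());
  for (int i = 0; i < energy_keV.size(); ++i)
    out[i] = tb.interp(tb.spmod, energy_keV[i] * 1000.0) / 1000.0; // keV/um
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_csda_range(NumericVector energy_keV) {
  const Tables& tb = tables();
  NumericVector out(energy_keV.size());
  for (int i = 0; i < energy_keV.size(); ++i)
    out[i] = tb.interp(tb.csda, energy_keV[i] * 1000.0);
  return out;
}

// [[Rcpp::export]]
List cpp_transport_electron(double energy_keV, NumericVector origin,
                            NumericVector direction, double cutoff_eV,
                            int seed, int stream) {
  std::vector<double> x, y, z, e;
  Scorer sc;
  sc.mode = 0;
  sc.evx = &x; sc.evy = &y; sc.evz = &z; sc.eve = &e;
  Rng rng(Rng::key((uint64_t)seed, (uint64_t)stream, 0x7261646fULL));
  Vec3 pos = {origin[0], origin[1], origin[2]};
  Vec3 dir = {direction[0], direction[1], direction[2]};
  double E = energy_keV * 1000.0;
  double edep;
  if (E <= cutoff_eV) {
    x.push_back(pos.x); y.push_back(pos.y); z.push_back(pos.z); e.push_back(E);
    edep = E;
  } else {
    edep = transportCascade(rng, sc, E, pos, dir, cutoff_eV);
  }
  return List::create(_["x_um"] = x, _["y_um"] = y, _["z_um"] = z,
                      _["edep_eV"] = e, _["edep_total_eV"] = edep);
}

// [[Rcpp::export]]
List cpp_radial_profile(List scheme, int n_histories, double shell_um,
                        int n_shells, double cutoff_eV, int seed,
                        int expected_mode) {
  Scheme sch = schemeFromR(scheme);
  std::vector<double> bins(n_shells + 1, 0.0);
  Scorer sc;
  sc.mode = 1;
  sc.inv_shell = 1.0 / shell_um;
  sc.nshell = n_shells;
  sc.rbins = bins.data();
  double released = 0.0;
  Vec3 origin = {0, 0, 0};
  for (int h = 0; h < n_histories; ++h) {
    Rng rng(Rng::key((uint64_t)seed, 0, (uint64_t)h));
    released += simulateDecay(rng, sc, sch, origin, cutoff_eV, expected_mode);
    if ((h & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["energy_eV"] = NumericVector(bins.begin(), bins.end()),
                      _["released_eV"] = released);
}

// [[Rcpp::export]]
List cpp_run_histories(List scheme, int geom_kind, double sphere_R,
                       NumericMatrix centers, int dist, int source_cell,
                       int n_histories, int n_batches, double cutoff_eV,
                       int seed, int stream_key, int expected_mode) {
  Scheme sch = schemeFromR(scheme);
  Geom g;
  g.kind = geom_kind;
  g.R = sphere_R;
  if (geom_kind == 2) {
    for (int i = 0; i < centers.nrow(); ++i) {
      g.cx.push_back(centers(i, 0));
      g.cy.push_back(centers(i, 1));
      g.cz.push_back(centers(i, 2));
    }
  }
  int nbins = (geom_kind == 1) ? 2 : 1 + 3 * (int)g.cx.size();
  int slab = nbins * 3 * 2;
  std::vector<double> tally((size_t)slab * n_batches, 0.0);
  std::vector<double> released(n_batches, 0.0);

  Scorer sc;
  sc.mode = 2;
  sc.geom = &g;
  sc.nbins = nbins;

  for (int h = 0; h < n_histories; ++h) {
    int b = (int)((long long)h * n_batches / n_histories);
    sc.tally = tally.data() + (size_t)b * slab;
    Rng rng(Rng::key((uint64_t)seed, (uint64_t)stream_key, (uint64_t)h));
    Vec3 src = samplePosition(rng, dist, sphere_R, g, source_cell);
    released[b] += simulateDecay(rng, sc, sch, src, cutoff_eV, expected_mode);
    if ((h & 255) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector arr((size_t)slab * n_batches);
  std::copy(tally.begin(), tally.end(), arr.begin());
  arr.attr("dim") = IntegerVector::create(nbins, 3, 2, n_batches);
  return List::create(_["energy_eV"] = arr,
                      _["released_eV"] = NumericVector(released.begin(), released.end()),
                      _["n_histories"] = n_histories);
}

// [[Rcpp::export]]
List cpp_sample_source(int geom_kind, double sphere_R, NumericMatrix centers,
                       int dist, int source_cell, int n, int seed) {
  Geom g;
  g.kind = geom_kind;
  g.R = sphere_R;
  if (geom_kind == 2) {
    for (int i = 0; i < centers.nrow(); ++i) {
      g.cx.push_back(centers(i, 0));
      g.cy.push_back(centers(i, 1));
      g.cz.push_back(centers(i, 2));
    }
  }
  NumericMatrix out(n, 3);
  for (int h = 0; h < n; ++h) {
    Rng rng(Rng::key((uint64_t)seed, 0x736f7572ULL, (uint64_t)h));
    Vec3 p = samplePosition(rng, dist, sphere_R, g, source_cell);
    out(h, 0) = p.x; out(h, 1) = p.y; out(h, 2) = p.z;
  }
  return List::create(_["positions"] = out);
}
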