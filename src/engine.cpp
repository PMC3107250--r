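// Brownian-dynamics engine for the coarse-grained NPC model.
//
// Works entirely in reduced units: energy kT, length nm, time 0.1 ns.
// The overdamped update for a mobile bead is
//   x <- x + D F dt + N(0, 2 D dt)
// followed by rejection of moves that (a) overstretch a wormlike-chain
// segment (Ottinger's scheme) or (b) enter the rigid nuclear-envelope slab
// or leave the optional confinement box.
//
// Group codes: 0 pom anchor (immobile, no nonbonded terms), 1 scaffold,
// 2 central FG, 3 peripheral FG, 4 cargo body.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <cmath>
#include <cstdint>
#include <cstring>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded by splitmix64, polar-method normals.
// A single stream per run keeps batch runs reproducible from their seeds.

namespace {

// Fast double-precision exp: range reduction to |f| <= ln2/2 plus a
// degree-8 Taylor kernel (relative error ~1e-12), scaled by 2^k through the
// exponent bits. The pair loops are exp-bound, so this matters.
inline double fexp(double x) {
  double kd = std::nearbyint(x * 1.4426950408889634);
  double f = x - kd * 0.693147180559945286;
  f -= kd * 1.9082149292705877e-10; // tail of ln2
  double p = 1.0 + f * (1.0 + f * (0.5 + f * (1.0 / 6 + f * (1.0 / 24 +
             f * (1.0 / 120 + f * (1.0 / 720 + f * (1.0 / 5040 +
             f / 40320)))))));
  int64_t bits;
  std::memcpy(&bits, &p, 8);
  bits += (int64_t)kd << 52;
  std::memcpy(&p, &bits, 8);
  return p;
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
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
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool has_cache = false;
  double cache = 0.0;
  inline double normal() {
    if (has_cache) { has_cache = false; return cache; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(s2) / s2);
    cache = v * f; has_cache = true;
    return u * f;
  }
};

struct Wall {
  bool enabled = false;
  double y_lo = 0, y_hi = 0, r_waist = 0, r_entr = 0, margin = 0;
  bool box = false;
  double box_x = 0, box_ytop = 0, box_ybot = 0;
  inline double profile(double y) const {
    double mid = 0.5 * (y_lo + y_hi), half = 0.5 * (y_hi - y_lo);
    double t = (y - mid) / half;
    return r_waist + (r_entr - r_waist) * t * t;
  }
  inline bool forbidden_point(double x, double y) const {
    if (enabled && y >= y_lo && y <= y_hi &&
        std::fabs(x) >= profile(y) + margin) return true;
    if (box && (std::fabs(x) > box_x || y > box_ytop || y < box_ybot))
      return true;
    return false;
  }
  // Finite-size test: sample the sphere perimeter (8 points + center).
  inline bool forbidden_sphere(double x, double y, double R) const {
    if (forbidden_point(x, y)) return true;
    if (R <= 0) return false;
    static const double c45 = 0.70710678118654752;
    const double dx[8] = {1, c45, 0, -c45, -1, -c45, 0, c45};
    const double dy[8] = {0, c45, 1, c45, 0, -c45, -1, -c45};
    for (int k = 0; k < 8; ++k)
      if (forbidden_point(x + R * dx[k], y + R * dy[k])) return true;
    return false;
  }
};

struct Rules {
  double eps_ff, xi_ff, cut_h;
  double eps_rep, sigma, cut_rep;
};

struct CargoP {
  bool has = false;
  int idx = -1;          // 0-based bead index of the cargo body
  double radius = 0;
  std::vector<double> sx, sy; // body-fixed spot offsets
  double eps = 0, xi = 0, cutoff = 0;
};

struct Sys {
  int N = 0;
  std::vector<int> group;
  std::vector<char> mobile;
  std::vector<double> D;
  // bonds: i j k r0 ; angles: i j k ktheta theta0 ; wlc: i j Ls lp
  std::vector<double> bonds, angles, wlc;
  int nb = 0, na = 0, nw = 0;
  std::unordered_set<int64_t> excl;
  Rules rules;
  Wall wall;
  CargoP cargo;
  inline bool excluded(int i, int j) const {
    int a = i < j ? i : j, b = i < j ? j : i;
    return excl.count((int64_t)a * N + b) > 0;
  }
};

struct PairLists {
  std::vector<int> hp;      // central-FG/central-FG pairs (flattened i,j)
  std::vector<int> rp;      // all other nonbonded bead pairs (repulsion only)
  std::vector<int> cnb_fg;  // FG beads near cargo (spot interactions)
  std::vector<int> cnb_all; // beads near cargo (body repulsion)
  std::vector<double> refx, refy;
  double maxdisp = 0;
  bool valid = false;
};

struct Energies {
  double bond = 0, angle = 0, wlc = 0, hff = 0, hkf = 0, rep = 0;
};

inline int64_t cellkey(int cx, int cy) {
  return ((int64_t)(cx + 1000000) << 24) ^ (int64_t)(cy + 1000000);
}

void build_pairlists(const Sys& S, const std::vector<double>& X,
                     const std::vector<double>& Y, double skin,
                     PairLists& PL) {
  const double cut_h = S.rules.cut_h, cut_rep = S.rules.cut_rep;
  const double rh = cut_h + skin, rr = cut_rep + skin;
  const double rh2 = rh * rh, rr2 = rr * rr;
  const double cs = rh; // cell size
  PL.hp.clear(); PL.rp.clear(); PL.cnb_fg.clear(); PL.cnb_all.clear();
  std::unordered_map<int64_t, std::vector<int>> grid;
  grid.reserve(S.N * 2);
  for (int i = 0; i < S.N; ++i) {
    if (S.group[i] == 0 || S.group[i] == 4) continue;
    grid[cellkey((int)std::floor(X[i] / cs),
                 (int)std::floor(Y[i] / cs))].push_back(i);
  }
  for (const auto& kv : grid) {
    int cx = (int)((kv.first >> 24) - 1000000);
    int cy = (int)((kv.first & 0xffffff) - 1000000);
    // guard against sign issues: recompute from a member bead
    cx = (int)std::floor(X[kv.second[0]] / cs);
    cy = (int)std::floor(Y[kv.second[0]] / cs);
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        auto it = grid.find(cellkey(cx + dx, cy + dy));
        if (it == grid.end()) continue;
        const std::vector<int>& other = it->second;
        for (int a : kv.second) {
          for (int b : other) {
            if (b <= a) continue;
            double ddx = X[a] - X[b], ddy = Y[a] - Y[b];
            double r2 = ddx * ddx + ddy * ddy;
            bool hydro = (S.group[a] == 2 && S.group[b] == 2);
            if (hydro) {
              if (r2 < rh2 && !S.excluded(a, b)) {
                PL.hp.push_back(a); PL.hp.push_back(b);
              }
            } else if (r2 < rr2 && !S.excluded(a, b)) {
              PL.rp.push_back(a); PL.rp.push_back(b);
            }
          }
        }
      }
    }
  }
  if (S.cargo.has) {
    int c = S.cargo.idx;
    double rfg = S.cargo.cutoff + S.cargo.radius + skin;
    double rall = cut_rep + S.cargo.radius + skin;
    double rfg2 = rfg * rfg, rall2 = rall * rall;
    for (int i = 0; i < S.N; ++i) {
      if (i == c || S.group[i] == 0) continue;
      double ddx = X[i] - X[c], ddy = Y[i] - Y[c];
      double r2 = ddx * ddx + ddy * ddy;
      if ((S.group[i] == 2 || S.group[i] == 3) && r2 < rfg2)
        PL.cnb_fg.push_back(i);
      if (r2 < rall2) PL.cnb_all.push_back(i);
    }
  }
  PL.refx = X; PL.refy = Y; PL.maxdisp = 0; PL.valid = true;
}

// Contact record used for bond-lifetime bookkeeping: key = spot * N + bead.
// `participating` counts the binding spots with any FG motif inside the
// hydrophobic cutoff (the 'participation' statistic); `current` holds the
// tight contacts (within contact_radius) that define bond episodes.
struct Contacts {
  std::vector<int64_t> current;
  std::vector<char> spot_part;
  int participating = 0;
};

void compute_forces(const Sys& S, const std::vector<double>& X,
                    const std::vector<double>& Y, std::vector<double>& FX,
                    std::vector<double>& FY, Energies& E, const PairLists& PL,
                    bool all_pairs, double contact_radius, Contacts* contacts,
                    double* max_wlc_ratio) {
  const int N = S.N;
  std::fill(FX.begin(), FX.end(), 0.0);
  std::fill(FY.begin(), FY.end(), 0.0);
  E = Energies();

  // bonds (harmonic, includes pom springs and the distal-ring tie)
  for (int b = 0; b < S.nb; ++b) {
    int i = (int)S.bonds[4 * b], j = (int)S.bonds[4 * b + 1];
    double k = S.bonds[4 * b + 2], r0 = S.bonds[4 * b + 3];
    double dx = X[i] - X[j], dy = Y[i] - Y[j];
    double r = std::sqrt(dx * dx + dy * dy);
    if (r < 1e-12) {
      if (r0 > 0) stop("zero-length bond between overlapping beads");
      continue; // r0 = 0 well: force vanishes smoothly at the center
    }
    double dr = r - r0;
    E.bond += 0.5 * k * dr * dr;
    double f = -k * dr / r; // along (i-j); negative when stretched
    FX[i] += f * dx; FY[i] += f * dy;
    FX[j] -= f * dx; FY[j] -= f * dy;
  }

  // angles (cosine bending), theta at middle bead j; the trigonometry
  // comes from dot and cross products, with cos/sin(theta0) precomputed.
  for (int a = 0; a < S.na; ++a) {
    const double* A = &S.angles[7 * a];
    int i = (int)A[0], j = (int)A[1], k = (int)A[2];
    double kt = A[3], c0 = A[5], s0 = A[6];
    double ax = X[i] - X[j], ay = Y[i] - Y[j];
    double bx = X[k] - X[j], by = Y[k] - Y[j];
    double ra2 = ax * ax + ay * ay, rb2 = bx * bx + by * by;
    if (ra2 < 1e-24 || rb2 < 1e-24)
      stop("overlapping beads in bending angle");
    double ira = 1.0 / std::sqrt(ra2), irb = 1.0 / std::sqrt(rb2);
    double ct = (ax * bx + ay * by) * ira * irb;
    ct = std::max(-1.0, std::min(1.0, ct));
    double st = std::fabs(ax * by - ay * bx) * ira * irb; // sin, theta in [0,pi]
    E.angle += kt * (1.0 - (ct * c0 + st * s0));
    // dE/dtheta = kt sin(theta - theta0); force needs dEdT / sin(theta)
    if (st < 1e-8) {
      if (std::fabs(s0) > 1e-8) continue; // collinear: direction degenerate
      // theta0 at 0 or pi: dEdT/st -> kt * c0 smoothly
    }
    double g = (st < 1e-8) ? kt * c0 : kt * (st * c0 - ct * s0) / st;
    double iax = ax * ira, iay = ay * ira, ibx = bx * irb, iby = by * irb;
    FX[i] -= g * (ct * iax - ibx) * ira; FY[i] -= g * (ct * iay - iby) * ira;
    FX[k] -= g * (ct * ibx - iax) * irb; FY[k] -= g * (ct * iby - iay) * irb;
    FX[j] += g * ((ct * iax - ibx) * ira + (ct * ibx - iax) * irb);
    FY[j] += g * ((ct * iay - iby) * ira + (ct * iby - iay) * irb);
  }

  // wormlike-chain segments (Marko-Siggia)
  if (max_wlc_ratio) *max_wlc_ratio = 0.0;
  for (int w = 0; w < S.nw; ++w) {
    int i = (int)S.wlc[4 * w], j = (int)S.wlc[4 * w + 1];
    double Ls = S.wlc[4 * w + 2], lp = S.wlc[4 * w + 3];
    double dx = X[i] - X[j], dy = Y[i] - Y[j];
    double r = std::sqrt(dx * dx + dy * dy);
    double x = r / Ls;
    if (max_wlc_ratio && x > *max_wlc_ratio) *max_wlc_ratio = x;
    if (x >= 1.0)
      stop("WLC segment at or beyond its contour length (extensibility violation)");
    double om = 1.0 - x;
    E.wlc += (Ls / lp) * (0.25 / om - 0.25 - 0.25 * x + 0.5 * x * x);
    double fmag = (1.0 / lp) * (0.25 / (om * om) - 0.25 + x); // restoring
    if (r > 1e-12) {
      double f = -fmag / r;
      FX[i] += f * dx; FY[i] += f * dy;
      FX[j] -= f * dx; FY[j] -= f * dy;
    }
  }

  const Rules& R = S.rules;
  double shift_ff = std::exp(-R.cut_h / R.xi_ff);
  double shift_rep = std::exp(-R.cut_rep / R.sigma);
  double ch2 = R.cut_h * R.cut_h, cr2 = R.cut_rep * R.cut_rep;

  auto pair_hydro_ff = [&](int i, int j, double r2) {
    double r = std::sqrt(r2);
    double e = fexp(-r / R.xi_ff);
    E.hff -= R.eps_ff * (e - shift_ff);
    double f = -(R.eps_ff / R.xi_ff) * e / std::max(r, 1e-12);
    double dx = X[i] - X[j], dy = Y[i] - Y[j];
    FX[i] += f * dx; FY[i] += f * dy;
    FX[j] -= f * dx; FY[j] -= f * dy;
  };
  auto pair_rep = [&](int i, int j, double r2) {
    double r = std::sqrt(r2);
    double e = fexp(-r / R.sigma);
    E.rep += R.eps_rep * (e - shift_rep);
    double f = (R.eps_rep / R.sigma) * e / std::max(r, 1e-12);
    double dx = X[i] - X[j], dy = Y[i] - Y[j];
    FX[i] += f * dx; FY[i] += f * dy;
    FX[j] -= f * dx; FY[j] -= f * dy;
  };

  if (all_pairs) {
    for (int i = 0; i < N; ++i) {
      if (S.group[i] == 0 || S.group[i] == 4) continue;
      for (int j = i + 1; j < N; ++j) {
        if (S.group[j] == 0 || S.group[j] == 4) continue;
        if (S.excluded(i, j)) continue;
        double dx = X[i] - X[j], dy = Y[i] - Y[j];
        double r2 = dx * dx + dy * dy;
        if (S.group[i] == 2 && S.group[j] == 2 && r2 < ch2)
          pair_hydro_ff(i, j, r2);
        if (r2 < cr2) pair_rep(i, j, r2);
      }
    }
  } else {
    for (size_t p = 0; p < PL.hp.size(); p += 2) {
      int i = PL.hp[p], j = PL.hp[p + 1];
      double dx = X[i] - X[j], dy = Y[i] - Y[j];
      double r2 = dx * dx + dy * dy;
      if (r2 < ch2) pair_hydro_ff(i, j, r2);
      if (r2 < cr2) pair_rep(i, j, r2);
    }
    for (size_t p = 0; p < PL.rp.size(); p += 2) {
      int i = PL.rp[p], j = PL.rp[p + 1];
      double dx = X[i] - X[j], dy = Y[i] - Y[j];
      double r2 = dx * dx + dy * dy;
      if (r2 < cr2) pair_rep(i, j, r2);
    }
  }

  // cargo: binding-spot hydrophobics (force applied to the rigid body
  // center; the arc is body-fixed, no rotation) and body repulsion measured
  // center-to-surface.
  if (S.cargo.has) {
    const CargoP& C = S.cargo;
    int c = C.idx;
    int nspots = (int)C.sx.size();
    double shift_kf = std::exp(-C.cutoff / C.xi);
    double ck2 = C.cutoff * C.cutoff;
    double cr_rad2 = contact_radius * contact_radius;
    if (contacts) {
      contacts->current.clear();
      contacts->spot_part.assign(nspots, 0);
      contacts->participating = 0;
    }
    auto fg_loop = [&](int i) {
      for (int s = 0; s < nspots; ++s) {
        double sxp = X[c] + C.sx[s], syp = Y[c] + C.sy[s];
        double dx = sxp - X[i], dy = syp - Y[i];
        double r2 = dx * dx + dy * dy;
        if (r2 < ck2) {
          double r = std::sqrt(r2);
          double e = fexp(-r / C.xi);
          E.hkf -= C.eps * (e - shift_kf);
          double f = -(C.eps / C.xi) * e / std::max(r, 1e-12);
          FX[c] += f * dx; FY[c] += f * dy;
          FX[i] -= f * dx; FY[i] -= f * dy;
          if (contacts) {
            contacts->spot_part[s] = 1;
            if (r2 < cr_rad2)
              contacts->current.push_back((int64_t)s * N + i);
          }
        }
      }
    };
    auto body_rep = [&](int i) {
      double dx = X[c] - X[i], dy = Y[c] - Y[i];
      double r = std::sqrt(dx * dx + dy * dy);
      double reff = r - C.radius;
      if (reff < R.cut_rep) {
        double e = fexp(-reff / R.sigma);
        E.rep += R.eps_rep * (e - shift_rep);
        double f = (R.eps_rep / R.sigma) * e / std::max(r, 1e-12);
        FX[c] += f * dx; FY[c] += f * dy;
        FX[i] -= f * dx; FY[i] -= f * dy;
      }
    };
    if (all_pairs) {
      for (int i = 0; i < N; ++i) {
        if (i == c || S.group[i] == 0) continue;
        if (S.group[i] == 2 || S.group[i] == 3) fg_loop(i);
        body_rep(i);
      }
    } else {
      for (int i : PL.cnb_fg) fg_loop(i);
      for (int i : PL.cnb_all) body_rep(i);
    }
    if (contacts) {
      for (int s = 0; s < nspots; ++s)
        contacts->participating += contacts->spot_part[s];
    }
  }
}

Sys unpack_sys(const NumericMatrix& pos, const IntegerVector& group,
               const LogicalVector& mobile, const NumericVector& D,
               const NumericMatrix& bonds, const NumericMatrix& angles,
               const NumericMatrix& wlcm, const IntegerMatrix& excl,
               const List& rules, const List& wall, const List& cargo) {
  Sys S;
  S.N = pos.nrow();
  S.group.assign(group.begin(), group.end());
  S.mobile.resize(S.N);
  for (int i = 0; i < S.N; ++i) S.mobile[i] = mobile[i] ? 1 : 0;
  S.D.resize(S.N);
  for (int i = 0; i < S.N; ++i) S.D[i] = D.size() == S.N ? D[i] : 0.0;
  S.nb = bonds.nrow(); S.na = angles.nrow(); S.nw = wlcm.nrow();
  S.bonds.resize(4 * S.nb);
  for (int b = 0; b < S.nb; ++b) {
    S.bonds[4 * b] = bonds(b, 0) - 1; S.bonds[4 * b + 1] = bonds(b, 1) - 1;
    S.bonds[4 * b + 2] = bonds(b, 2); S.bonds[4 * b + 3] = bonds(b, 3);
  }
  S.angles.resize(7 * S.na);
  for (int a = 0; a < S.na; ++a) {
    S.angles[7 * a] = angles(a, 0) - 1;
    S.angles[7 * a + 1] = angles(a, 1) - 1;
    S.angles[7 * a + 2] = angles(a, 2) - 1;
    S.angles[7 * a + 3] = angles(a, 3);
    S.angles[7 * a + 4] = angles(a, 4);
    S.angles[7 * a + 5] = std::cos(angles(a, 4));
    S.angles[7 * a + 6] = std::sin(angles(a, 4));
  }
  S.wlc.resize(4 * S.nw);
  for (int w = 0; w < S.nw; ++w) {
    S.wlc[4 * w] = wlcm(w, 0) - 1; S.wlc[4 * w + 1] = wlcm(w, 1) - 1;
    S.wlc[4 * w + 2] = wlcm(w, 2); S.wlc[4 * w + 3] = wlcm(w, 3);
  }
  for (int e = 0; e < excl.nrow(); ++e) {
    int a = excl(e, 0) - 1, b = excl(e, 1) - 1;
    if (a > b) std::swap(a, b);
    S.excl.insert((int64_t)a * S.N + b);
  }
  S.rules.eps_ff = as<double>(rules["eps_ff"]);
  S.rules.xi_ff = as<double>(rules["xi_ff"]);
  S.rules.cut_h = as<double>(rules["cut_h"]);
  S.rules.eps_rep = as<double>(rules["eps_rep"]);
  S.rules.sigma = as<double>(rules["sigma"]);
  S.rules.cut_rep = as<double>(rules["cut_rep"]);
  S.wall.enabled = as<bool>(wall["enabled"]);
  if (S.wall.enabled) {
    S.wall.y_lo = as<double>(wall["y_lo"]);
    S.wall.y_hi = as<double>(wall["y_hi"]);
    S.wall.r_waist = as<double>(wall["r_waist"]);
    S.wall.r_entr = as<double>(wall["r_entr"]);
    S.wall.margin = as<double>(wall["margin"]);
  }
  S.wall.box = as<bool>(wall["box"]);
  if (S.wall.box) {
    S.wall.box_x = as<double>(wall["box_x"]);
    S.wall.box_ytop = as<double>(wall["box_ytop"]);
    S.wall.box_ybot = as<double>(wall["box_ybot"]);
  }
  S.cargo.has = as<bool>(cargo["has"]);
  if (S.cargo.has) {
    S.cargo.idx = as<int>(cargo["idx"]) - 1;
    S.cargo.radius = as<double>(cargo["radius"]);
    NumericMatrix sp = cargo["spots"];
    for (int s = 0; s < sp.nrow(); ++s) {
      S.cargo.sx.push_back(sp(s, 0));
      S.cargo.sy.push_back(sp(s, 1));
    }
    S.cargo.eps = as<double>(cargo["eps"]);
    S.cargo.xi = as<double>(cargo["xi"]);
    S.cargo.cutoff = as<double>(cargo["cutoff"]);
  }
  return S;
}

} // namespace

// [[Rcpp::export]]
List cpp_total_forces(NumericMatrix pos, IntegerVector group,
                      LogicalVector mobile, NumericVector D,
                      NumericMatrix bonds, NumericMatrix angles,
                      NumericMatrix wlc, IntegerMatrix excl, List rules,
                      List wall, List cargo, bool use_neighbor_list = false,
                      double skin = 2.0) {
  Sys S = unpack_sys(pos, group, mobile, D, bonds, angles, wlc, excl, rules,
                     wall, cargo);
  std::vector<double> X(S.N), Y(S.N), FX(S.N), FY(S.N);
  for (int i = 0; i < S.N; ++i) { X[i] = pos(i, 0); Y[i] = pos(i, 1); }
  PairLists PL;
  if (use_neighbor_list) build_pairlists(S, X, Y, skin, PL);
  Energies E;
  double maxr = 0;
  compute_forces(S, X, Y, FX, FY, E, PL, !use_neighbor_list, 0.0, nullptr,
                 &maxr);
  NumericMatrix F(S.N, 2);
  for (int i = 0; i < S.N; ++i) { F(i, 0) = FX[i]; F(i, 1) = FY[i]; }
  return List::create(
      _["forces"] = F,
      _["energy"] = NumericVector::create(
          _["bond"] = E.bond, _["angle"] = E.angle, _["wlc"] = E.wlc,
          _["hydrophobic_fg_fg"] = E.hff, _["hydrophobic_kap_fg"] = E.hkf,
          _["repulsive"] = E.rep),
      _["max_wlc_ratio"] = maxr);
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, IntegerVector group, LogicalVector mobile,
             NumericVector D, NumericMatrix bonds, NumericMatrix angles,
             NumericMatrix wlc, IntegerMatrix excl, List rules, List wall,
             List cargo, List control) {
  Sys S = unpack_sys(pos, group, mobile, D, bonds, angles, wlc, excl, rules,
                     wall, cargo);
  const int N = S.N;
  const double dt = as<double>(control["dt"]);
  const double fmax = as<double>(control["f_max"]);
  const long nsteps = (long)as<double>(control["n_steps"]);
  const int sample_every = as<int>(control["sample_every"]);
  const bool noise = as<bool>(control["noise"]);
  const double skin = as<double>(control["skin"]);
  const uint64_t seed = (uint64_t)as<double>(control["seed"]);
  const double contact_radius = as<double>(control["contact_radius"]);
  const bool record_log = as<bool>(control["record_contact_log"]);
  const bool detect = as<bool>(control["detect_events"]);
  const bool stop_on_end = as<bool>(control["stop_on_end"]);
  const double y_basket_top = as<double>(control["y_basket_top"]);
  const double y_basket_bottom = as<double>(control["y_basket_bottom"]);
  LogicalVector filament_fg = control["filament_fg"];
  int track_bead = as<int>(control["track_bead"]) - 1; // -2 => cargo if any
  if (track_bead < 0 && S.cargo.has) track_bead = S.cargo.idx;

  Xoshiro rng(seed);
  std::vector<double> X(N), Y(N), FX(N), FY(N), PX(N), PY(N);
  for (int i = 0; i < N; ++i) { X[i] = pos(i, 0); Y[i] = pos(i, 1); }

  PairLists PL;
  Energies E;
  Contacts contacts;
  std::unordered_map<int64_t, long> open_epi;
  std::vector<double> epi_rows; // spot, motif, start, end
  std::vector<double> log_rows; // step, spot, motif
  std::vector<double> track;    // step, x, y, engaged
  long t_start = -1, t_end = -1;
  double occupancy_sum = 0; long engaged_steps = 0;
  double min_y = R_PosInf;
  double max_wlc_seen = 0;
  long n_rej_wlc = 0, n_rej_wall = 0;
  long step = 0;

  const double ck2 = S.cargo.has ? S.cargo.cutoff * S.cargo.cutoff : 0.0;

  // sample initial state
  auto sample_row = [&](long st) {
    if (track_bead >= 0) {
      track.push_back((double)st);
      track.push_back(X[track_bead]);
      track.push_back(Y[track_bead]);
      track.push_back(S.cargo.has ? (double)contacts.participating : 0.0);
    }
  };

  for (step = 0; step < nsteps; ++step) {
    if (!PL.valid || 2.0 * PL.maxdisp > skin)
      build_pairlists(S, X, Y, skin, PL);

    double maxr = 0;
    compute_forces(S, X, Y, FX, FY, E, PL, false, contact_radius,
                   S.cargo.has ? &contacts : nullptr, &maxr);
    if (maxr > max_wlc_seen) max_wlc_seen = maxr;

    if (step % sample_every == 0) sample_row(step);

    // contact bookkeeping: maximal runs of consecutive in-contact steps
    if (S.cargo.has) {
      std::unordered_set<int64_t> cur(contacts.current.begin(),
                                      contacts.current.end());
      for (auto it = open_epi.begin(); it != open_epi.end();) {
        if (!cur.count(it->first)) {
          epi_rows.push_back((double)(it->first / N));
          epi_rows.push_back((double)(it->first % N));
          epi_rows.push_back((double)it->second);
          epi_rows.push_back((double)(step - 1));
          it = open_epi.erase(it);
        } else ++it;
      }
      for (int64_t key : contacts.current)
        if (!open_epi.count(key)) open_epi[key] = step;
      if (contacts.participating > 0) {
        occupancy_sum += (double)contacts.participating;
        ++engaged_steps;
      }
      if (record_log) {
        for (int64_t key : contacts.current) {
          log_rows.push_back((double)step);
          log_rows.push_back((double)(key / N));
          log_rows.push_back((double)(key % N));
        }
      }
    }

    // event detection
    if (detect && S.cargo.has) {
      int c = S.cargo.idx;
      if (Y[c] < min_y) min_y = Y[c];
      if (t_start < 0 && !S.cargo.sx.empty()) {
        for (int i : PL.cnb_fg) {
          if (!filament_fg[i]) continue;
          bool hit = false;
          for (size_t s = 0; s < S.cargo.sx.size(); ++s) {
            double dx = X[c] + S.cargo.sx[s] - X[i];
            double dy = Y[c] + S.cargo.sy[s] - Y[i];
            if (dx * dx + dy * dy < ck2) { hit = true; break; }
          }
          if (hit) { t_start = step; break; }
        }
      }
      if (Y[c] + S.cargo.radius <= y_basket_top &&
          Y[c] - S.cargo.radius >= y_basket_bottom) {
        if (t_end < 0) t_end = step;
        if (stop_on_end) { ++step; break; }
      }
    }

    // propose
    double sf = noise ? 1.0 : 0.0;
    for (int i = 0; i < N; ++i) {
      if (!S.mobile[i]) { PX[i] = X[i]; PY[i] = Y[i]; continue; }
      double amp = sf * std::sqrt(2.0 * S.D[i] * dt);
      PX[i] = X[i] + S.D[i] * FX[i] * dt + amp * rng.normal();
      PY[i] = Y[i] + S.D[i] * FY[i] * dt + amp * rng.normal();
      if (!std::isfinite(PX[i]) || !std::isfinite(PY[i]))
        stop("non-finite force/displacement at step %ld, bead %d", step, i + 1);
    }

    // wall / box rejection
    if (S.wall.enabled || S.wall.box) {
      for (int i = 0; i < N; ++i) {
        if (!S.mobile[i]) continue;
        double R = (S.cargo.has && i == S.cargo.idx) ? S.cargo.radius : 0.0;
        bool bad = R > 0 ? S.wall.forbidden_sphere(PX[i], PY[i], R)
                         : S.wall.forbidden_point(PX[i], PY[i]);
        if (bad) { PX[i] = X[i]; PY[i] = Y[i]; ++n_rej_wall; }
      }
    }

    // Ottinger rejection: revert every bead whose move would push an
    // adjacent WLC segment to >= fmax * Ls; iterate to a fixed point.
    for (int pass = 0; pass < 50; ++pass) {
      bool any = false;
      for (int w = 0; w < S.nw; ++w) {
        int i = (int)S.wlc[4 * w], j = (int)S.wlc[4 * w + 1];
        double Ls = S.wlc[4 * w + 2];
        double dx = PX[i] - PX[j], dy = PY[i] - PY[j];
        if (dx * dx + dy * dy >= fmax * fmax * Ls * Ls) {
          bool moved_i = (PX[i] != X[i] || PY[i] != Y[i]);
          bool moved_j = (PX[j] != X[j] || PY[j] != Y[j]);
          if (moved_i) { PX[i] = X[i]; PY[i] = Y[i]; ++n_rej_wlc; any = true; }
          if (moved_j) { PX[j] = X[j]; PY[j] = Y[j]; ++n_rej_wlc; any = true; }
          if (!moved_i && !moved_j)
            stop("WLC invariant violated in the accepted state");
        }
      }
      if (!any) break;
    }

    double md = PL.maxdisp;
    for (int i = 0; i < N; ++i) {
      if (!S.mobile[i]) continue;
      X[i] = PX[i]; Y[i] = PY[i];
      double ddx = X[i] - PL.refx[i], ddy = Y[i] - PL.refy[i];
      double d = std::sqrt(ddx * ddx + ddy * ddy);
      if (d > md) md = d;
    }
    PL.maxdisp = md;
  }

  // close open episodes at the last simulated step
  for (const auto& kv : open_epi) {
    epi_rows.push_back((double)(kv.first / N));
    epi_rows.push_back((double)(kv.first % N));
    epi_rows.push_back((double)kv.second);
    epi_rows.push_back((double)(step - 1));
  }
  sample_row(step);

  NumericMatrix fpos(N, 2);
  for (int i = 0; i < N; ++i) { fpos(i, 0) = X[i]; fpos(i, 1) = Y[i]; }
  int ntr = (int)(track.size() / 4);
  NumericMatrix trm(ntr, 4);
  for (int r = 0; r < ntr; ++r)
    for (int c2 = 0; c2 < 4; ++c2) trm(r, c2) = track[4 * r + c2];
  colnames(trm) = CharacterVector::create("step", "x", "y", "engaged_spots");
  int nep = (int)(epi_rows.size() / 4);
  NumericMatrix epm(nep, 4);
  for (int r = 0; r < nep; ++r)
    for (int c2 = 0; c2 < 4; ++c2) epm(r, c2) = epi_rows[4 * r + c2];
  colnames(epm) = CharacterVector::create("spot", "motif", "start", "end");
  int nlg = (int)(log_rows.size() / 3);
  NumericMatrix lgm(nlg, 3);
  for (int r = 0; r < nlg; ++r)
    for (int c2 = 0; c2 < 3; ++c2) lgm(r, c2) = log_rows[3 * r + c2];
  colnames(lgm) = CharacterVector::create("step", "spot", "motif");

  return List::create(
      _["positions"] = fpos, _["track"] = trm, _["episodes"] = epm,
      _["contact_log"] = lgm, _["steps_run"] = (double)step,
      _["t_start"] = (double)t_start, _["t_end"] = (double)t_end,
      _["occupancy_sum"] = occupancy_sum,
      _["engaged_steps"] = (double)engaged_steps,
      _["min_y"] = min_y, _["max_wlc_ratio"] = max_wlc_seen,
      _["n_rejected_wlc"] = (double)n_rej_wlc,
      _["n_rejected_wall"] = (double)n_rej_wall);
}
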