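// Compiled cores for the pairwise electrostatic evaluators, the plain Ewald
// reference, and the toy force field.  Pair enumeration is direct O(n^2):
// the package targets desk-scale systems (<= a few thousand particles) whose
// boxes are only two to three cutoffs wide.
//
// Unit conventions (fixed package-wide): positions in Angstrom, charges in
// elementary charge units, energies in kcal/mol once multiplied by the
// Coulomb constant passed in from R.

#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

static const double SQRT_PI = 1.7724538509055160273;

// key for an unordered pair (i < j), 0-based
static inline long long pair_key(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * (long long)n + (long long)j;
}

typedef std::unordered_map<long long, double> PairMap;

// exclusion table: weight w applies to the bare 1/r part only
// (w = 0 full 1-2/1-3 exclusion, 0 < w < 1 scaled 1-4)
static PairMap build_pair_map(const IntegerMatrix& excl,
                              const NumericVector& w, int n) {
  PairMap m;
  for (int k = 0; k < excl.nrow(); ++k)
    m[pair_key(excl(k, 0), excl(k, 1), n)] = w[k];
  return m;
}

struct Box {
  bool periodic;
  double L[3];
};

static Box make_box(const NumericVector& box) {
  Box b;
  b.periodic = box.size() == 3;
  for (int d = 0; d < 3; ++d) b.L[d] = b.periodic ? box[d] : 0.0;
  return b;
}

// minimum-image displacement j -> i
static inline void min_image(const Box& b, double* dx) {
  if (!b.periodic) return;
  for (int d = 0; d < 3; ++d) {
    double L = b.L[d];
    dx[d] -= L * std::round(dx[d] / L);
  }
}

// ---------------------------------------------------------------------------
// cutoff kernels: u(r) and -du/dr for zd / wolf / shifted-force
// method codes: 1 = zd, 2 = wolf, 3 = shifted_force
// ---------------------------------------------------------------------------

struct KernelCoef {
  int method;
  double alpha, rc;
  double A, B;      // zd completion coefficients
  double shift;     // wolf potential shift f(rc)
  double self;      // per-particle self coefficient (times q_i^2)
};

static KernelCoef kernel_setup(int method, double alpha, double rc) {
  KernelCoef kc;
  kc.method = method;
  kc.alpha = alpha;
  kc.rc = rc;
  double frc = std::erfc(alpha * rc) / rc;
  double dfrc = -std::erfc(alpha * rc) / (rc * rc)
    - (2.0 * alpha / SQRT_PI) * std::exp(-alpha * alpha * rc * rc) / rc;
  if (method == 1) {            // zero-dipole
    kc.A = -dfrc / (2.0 * rc);
    kc.B = -frc - kc.A * rc * rc;
    kc.shift = 0.0;
    kc.self = kc.B / 2.0 - alpha / SQRT_PI;
  } else if (method == 2) {     // zero-charge Wolf
    kc.A = 0.0;
    kc.B = -frc;
    kc.shift = frc;
    kc.self = -frc / 2.0 - alpha / SQRT_PI;
  } else {                      // shifted force (purely pairwise, no self)
    kc.A = 0.0;
    kc.B = 0.0;
    kc.shift = 0.0;
    kc.self = 0.0;
  }
  return kc;
}

static inline double kernel_u(const KernelCoef& kc, double r) {
  switch (kc.method) {
  case 1:
    if (kc.alpha == 0.0)
      return 1.0 / r + kc.A * r * r + kc.B;
    return std::erfc(kc.alpha * r) / r + kc.A * r * r + kc.B;
  case 2:
    if (kc.alpha == 0.0) return 1.0 / r - kc.shift;
    return std::erfc(kc.alpha * r) / r - kc.shift;
  default: {
    double rc = kc.rc;
    return 1.0 / r - 1.0 / rc + (r - rc) / (rc * rc);
  }
  }
}

// du/dr
static inline double kernel_du(const KernelCoef& kc, double r) {
  double a = kc.alpha;
  double base;
  if (a == 0.0) {
    base = -1.0 / (r * r);
  } else {
    base = -std::erfc(a * r) / (r * r)
      - (2.0 * a / SQRT_PI) * std::exp(-a * a * r * r) / r;
  }
  switch (kc.method) {
  case 1: return base + 2.0 * kc.A * r;
  case 2: return base;
  default: return -1.0 / (r * r) + 1.0 / (kc.rc * kc.rc);
  }
}

// [[Rcpp::export]]
List cpp_pair_electro(NumericMatrix pos, NumericVector q, NumericVector box,
                      double rc, double alpha, int method,
                      IntegerMatrix excl, NumericVector exclw,
                      double coulomb, bool want_forces) {
  int n = pos.nrow();
  Box b = make_box(box);
  KernelCoef kc = kernel_setup(method, alpha, rc);
  PairMap em = build_pair_map(excl, exclw, n);

  NumericVector per_atom(n);
  NumericMatrix F(want_forces ? n : 1, 3);
  double pair_sum = 0.0, excl_sum = 0.0, self_sum = 0.0;

  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx[3];
      for (int d = 0; d < 3; ++d) dx[d] = pos(i, d) - pos(j, d);
      min_image(b, dx);
      double r2 = dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2];
      if (r2 >= rc * rc) continue;
      double r = std::sqrt(r2);
      double qq = q[i] * q[j];
      PairMap::const_iterator it = em.find(pair_key(i, j, n));
      double e, du;
      if (it == em.end()) {
        e = qq * kernel_u(kc, r);
        du = qq * kernel_du(kc, r);
        pair_sum += e;
      } else {
        // completion terms retained; bare Coulomb removed / rescaled
        double w = it->second;
        e = qq * (kernel_u(kc, r) - (1.0 - w) / r);
        du = qq * (kernel_du(kc, r) + (1.0 - w) / r2);
        excl_sum += e;
      }
      per_atom[i] += 0.5 * e;
      per_atom[j] += 0.5 * e;
      if (want_forces) {
        double fmag = -du / r;       // F_i = -du/dr * rhat_ij
        for (int d = 0; d < 3; ++d) {
          F(i, d) += fmag * dx[d];
          F(j, d) -= fmag * dx[d];
        }
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    double e = kc.self * q[i] * q[i];
    self_sum += e;
    per_atom[i] += e;
  }

  double total = coulomb * (pair_sum + excl_sum + self_sum);
  for (int i = 0; i < n; ++i) per_atom[i] *= coulomb;
  if (want_forces)
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) F(i, d) *= coulomb;

  return List::create(_["total"] = total, _["per_atom"] = per_atom,
                      _["pair"] = coulomb * pair_sum,
                      _["self"] = coulomb * self_sum,
                      _["exclusion"] = coulomb * excl_sum,
                      _["forces"] = want_forces ? F : NumericMatrix(0, 3));
}

// ---------------------------------------------------------------------------
// RESA: residue-based cutoff of the bare Coulomb potential.  All atoms of a
// residue interact with atom i if any atom of that residue lies within rc of
// i; the asymmetric double sum is halved, so one-sided pairs get half weight.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_resa(NumericMatrix pos, NumericVector q, NumericVector box,
              double rc, IntegerVector resid0, IntegerMatrix excl,
              NumericVector exclw, double coulomb, bool want_forces) {
  int n = pos.nrow();
  Box b = make_box(box);
  PairMap em = build_pair_map(excl, exclw, n);
  int nres = 0;
  for (int i = 0; i < n; ++i) nres = std::max(nres, resid0[i] + 1);

  // visibility: vis[i * nres + R] = residue R has an atom within rc of i
  std::vector<char> vis((size_t)n * nres, 0);
  for (int i = 0; i < n; ++i) {
    vis[(size_t)i * nres + resid0[i]] = 1;   // own residue always counted
    for (int j = i + 1; j < n; ++j) {
      double dx[3];
      for (int d = 0; d < 3; ++d) dx[d] = pos(i, d) - pos(j, d);
      min_image(b, dx);
      double r2 = dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2];
      if (r2 < rc * rc) {
        vis[(size_t)i * nres + resid0[j]] = 1;
        vis[(size_t)j * nres + resid0[i]] = 1;
      }
    }
  }

  NumericVector per_atom(n);
  NumericMatrix F(want_forces ? n : 1, 3);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double w = 0.5 * (vis[(size_t)i * nres + resid0[j]] +
                        vis[(size_t)j * nres + resid0[i]]);
      if (w == 0.0) continue;
      PairMap::const_iterator it = em.find(pair_key(i, j, n));
      if (it != em.end()) {
        if (it->second == 0.0) continue;     // excluded pair dropped
        w *= it->second;                     // scaled 1-4
      }
      double dx[3];
      for (int d = 0; d < 3; ++d) dx[d] = pos(i, d) - pos(j, d);
      min_image(b, dx);
      double r = std::sqrt(dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2]);
      double e = w * q[i] * q[j] / r;
      total += e;
      per_atom[i] += 0.5 * e;
      per_atom[j] += 0.5 * e;
      if (want_forces) {
        double fmag = w * q[i] * q[j] / (r * r * r);
        for (int d = 0; d < 3; ++d) {
          F(i, d) += fmag * dx[d];
          F(j, d) -= fmag * dx[d];
        }
      }
    }
  }
  total *= coulomb;
  for (int i = 0; i < n; ++i) per_atom[i] *= coulomb;
  if (want_forces)
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) F(i, d) *= coulomb;
  return List::create(_["total"] = total, _["per_atom"] = per_atom,
                      _["pair"] = total, _["self"] = 0.0,
                      _["exclusion"] = 0.0,
                      _["forces"] = want_forces ? F : NumericMatrix(0, 3));
}

// ---------------------------------------------------------------------------
// plain Ewald summation, tinfoil boundary conditions
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_ewald(NumericMatrix pos, NumericVector q, NumericVector box,
               double alpha, double rcut, IntegerVector kmax,
               IntegerMatrix excl, NumericVector exclw, double coulomb,
               bool want_forces, bool background) {
  int n = pos.nrow();
  Box b = make_box(box);
  PairMap em = build_pair_map(excl, exclw, n);
  double V = box[0] * box[1] * box[2];
  double TWO_PI = 2.0 * M_PI;

  NumericVector per_atom(n);
  NumericMatrix F(want_forces ? n : 1, 3);
  double e_real = 0.0, e_recip = 0.0, e_self = 0.0, e_corr = 0.0, e_bg = 0.0;

  // real space (excluded/scaled pairs skipped here, handled in correction)
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (em.find(pair_key(i, j, n)) != em.end()) continue;
      double dx[3];
      for (int d = 0; d < 3; ++d) dx[d] = pos(i, d) - pos(j, d);
      min_image(b, dx);
      double r2 = dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2];
      if (r2 >= rcut * rcut) continue;
      double r = std::sqrt(r2);
      double qq = q[i] * q[j];
      double e = qq * std::erfc(alpha * r) / r;
      e_real += e;
      per_atom[i] += 0.5 * e;
      per_atom[j] += 0.5 * e;
      if (want_forces) {
        double fmag = qq * (std::erfc(alpha * r) / r2
          + (2.0 * alpha / SQRT_PI) * std::exp(-alpha * alpha * r2) / r) / r;
        for (int d = 0; d < 3; ++d) {
          F(i, d) += fmag * dx[d];
          F(j, d) -= fmag * dx[d];
        }
      }
    }
  }

  // reciprocal space, half-space k enumeration with factor 2; per-axis
  // complex exponentials are built once by recursion (structure-factor
  // trick), so the k loop does complex multiplies only
  {
    int kx = kmax[0], ky = kmax[1], kz = kmax[2];
    std::vector<double> exc((size_t)n * (kx + 1)), exs((size_t)n * (kx + 1));
    std::vector<double> eyc((size_t)n * (2 * ky + 1)),
      eys((size_t)n * (2 * ky + 1));
    std::vector<double> ezc((size_t)n * (2 * kz + 1)),
      ezs((size_t)n * (2 * kz + 1));
    for (int i = 0; i < n; ++i) {
      double ax = TWO_PI * pos(i, 0) / box[0];
      double ay = TWO_PI * pos(i, 1) / box[1];
      double az = TWO_PI * pos(i, 2) / box[2];
      double c1 = std::cos(ax), s1 = std::sin(ax);
      exc[i] = 1.0; exs[i] = 0.0;
      for (int m = 1; m <= kx; ++m) {
        double pc = exc[(size_t)(m - 1) * n + i],
               ps = exs[(size_t)(m - 1) * n + i];
        exc[(size_t)m * n + i] = pc * c1 - ps * s1;
        exs[(size_t)m * n + i] = pc * s1 + ps * c1;
      }
      c1 = std::cos(ay); s1 = std::sin(ay);
      eyc[(size_t)ky * n + i] = 1.0; eys[(size_t)ky * n + i] = 0.0;
      for (int m = 1; m <= ky; ++m) {
        double pc = eyc[(size_t)(ky + m - 1) * n + i],
               ps = eys[(size_t)(ky + m - 1) * n + i];
        eyc[(size_t)(ky + m) * n + i] = pc * c1 - ps * s1;
        eys[(size_t)(ky + m) * n + i] = pc * s1 + ps * c1;
        eyc[(size_t)(ky - m) * n + i] = eyc[(size_t)(ky + m) * n + i];
        eys[(size_t)(ky - m) * n + i] = -eys[(size_t)(ky + m) * n + i];
      }
      c1 = std::cos(az); s1 = std::sin(az);
      ezc[(size_t)kz * n + i] = 1.0; ezs[(size_t)kz * n + i] = 0.0;
      for (int m = 1; m <= kz; ++m) {
        double pc = ezc[(size_t)(kz + m - 1) * n + i],
               ps = ezs[(size_t)(kz + m - 1) * n + i];
        ezc[(size_t)(kz + m) * n + i] = pc * c1 - ps * s1;
        ezs[(size_t)(kz + m) * n + i] = pc * s1 + ps * c1;
        ezc[(size_t)(kz - m) * n + i] = ezc[(size_t)(kz + m) * n + i];
        ezs[(size_t)(kz - m) * n + i] = -ezs[(size_t)(kz + m) * n + i];
      }
    }
    std::vector<double> xyc(n), xys(n), cs(n), sn(n);
    double pref = TWO_PI / V;
    for (int mx = 0; mx <= kx; ++mx) {
      int my0 = (mx == 0) ? 0 : -ky;
      const double* cx = &exc[(size_t)mx * n];
      const double* sx = &exs[(size_t)mx * n];
      for (int my = my0; my <= ky; ++my) {
        const double* cy = &eyc[(size_t)(ky + my) * n];
        const double* sy = &eys[(size_t)(ky + my) * n];
        for (int i = 0; i < n; ++i) {
          xyc[i] = cx[i] * cy[i] - sx[i] * sy[i];
          xys[i] = cx[i] * sy[i] + sx[i] * cy[i];
        }
        int mz0 = (mx == 0 && my == 0) ? 1 : -kz;
        for (int mz = mz0; mz <= kz; ++mz) {
          double kv[3] = { TWO_PI * mx / box[0], TWO_PI * my / box[1],
                           TWO_PI * mz / box[2] };
          double k2 = kv[0] * kv[0] + kv[1] * kv[1] + kv[2] * kv[2];
          double g = std::exp(-k2 / (4.0 * alpha * alpha)) / k2;
          const double* cz = &ezc[(size_t)(kz + mz) * n];
          const double* sz = &ezs[(size_t)(kz + mz) * n];
          double A = 0.0, B = 0.0;
          for (int i = 0; i < n; ++i) {
            cs[i] = xyc[i] * cz[i] - xys[i] * sz[i];
            sn[i] = xyc[i] * sz[i] + xys[i] * cz[i];
            A += q[i] * cs[i];
            B += q[i] * sn[i];
          }
          double w = 2.0 * pref * g;
          e_recip += w * (A * A + B * B);
          for (int i = 0; i < n; ++i)
            per_atom[i] += w * q[i] * (cs[i] * A + sn[i] * B);
          if (want_forces) {
            for (int i = 0; i < n; ++i) {
              double fm = 2.0 * w * q[i] * (sn[i] * A - cs[i] * B);
              for (int d = 0; d < 3; ++d) F(i, d) += fm * kv[d];
            }
          }
        }
      }
    }
  }

  // self term
  for (int i = 0; i < n; ++i) {
    double e = -alpha / SQRT_PI * q[i] * q[i];
    e_self += e;
    per_atom[i] += e;
  }

  // exclusion corrections: listed pair (weight w) should contribute w*qq/r;
  // reciprocal space already added erf(alpha r)/r
  for (PairMap::const_iterator it = em.begin(); it != em.end(); ++it) {
    int i = (int)(it->first / n), j = (int)(it->first % n);
    double w = it->second;
    double dx[3];
    for (int d = 0; d < 3; ++d) dx[d] = pos(i, d) - pos(j, d);
    min_image(b, dx);
    double r2 = dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2];
    double r = std::sqrt(r2);
    double qq = q[i] * q[j];
    double e = qq * (w - std::erf(alpha * r)) / r;
    e_corr += e;
    per_atom[i] += 0.5 * e;
    per_atom[j] += 0.5 * e;
    if (want_forces) {
      // dE/dr = qq * (-w/r2 - 2a/sqrt(pi) exp(-a2 r2)/r + erf(ar)/r2)
      double dedr = qq * (-w / r2
        - (2.0 * alpha / SQRT_PI) * std::exp(-alpha * alpha * r2) / r
        + std::erf(alpha * r) / r2);
      double fmag = -dedr / r;
      for (int d = 0; d < 3; ++d) {
        F(i, d) += fmag * dx[d];
        F(j, d) -= fmag * dx[d];
      }
    }
  }

  // optional uniform background correction for net-charged cells
  if (background) {
    double Q = 0.0;
    for (int i = 0; i < n; ++i) Q += q[i];
    double c = -M_PI / (2.0 * alpha * alpha * V);
    e_bg = c * Q * Q;
    for (int i = 0; i < n; ++i) per_atom[i] += c * q[i] * Q;
  }

  double total = coulomb * (e_real + e_recip + e_self + e_corr + e_bg);
  for (int i = 0; i < n; ++i) per_atom[i] *= coulomb;
  if (want_forces)
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) F(i, d) *= coulomb;

  return List::create(_["total"] = total, _["per_atom"] = per_atom,
                      _["real"] = coulomb * e_real,
                      _["reciprocal"] = coulomb * e_recip,
                      _["self"] = coulomb * e_self,
                      _["exclusion"] = coulomb * e_corr,
                      _["background"] = coulomb * e_bg,
                      _["forces"] = want_forces ? F : NumericMatrix(0, 3));
}

// ---------------------------------------------------------------------------
// direct Coulomb sum for open clusters (brute-force oracle)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_direct(NumericMatrix pos, NumericVector q, IntegerMatrix excl,
                NumericVector exclw, double coulomb, bool want_forces) {
  int n = pos.nrow();
  PairMap em = build_pair_map(excl, exclw, n);
  NumericVector per_atom(n);
  NumericMatrix F(want_forces ? n : 1, 3);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double w = 1.0;
      PairMap::const_iterator it = em.find(pair_key(i, j, n));
      if (it != em.end()) w = it->second;
      if (w == 0.0) continue;
      double dx[3];
      for (int d = 0; d < 3; ++d) dx[d] = pos(i, d) - pos(j, d);
      double r = std::sqrt(dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2]);
      double e = w * q[i] * q[j] / r;
      total += e;
      per_atom[i] += 0.5 * e;
      per_atom[j] += 0.5 * e;
      if (want_forces) {
        double fmag = w * q[i] * q[j] / (r * r * r);
        for (int d = 0; d < 3; ++d) {
          F(i, d) += fmag * dx[d];
          F(j, d) -= fmag * dx[d];
        }
      }
    }
  }
  total *= coulomb;
  for (int i = 0; i < n; ++i) per_atom[i] *= coulomb;
  if (want_forces)
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) F(i, d) *= coulomb;
  return List::create(_["total"] = total, _["per_atom"] = per_atom,
                      _["forces"] = want_forces ? F : NumericMatrix(0, 3));
}

// ---------------------------------------------------------------------------
// shifted-force Lennard-Jones (smooth at the cutoff, for clean NVE)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_lj(NumericMatrix pos, NumericVector box, NumericVector eps,
            NumericVector sig, double rc, IntegerMatrix excl,
            NumericVector exclw, bool want_forces) {
  int n = pos.nrow();
  Box b = make_box(box);
  PairMap em = build_pair_map(excl, exclw, n);
  NumericMatrix F(want_forces ? n : 1, 3);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    if (eps[i] == 0.0) continue;
    for (int j = i + 1; j < n; ++j) {
      if (eps[j] == 0.0) continue;
      PairMap::const_iterator it = em.find(pair_key(i, j, n));
      if (it != em.end() && it->second < 1.0) continue;  // bonded: no LJ
      double dx[3];
      for (int d = 0; d < 3; ++d) dx[d] = pos(i, d) - pos(j, d);
      min_image(b, dx);
      double r2 = dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2];
      if (r2 >= rc * rc) continue;
      double r = std::sqrt(r2);
      double e0 = std::sqrt(eps[i] * eps[j]);
      double s = 0.5 * (sig[i] + sig[j]);
      double sr2 = s * s / r2, sc2 = s * s / (rc * rc);
      double sr6 = sr2 * sr2 * sr2, sc6 = sc2 * sc2 * sc2;
      double u = 4.0 * e0 * (sr6 * sr6 - sr6);
      double urc = 4.0 * e0 * (sc6 * sc6 - sc6);
      double du = 4.0 * e0 * (-12.0 * sr6 * sr6 + 6.0 * sr6) / r;
      double durc = 4.0 * e0 * (-12.0 * sc6 * sc6 + 6.0 * sc6) / rc;
      total += u - urc - (r - rc) * durc;
      if (want_forces) {
        double fmag = -(du - durc) / r;
        for (int d = 0; d < 3; ++d) {
          F(i, d) += fmag * dx[d];
          F(j, d) -= fmag * dx[d];
        }
      }
    }
  }
  return List::create(_["total"] = total,
                      _["forces"] = want_forces ? F : NumericMatrix(0, 3));
}

// ---------------------------------------------------------------------------
// harmonic bonds and angles: E = k (r - r0)^2, E = k (theta - theta0)^2
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_bonds(NumericMatrix pos, NumericVector box, IntegerVector bi,
               IntegerVector bj, NumericVector kb, NumericVector r0,
               bool want_forces) {
  int n = pos.nrow(), m = bi.size();
  Box b = make_box(box);
  NumericMatrix F(want_forces ? n : 1, 3);
  double total = 0.0;
  for (int k = 0; k < m; ++k) {
    int i = bi[k], j = bj[k];
    double dx[3];
    for (int d = 0; d < 3; ++d) dx[d] = pos(i, d) - pos(j, d);
    min_image(b, dx);
    double r = std::sqrt(dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2]);
    double dr = r - r0[k];
    total += kb[k] * dr * dr;
    if (want_forces) {
      double fmag = -2.0 * kb[k] * dr / r;
      for (int d = 0; d < 3; ++d) {
        F(i, d) += fmag * dx[d];
        F(j, d) -= fmag * dx[d];
      }
    }
  }
  return List::create(_["total"] = total,
                      _["forces"] = want_forces ? F : NumericMatrix(0, 3));
}

// [[Rcpp::export]]
List cpp_angles(NumericMatrix pos, NumericVector box, IntegerVector ai,
                IntegerVector aj, IntegerVector ak, NumericVector ka,
                NumericVector th0, bool want_forces) {
  int n = pos.nrow(), m = ai.size();
  Box b = make_box(box);
  NumericMatrix F(want_forces ? n : 1, 3);
  double total = 0.0;
  for (int t = 0; t < m; ++t) {
    int i = ai[t], j = aj[t], k = ak[t];
    double rij[3], rkj[3];
    for (int d = 0; d < 3; ++d) {
      rij[d] = pos(i, d) - pos(j, d);
      rkj[d] = pos(k, d) - pos(j, d);
    }
    min_image(b, rij);
    min_image(b, rkj);
    double nij = std::sqrt(rij[0]*rij[0] + rij[1]*rij[1] + rij[2]*rij[2]);
    double nkj = std::sqrt(rkj[0]*rkj[0] + rkj[1]*rkj[1] + rkj[2]*rkj[2]);
    double cosx = (rij[0]*rkj[0] + rij[1]*rkj[1] + rij[2]*rkj[2]) / (nij*nkj);
    cosx = std::max(-1.0, std::min(1.0, cosx));
    double th = std::acos(cosx);
    double dth = th - th0[t];
    total += ka[t] * dth * dth;
    if (want_forces) {
      double sinx = std::sqrt(std::max(1e-12, 1.0 - cosx * cosx));
      double c = 2.0 * ka[t] * dth / sinx;   // dE/dcos = -2k dth / sin
      for (int d = 0; d < 3; ++d) {
        double gi = (rkj[d] / (nij * nkj) - cosx * rij[d] / (nij * nij));
        double gk = (rij[d] / (nij * nkj) - cosx * rkj[d] / (nkj * nkj));
        F(i, d) += c * gi;
        F(k, d) += c * gk;
        F(j, d) -= c * (gi + gk);
      }
    }
  }
  return List::create(_["total"] = total,
                      _["forces"] = want_forces ? F : NumericMatrix(0, 3));
}
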