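// Valence force-field energy/gradient, square-well restraints, FIRE minimizer,
// and Kabsch superposition utilities. Coordinates in Angstrom, energies in
// kcal/mol, penalties in kcal/mol/A^2 (distance, pin) or kcal/mol/deg^2
// (torsion wells). Atom indices arriving from R are 1-based. Inner loops use
// scalar math; Armadillo is used only for the 3x3 SVD in Kabsch fits.
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double RAD2DEG = 57.29577951308232;

// ---- small vector helpers on double[3] ----
static inline void vsub(const double* a, const double* b, double* o) {
  o[0] = a[0] - b[0]; o[1] = a[1] - b[1]; o[2] = a[2] - b[2];
}
static inline void vcross(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }

struct Terms {
  arma::mat bonds;     // i j r0 k
  arma::mat angles;    // i j k theta0 kth   (j central)
  arma::mat torsions;  // i j k l V n phi0
  arma::mat oops;      // c n1 n2 n3 k
  arma::mat nb;        // i j eps rmin qq
};

struct DWell { std::vector<int> a, b; double dist, wiggle, penalty; };

struct Restraints {
  arma::mat pins;      // i x y z k
  std::vector<DWell> dwells;
  arma::mat twells;    // i j k l lo hi k (lo/hi in degrees)
  arma::mat chir;      // c n1 n2 n3 sign k
};

static arma::mat getmat(const List& L, const char* nm) {
  if (!L.containsElementNamed(nm)) return arma::mat(0, 0);
  SEXP s = L[nm];
  if (Rf_isNull(s)) return arma::mat(0, 0);
  NumericMatrix m(s);
  arma::mat out(m.begin(), m.nrow(), m.ncol(), true);
  return out;
}

static Terms parse_terms(const List& L) {
  Terms t;
  t.bonds = getmat(L, "bonds");
  t.angles = getmat(L, "angles");
  t.torsions = getmat(L, "torsions");
  t.oops = getmat(L, "oops");
  t.nb = getmat(L, "nb");
  return t;
}

static Restraints parse_restraints(const List& L) {
  Restraints r;
  r.pins = getmat(L, "pins");
  r.twells = getmat(L, "twells");
  r.chir = getmat(L, "chir");
  if (L.containsElementNamed("dwells") && !Rf_isNull(L["dwells"])) {
    List dw = L["dwells"];
    for (int m = 0; m < dw.size(); ++m) {
      List w = dw[m];
      DWell d;
      IntegerVector ai = w["a"], bi = w["b"];
      d.a.assign(ai.begin(), ai.end());
      d.b.assign(bi.begin(), bi.end());
      d.dist = as<double>(w["dist"]);
      d.wiggle = as<double>(w["wiggle"]);
      d.penalty = as<double>(w["penalty"]);
      r.dwells.push_back(d);
    }
  }
  return r;
}

// torsion angle (radians, in (-pi, pi]); optionally gradient wrt the 4 atoms
// (g: 12 doubles, dri drj drk drl)
static double torsion_angle_g(const double* ri, const double* rj,
                              const double* rk, const double* rl,
                              double* g = nullptr) {
  double b1[3], b2[3], b3[3], n1[3], n2[3], cr[3];
  vsub(rj, ri, b1); vsub(rk, rj, b2); vsub(rl, rk, b3);
  vcross(b1, b2, n1); vcross(b2, b3, n2);
  double nb2 = vnorm(b2);
  double x = vdot(n1, n2);
  vcross(n1, n2, cr);
  double y = vdot(cr, b2) / std::max(nb2, 1e-12);
  double phi = std::atan2(y, x);
  if (g) {
    double n1sq = std::max(vdot(n1, n1), 1e-12);
    double n2sq = std::max(vdot(n2, n2), 1e-12);
    double f1 = -nb2 / n1sq, f4 = nb2 / n2sq;
    double c1 = vdot(b1, b2) / std::max(nb2 * nb2, 1e-12);
    double c2 = vdot(b3, b2) / std::max(nb2 * nb2, 1e-12);
    for (int d = 0; d < 3; ++d) {
      double F = f1 * n1[d], G = f4 * n2[d];
      double A = c2 * G - c1 * F;
      g[d] = F;
      g[3 + d] = -F + A;
      g[6 + d] = -G - A;
      g[9 + d] = G;
    }
  }
  return phi;
}

// signed normalized tetrahedral volume at center c; optional gradient
// (g: 12 doubles, dc dn1 dn2 dn3)
static double chir_volume_g(const double* rc, const double* r1,
                            const double* r2, const double* r3,
                            double* g = nullptr) {
  double u1[3], u2[3], u3[3], c12[3];
  vsub(r1, rc, u1); vsub(r2, rc, u2); vsub(r3, rc, u3);
  double l1 = std::max(vnorm(u1), 1e-9);
  double l2 = std::max(vnorm(u2), 1e-9);
  double l3 = std::max(vnorm(u3), 1e-9);
  vcross(u1, u2, c12);
  double T = vdot(c12, u3);
  double P = l1 * l2 * l3;
  double v = T / P;
  if (g) {
    double d1[3], d2[3], d3[3];
    vcross(u2, u3, d1); vcross(u3, u1, d2); vcross(u1, u2, d3);
    for (int d = 0; d < 3; ++d) {
      double g1 = (d1[d] - v * P * u1[d] / (l1 * l1)) / P;
      double g2 = (d2[d] - v * P * u2[d] / (l2 * l2)) / P;
      double g3 = (d3[d] - v * P * u3[d] / (l3 * l3)) / P;
      g[3 + d] = g1; g[6 + d] = g2; g[9 + d] = g3;
      g[d] = -(g1 + g2 + g3);
    }
  }
  return v;
}

// energy + gradient over raw column-major n x 3 coordinates
static void eval_all(const double* X, int n, const Terms& t,
                     const Restraints& r, double& e_ff, double& e_viol,
                     double* grad) {
  e_ff = 0.0; e_viol = 0.0;
  if (grad) std::fill(grad, grad + 3 * n, 0.0);
  // local row accessor: atom a -> (X[a], X[a+n], X[a+2n])
  #define ROW(a, p) { p[0] = X[(a)]; p[1] = X[(a) + n]; p[2] = X[(a) + 2 * n]; }
  #define ADDG(a, v, f) if (grad) { grad[(a)] += (f) * (v)[0]; \
    grad[(a) + n] += (f) * (v)[1]; grad[(a) + 2 * n] += (f) * (v)[2]; }

  double pi_[3], pj_[3], pk_[3], pl_[3], d[3];

  for (arma::uword m = 0; m < t.bonds.n_rows; ++m) {
    int i = (int)t.bonds(m, 0) - 1, j = (int)t.bonds(m, 1) - 1;
    double r0 = t.bonds(m, 2), k = t.bonds(m, 3);
    ROW(i, pi_); ROW(j, pj_); vsub(pi_, pj_, d);
    double rr = std::max(vnorm(d), 1e-9);
    double dr = rr - r0;
    e_ff += k * dr * dr;
    double f = 2.0 * k * dr / rr;
    ADDG(i, d, f); ADDG(j, d, -f);
  }
  for (arma::uword m = 0; m < t.angles.n_rows; ++m) {
    int i = (int)t.angles(m, 0) - 1, j = (int)t.angles(m, 1) - 1,
        k = (int)t.angles(m, 2) - 1;
    double th0 = t.angles(m, 3), kth = t.angles(m, 4);
    double u[3], v[3];
    ROW(i, pi_); ROW(j, pj_); ROW(k, pk_);
    vsub(pi_, pj_, u); vsub(pk_, pj_, v);
    double lu = std::max(vnorm(u), 1e-9), lv = std::max(vnorm(v), 1e-9);
    double c = vdot(u, v) / (lu * lv);
    c = std::min(1.0 - 1e-10, std::max(-1.0 + 1e-10, c));
    double th = std::acos(c);
    double dth = th - th0;
    e_ff += kth * dth * dth;
    if (grad) {
      double s = std::sqrt(1.0 - c * c);
      double f = -2.0 * kth * dth / s;
      for (int dd = 0; dd < 3; ++dd) {
        double dci = v[dd] / (lu * lv) - c * u[dd] / (lu * lu);
        double dck = u[dd] / (lu * lv) - c * v[dd] / (lv * lv);
        grad[i + dd * n] += f * dci;
        grad[k + dd * n] += f * dck;
        grad[j + dd * n] -= f * (dci + dck);
      }
    }
  }
  for (arma::uword m = 0; m < t.torsions.n_rows; ++m) {
    int i = (int)t.torsions(m, 0) - 1, j = (int)t.torsions(m, 1) - 1,
        k = (int)t.torsions(m, 2) - 1, l = (int)t.torsions(m, 3) - 1;
    double V = t.torsions(m, 4), nn = t.torsions(m, 5), p0 = t.torsions(m, 6);
    double g12[12];
    ROW(i, pi_); ROW(j, pj_); ROW(k, pk_); ROW(l, pl_);
    double phi = torsion_angle_g(pi_, pj_, pk_, pl_, grad ? g12 : nullptr);
    e_ff += 0.5 * V * (1.0 + std::cos(nn * phi - p0));
    if (grad) {
      double dE = -0.5 * V * nn * std::sin(nn * phi - p0);
      for (int dd = 0; dd < 3; ++dd) {
        grad[i + dd * n] += dE * g12[dd];
        grad[j + dd * n] += dE * g12[3 + dd];
        grad[k + dd * n] += dE * g12[6 + dd];
        grad[l + dd * n] += dE * g12[9 + dd];
      }
    }
  }
  // out-of-plane: E = k h^2, h = height of center over neighbor plane
  for (arma::uword m = 0; m < t.oops.n_rows; ++m) {
    int c = (int)t.oops(m, 0) - 1, a1 = (int)t.oops(m, 1) - 1,
        a2 = (int)t.oops(m, 2) - 1, a3 = (int)t.oops(m, 3) - 1;
    double k = t.oops(m, 4);
    double p1[3], p2[3], p3[3], pc[3], a[3], b[3], dd[3], nn_[3];
    ROW(a1, p1); ROW(a2, p2); ROW(a3, p3); ROW(c, pc);
    vsub(p2, p1, a); vsub(p3, p1, b); vsub(pc, p1, dd);
    vcross(a, b, nn_);
    double ln = std::max(vnorm(nn_), 1e-9);
    double dn = vdot(dd, nn_);
    double h = dn / ln;
    e_ff += k * h * h;
    if (grad) {
      double nh[3] = { nn_[0] / ln, nn_[1] / ln, nn_[2] / ln };
      double f = 2.0 * k * h;
      double t23[3], dd1[3], dl1[3], dd2[3], dl2[3], dd3[3], dl3[3], amb[3];
      vsub(p2, p3, t23);
      vcross(t23, dd, dd1);
      dd1[0] -= nn_[0]; dd1[1] -= nn_[1]; dd1[2] -= nn_[2];
      vsub(a, b, amb); vcross(amb, nh, dl1);
      vcross(b, dd, dd2); vcross(b, nh, dl2);
      vcross(dd, a, dd3); vcross(nh, a, dl3);
      for (int z = 0; z < 3; ++z) {
        grad[c + z * n] += f * nh[z];
        grad[a1 + z * n] += f * (dd1[z] * ln - dn * dl1[z]) / (ln * ln);
        grad[a2 + z * n] += f * (dd2[z] * ln - dn * dl2[z]) / (ln * ln);
        grad[a3 + z * n] += f * (dd3[z] * ln - dn * dl3[z]) / (ln * ln);
      }
    }
  }
  // nonbonded: LJ (Rmin form) + screened Coulomb qq/(2 r^2)
  {
    const arma::mat& nbm = t.nb;
    for (arma::uword m = 0; m < nbm.n_rows; ++m) {
      int i = (int)nbm(m, 0) - 1, j = (int)nbm(m, 1) - 1;
      double eps = nbm(m, 2), rmin = nbm(m, 3), qq = nbm(m, 4);
      double dx = X[i] - X[j], dy = X[i + n] - X[j + n],
             dz = X[i + 2 * n] - X[j + 2 * n];
      double rr = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (rr < 0.3) rr = 0.3;
      double q = rmin / rr;
      double q3 = q * q * q;
      double q6 = q3 * q3, q12 = q6 * q6;
      e_ff += eps * (q12 - 2.0 * q6) + qq / (2.0 * rr * rr);
      if (grad) {
        double dE = (-12.0 * eps * (q12 - q6) / rr) - qq / (rr * rr * rr);
        double f = dE / rr;
        grad[i] += f * dx; grad[i + n] += f * dy; grad[i + 2 * n] += f * dz;
        grad[j] -= f * dx; grad[j + n] -= f * dy; grad[j + 2 * n] -= f * dz;
      }
    }
  }
  // pins
  for (arma::uword m = 0; m < r.pins.n_rows; ++m) {
    int i = (int)r.pins(m, 0) - 1;
    double k = r.pins(m, 4);
    double dx = X[i] - r.pins(m, 1), dy = X[i + n] - r.pins(m, 2),
           dz = X[i + 2 * n] - r.pins(m, 3);
    e_viol += k * (dx * dx + dy * dy + dz * dz);
    if (grad) {
      grad[i] += 2.0 * k * dx; grad[i + n] += 2.0 * k * dy;
      grad[i + 2 * n] += 2.0 * k * dz;
    }
  }
  // distance square wells between set centroids
  for (size_t m = 0; m < r.dwells.size(); ++m) {
    const DWell& w = r.dwells[m];
    double ca[3] = {0, 0, 0}, cb[3] = {0, 0, 0};
    for (size_t s = 0; s < w.a.size(); ++s) {
      int a = w.a[s] - 1;
      ca[0] += X[a]; ca[1] += X[a + n]; ca[2] += X[a + 2 * n];
    }
    for (size_t s = 0; s < w.b.size(); ++s) {
      int b = w.b[s] - 1;
      cb[0] += X[b]; cb[1] += X[b + n]; cb[2] += X[b + 2 * n];
    }
    for (int z = 0; z < 3; ++z) { ca[z] /= w.a.size(); cb[z] /= w.b.size(); }
    double dv[3]; vsub(ca, cb, dv);
    double rr = std::max(vnorm(dv), 1e-9);
    double exc = std::fabs(rr - w.dist) - w.wiggle;
    if (exc > 0) {
      e_viol += w.penalty * exc * exc;
      if (grad) {
        double sgn = (rr - w.dist) >= 0 ? 1.0 : -1.0;
        double f = 2.0 * w.penalty * exc * sgn / rr;
        for (int z = 0; z < 3; ++z) {
          double gz = f * dv[z];
          for (size_t s = 0; s < w.a.size(); ++s)
            grad[w.a[s] - 1 + z * n] += gz / w.a.size();
          for (size_t s = 0; s < w.b.size(); ++s)
            grad[w.b[s] - 1 + z * n] -= gz / w.b.size();
        }
      }
    }
  }
  // torsion square wells (degrees)
  for (arma::uword m = 0; m < r.twells.n_rows; ++m) {
    int i = (int)r.twells(m, 0) - 1, j = (int)r.twells(m, 1) - 1,
        k = (int)r.twells(m, 2) - 1, l = (int)r.twells(m, 3) - 1;
    double lo = r.twells(m, 4), hi = r.twells(m, 5), kp = r.twells(m, 6);
    double g12[12];
    ROW(i, pi_); ROW(j, pj_); ROW(k, pk_); ROW(l, pl_);
    double phi = torsion_angle_g(pi_, pj_, pk_, pl_, grad ? g12 : nullptr)
                 * RAD2DEG;
    bool inside = false;
    for (int wrap = -1; wrap <= 1 && !inside; ++wrap) {
      double p = phi + 360.0 * wrap;
      if (p >= lo && p <= hi) inside = true;
    }
    if (!inside) {
      double best = 1e18, sgn = 1.0;
      for (int wrap = -1; wrap <= 1; ++wrap) {
        double p = phi + 360.0 * wrap;
        double dlo = lo - p, dhi = p - hi;
        if (dlo > 0 && dlo < best) { best = dlo; sgn = -1.0; }
        if (dhi > 0 && dhi < best) { best = dhi; sgn = 1.0; }
      }
      e_viol += kp * best * best;
      if (grad) {
        double dE = 2.0 * kp * best * sgn * RAD2DEG;
        for (int dd = 0; dd < 3; ++dd) {
          grad[i + dd * n] += dE * g12[dd];
          grad[j + dd * n] += dE * g12[3 + dd];
          grad[k + dd * n] += dE * g12[6 + dd];
          grad[l + dd * n] += dE * g12[9 + dd];
        }
      }
    }
  }
  // chirality enforcement: E = k max(0, m0 - s*v)^2 (margin per-term, col 7;
  // default 0.25 when absent)

  for (arma::uword m = 0; m < r.chir.n_rows; ++m) {
    int c = (int)r.chir(m, 0) - 1, a1 = (int)r.chir(m, 1) - 1,
        a2 = (int)r.chir(m, 2) - 1, a3 = (int)r.chir(m, 3) - 1;
    double s = r.chir(m, 4), k = r.chir(m, 5);
    double m0 = r.chir.n_cols > 6 ? r.chir(m, 6) : 0.25;
    double gv[12];
    double pc[3], p1[3], p2[3], p3[3];
    ROW(c, pc); ROW(a1, p1); ROW(a2, p2); ROW(a3, p3);
    double v = chir_volume_g(pc, p1, p2, p3, grad ? gv : nullptr);
    double def = m0 - s * v;
    if (def > 0) {
      e_viol += k * def * def;
      if (grad) {
        double f = -2.0 * k * def * s;
        for (int dd = 0; dd < 3; ++dd) {
          grad[c + dd * n] += f * gv[dd];
          grad[a1 + dd * n] += f * gv[3 + dd];
          grad[a2 + dd * n] += f * gv[6 + dd];
          grad[a3 + dd * n] += f * gv[9 + dd];
        }
      }
    }
  }
  #undef ROW
  #undef ADDG
}

// [[Rcpp::export]]
List ff_eval(NumericMatrix xyz, List terms, List restraints,
             bool gradient = false) {
  Terms t = parse_terms(terms);
  Restraints r = parse_restraints(restraints);
  int n = xyz.nrow();
  double e_ff, e_viol;
  std::vector<double> g;
  if (gradient) g.resize(3 * n);
  eval_all(xyz.begin(), n, t, r, e_ff, e_viol, gradient ? g.data() : nullptr);
  List out = List::create(_["ff"] = e_ff, _["violation"] = e_viol,
                          _["total"] = e_ff + e_viol);
  if (gradient) {
    NumericMatrix gm(n, 3);
    std::copy(g.begin(), g.end(), gm.begin());
    out["gradient"] = gm;
  }
  return out;
}

// [[Rcpp::export]]
double torsion_angle_cpp(NumericMatrix xyz, int i, int j, int k, int l) {
  int n = xyz.nrow();
  const double* X = xyz.begin();
  double pi_[3], pj_[3], pk_[3], pl_[3];
  for (int d = 0; d < 3; ++d) {
    pi_[d] = X[i - 1 + d * n]; pj_[d] = X[j - 1 + d * n];
    pk_[d] = X[k - 1 + d * n]; pl_[d] = X[l - 1 + d * n];
  }
  return torsion_angle_g(pi_, pj_, pk_, pl_);
}

// [[Rcpp::export]]
double chir_volume_cpp(NumericMatrix xyz, int c, int n1, int n2, int n3) {
  int n = xyz.nrow();
  const double* X = xyz.begin();
  double pc[3], p1[3], p2[3], p3[3];
  for (int d = 0; d < 3; ++d) {
    pc[d] = X[c - 1 + d * n]; p1[d] = X[n1 - 1 + d * n];
    p2[d] = X[n2 - 1 + d * n]; p3[d] = X[n3 - 1 + d * n];
  }
  return chir_volume_g(pc, p1, p2, p3);
}

// L-BFGS minimizer (two-loop recursion, Armijo backtracking line search);
// deterministic. Returns best-so-far coordinates; recovers from non-finite
// energies by shrinking the step.
// [[Rcpp::export]]
List ff_minimize_cpp(NumericMatrix xyz, List terms, List restraints,
                     double tol = 1e-4, int maxit = 2000) {
  Terms t = parse_terms(terms);
  Restraints r = parse_restraints(restraints);
  const int n = xyz.nrow();
  const int n3 = 3 * n;
  std::vector<double> x(xyz.begin(), xyz.begin() + n3);
  std::vector<double> g(n3), gnew(n3), xnew(n3), dir(n3);
  double e_ff, e_viol;
  eval_all(x.data(), n, t, r, e_ff, e_viol, g.data());
  double e = e_ff + e_viol;
  std::vector<double> xbest = x;
  double ebest = e, ff_best = e_ff, viol_best = e_viol;

  const int hist = 7;
  std::vector<std::vector<double> > S, Y;
  std::vector<double> rho;

  auto gss_of = [&](const std::vector<double>& v) {
    double s = 0; for (int z = 0; z < n3; ++z) s += v[z] * v[z]; return s;
  };
  double grms = std::sqrt(gss_of(g) / n3);
  bool converged = grms <= tol;
  int it = 0;
  double e_mark = e; int mark_it = 0;

  for (it = 0; it < maxit && !converged; ++it) {
    // two-loop recursion: dir = -H g
    std::copy(g.begin(), g.end(), dir.begin());
    int m = (int)S.size();
    std::vector<double> a(m);
    for (int k = m - 1; k >= 0; --k) {
      double sq = 0; for (int z = 0; z < n3; ++z) sq += S[k][z] * dir[z];
      a[k] = rho[k] * sq;
      for (int z = 0; z < n3; ++z) dir[z] -= a[k] * Y[k][z];
    }
    if (m > 0) {
      double yy = gss_of(Y[m - 1]);
      double sy = 1.0 / rho[m - 1];
      double gamma = sy / std::max(yy, 1e-12);
      for (int z = 0; z < n3; ++z) dir[z] *= gamma;
    } else {
      for (int z = 0; z < n3; ++z) dir[z] *= 1e-3;  // cautious first step
    }
    for (int k = 0; k < m; ++k) {
      double yq = 0; for (int z = 0; z < n3; ++z) yq += Y[k][z] * dir[z];
      double b = rho[k] * yq;
      for (int z = 0; z < n3; ++z) dir[z] += S[k][z] * (a[k] - b);
    }
    for (int z = 0; z < n3; ++z) dir[z] = -dir[z];

    double gd = 0; for (int z = 0; z < n3; ++z) gd += g[z] * dir[z];
    if (gd >= 0) {  // not a descent direction: reset
      S.clear(); Y.clear(); rho.clear();
      for (int z = 0; z < n3; ++z) dir[z] = -g[z] * 1e-3;
      gd = 0; for (int z = 0; z < n3; ++z) gd += g[z] * dir[z];
    }
    // cap the maximum per-coordinate displacement at 0.5 A
    double dmax = 0;
    for (int z = 0; z < n3; ++z) dmax = std::max(dmax, std::fabs(dir[z]));
    if (dmax > 0.5) {
      double sc = 0.5 / dmax;
      for (int z = 0; z < n3; ++z) dir[z] *= sc;
      gd *= sc;
    }
    // Armijo backtracking
    double alpha = 1.0, enew = 0, eff_new = 0, ev_new = 0;
    bool ok = false;
    for (int ls = 0; ls < 25; ++ls) {
      for (int z = 0; z < n3; ++z) xnew[z] = x[z] + alpha * dir[z];
      eval_all(xnew.data(), n, t, r, eff_new, ev_new, nullptr);
      enew = eff_new + ev_new;
      if (std::isfinite(enew) && enew <= e + 1e-4 * alpha * gd) {
        ok = true; break;
      }
      alpha *= 0.5;
    }
    if (!ok) {  // line search failed: give up from the best point
      break;
    }
    eval_all(xnew.data(), n, t, r, eff_new, ev_new, gnew.data());
    enew = eff_new + ev_new;
    // curvature update
    std::vector<double> s(n3), y(n3);
    double sy = 0;
    for (int z = 0; z < n3; ++z) {
      s[z] = xnew[z] - x[z];
      y[z] = gnew[z] - g[z];
      sy += s[z] * y[z];
    }
    if (sy > 1e-10) {
      S.push_back(s); Y.push_back(y); rho.push_back(1.0 / sy);
      if ((int)S.size() > hist) {
        S.erase(S.begin()); Y.erase(Y.begin()); rho.erase(rho.begin());
      }
    }
    x.swap(xnew);
    g.swap(gnew);
    e = enew; e_ff = eff_new; e_viol = ev_new;
    if (e < ebest) { ebest = e; xbest = x; ff_best = e_ff; viol_best = e_viol; }
    grms = std::sqrt(gss_of(g) / n3);
    converged = grms <= tol;
    // plateau exit: negligible progress near a flat minimum
    if (it - mark_it >= 30) {
      if (e_mark - ebest < 3e-7 && grms < 100 * tol) converged = true;
      e_mark = ebest; mark_it = it;
    }
  }
  NumericMatrix xb(n, 3);
  std::copy(xbest.begin(), xbest.end(), xb.begin());
  return List::create(_["xyz"] = xb, _["energy"] = ff_best,
                      _["violation"] = viol_best, _["total"] = ebest,
                      _["converged"] = converged, _["iterations"] = it,
                      _["grad_norm"] = grms);
}

// Kabsch RMSD after optimal rigid superposition of B onto A (no reflection)
static double kabsch_rmsd(const arma::mat& A, const arma::mat& B) {
  arma::rowvec ca = arma::mean(A, 0), cb = arma::mean(B, 0);
  arma::mat A0 = A.each_row() - ca, B0 = B.each_row() - cb;
  arma::mat H = B0.t() * A0;
  arma::mat U, V; arma::vec s;
  if (!arma::svd(U, s, V, H)) return arma::datum::inf;
  double d = arma::det(V * U.t());
  arma::mat D = arma::eye(3, 3);
  if (d < 0) D(2, 2) = -1;
  arma::mat R = V * D * U.t();
  arma::mat Bf = B0 * R.t();
  arma::mat diff = A0 - Bf;
  return std::sqrt(arma::accu(diff % diff) / A.n_rows);
}

// [[Rcpp::export]]
double kabsch_rmsd_cpp(NumericMatrix A, NumericMatrix B) {
  arma::mat a(A.begin(), A.nrow(), A.ncol(), false);
  arma::mat b(B.begin(), B.nrow(), B.ncol(), false);
  return kabsch_rmsd(a, b);
}

// Minimum RMSD between conformers A and B over atom mappings.
// maps: k x m matrix, row = automorphism; entry (m, a) = image of atom a.
// subset: atoms of A over which RMSD is computed (1-based).
// [[Rcpp::export]]
double min_map_rmsd_cpp(NumericMatrix A, NumericMatrix B, IntegerMatrix maps,
                        IntegerVector subset) {
  arma::mat a(A.begin(), A.nrow(), A.ncol(), false);
  arma::mat b(B.begin(), B.nrow(), B.ncol(), false);
  int ns = subset.size();
  arma::mat As(ns, 3), Bs(ns, 3);
  for (int s = 0; s < ns; ++s) As.row(s) = a.row(subset[s] - 1);
  double best = arma::datum::inf;
  for (int m = 0; m < maps.nrow(); ++m) {
    for (int s = 0; s < ns; ++s) Bs.row(s) = b.row(maps(m, subset[s] - 1) - 1);
    double r = kabsch_rmsd(As, Bs);
    if (r < best) best = r;
  }
  return best;
}

// Rotate points by angle about axis through p0 along u (Rodrigues)
// [[Rcpp::export]]
NumericMatrix rotate_about_axis_cpp(NumericMatrix pts, NumericVector p0v,
                                    NumericVector uv, double angle) {
  arma::mat P(pts.begin(), pts.nrow(), pts.ncol(), true);
  arma::rowvec p0(3), u(3);
  for (int d = 0; d < 3; ++d) { p0[d] = p0v[d]; u[d] = uv[d]; }
  u /= std::max(arma::norm(u), 1e-12);
  double c = std::cos(angle), s = std::sin(angle);
  for (arma::uword i = 0; i < P.n_rows; ++i) {
    arma::rowvec d = P.row(i) - p0;
    arma::rowvec rot = d * c + arma::cross(u, d) * s +
                       u * arma::dot(u, d) * (1 - c);
    P.row(i) = p0 + rot;
  }
  return wrap(P);
}
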