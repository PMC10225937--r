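// Compiled numerical core: thermodynamic circuit RHS, analytic Jacobians,
// batched damped-Newton equilibrium solving, and saddle-node polishing.
// Only the model evaluation and root-finding hot paths live here; all
// orchestration (tracing, classification, optimization) is R code.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Model {
  int n, hn, me;
  double k;
  std::vector<double> p, l, R, K, d;
  std::vector<int> mask;
  std::vector<int> act, rep; // n*n, column-major: entry(i,j) = v[i + n*j]
};

Model unpack(const List& cm) {
  Model M;
  M.n  = as<int>(cm["n"]);
  M.hn = as<int>(cm["hn"]);
  M.me = as<int>(cm["me"]);
  M.k  = as<double>(cm["k"]);
  M.p    = as<std::vector<double> >(cm["p"]);
  M.l    = as<std::vector<double> >(cm["l"]);
  M.R    = as<std::vector<double> >(cm["R"]);
  M.K    = as<std::vector<double> >(cm["K"]);
  M.d    = as<std::vector<double> >(cm["d"]);
  M.mask = as<std::vector<int> >(cm["mask"]);
  M.act  = as<std::vector<int> >(cm["act"]);
  M.rep  = as<std::vector<int> >(cm["rep"]);
  return M;
}

inline double ipow(double x, int n) {
  double r = 1.0;
  for (int i = 0; i < n; ++i) r *= x;
  return r;
}

inline double hillq(const Model& M, int i, double S) {
  if (!M.mask[i]) return 0.0;
  double Sn = ipow(S, M.hn), Kn = ipow(M.K[i], M.hn);
  return M.R[i] * Sn / (Kn + Sn);
}

inline double hillq_dS(const Model& M, int i, double S) {
  if (!M.mask[i]) return 0.0;
  double Sn = ipow(S, M.hn), Kn = ipow(M.K[i], M.hn);
  double den = Kn + Sn;
  return M.R[i] * M.hn * Kn * ipow(S, M.hn - 1) / (den * den);
}

// f, with the regulatory numerator/denominator cached for reuse
void rhs_point(const Model& M, const double* w, double S,
               double* f, double* Ncache, double* Dcache) {
  int n = M.n;
  for (int i = 0; i < n; ++i) {
    double A = 0.0, Rp = 0.0;
    for (int j = 0; j < n; ++j) {
      double t = M.k * ipow(w[j], M.me);
      if (M.act[i + n * j]) A += t;
      if (M.rep[i + n * j]) Rp += t;
    }
    double N = M.l[i] + hillq(M, i, S) + A;
    double D = 1.0 + N + Rp;
    f[i] = M.p[i] * N / D - M.d[i] * w[i];
    if (Ncache) Ncache[i] = N;
    if (Dcache) Dcache[i] = D;
  }
}

// state Jacobian, column-major into J (n*n); N/D must come from rhs_point
void jac_point(const Model& M, const double* w, const double* Ncache,
               const double* Dcache, double* J) {
  int n = M.n;
  for (int j = 0; j < n; ++j) {
    double wp = M.me * ipow(w[j], M.me - 1) * M.k;
    for (int i = 0; i < n; ++i) {
      double Np = M.act[i + n * j] ? wp : 0.0;
      double Dp = Np + (M.rep[i + n * j] ? wp : 0.0);
      double D = Dcache[i];
      double v = M.p[i] * (Np * D - Ncache[i] * Dp) / (D * D);
      if (i == j) v -= M.d[i];
      J[i + n * j] = v;
    }
  }
}

// dF/dS column; dN/dS = dD/dS = mask * q'(S), so dF_i/dS = p q' (D-N)/D^2
void dS_point(const Model& M, double S, const double* Ncache,
              const double* Dcache, double* col) {
  int n = M.n;
  for (int i = 0; i < n; ++i) {
    double qp = hillq_dS(M, i, S);
    double D = Dcache[i];
    col[i] = M.p[i] * qp * (D - Ncache[i]) / (D * D);
  }
}

// solve A x = b in place (A col-major n x n, destroyed); partial pivoting
bool solve_small(int n, double* A, double* b) {
  std::vector<int> piv(n);
  for (int i = 0; i < n; ++i) piv[i] = i;
  for (int c = 0; c < n; ++c) {
    int pr = c;
    double best = std::fabs(A[c + n * c]);
    for (int r = c + 1; r < n; ++r) {
      double v = std::fabs(A[r + n * c]);
      if (v > best) { best = v; pr = r; }
    }
    if (best < 1e-300) return false;
    if (pr != c) {
      for (int j = 0; j < n; ++j) std::swap(A[c + n * j], A[pr + n * j]);
      std::swap(b[c], b[pr]);
    }
    double pivv = A[c + n * c];
    for (int r = c + 1; r < n; ++r) {
      double m = A[r + n * c] / pivv;
      if (m == 0.0) continue;
      for (int j = c; j < n; ++j) A[r + n * j] -= m * A[c + n * j];
      b[r] -= m * b[c];
    }
  }
  for (int r = n - 1; r >= 0; --r) {
    double s = b[r];
    for (int j = r + 1; j < n; ++j) s -= A[r + n * j] * b[j];
    b[r] = s / A[r + n * r];
  }
  return true;
}

double det_small(int n, const double* Jin) {
  if (n == 1) return Jin[0];
  if (n == 2) return Jin[0] * Jin[3] - Jin[2] * Jin[1];
  if (n == 3) {
    const double* J = Jin;
    return J[0] * (J[4] * J[8] - J[7] * J[5])
         - J[3] * (J[1] * J[8] - J[7] * J[2])
         + J[6] * (J[1] * J[5] - J[4] * J[2]);
  }
  // LU for larger systems
  std::vector<double> A(Jin, Jin + n * n);
  double det = 1.0;
  for (int c = 0; c < n; ++c) {
    int pr = c;
    double best = std::fabs(A[c + n * c]);
    for (int r = c + 1; r < n; ++r)
      if (std::fabs(A[r + n * c]) > best) { best = std::fabs(A[r + n * c]); pr = r; }
    if (best < 1e-300) return 0.0;
    if (pr != c) {
      for (int j = 0; j < n; ++j) std::swap(A[c + n * j], A[pr + n * j]);
      det = -det;
    }
    det *= A[c + n * c];
    for (int r = c + 1; r < n; ++r) {
      double m = A[r + n * c] / A[c + n * c];
      for (int j = c; j < n; ++j) A[r + n * j] -= m * A[c + n * j];
    }
  }
  return det;
}

// determinant scaled by the product of row norms (dimensionless fold gauge)
double det_scaled(int n, const double* J) {
  double det = det_small(n, J);
  double scale = 1.0;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += J[i + n * j] * J[i + n * j];
    scale *= std::sqrt(s);
  }
  if (scale < 1e-300) return det;
  return det / scale;
}

// stability by Routh-Hurwitz for n <= 3; larger systems handled in R
int stable_small(int n, const double* J) {
  if (n == 1) return J[0] < 0.0;
  if (n == 2) {
    double tr = J[0] + J[3];
    double det = J[0] * J[3] - J[2] * J[1];
    return (tr < 0.0) && (det > 0.0);
  }
  if (n == 3) {
    double tr = J[0] + J[4] + J[8];
    double m1 = J[4] * J[8] - J[7] * J[5];
    double m2 = J[0] * J[8] - J[6] * J[2];
    double m3 = J[0] * J[4] - J[3] * J[1];
    double det = det_small(3, J);
    double a1 = -tr, a2 = m1 + m2 + m3, a3 = -det;
    return (a1 > 0.0) && (a3 > 0.0) && (a1 * a2 > a3);
  }
  return NA_INTEGER;
}

// null vector of the N x (N+1) extended Jacobian via generalized cross
// product (exact for n = 1, 2, 3); returns false if degenerate
bool null_vec(int n, const double* Q, double* beta) {
  int m = n + 1;
  if (n == 1) {
    // Q is 1 x 2; null of (a, b) is (-b, a)
    beta[0] = -Q[1]; beta[1] = Q[0];
  } else if (n == 2) {
    // rows r1, r2 are 3-vectors; beta = r1 x r2
    double r1[3] = { Q[0], Q[2], Q[4] };
    double r2[3] = { Q[1], Q[3], Q[5] };
    beta[0] = r1[1] * r2[2] - r1[2] * r2[1];
    beta[1] = r1[2] * r2[0] - r1[0] * r2[2];
    beta[2] = r1[0] * r2[1] - r1[1] * r2[0];
  } else if (n == 3) {
    // signed 3x3 minors of the 3 x 4 matrix
    for (int c = 0; c < 4; ++c) {
      double Mnr[9];
      int cc = 0;
      for (int j = 0; j < 4; ++j) {
        if (j == c) continue;
        for (int i = 0; i < 3; ++i) Mnr[i + 3 * cc] = Q[i + 3 * j];
        ++cc;
      }
      beta[c] = ((c % 2) ? -1.0 : 1.0) * det_small(3, Mnr);
    }
  } else {
    return false; // R falls back to SVD
  }
  double nrm = 0.0, qs = 0.0;
  for (int i = 0; i < m; ++i) nrm += beta[i] * beta[i];
  for (int i = 0; i < m * n; ++i) qs += Q[i] * Q[i];
  nrm = std::sqrt(nrm);
  // degenerate if the cross product is negligible against the matrix scale
  double gauge = std::pow(std::sqrt(qs) / std::sqrt((double)n), (double)n);
  if (!(nrm > 1e-12 * gauge)) return false;
  double mx = 0.0; int mi = 0;
  for (int i = 0; i < m; ++i) {
    beta[i] /= nrm;
    if (std::fabs(beta[i]) > mx) { mx = std::fabs(beta[i]); mi = i; }
  }
  if (beta[mi] < 0.0) for (int i = 0; i < m; ++i) beta[i] = -beta[i];
  return true;
}

// damped Newton from a single seed; returns true on convergence
bool newton_point(const Model& M, double* w, double S, double ftol, int maxit) {
  int n = M.n;
  std::vector<double> f(n), N(n), D(n), J(n * n), step(n), cap(n);
  for (int i = 0; i < n; ++i) cap[i] = 0.35 * (M.p[i] / M.d[i]) + 1.0;
  for (int it = 0; it < maxit; ++it) {
    rhs_point(M, w, S, &f[0], &N[0], &D[0]);
    double worst = 0.0;
    for (int i = 0; i < n; ++i) {
      double r = std::fabs(f[i]) / std::max(1.0, M.p[i]);
      if (r > worst) worst = r;
    }
    if (worst < ftol) return true;
    jac_point(M, w, &N[0], &D[0], &J[0]);
    for (int i = 0; i < n; ++i) step[i] = f[i];
    std::vector<double> A(J);
    if (!solve_small(n, &A[0], &step[0])) return false;
    for (int i = 0; i < n; ++i) {
      double s = step[i];
      if (s >  cap[i]) s =  cap[i];
      if (s < -cap[i]) s = -cap[i];
      w[i] -= s;
      if (w[i] < 0.0) w[i] = 0.0;
    }
  }
  return false;
}

double rel_dist(int n, const double* a, const double* b) {
  double d2 = 0.0, na = 0.0, nb = 0.0;
  for (int i = 0; i < n; ++i) {
    double df = a[i] - b[i];
    d2 += df * df; na += a[i] * a[i]; nb += b[i] * b[i];
  }
  return std::sqrt(d2) / (1.0 + std::sqrt(std::max(na, nb)));
}

// Newton from all seeds at one S, deduplicated; appends to roots/stab
void roots_at(const Model& M, const NumericMatrix& W0, double S, double ftol,
              int maxit, double dedup, std::vector<double>& roots,
              std::vector<int>& stab) {
  int n = M.n;
  std::vector<double> w(n), f(n), N(n), D(n), J(n * n);
  for (int s = 0; s < W0.nrow(); ++s) {
    for (int i = 0; i < n; ++i) w[i] = W0(s, i);
    if (!newton_point(M, &w[0], S, ftol, maxit)) continue;
    bool dup = false;
    for (size_t r = 0; r < roots.size() / n; ++r) {
      if (rel_dist(n, &w[0], &roots[r * n]) < dedup) { dup = true; break; }
    }
    if (dup) continue;
    rhs_point(M, &w[0], S, &f[0], &N[0], &D[0]);
    jac_point(M, &w[0], &N[0], &D[0], &J[0]);
    for (int i = 0; i < n; ++i) roots.push_back(w[i]);
    stab.push_back(stable_small(n, &J[0]));
  }
}

List pack_roots(int n, const std::vector<double>& roots,
                const std::vector<int>& stab) {
  int r = (int)stab.size();
  NumericMatrix Rm(r, n);
  LogicalVector st(r);
  for (int i = 0; i < r; ++i) {
    for (int j = 0; j < n; ++j) Rm(i, j) = roots[i * n + j];
    st[i] = stab[i] == NA_INTEGER ? NA_LOGICAL : (stab[i] ? TRUE : FALSE);
  }
  return List::create(_["states"] = Rm, _["stable"] = st);
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_rhs(List cm, NumericMatrix W, double S) {
  Model M = unpack(cm);
  int n = M.n, m = W.nrow();
  NumericMatrix out(m, n);
  std::vector<double> w(n), f(n);
  for (int r = 0; r < m; ++r) {
    for (int i = 0; i < n; ++i) w[i] = W(r, i);
    rhs_point(M, &w[0], S, &f[0], NULL, NULL);
    for (int i = 0; i < n; ++i) out(r, i) = f[i];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_state_jac(List cm, NumericVector w, double S) {
  Model M = unpack(cm);
  int n = M.n;
  std::vector<double> f(n), N(n), D(n), J(n * n);
  rhs_point(M, &w[0], S, &f[0], &N[0], &D[0]);
  jac_point(M, &w[0], &N[0], &D[0], &J[0]);
  NumericMatrix out(n, n);
  std::copy(J.begin(), J.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_ext_jac(List cm, NumericVector w, double S) {
  Model M = unpack(cm);
  int n = M.n;
  std::vector<double> f(n), N(n), D(n), J(n * n), c(n);
  rhs_point(M, &w[0], S, &f[0], &N[0], &D[0]);
  jac_point(M, &w[0], &N[0], &D[0], &J[0]);
  dS_point(M, S, &N[0], &D[0], &c[0]);
  NumericMatrix out(n, n + 1);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) out(i, j) = J[i + n * j];
  for (int i = 0; i < n; ++i) out(i, n) = c[i];
  return out;
}

// [[Rcpp::export]]
SEXP cpp_beta(List cm, NumericVector w, double S) {
  Model M = unpack(cm);
  int n = M.n;
  std::vector<double> f(n), N(n), D(n), J(n * n), c(n), Q(n * (n + 1)),
      beta(n + 1);
  rhs_point(M, &w[0], S, &f[0], &N[0], &D[0]);
  jac_point(M, &w[0], &N[0], &D[0], &J[0]);
  dS_point(M, S, &N[0], &D[0], &c[0]);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) Q[i + n * j] = J[i + n * j];
  for (int i = 0; i < n; ++i) Q[i + n * n] = c[i];
  if (!null_vec(n, &Q[0], &beta[0])) return R_NilValue;
  return wrap(NumericVector(beta.begin(), beta.end()));
}

// [[Rcpp::export]]
List cpp_steady_states(List cm, double S, NumericMatrix W0, double ftol,
                       int maxit, double dedup) {
  Model M = unpack(cm);
  std::vector<double> roots;
  std::vector<int> stab;
  roots_at(M, W0, S, ftol, maxit, dedup, roots, stab);
  return pack_roots(M.n, roots, stab);
}

// Sweep an S grid; each grid point is seeded with the lattice plus the
// roots found at the previous grid point (helps follow steep branches).
// [[Rcpp::export]]
List cpp_sweep(List cm, NumericVector Sgrid, NumericMatrix W0, double ftol,
               int maxit, double dedup) {
  Model M = unpack(cm);
  int n = M.n, ns = Sgrid.size();
  List out(ns);
  std::vector<double> prev;
  for (int g = 0; g < ns; ++g) {
    NumericMatrix seeds;
    int extra = (int)(prev.size() / n);
    seeds = NumericMatrix(W0.nrow() + extra, n);
    for (int r = 0; r < W0.nrow(); ++r)
      for (int j = 0; j < n; ++j) seeds(r, j) = W0(r, j);
    for (int r = 0; r < extra; ++r)
      for (int j = 0; j < n; ++j) seeds(W0.nrow() + r, j) = prev[r * n + j];
    std::vector<double> roots;
    std::vector<int> stab;
    roots_at(M, seeds, Sgrid[g], ftol, maxit, dedup, roots, stab);
    out[g] = pack_roots(n, roots, stab);
    prev = roots;
  }
  return out;
}

// Newton on the fold system [f(w,S); det_scaled(Dw f)] = 0 in (w, S).
// The last equation's derivatives are taken by central finite differences.
// [[Rcpp::export]]
List cpp_fold_polish(List cm, NumericVector w0, double S0, double gtol,
                     int maxit) {
  Model M = unpack(cm);
  int n = M.n, m = n + 1;
  std::vector<double> z(m);
  for (int i = 0; i < n; ++i) z[i] = w0[i];
  z[n] = S0;
  std::vector<double> f(n), N(n), D(n), J(n * n), c(n), G(m), A(m * m);
  bool ok = false;
  for (int it = 0; it < maxit; ++it) {
    rhs_point(M, &z[0], z[n], &f[0], &N[0], &D[0]);
    jac_point(M, &z[0], &N[0], &D[0], &J[0]);
    dS_point(M, z[n], &N[0], &D[0], &c[0]);
    double g = det_scaled(n, &J[0]);
    double worst = std::fabs(g);
    for (int i = 0; i < n; ++i)
      worst = std::max(worst, std::fabs(f[i]) / std::max(1.0, M.p[i]));
    if (worst < gtol) { ok = true; break; }
    // assemble extended Jacobian of G
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) A[i + m * j] = J[i + n * j];
    for (int i = 0; i < n; ++i) A[i + m * n] = c[i];
    // FD derivatives of det_scaled wrt each unknown
    std::vector<double> fp(n), Np(n), Dp(n), Jp(n * n);
    for (int j = 0; j < m; ++j) {
      double h = 1e-6 * (1.0 + std::fabs(z[j]));
      double zs = z[j];
      z[j] = zs + h;
      rhs_point(M, &z[0], z[n], &fp[0], &Np[0], &Dp[0]);
      jac_point(M, &z[0], &Np[0], &Dp[0], &Jp[0]);
      double gp = det_scaled(n, &Jp[0]);
      z[j] = zs - h;
      rhs_point(M, &z[0], z[n], &fp[0], &Np[0], &Dp[0]);
      jac_point(M, &z[0], &Np[0], &Dp[0], &Jp[0]);
      double gm = det_scaled(n, &Jp[0]);
      z[j] = zs;
      A[n + m * j] = (gp - gm) / (2.0 * h);
    }
    for (int i = 0; i < n; ++i) G[i] = f[i];
    G[n] = g;
    if (!solve_small(m, &A[0], &G[0])) break;
    for (int i = 0; i < m; ++i) {
      double capv = 0.25 * (1.0 + std::fabs(z[i]));
      double s = G[i];
      if (s >  capv) s =  capv;
      if (s < -capv) s = -capv;
      z[i] -= s;
      if (z[i] < 0.0) z[i] = 0.0;
    }
  }
  NumericVector w(n);
  for (int i = 0; i < n; ++i) w[i] = z[i];
  return List::create(_["omega"] = w, _["S"] = z[n], _["converged"] = ok);
}

// Residuals for the design least-squares solve: for each prescribed fold k,
// the scaled equilibrium residuals f(w_k, S_k)/max(1, p) followed by the
// last component of the unit tangent vector at (w_k, S_k).
// [[Rcpp::export]]
NumericVector cpp_fold_system(List cm, NumericMatrix Wf, NumericVector Sf) {
  Model M = unpack(cm);
  int n = M.n, nf = Wf.nrow();
  NumericVector out(nf * n + nf);
  std::vector<double> w(n), f(n), N(n), D(n), J(n * n), c(n),
      Q(n * (n + 1)), beta(n + 1);
  for (int k = 0; k < nf; ++k) {
    for (int i = 0; i < n; ++i) w[i] = Wf(k, i);
    rhs_point(M, &w[0], Sf[k], &f[0], &N[0], &D[0]);
    for (int i = 0; i < n; ++i)
      out[k * n + i] = f[i] / std::max(1.0, M.p[i]);
    jac_point(M, &w[0], &N[0], &D[0], &J[0]);
    dS_point(M, Sf[k], &N[0], &D[0], &c[0]);
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) Q[i + n * j] = J[i + n * j];
    for (int i = 0; i < n; ++i) Q[i + n * n] = c[i];
    out[nf * n + k] = null_vec(n, &Q[0], &beta[0]) ? beta[n] : 1.0;
  }
  return out;
}
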