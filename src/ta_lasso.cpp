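#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Coordinate descent for the innovation-domain lasso shared by all voxels
// of one run:  min_s 0.5*||y - A s||^2 + lambda*||s||_1, parameterized
// through the Gram matrix G = A'A (p x p, shared) and the per-voxel
// correlation vector A'y.  Active-set strategy: a full cyclic sweep
// locates violating coordinates, then inner sweeps iterate the nonzero set
// until progress stalls; stops at relative duality gap <= tol.
//
// G      : p x p Gram matrix
// AtY    : p x V matrix of A'y per voxel
// yty    : length-V vector of ||y||^2
// lambda : length-V penalty weights
// S0     : p x V warm-start coefficients (may be zeros)
// [[Rcpp::export(name = ".ta_lasso_cd")]]
List ta_lasso_cd(const NumericMatrix& G, const NumericMatrix& AtY,
                 const NumericVector& yty, const NumericVector& lambda,
                 const NumericMatrix& S0, double tol, int max_sweeps) {
  const int p = G.nrow();
  const int V = AtY.ncol();
  NumericMatrix S(p, V);
  NumericVector gap(V), primal(V);
  IntegerVector sweeps(V);

  const double* g = REAL(G);        // column-major p x p
  const double* aty = REAL(AtY);    // column-major p x V
  std::vector<double> diag(p);
  for (int j = 0; j < p; ++j) diag[j] = std::max(g[j + (size_t)j * p], 1e-300);

  std::vector<double> s(p), q(p);

  for (int v = 0; v < V; ++v) {
    const double* atyv = aty + (size_t)v * p;
    std::fill(q.begin(), q.end(), 0.0);
    for (int j = 0; j < p; ++j) {
      s[j] = S0(j, v);
      if (s[j] != 0.0) {
        const double sj = s[j];
        const double* gj = g + (size_t)j * p;
        for (int i = 0; i < p; ++i) q[i] += gj[i] * sj;
      }
    }
    const double lam = lambda[v];
    const double yy = yty[v];
    double gp = R_PosInf, pr = 0.5 * yy;
    int it = 0;

    for (it = 1; it <= max_sweeps; ++it) {
      // full cyclic sweep (admits new coordinates)
      double max_delta = 0.0;
      for (int j = 0; j < p; ++j) {
        const double sj = s[j];
        const double z = atyv[j] - q[j] + diag[j] * sj;
        double snew;
        if (z > lam) snew = (z - lam) / diag[j];
        else if (z < -lam) snew = (z + lam) / diag[j];
        else snew = 0.0;
        const double d = snew - sj;
        if (d != 0.0) {
          s[j] = snew;
          const double* gj = g + (size_t)j * p;
          for (int i = 0; i < p; ++i) q[i] += gj[i] * d;
          const double ad = std::fabs(d);
          if (ad > max_delta) max_delta = ad;
        }
      }

      // inner sweeps on the active set; stop on geometric progress —
      // the outer duality-gap test governs final accuracy
      double d_first = -1.0;
      for (int inner = 0; inner < 10; ++inner) {
        double d_in = 0.0;
        for (int j = 0; j < p; ++j) {
          const double sj = s[j];
          if (sj == 0.0) continue;
          const double z = atyv[j] - q[j] + diag[j] * sj;
          double snew;
          if (z > lam) snew = (z - lam) / diag[j];
          else if (z < -lam) snew = (z + lam) / diag[j];
          else snew = 0.0;
          const double d = snew - sj;
          if (d != 0.0) {
            s[j] = snew;
            const double* gj = g + (size_t)j * p;
            for (int i = 0; i < p; ++i) q[i] += gj[i] * d;
            const double ad = std::fabs(d);
            if (ad > d_in) d_in = ad;
          }
        }
        if (d_first < 0.0) d_first = d_in;
        if (d_in < 1e-12 || d_in < 1e-2 * d_first) break;
      }

      // duality gap from Gram quantities
      double sAty = 0.0, sq = 0.0, l1 = 0.0, ginf = 0.0;
      for (int j = 0; j < p; ++j) {
        sAty += s[j] * atyv[j];
        sq += s[j] * q[j];
        l1 += std::fabs(s[j]);
        const double gr = std::fabs(atyv[j] - q[j]); // |A'r|_j
        if (gr > ginf) ginf = gr;
      }
      const double rr = std::max(yy - 2.0 * sAty + sq, 0.0); // ||r||^2
      pr = 0.5 * rr + lam * l1;
      const double c = (ginf > lam && ginf > 0.0) ? lam / ginf : 1.0;
      const double rty = rr + (sAty - sq);           // r'y
      const double dual = 0.5 * yy - 0.5 * (yy - 2.0 * c * rty + c * c * rr);
      gp = pr - dual;
      const double scale = std::max(pr, 0.5 * yy);
      if (scale <= 0.0 || gp <= tol * scale) break;
      if (max_delta < 1e-14 && it > 1) break;        // fixed point reached
    }
    for (int j = 0; j < p; ++j) S(j, v) = s[j];
    gap[v] = gp;
    primal[v] = pr;
    sweeps[v] = std::min(it, max_sweeps);
  }
  return List::create(_["S"] = S, _["gap"] = gap, _["primal"] = primal,
                      _["sweeps"] = sweeps);
}
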