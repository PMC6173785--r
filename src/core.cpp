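#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Synchronous explicit update of intracellular concentrations over nsub
// 3-s substeps on a fixed contact network. Per substep and per cell:
//   dC_i = sum_j pm_ij (C_j - C_i) + vp_i / (1 + C_i / k50_i) - kd C_i
// evaluated from the pre-substep state. Edge indices are 0-based.
// [[Rcpp::export]]
List diffuse_cpp(NumericVector conc, IntegerVector edge_i, IntegerVector edge_j,
                 NumericVector pm, NumericVector vp, NumericVector k50,
                 double kd, int nsub, bool clip) {
  const int n = conc.size();
  const int m = edge_i.size();
  if (edge_j.size() != m || pm.size() != m)
    stop("edge arrays must have equal length");
  if (vp.size() != n || k50.size() != n)
    stop("per-cell parameter arrays must match the number of cells");
  std::vector<double> c(conc.begin(), conc.end());
  std::vector<double> d(n);
  long long nclip = 0;
  for (int s = 0; s < nsub; ++s) {
    std::fill(d.begin(), d.end(), 0.0);
    for (int e = 0; e < m; ++e) {
      const int i = edge_i[e], j = edge_j[e];
      const double f = pm[e] * (c[j] - c[i]);
      d[i] += f;
      d[j] -= f;
    }
    for (int i = 0; i < n; ++i) {
      double prod = 0.0;
      if (vp[i] != 0.0) prod = vp[i] / (1.0 + c[i] / k50[i]);
      c[i] += d[i] + prod - kd * c[i];
      if (c[i] < 0.0) {
        ++nclip;
        if (clip) c[i] = 0.0;
      }
    }
  }
  return List::create(_["conc"] = NumericVector(c.begin(), c.end()),
                      _["n_clipped"] = (double)nclip);
}

// Iterative pairwise relaxation of overlapping rigid disks. Overlapping
// pairs are pushed apart along their center line until no pair overlaps by
// more than tol; of the two cells, the one farther from the colony centroid
// takes the larger displacement share, producing outward colony growth.
// Positions are updated in place within a sweep (Gauss-Seidel), which
// converges much faster than a synchronous scheme.
// [[Rcpp::export]]
List relax_cpp(NumericVector x0, NumericVector y0, NumericVector r,
               double tol, int maxit) {
  const int n = x0.size();
  if (y0.size() != n || r.size() != n) stop("coordinate arrays must match");
  NumericVector x = clone(x0), y = clone(y0);
  int it = 0;
  bool converged = (n < 2);
  double max_ov = 0.0;
  for (it = 0; it < maxit && !converged; ++it) {
    double cx = 0.0, cy = 0.0;
    for (int i = 0; i < n; ++i) { cx += x[i]; cy += y[i]; }
    cx /= n; cy /= n;
    bool any = false;
    max_ov = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        const double dx = x[j] - x[i], dy = y[j] - y[i];
        const double sumr = r[i] + r[j];
        const double d2 = dx * dx + dy * dy;
        if (d2 >= sumr * sumr) continue;
        const double d = std::sqrt(d2);
        const double ov = sumr - d;
        if (ov > max_ov) max_ov = ov;
        if (ov <= tol) continue;
        any = true;
        double ux, uy;
        if (d < 1e-12) {
          // coincident centers: deterministic direction from indices
          const double a = 2.39996322972865332 * (i + 1) + 0.71 * j;
          ux = std::cos(a); uy = std::sin(a);
        } else {
          ux = dx / d; uy = dy / d;
        }
        const double di = std::hypot(x[i] - cx, y[i] - cy);
        const double dj = std::hypot(x[j] - cx, y[j] - cy);
        const double wj = (di + dj > 1e-12) ? dj / (di + dj) : 0.5;
        const double wi = 1.0 - wj;
        const double push = ov + 1e-9;
        x[i] -= push * wi * ux; y[i] -= push * wi * uy;
        x[j] += push * wj * ux; y[j] += push * wj * uy;
      }
    }
    if (!any) converged = true;
  }
  return List::create(_["x"] = x, _["y"] = y, _["iterations"] = it,
                      _["converged"] = converged, _["max_overlap"] = max_ov);
}
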