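#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Squared Euclidean distance between row i of a and row j of b.
// Matrices are n x dim with column-major storage; dim is small (<= ~15).
static inline double sqdist_rows(const double* a, int na, const double* b,
                                 int nb, int i, int j, int dim) {
  double s = 0.0;
  for (int k = 0; k < dim; ++k) {
    double d = a[i + (R_xlen_t)k * na] - b[j + (R_xlen_t)k * nb];
    s += d * d;
  }
  return s;
}

// Recurrence count, recurrence rate and longest diagonal line of the
// cross-recurrence matrix R[i,j] = 1{ ||ex_i - ey_j|| <= radius }, scanned
// diagonal-by-diagonal so the matrix is never materialised.
// [[Rcpp::export]]
List cpp_rec_stats(NumericMatrix ex, NumericMatrix ey, double radius,
                   int min_line) {
  const int nx = ex.nrow(), ny = ey.nrow(), dim = ex.ncol();
  if (ey.ncol() != dim) stop("embedding dimension mismatch");
  const double r2 = radius * radius;
  const double* px = ex.begin();
  const double* py = ey.begin();
  double count = 0.0;
  int maxline = 0;
  for (int off = -(nx - 1); off <= ny - 1; ++off) {
    int i = off < 0 ? -off : 0;
    int j = off < 0 ? 0 : off;
    int run = 0;
    for (; i < nx && j < ny; ++i, ++j) {
      if (sqdist_rows(px, nx, py, ny, i, j, dim) <= r2) {
        count += 1.0;
        ++run;
        if (run >= min_line && run > maxline) maxline = run;
      } else {
        run = 0;
      }
    }
  }
  double rec_pct = 100.0 * count / ((double)nx * (double)ny);
  return List::create(_["count"] = count, _["rec_pct"] = rec_pct,
                      _["maxline"] = maxline);
}

// [[Rcpp::export]]
IntegerMatrix cpp_recurrence_matrix(NumericMatrix ex, NumericMatrix ey,
                                    double radius) {
  const int nx = ex.nrow(), ny = ey.nrow(), dim = ex.ncol();
  if (ey.ncol() != dim) stop("embedding dimension mismatch");
  const double r2 = radius * radius;
  IntegerMatrix R(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      R(i, j) = sqdist_rows(ex.begin(), nx, ey.begin(), ny, i, j, dim) <= r2;
  return R;
}

// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix ex, NumericMatrix ey) {
  const int nx = ex.nrow(), ny = ey.nrow(), dim = ex.ncol();
  double best = 0.0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double d = sqdist_rows(ex.begin(), nx, ey.begin(), ny, i, j, dim);
      if (d > best) best = d;
    }
  return std::sqrt(best);
}

// Kennel false-nearest-neighbour fractions for dimensions 1..max_dim.
// The test for dimension d uses the (d+1)-th delay coordinate, so only the
// first N - d*delay points are eligible at dimension d. A neighbour is
// false when the distance-increase ratio exceeds rtol or the (d+1)-dim
// distance exceeds atol_abs (Atol * SD of the series). Self-matches are
// excluded; ties resolve to the first minimal index.
// [[Rcpp::export]]
NumericVector cpp_fnn(NumericVector x, int delay, int max_dim, double rtol,
                      double atol_abs) {
  const int N = x.size();
  NumericVector frac(max_dim, NA_REAL);
  for (int d = 1; d <= max_dim; ++d) {
    const int n = N - d * delay;
    if (n < 2) break;
    int nfalse = 0;
    for (int i = 0; i < n; ++i) {
      double bestd = R_PosInf;
      int bestj = -1;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double s = 0.0;
        for (int k = 0; k < d; ++k) {
          double dd = x[i + k * delay] - x[j + k * delay];
          s += dd * dd;
        }
        if (s < bestd) { bestd = s; bestj = j; }
      }
      double extra = x[i + d * delay] - x[bestj + d * delay];
      double dist_d = std::sqrt(bestd);
      double dist_d1 = std::sqrt(bestd + extra * extra);
      bool false_nb;
      if (dist_d == 0.0) {
        false_nb = std::fabs(extra) > 0.0;
      } else {
        false_nb = (std::fabs(extra) / dist_d > rtol) || (dist_d1 > atol_abs);
      }
      if (false_nb) ++nfalse;
    }
    frac[d - 1] = (double)nfalse / (double)n;
  }
  return frac;
}
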