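#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Trace one segment through the n x n grid on E = [-1,1]^2.
// Appends (0-based pixel index, intersection length) pairs, sorted by pixel
// index with duplicates merged.  Pixel (r, c) is row-major with row 0 at the
// top; a pixel owns its lower x-boundary and upper y-boundary, which the
// midpoint classification below realises without explicit tie-breaking.
static void trace_segment(double x0, double y0, double x1, double y1, int n,
                          std::vector<int>& cols, std::vector<double>& lens) {
  const double h = 2.0 / n;
  const double dx = x1 - x0, dy = y1 - y0;
  const double seg_len = std::sqrt(dx * dx + dy * dy);

  std::vector<double> alphas;
  alphas.reserve(2 * n + 4);
  alphas.push_back(0.0);
  alphas.push_back(1.0);
  if (dx != 0.0) {
    for (int c = 1; c < n; ++c) {
      double a = (-1.0 + c * h - x0) / dx;
      if (a > 0.0 && a < 1.0) alphas.push_back(a);
    }
  }
  if (dy != 0.0) {
    for (int r = 1; r < n; ++r) {
      double a = (-1.0 + r * h - y0) / dy;
      if (a > 0.0 && a < 1.0) alphas.push_back(a);
    }
  }
  std::sort(alphas.begin(), alphas.end());

  std::vector<std::pair<int, double> > hits;
  hits.reserve(2 * n);
  double prev = alphas[0];
  for (size_t k = 1; k < alphas.size(); ++k) {
    double a = alphas[k];
    double da = a - prev;
    if (da <= 1e-14) { prev = std::max(prev, a); continue; }
    double am = 0.5 * (prev + a);
    double xm = x0 + am * dx, ym = y0 + am * dy;
    int c = (int)std::floor((xm + 1.0) / h);
    int r = (int)std::floor((1.0 - ym) / h);
    if (c < 0) c = 0; if (c >= n) c = n - 1;
    if (r < 0) r = 0; if (r >= n) r = n - 1;
    double len = da * seg_len;
    if (len > 0.0) hits.push_back(std::make_pair(r * n + c, len));
    prev = a;
  }

  std::sort(hits.begin(), hits.end());
  for (size_t k = 0; k < hits.size(); ++k) {
    if (k > 0 && hits[k].first == hits[k - 1].first) {
      lens.back() += hits[k].second;
    } else {
      cols.push_back(hits[k].first);
      lens.push_back(hits[k].second);
    }
  }
}

// [[Rcpp::export]]
List trace_ray_cpp(double x0, double y0, double x1, double y1, int n) {
  std::vector<int> cols;
  std::vector<double> lens;
  trace_segment(x0, y0, x1, y1, n, cols, lens);
  return List::create(_["j"] = wrap(cols), _["x"] = wrap(lens));
}

// Assemble the full system matrix in CSR order.  `rays` has one row per ray:
// source_x, source_y, detector_x, detector_y.
// [[Rcpp::export]]
List build_system_cpp(NumericMatrix rays, int n) {
  const int m = rays.nrow();
  std::vector<int> p(m + 1, 0);
  std::vector<int> j;
  std::vector<double> x;
  j.reserve((size_t)m * 8);
  x.reserve((size_t)m * 8);

  std::vector<int> cols;
  std::vector<double> lens;
  for (int i = 0; i < m; ++i) {
    cols.clear();
    lens.clear();
    trace_segment(rays(i, 0), rays(i, 1), rays(i, 2), rays(i, 3), n, cols, lens);
    if (cols.empty()) stop("degenerate ray (empty chord) at ray id %d", i + 1);
    j.insert(j.end(), cols.begin(), cols.end());
    x.insert(x.end(), lens.begin(), lens.end());
    p[i + 1] = (int)j.size();
  }
  return List::create(_["p"] = wrap(p), _["j"] = wrap(j), _["x"] = wrap(x));
}

// Squared Euclidean norm of each CSR row.
// [[Rcpp::export]]
NumericVector row_norms2_cpp(IntegerVector Ap, NumericVector Ax) {
  const int m = Ap.size() - 1;
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    for (int k = Ap[i]; k < Ap[i + 1]; ++k) s += Ax[k] * Ax[k];
    out[i] = s;
  }
  return out;
}

// Column sums restricted to a contiguous CSR row range [row_start, row_end).
// [[Rcpp::export]]
NumericVector col_sums_range_cpp(IntegerVector Ap, IntegerVector Aj,
                                 NumericVector Ax, int ncol,
                                 int row_start, int row_end) {
  NumericVector out(ncol);
  for (int i = row_start; i < row_end; ++i)
    for (int k = Ap[i]; k < Ap[i + 1]; ++k) out[Aj[k]] += Ax[k];
  return out;
}
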