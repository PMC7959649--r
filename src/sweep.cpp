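#include <Rcpp.h>
using namespace Rcpp;

// One relaxed orthogonal-projection (row-action) update of x onto the
// hyperplane of CSR row i:  x <- x + lam * (b_i - a_i . x) / ||a_i||^2 * a_i.
// With relax = false the bare Kaczmarz projection is applied (no relaxation
// factor appears in the arithmetic at all).  With clamp = true every entry
// the row touches is clamped to zero from below immediately after the update
// (per-step constraining); entries the row does not touch cannot have become
// negative, so clamping the touched ones is equivalent to clamping the whole
// vector, provided x was non-negative on entry.
static inline void row_update(const int* Ap, const int* Aj, const double* Ax,
                              const double* rn2, const double* b, int i,
                              double lam, bool relax, bool clamp, double* x) {
  const int s = Ap[i], e = Ap[i + 1];
  double dot = 0.0;
  for (int k = s; k < e; ++k) dot += Ax[k] * x[Aj[k]];
  double f = (b[i] - dot) / rn2[i];
  if (relax) f = lam * f;
  for (int k = s; k < e; ++k) {
    const int j = Aj[k];
    double v = x[j] + f * Ax[k];
    if (clamp && v < 0.0) v = 0.0;
    x[j] = v;
  }
}

// Sweep CSR rows [row_start, row_end) (0-based, half-open) in ascending
// order, starting from a copy of x.  Returns the updated vector.
// [[Rcpp::export]]
NumericVector sweep_rows_cpp(IntegerVector Ap, IntegerVector Aj,
                             NumericVector Ax, NumericVector rn2,
                             NumericVector b, NumericVector x,
                             int row_start, int row_end,
                             double lam, bool relax, bool clamp) {
  NumericVector y = clone(x);
  const int* pAp = INTEGER(Ap);
  const int* pAj = INTEGER(Aj);
  const double* pAx = REAL(Ax);
  const double* prn = REAL(rn2);
  const double* pb = REAL(b);
  double* py = REAL(y);
  for (int i = row_start; i < row_end; ++i)
    row_update(pAp, pAj, pAx, prn, pb, i, lam, relax, clamp, py);
  return y;
}
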