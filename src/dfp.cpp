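#include <Rcpp.h>
#include <cmath>
#include "dfp_core.h"
using namespace Rcpp;
using namespace dfpc;

// R-facing dynamic fixed-point kernels.  Mantissa matrices travel as numeric
// matrices holding exact integers (|m| < 2^53); one exponent per row.

static inline int64_t d2i(double x) { return (int64_t)x; }

// [[Rcpp::export]]
int dfp_exp_zero_cpp() { return EXP_ZERO; }

// [[Rcpp::export]]
List dfp_from_real_cpp(NumericMatrix x, int F) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix m(nr, nc);
  IntegerVector e(nr);
  for (int i = 0; i < nr; ++i) {
    double mx = 0;
    for (int j = 0; j < nc; ++j) mx = std::max(mx, std::fabs(x(i, j)));
    if (mx == 0) {
      e[i] = EXP_ZERO;
      continue;
    }
    int k;
    std::frexp(mx, &k); // mx = f * 2^k, f in [0.5, 1)
    double scale = std::ldexp(1.0, F - k);
    std::vector<int64_t> row(nc);
    for (int j = 0; j < nc; ++j) row[j] = (int64_t)std::nearbyint(x(i, j) * scale);
    int ne = normalize_arr(row.data(), nc, F, k); // rounding can hit 2^F
    e[i] = ne;
    for (int j = 0; j < nc; ++j) m(i, j) = (double)row[j];
  }
  return List::create(_["m"] = m, _["e"] = e);
}

// [[Rcpp::export]]
NumericMatrix dfp_to_real_cpp(NumericMatrix m, IntegerVector e, int F) {
  int nr = m.nrow(), nc = m.ncol();
  NumericMatrix x(nr, nc);
  for (int i = 0; i < nr; ++i) {
    if (e[i] == EXP_ZERO) continue;
    double s = std::ldexp(1.0, e[i] - F);
    for (int j = 0; j < nc; ++j) x(i, j) = m(i, j) * s;
  }
  return x;
}

// [[Rcpp::export]]
List dfp_normalize_cpp(NumericMatrix m, IntegerVector e, int F) {
  int nr = m.nrow(), nc = m.ncol();
  NumericMatrix om(nr, nc);
  IntegerVector oe(nr);
  std::vector<int64_t> row(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) row[j] = d2i(m(i, j));
    oe[i] = normalize_arr(row.data(), nc, F, e[i]);
    for (int j = 0; j < nc; ++j) om(i, j) = (double)row[j];
  }
  return List::create(_["m"] = om, _["e"] = oe);
}

// Row-wise addition: shift both operands to max(ea, eb) + 1 (headroom bit),
// add mantissas, renormalize.
// [[Rcpp::export]]
List dfp_add_cpp(NumericMatrix ma, IntegerVector ea, NumericMatrix mb,
                 IntegerVector eb, int F) {
  int nr = ma.nrow(), nc = ma.ncol();
  NumericMatrix om(nr, nc);
  IntegerVector oe(nr);
  std::vector<int64_t> row(nc);
  for (int i = 0; i < nr; ++i) {
    int t = std::max(ea[i], eb[i]) + 1;
    int sa = t - ea[i], sb = t - eb[i];
    for (int j = 0; j < nc; ++j)
      row[j] = shr_tz(d2i(ma(i, j)), sa) + shr_tz(d2i(mb(i, j)), sb);
    oe[i] = normalize_arr(row.data(), nc, F, t);
    for (int j = 0; j < nc; ++j) om(i, j) = (double)row[j];
  }
  return List::create(_["m"] = om, _["e"] = oe);
}

// Element-wise product: double-width mantissa product shifted down by F,
// row exponents summed, renormalize.
// [[Rcpp::export]]
List dfp_mul_cpp(NumericMatrix ma, IntegerVector ea, NumericMatrix mb,
                 IntegerVector eb, int F) {
  int nr = ma.nrow(), nc = ma.ncol();
  NumericMatrix om(nr, nc);
  IntegerVector oe(nr);
  std::vector<int64_t> row(nc);
  for (int i = 0; i < nr; ++i) {
    long long esum = (long long)ea[i] + eb[i];
    if (esum < EXP_ZERO) esum = EXP_ZERO;
    for (int j = 0; j < nc; ++j) row[j] = mul_shr(d2i(ma(i, j)), d2i(mb(i, j)), F);
    oe[i] = normalize_arr(row.data(), nc, F, (int)esum);
    for (int j = 0; j < nc; ++j) om(i, j) = (double)row[j];
  }
  return List::create(_["m"] = om, _["e"] = oe);
}

// Column sums: bring all rows to the highest scale, sum columns in 64-bit
// integers (which leave ample headroom above the 53-bit mantissas), and
// renormalize the single output row.
// [[Rcpp::export]]
List dfp_col_sum_cpp(NumericMatrix m, IntegerVector e, int F) {
  int nr = m.nrow(), nc = m.ncol();
  int emax = EXP_ZERO;
  for (int i = 0; i < nr; ++i) emax = std::max(emax, (int)e[i]);
  std::vector<int64_t> acc(nc, 0);
  int t = emax;
  if (emax != EXP_ZERO) {
    for (int i = 0; i < nr; ++i) {
      int s = t - e[i];
      for (int j = 0; j < nc; ++j) acc[j] += shr_tz(d2i(m(i, j)), s);
    }
  }
  int oe = normalize_arr(acc.data(), nc, F, t);
  NumericMatrix om(1, nc);
  for (int j = 0; j < nc; ++j) om(0, j) = (double)acc[j];
  return List::create(_["m"] = om, _["e"] = IntegerVector::create(oe));
}

// matvec: y_j = sum_i v_i * m_ij, as the composition of per-row scaling by
// v_i and a column sum (the forward-pass pattern).
// [[Rcpp::export]]
List dfp_matvec_cpp(NumericMatrix m, IntegerVector e, NumericVector vm, int ve,
                    int F) {
  int nr = m.nrow(), nc = m.ncol();
  NumericMatrix pm(nr, nc);
  IntegerVector pe(nr);
  for (int i = 0; i < nr; ++i) {
    long long esum = (long long)e[i] + ve;
    if (esum < EXP_ZERO) esum = EXP_ZERO;
    std::vector<int64_t> row(nc);
    for (int j = 0; j < nc; ++j) row[j] = mul_shr(d2i(m(i, j)), d2i(vm[i]), F);
    pe[i] = normalize_arr(row.data(), nc, F, (int)esum);
    for (int j = 0; j < nc; ++j) pm(i, j) = (double)row[j];
  }
  return dfp_col_sum_cpp(pm, pe, F);
}

// Static fixed-point reference chain: repeated multiplication by a constant
// factor at a fixed scale (no dynamic exponents), truncating toward zero.
// Returns the trajectory of stored values; underflow shows up as exact zeros.
// [[Rcpp::export]]
NumericMatrix dfp_static_chain_cpp(NumericVector v0, double factor, int steps,
                                   int F) {
  int n = v0.size();
  NumericMatrix out(steps + 1, n);
  std::vector<int64_t> m(n);
  int64_t fm = (int64_t)std::nearbyint(factor * std::ldexp(1.0, F));
  double s = std::ldexp(1.0, -F);
  for (int j = 0; j < n; ++j) {
    m[j] = (int64_t)std::nearbyint(v0[j] * std::ldexp(1.0, F));
    out(0, j) = m[j] * s;
  }
  for (int t = 1; t <= steps; ++t)
    for (int j = 0; j < n; ++j) {
      m[j] = mul_shr(m[j], fm, F);
      out(t, j) = m[j] * s;
    }
  return out;
}

// Divide a nonnegative vector by its sum via a constant-time reciprocal;
// all-zero input yields the uniform distribution.
// [[Rcpp::export]]
List dfp_renorm_dist_cpp(NumericVector vm, int ve, int F) {
  int n = vm.size();
  std::vector<int64_t> v(n);
  for (int i = 0; i < n; ++i) v[i] = d2i(vm[i]);
  int oe = renorm_dist(v.data(), n, F);
  NumericVector om(n);
  for (int i = 0; i < n; ++i) om[i] = (double)v[i];
  return List::create(_["m"] = om, _["e"] = IntegerVector::create(oe));
}
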