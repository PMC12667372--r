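#include <Rcpp.h>
#include "recorder.h"
#include "dfp_core.h"
using namespace Rcpp;

// Data-oblivious primitive layer.  Every routine touches memory in an order
// that depends only on public shape parameters; the recorder (when enabled)
// captures the logical access sequence so tests can assert trace invariance.

// [[Rcpp::export]]
void trace_start_cpp() {
  obli::recorder().clear();
  obli::recorder().enabled = true;
}

// [[Rcpp::export]]
List trace_stop_cpp() {
  obli::Recorder &r = obli::recorder();
  r.enabled = false;
  List out = List::create(_["op"] = IntegerVector(r.op.begin(), r.op.end()),
                          _["label"] = IntegerVector(r.label.begin(), r.label.end()),
                          _["index"] = IntegerVector(r.index.begin(), r.index.end()));
  r.clear();
  return out;
}

// [[Rcpp::export]]
bool trace_enabled_cpp() { return obli::recorder().enabled; }

// Linear-scan ORAM read: every slot is touched in ascending order; the
// requested value is latched with a select.  Out-of-range yields NA.
// [[Rcpp::export]]
double ob_read_cpp(NumericVector arr, int idx, int label) {
  int n = arr.size();
  double acc = NA_REAL;
  for (int i = 0; i < n; ++i) {
    obli::rec(obli::OP_READ, label, i);
    acc = (i == idx) ? arr[i] : acc;
  }
  return acc;
}

// Linear-scan ORAM write: every slot is rewritten (unchanged values included).
// [[Rcpp::export]]
NumericVector ob_write_cpp(NumericVector arr, int idx, double v, int label) {
  int n = arr.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    obli::rec(obli::OP_WRITE, label, i);
    out[i] = (i == idx) ? v : arr[i];
  }
  return out;
}

// Bitonic sorting network on (key, original index) composite keys, padded to
// the next power of two with +Inf sentinels.  Returns the 1-based permutation
// that sorts ascending, stably; attribute "ncomparisons" counts the
// compare-exchanges of the padded network.
// [[Rcpp::export]]
IntegerVector bitonic_sort_cpp(NumericVector key, int label) {
  int n = key.size();
  int m = 1;
  while (m < n) m <<= 1;
  std::vector<double> k(m);
  std::vector<int> id(m);
  for (int i = 0; i < m; ++i) {
    k[i] = (i < n) ? key[i] : R_PosInf;
    id[i] = i;
  }
  long ncmp = 0;
  for (int size = 2; size <= m; size <<= 1) {
    for (int stride = size >> 1; stride > 0; stride >>= 1) {
      for (int i = 0; i < m; ++i) {
        int l = i ^ stride;
        if (l > i) {
          ++ncmp;
          obli::rec(obli::OP_CMPX, label, i);
          obli::rec(obli::OP_CMPX, label, l);
          bool asc = ((i & size) == 0);
          bool gt = (k[i] > k[l]) || (k[i] == k[l] && id[i] > id[l]);
          if (gt == asc) {
            std::swap(k[i], k[l]);
            std::swap(id[i], id[l]);
          }
        }
      }
    }
  }
  IntegerVector perm(n);
  for (int i = 0; i < n; ++i) perm[i] = id[i] + 1;
  perm.attr("ncomparisons") = (double)ncmp;
  return perm;
}

// Oblivious filter: route mask==1 elements to the front (preserving relative
// order) by sorting the composite key (1-mask, index) through the bitonic
// network, then truncate to the public length out_len.  Returns 1-based source
// indices with NA sentinels where fewer than out_len elements were selected.
// [[Rcpp::export]]
IntegerVector oblivious_filter_idx_cpp(NumericVector mask, int out_len, int label) {
  int n = mask.size();
  NumericVector key(n);
  for (int i = 0; i < n; ++i) key[i] = (1.0 - mask[i]) * (double)(n + 1) + (double)i;
  IntegerVector perm = bitonic_sort_cpp(key, label);
  IntegerVector out(out_len);
  for (int i = 0; i < out_len; ++i) {
    if (i < n && mask[perm[i] - 1] == 1.0)
      out[i] = perm[i];
    else
      out[i] = NA_INTEGER;
  }
  return out;
}

// Deterministic multiplexer: both operands are materialised and the outcome
// is latched without branching on the condition in the recorded trace.
// [[Rcpp::export]]
double ob_select_cpp(int c, double a, double b) {
  obli::rec(obli::OP_SELECT, 0, 0);
  return c ? a : b;
}

// Constant-time integer division: restoring long division with exactly
// `width` iterations.  den == 0 returns the all-ones sentinel of the width.
// [[Rcpp::export]]
double ct_divide_cpp(double num, double den, int width) {
  obli::rec(obli::OP_DIV, 0, width);
  int neg = num < 0;
  uint64_t a = (uint64_t)(neg ? -num : num);
  uint64_t d = (uint64_t)den;
  uint64_t q = dfpc::ct_div_u64(a, d, width);
  double out = (double)q;
  return neg ? -out : out;
}

// [[Rcpp::export]]
NumericVector ct_divide_vec_cpp(NumericVector num, NumericVector den, int width) {
  int n = num.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ct_divide_cpp(num[i], den[i], width);
  return out;
}
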