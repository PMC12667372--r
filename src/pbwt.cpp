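#include <Rcpp.h>
#include "recorder.h"
using namespace Rcpp;

// Positional Burrows-Wheeler transform over the unique haplotypes of one
// compressed block, and oblivious insertion of a (secret) target haplotype.
//
// Conventions: column c describes prefixes of length c (sites 0..c-1 of the
// block, 0-based).  ord(c, i) is the id of the unique haplotype at rank i of
// the positional prefix order; div(c, i) is the start position of the longest
// match between ranks i and i-1 ending at c (div = c means no match, and the
// first rank always carries div = c for c > 0, 0 at c = 0).

// [[Rcpp::export]]
List pbwt_build_cpp(IntegerMatrix U) {
  int n = U.nrow(), w = U.ncol();
  IntegerMatrix ord(w + 1, n), div(w + 1, n);
  std::vector<int> a(n), d(n), a0(n), a1(n), d0(n), d1(n);
  for (int i = 0; i < n; ++i) {
    a[i] = i;
    d[i] = 0;
    ord(0, i) = i;
    div(0, i) = 0;
  }
  for (int c = 0; c < w; ++c) {
    int p = c + 1, q = c + 1, n0 = 0, n1 = 0;
    for (int i = 0; i < n; ++i) {
      p = std::max(p, d[i]);
      q = std::max(q, d[i]);
      if (U(a[i], c) == 0) {
        a0[n0] = a[i];
        d0[n0++] = p;
        p = 0;
      } else {
        a1[n1] = a[i];
        d1[n1++] = q;
        q = 0;
      }
    }
    for (int i = 0; i < n0; ++i) {
      a[i] = a0[i];
      d[i] = d0[i];
    }
    for (int i = 0; i < n1; ++i) {
      a[n0 + i] = a1[i];
      d[n0 + i] = d1[i];
    }
    for (int i = 0; i < n; ++i) {
      ord(c + 1, i) = a[i];
      div(c + 1, i) = d[i];
    }
  }
  return List::create(_["ord"] = ord, _["div"] = div);
}

// Oblivious insertion of target z into a block's PBWT.  Returns, per column c:
// the insertion rank (ties place the target before equal prefixes), and the
// match-start of z against the rank above (dzu) and below (dzd); plus the
// block-level LCS of z against every unique haplotype at the final column.
// All scans run over the full public shape regardless of z.
// [[Rcpp::export]]
List pbwt_insert_cpp(IntegerMatrix U, IntegerMatrix ord, IntegerVector z, int label) {
  int n = U.nrow(), w = U.ncol();
  IntegerVector rank(w + 1), dzu(w + 1), dzd(w + 1);
  std::vector<int> ms(n, 0); // match-start of z vs each unique at current column
  rank[0] = 0;
  for (int c = 0; c <= w; ++c) {
    int r = rank[c];
    // divergences to the neighbours in positional prefix order, fetched by a
    // linear scan selecting on the secret rank
    int up = c, dn = c;
    for (int i = 0; i < n; ++i) {
      obli::rec(obli::OP_SCAN, label, i);
      int msi = ms[ord(c, i)];
      up = (i == r - 1) ? msi : up;
      dn = (i == r) ? msi : dn;
    }
    dzu[c] = up;
    dzd[c] = dn;
    if (c == w) break;
    // rank update via allele counts in positional prefix order
    int zc = z[c];
    int c0b = 0, c0t = 0;
    for (int i = 0; i < n; ++i) {
      obli::rec(obli::OP_SCAN, label, i);
      int y = U(ord(c, i), c);
      c0t += (y == 0);
      c0b += (y == 0) && (i < r);
    }
    int c1b = r - c0b;
    rank[c + 1] = (zc == 0) ? c0b : (c0t + c1b);
    // extend match-starts by one site for every unique, uniformly
    for (int u = 0; u < n; ++u) {
      obli::rec(obli::OP_SCAN, label, n + u);
      ms[u] = (U(u, c) == zc) ? ms[u] : (c + 1);
    }
  }
  IntegerVector end_lcs(n);
  for (int u = 0; u < n; ++u) end_lcs[u] = w - ms[u];
  return List::create(_["rank"] = rank, _["dzu"] = dzu, _["dzd"] = dzd,
                      _["end_lcs"] = end_lcs);
}

// Block-level LCS of the inserted target against every unique haplotype at
// column c, reconstructed from the divergence arrays by running maxima away
// from the insertion rank (the PBWT locality property).
// [[Rcpp::export]]
IntegerVector pbwt_lcs_at_col_cpp(IntegerMatrix ord, IntegerMatrix div, int c,
                                  int rank, int dzu, int dzd, int label) {
  int n = ord.ncol();
  std::vector<int> up(n), dn(n);
  // descending pass for ranks above the insertion point; full fixed range,
  // values gated on comparisons against the secret rank
  int run = c;
  for (int j = n - 1; j >= 0; --j) {
    obli::rec(obli::OP_SCAN, label, j);
    run = (j == rank - 1) ? dzu : run;
    up[j] = run;
    run = (j < rank && j > 0) ? std::max(run, div(c, j)) : run;
  }
  // ascending pass for ranks at/below the insertion point
  run = c;
  for (int j = 0; j < n; ++j) {
    obli::rec(obli::OP_SCAN, label, n + j);
    run = (j == rank) ? dzd : ((j > rank) ? std::max(run, div(c, j)) : run);
    dn[j] = run;
  }
  IntegerVector lcs(n); // indexed by unique id
  for (int j = 0; j < n; ++j) {
    int m = (j < rank) ? up[j] : dn[j];
    lcs[ord(c, j)] = c - m;
  }
  return lcs;
}
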