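#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include "dfp_core.h"
using namespace Rcpp;
using namespace dfpc;

// Diploid Li-Stephens HMM over a conditioned reference panel and a genotype
// graph, evaluated in dynamic fixed point.  The site-level state is
// (k1, k2, option): the two target haplotypes implied by the current
// segment's phase option copy from conditioned haplotypes k1 and k2 with
// emission 1-eps on allele match and eps on mismatch; each copy process
// switches haplotype with probability rho per interval (jumping uniformly
// over the valid panel rows); at segment boundaries the option transitions
// under a uniform prior.  Padding rows (valid == 0) carry zero weight.
//
// All loop bounds and memory access orders depend only on public shapes
// (K, L, segment layout); secret-dependent values flow through arithmetic
// selects, and per-site renormalisation divides by the distribution sum via
// a constant-time reciprocal.  The transition operator A = (1-rho) I +
// rho w 1^T is applied in its expanded rank-one form, one multiply per
// state: M' = a^2 M + ab (w_i C_j + w_j R_i) + b^2 w_i w_j T.

namespace {

// nonnegative fixed-point product (all HMM quantities are >= 0)
inline int64_t mulp(int64_t a, int64_t b, int s) {
  return (int64_t)(((unsigned __int128)(uint64_t)a * (uint64_t)b) >> s);
}

struct Shapes {
  int K, L, nseg, maxopt;
  std::vector<int> fseg, bsite;
};

Shapes shapes_of(const IntegerVector &segid, int nseg, int K, int maxopt) {
  Shapes sh;
  sh.K = K;
  sh.L = segid.size();
  sh.nseg = nseg;
  sh.maxopt = maxopt;
  sh.fseg.assign(nseg, -1);
  sh.bsite.assign(nseg, -1);
  for (int t = 0; t < sh.L; ++t) {
    int s = segid[t];
    if (sh.fseg[s] < 0) sh.fseg[s] = t;
    sh.bsite[s] = t;
  }
  return sh;
}

struct Consts {
  int K, L, KK, F;
  int64_t hit, miss, e3[3]; // emission pair products by match count
  std::vector<int> vld;
  std::vector<int64_t> am, bm; // stay / per-target jump mantissas per site
};

Consts make_consts(const IntegerMatrix &panel, const IntegerVector &valid,
                   const NumericVector &rho, double eps, int F) {
  Consts c;
  c.K = panel.nrow();
  c.L = panel.ncol();
  c.KK = c.K * c.K;
  c.F = F;
  c.hit = (int64_t)std::llround((1.0 - eps) * std::ldexp(1.0, F));
  c.miss = (int64_t)std::llround(eps * std::ldexp(1.0, F));
  c.e3[0] = mulp(c.miss, c.miss, F);
  c.e3[1] = mulp(c.hit, c.miss, F);
  c.e3[2] = mulp(c.hit, c.hit, F);
  c.vld.resize(c.K);
  int64_t Kv = 0;
  for (int k = 0; k < c.K; ++k) {
    c.vld[k] = valid[k];
    Kv += valid[k];
  }
  int64_t invK = (int64_t)ct_div_u64(1ULL << F, (uint64_t)(Kv > 0 ? Kv : 1), 63);
  c.am.resize(c.L);
  c.bm.resize(c.L);
  for (int t = 0; t < c.L; ++t) {
    int64_t rm = (int64_t)std::llround(rho[t] * std::ldexp(1.0, F));
    c.am[t] = (int64_t)std::llround((1.0 - rho[t]) * std::ldexp(1.0, F));
    c.bm[t] = mulp(rm, invK, F);
  }
  return c;
}

// per-site match indicators for each option
void match_arrays(const Consts &c, const IntegerMatrix &panel,
                  const IntegerMatrix &hapA, const IntegerMatrix &hapB, int t,
                  int no, std::vector<int> &m1, std::vector<int> &m2) {
  for (int o = 0; o < no; ++o) {
    int aA = hapA(o, t), aB = hapB(o, t);
    for (int k = 0; k < c.K; ++k) {
      int pk = panel(k, t);
      m1[o * c.K + k] = (pk == aA);
      m2[o * c.K + k] = (pk == aB);
    }
  }
}

void apply_emission(const Consts &c, int64_t *f, const std::vector<int> &m1,
                    const std::vector<int> &m2, int no) {
  int K = c.K;
  for (int o = 0; o < no; ++o) {
    const int *a = m1.data() + o * K, *b = m2.data() + o * K;
    int64_t *fo = f + o * c.KK;
    for (int i = 0; i < K; ++i) {
      int ai = a[i];
      int64_t *row = fo + i * K;
      for (int j = 0; j < K; ++j) row[j] = mulp(row[j], c.e3[ai + b[j]], c.F);
    }
  }
}

// forward transition M' = A M A^T, expanded rank-one form
void ktrans_sum(const Consts &c, int64_t *M, int t, std::vector<int64_t> &scr) {
  int K = c.K, F = c.F;
  int64_t am = c.am[t], bm = c.bm[t];
  int64_t a2 = mulp(am, am, F), ab = mulp(am, bm, F), b2 = mulp(bm, bm, F);
  scr.assign(2 * K, 0);
  int64_t *abR = scr.data(), *abC = scr.data() + K;
  i128 T = 0;
  for (int i = 0; i < K; ++i) {
    i128 r = 0;
    for (int j = 0; j < K; ++j) r += M[i * K + j];
    T += r;
    abR[i] = (int64_t)(((unsigned __int128)(uint64_t)ab * (i128)r) >> F);
  }
  for (int j = 0; j < K; ++j) {
    i128 s = 0;
    for (int i = 0; i < K; ++i) s += M[i * K + j];
    abC[j] = (int64_t)(((unsigned __int128)(uint64_t)ab * (i128)s) >> F);
  }
  int64_t b2T = (int64_t)(((unsigned __int128)(uint64_t)b2 * (i128)T) >> F);
  for (int i = 0; i < K; ++i) {
    int wi = c.vld[i];
    int64_t wiT = wi ? b2T : 0;
    int64_t *row = M + i * K;
    for (int j = 0; j < K; ++j) {
      int wj = c.vld[j];
      row[j] = mulp(a2, row[j], F) + (wj ? abR[i] : 0) + (wi ? abC[j] : 0) +
               (wj ? wiT : 0);
    }
  }
}

// backward transition N[i,j] = sum A[i',i] A[j',j] X[i',j']
void ktrans_rev(const Consts &c, int64_t *M, int t, std::vector<int64_t> &scr) {
  int K = c.K, F = c.F;
  int64_t am = c.am[t], bm = c.bm[t];
  int64_t a2 = mulp(am, am, F), ab = mulp(am, bm, F), b2 = mulp(bm, bm, F);
  scr.assign(2 * K, 0);
  int64_t *abS2 = scr.data(), *abS1 = scr.data() + K;
  i128 S = 0;
  for (int j = 0; j < K; ++j) {
    i128 s = 0;
    for (int i = 0; i < K; ++i) s += (i128)c.vld[i] * M[i * K + j];
    if (c.vld[j]) S += s;
    abS1[j] = (int64_t)(((unsigned __int128)(uint64_t)ab * s) >> F);
  }
  for (int i = 0; i < K; ++i) {
    i128 s = 0;
    for (int j = 0; j < K; ++j) s += (i128)c.vld[j] * M[i * K + j];
    abS2[i] = (int64_t)(((unsigned __int128)(uint64_t)ab * s) >> F);
  }
  int64_t b2S = (int64_t)(((unsigned __int128)(uint64_t)b2 * S) >> F);
  for (int i = 0; i < K; ++i) {
    int64_t *row = M + i * K;
    int64_t s2 = abS2[i];
    for (int j = 0; j < K; ++j)
      row[j] = mulp(a2, row[j], F) + abS1[j] + s2 + b2S;
  }
}

// divide the active state vector by its sum (constant-time reciprocal);
// returns log2 of the pre-normalisation total, the per-site likelihood term
double renorm_site(int64_t *f, int n, int F) {
  i128 S = 0;
  for (int i = 0; i < n; ++i) S += f[i];
  if (S <= 0) {
    int64_t u = (int64_t)ct_div_u64(1ULL << F, (uint64_t)n, 63);
    for (int i = 0; i < n; ++i) f[i] = u;
    return R_NegInf;
  }
  int s = 0;
  for (int b = 0; b < 127; ++b) s = ((S >> b) & 1) ? b : s;
  i128 inv = ct_div_u128((i128)1 << (s + F + 6), S);
  for (int i = 0; i < n; ++i)
    f[i] = (int64_t)(((unsigned __int128)(uint64_t)f[i] * inv) >> (s + 6));
  return std::log2((double)S) - F;
}

void reduce128(const i128 *acc, int n, int F, int64_t *out) {
  i128 mx = 0;
  for (int i = 0; i < n; ++i) mx = acc[i] > mx ? acc[i] : mx;
  int msb = 0;
  for (int b = 0; b < 127; ++b) msb = ((mx >> b) & 1) ? b : msb;
  int sh = msb > (F - 1) ? msb - (F - 1) : 0;
  for (int i = 0; i < n; ++i) out[i] = (int64_t)(acc[i] >> sh);
}

} // namespace

// Forward-backward: returns per-segment option marginals and, per adjacent
// segment boundary, the joint posterior over (option, next option) as
// fixed-point mantissas with one exponent, plus the data log2-likelihood.
// With dynamic_scaling = FALSE the per-site renormalisation is skipped,
// reproducing a conventional static fixed-point pipeline in which small
// probabilities truncate to zero and distributions flatten to uniform.
// [[Rcpp::export]]
List hmm_fb_cpp(IntegerMatrix panel, IntegerVector valid, IntegerVector segid,
                IntegerVector nopt, IntegerMatrix hapA, IntegerMatrix hapB,
                NumericVector rho, double eps, int F, bool dynamic_scaling) {
  Consts c = make_consts(panel, valid, rho, eps, F);
  int K = c.K, L = c.L, KK = c.KK, nseg = nopt.size();
  int maxopt = hapA.nrow();
  Shapes sh = shapes_of(segid, nseg, K, maxopt);
  std::vector<int64_t> f(maxopt * KK), scr;
  std::vector<int> m1(maxopt * K), m2(maxopt * K);
  std::vector<int64_t> Fend((size_t)nseg * maxopt * KK, 0);
  double loglik = 0.0;

  // ---- forward ----
  int s0 = segid[0];
  match_arrays(c, panel, hapA, hapB, 0, nopt[s0], m1, m2);
  for (int o = 0; o < nopt[s0]; ++o)
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        f[o * KK + i * K + j] = (int64_t)(c.vld[i] & c.vld[j]) << F;
  apply_emission(c, f.data(), m1, m2, nopt[s0]);
  if (dynamic_scaling) {
    double l = renorm_site(f.data(), nopt[s0] * KK, F);
    if (R_finite(l)) loglik += l;
  }
  if (sh.bsite[s0] == 0)
    std::memcpy(&Fend[(size_t)s0 * maxopt * KK], f.data(),
                sizeof(int64_t) * nopt[s0] * KK);
  for (int t = 1; t < L; ++t) {
    int s = segid[t], sp = segid[t - 1];
    if (s != sp) {
      std::vector<int64_t> g(KK, 0);
      for (int o = 0; o < nopt[sp]; ++o)
        for (int x = 0; x < KK; ++x) g[x] += f[o * KK + x];
      for (int o = 0; o < nopt[s]; ++o)
        std::memcpy(&f[o * KK], g.data(), sizeof(int64_t) * KK);
    }
    for (int o = 0; o < nopt[s]; ++o) ktrans_sum(c, &f[o * KK], t, scr);
    match_arrays(c, panel, hapA, hapB, t, nopt[s], m1, m2);
    apply_emission(c, f.data(), m1, m2, nopt[s]);
    if (dynamic_scaling) {
      double l = renorm_site(f.data(), nopt[s] * KK, F);
      if (R_finite(l)) loglik += l;
    }
    if (sh.bsite[s] == t)
      std::memcpy(&Fend[(size_t)s * maxopt * KK], f.data(),
                  sizeof(int64_t) * nopt[s] * KK);
  }

  // ---- backward, emitting marginals and boundary posteriors ----
  List marg(nseg), tp(nseg > 1 ? nseg - 1 : 0);
  IntegerVector tp_e(nseg > 1 ? nseg - 1 : 0), marg_e(nseg);
  std::vector<int64_t> bwd(maxopt * KK), be(maxopt * KK), gp(KK);
  int slast = segid[L - 1];
  for (int o = 0; o < nopt[slast]; ++o)
    for (int x = 0; x < KK; ++x) bwd[o * KK + x] = (int64_t)1 << F;
  {
    int no = nopt[slast];
    std::vector<i128> acc(no, 0);
    const int64_t *fe = &Fend[(size_t)slast * maxopt * KK];
    for (int o = 0; o < no; ++o)
      for (int x = 0; x < KK; ++x)
        acc[o] += (i128)fe[o * KK + x] * bwd[o * KK + x];
    std::vector<int64_t> mm(no);
    reduce128(acc.data(), no, F, mm.data());
    marg_e[slast] = renorm_dist(mm.data(), no, F);
    NumericVector mv(no);
    for (int o = 0; o < no; ++o) mv[o] = (double)mm[o];
    marg[slast] = mv;
  }
  for (int t = L - 1; t >= 1; --t) {
    int s = segid[t], sp = segid[t - 1];
    int no = nopt[s];
    match_arrays(c, panel, hapA, hapB, t, no, m1, m2);
    std::memcpy(be.data(), bwd.data(), sizeof(int64_t) * no * KK);
    apply_emission(c, be.data(), m1, m2, no);
    if (s != sp) {
      int nop = nopt[sp];
      std::vector<i128> acc((size_t)nop * no, 0);
      const int64_t *fe = &Fend[(size_t)sp * maxopt * KK];
      for (int o = 0; o < nop; ++o) {
        std::memcpy(gp.data(), fe + (size_t)o * KK, sizeof(int64_t) * KK);
        ktrans_sum(c, gp.data(), t, scr);
        for (int op = 0; op < no; ++op) {
          i128 a = 0;
          for (int x = 0; x < KK; ++x) a += (i128)gp[x] * be[op * KK + x];
          acc[o * no + op] = a;
        }
      }
      std::vector<int64_t> tm((size_t)nop * no);
      reduce128(acc.data(), nop * no, F, tm.data());
      int te = renorm_dist(tm.data(), nop * no, F);
      NumericMatrix tmat(nop, no);
      for (int o = 0; o < nop; ++o)
        for (int op = 0; op < no; ++op) tmat(o, op) = (double)tm[o * no + op];
      tp[sp] = tmat;
      tp_e[sp] = te;
    }
    for (int o = 0; o < no; ++o) ktrans_rev(c, &be[o * KK], t, scr);
    if (s != sp) {
      std::vector<int64_t> g(KK, 0);
      for (int o = 0; o < no; ++o)
        for (int x = 0; x < KK; ++x) g[x] += be[o * KK + x];
      for (int o = 0; o < nopt[sp]; ++o)
        std::memcpy(&bwd[o * KK], g.data(), sizeof(int64_t) * KK);
    } else {
      std::memcpy(bwd.data(), be.data(), sizeof(int64_t) * no * KK);
    }
    if (dynamic_scaling) renorm_site(bwd.data(), nopt[sp] * KK, F);
    if (s != sp) {
      int nop = nopt[sp];
      std::vector<i128> acc(nop, 0);
      const int64_t *fe = &Fend[(size_t)sp * maxopt * KK];
      for (int o = 0; o < nop; ++o)
        for (int x = 0; x < KK; ++x)
          acc[o] += (i128)fe[o * KK + x] * bwd[o * KK + x];
      std::vector<int64_t> mm(nop);
      reduce128(acc.data(), nop, F, mm.data());
      marg_e[sp] = renorm_dist(mm.data(), nop, F);
      NumericVector mv(nop);
      for (int o = 0; o < nop; ++o) mv[o] = (double)mm[o];
      marg[sp] = mv;
    }
  }
  return List::create(_["marg"] = marg, _["marg_e"] = marg_e, _["tp"] = tp,
                      _["tp_e"] = tp_e, _["loglik"] = loglik, _["F"] = F);
}

// Viterbi decoding (max-product analogue): returns the argmax option per
// segment and the log2-likelihood of the decoded path.  Ties resolve to the
// lower index deterministically.
// [[Rcpp::export]]
List hmm_vit_cpp(IntegerMatrix panel, IntegerVector valid, IntegerVector segid,
                 IntegerVector nopt, IntegerMatrix hapA, IntegerMatrix hapB,
                 NumericVector rho, double eps, int F) {
  Consts c = make_consts(panel, valid, rho, eps, F);
  int K = c.K, L = c.L, KK = c.KK, nseg = nopt.size();
  int maxopt = hapA.nrow();
  std::vector<int64_t> V(maxopt * KK), scr(2 * K);
  std::vector<int> m1(maxopt * K), m2(maxopt * K);
  std::vector<uint8_t> bp((size_t)L * maxopt * KK, 0);
  std::vector<int16_t> ax1((size_t)L * maxopt * K, 0), ax2((size_t)L * maxopt * K, 0);
  std::vector<int8_t> bpo((size_t)nseg * KK, 0);
  double loglik = 0.0;

  int s0 = segid[0];
  match_arrays(c, panel, hapA, hapB, 0, nopt[s0], m1, m2);
  for (int o = 0; o < nopt[s0]; ++o)
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        V[o * KK + i * K + j] = (int64_t)(c.vld[i] & c.vld[j]) << F;
  apply_emission(c, V.data(), m1, m2, nopt[s0]);
  loglik += normalize_arr(V.data(), nopt[s0] * KK, F, 0);
  for (int t = 1; t < L; ++t) {
    int s = segid[t], sp = segid[t - 1];
    int no = nopt[s];
    if (s != sp) {
      int nop = nopt[sp];
      std::vector<int64_t> g(KK);
      int8_t *bo = &bpo[(size_t)s * KK];
      for (int x = 0; x < KK; ++x) {
        int64_t best = V[x];
        int bi = 0;
        for (int o = 1; o < nop; ++o) {
          int64_t v = V[o * KK + x];
          bi = (v > best) ? o : bi;
          best = (v > best) ? v : best;
        }
        g[x] = best;
        bo[x] = (int8_t)bi;
      }
      for (int o = 0; o < no; ++o)
        std::memcpy(&V[o * KK], g.data(), sizeof(int64_t) * KK);
    }
    for (int o = 0; o < no; ++o) {
      int64_t *M = &V[o * KK];
      uint8_t *bpt = &bp[((size_t)t * maxopt + o) * KK];
      int16_t *a1 = &ax1[((size_t)t * maxopt + o) * K];
      int16_t *a2 = &ax2[((size_t)t * maxopt + o) * K];
      // dim 1
      for (int j = 0; j < K; ++j) {
        int64_t best = M[j];
        int bi = 0;
        for (int i = 1; i < K; ++i) {
          int64_t v = M[i * K + j];
          bi = (v > best) ? i : bi;
          best = (v > best) ? v : best;
        }
        a1[j] = (int16_t)bi;
        scr[j] = mulp(c.bm[t], best, F);
      }
      for (int i = 0; i < K; ++i) {
        for (int j = 0; j < K; ++j) {
          int64_t stay = mulp(c.am[t], M[i * K + j], F);
          int64_t jmp = c.vld[i] ? scr[j] : 0;
          int st = (stay >= jmp);
          bpt[i * K + j] |= (uint8_t)st;
          M[i * K + j] = st ? stay : jmp;
        }
      }
      // dim 2
      for (int i = 0; i < K; ++i) {
        int64_t best = M[i * K];
        int bj = 0;
        for (int j = 1; j < K; ++j) {
          int64_t v = M[i * K + j];
          bj = (v > best) ? j : bj;
          best = (v > best) ? v : best;
        }
        a2[i] = (int16_t)bj;
        scr[K + i] = mulp(c.bm[t], best, F);
      }
      for (int i = 0; i < K; ++i) {
        for (int j = 0; j < K; ++j) {
          int64_t stay = mulp(c.am[t], M[i * K + j], F);
          int64_t jmp = c.vld[j] ? scr[K + i] : 0;
          int st = (stay >= jmp);
          bpt[i * K + j] |= (uint8_t)(st << 1);
          M[i * K + j] = st ? stay : jmp;
        }
      }
    }
    match_arrays(c, panel, hapA, hapB, t, no, m1, m2);
    apply_emission(c, V.data(), m1, m2, no);
    loglik += normalize_arr(V.data(), no * KK, F, 0);
  }
  int slast = segid[L - 1];
  int bo = 0, bi = 0, bj = 0;
  int64_t best = -1;
  for (int o = 0; o < nopt[slast]; ++o)
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j) {
        int64_t v = V[o * KK + i * K + j];
        if (v > best) {
          best = v;
          bo = o;
          bi = i;
          bj = j;
        }
      }
  loglik += std::log2((double)(best > 0 ? best : 1)) - F;
  IntegerVector path(nseg);
  path[slast] = bo;
  int o = bo, ci = bi, cj = bj;
  for (int t = L - 1; t >= 1; --t) {
    int s = segid[t], sp = segid[t - 1];
    uint8_t b = bp[((size_t)t * maxopt + o) * KK + ci * K + cj];
    int j2 = (b & 2) ? cj : ax2[((size_t)t * maxopt + o) * K + ci];
    uint8_t b1 = bp[((size_t)t * maxopt + o) * KK + ci * K + j2];
    int i2 = (b1 & 1) ? ci : ax1[((size_t)t * maxopt + o) * K + j2];
    ci = i2;
    cj = j2;
    if (s != sp) {
      o = bpo[(size_t)s * KK + ci * K + cj];
      path[sp] = o;
    }
  }
  return List::create(_["path"] = path, _["loglik"] = loglik);
}
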