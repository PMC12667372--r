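#pragma once
#include <cstdint>

// Dynamic fixed-point core: signed integer mantissas sharing one power-of-two
// exponent per row/vector; value = m * 2^(e - F).  Mantissas are kept below
// 2^53 in magnitude so they survive the R numeric (IEEE double) boundary
// exactly; all intermediate arithmetic is int64 with 128-bit products.
namespace dfpc {

typedef __int128 i128;

// Reserved exponent for all-zero rows; small enough to lose against any real
// exponent, large enough that sums of two never overflow int.
const int EXP_ZERO = -(1 << 28);

// Highest set bit (0-based); -1 for zero.  Fixed 64-iteration scan.
inline int msb64(uint64_t x) {
  int m = -1;
  for (int i = 0; i < 64; ++i) m = ((x >> i) & 1ULL) ? i : m;
  return m;
}

// Right shift truncating toward zero (branch-free enough for the trace-level
// contract; shifts compile to constant-latency ops).
inline int64_t shr_tz(int64_t v, int s) {
  uint64_t a = (uint64_t)(v < 0 ? -v : v);
  a >>= (s > 63 ? 63 : s);
  if (s > 63) a = 0;
  return v < 0 ? -(int64_t)a : (int64_t)a;
}

// (a * b) >> s with truncation toward zero, via 128-bit product.
inline int64_t mul_shr(int64_t a, int64_t b, int s) {
  i128 p = (i128)a * (i128)b;
  int neg = p < 0;
  i128 ap = neg ? -p : p;
  ap >>= s;
  int64_t r = (int64_t)ap;
  return neg ? -r : r;
}

// Restoring long division, fixed `width` iterations; den == 0 yields the
// all-ones sentinel within `width` bits, never a trap.
inline uint64_t ct_div_u64(uint64_t num, uint64_t den, int width) {
  uint64_t R = 0, Q = 0;
  for (int i = width - 1; i >= 0; --i) {
    R = (R << 1) | ((num >> i) & 1ULL);
    uint64_t ge = (uint64_t)(R >= den);
    R -= ge * den;
    Q |= ge << i;
  }
  return Q;
}

// 128-bit restoring division with a fixed 127-iteration schedule.
inline i128 ct_div_u128(i128 num, i128 den) {
  i128 R = 0, Q = 0;
  for (int i = 126; i >= 0; --i) {
    R = (R << 1) | ((num >> i) & 1);
    int ge = (R >= den);
    R -= ge ? den : (i128)0;
    Q |= (i128)ge << i;
  }
  return Q;
}

// Normalize an array sharing exponent e so that max|m| lands in
// [2^(F-1), 2^F); returns the new exponent (EXP_ZERO when all zero).
inline int normalize_arr(int64_t *m, int n, int F, int e) {
  uint64_t mx = 0;
  for (int i = 0; i < n; ++i) {
    uint64_t a = (uint64_t)(m[i] < 0 ? -m[i] : m[i]);
    mx = a > mx ? a : mx;
  }
  int msb = msb64(mx);
  if (msb < 0) {
    for (int i = 0; i < n; ++i) m[i] = 0;
    return EXP_ZERO;
  }
  int shift = msb - (F - 1);
  if (shift > 0) {
    for (int i = 0; i < n; ++i) m[i] = shr_tz(m[i], shift);
  } else if (shift < 0) {
    for (int i = 0; i < n; ++i) m[i] <<= (-shift);
  }
  return e + shift;
}

// Divide a nonnegative vector by its sum (constant-time reciprocal, then a
// branch-free elementwise multiply) so that entries sum to 1 at exponent 0.
// All-zero input becomes the uniform distribution 1/n.
inline int renorm_dist(int64_t *m, int n, int F) {
  int e = normalize_arr(m, n, F, 0); // exponent irrelevant: output is a distribution
  if (e == EXP_ZERO) {
    int64_t u = (int64_t)ct_div_u64(1ULL << F, (uint64_t)n, 63);
    for (int i = 0; i < n; ++i) m[i] = u;
    return normalize_arr(m, n, F, 0);
  }
  i128 S = 0;
  for (int i = 0; i < n; ++i) S += m[i];
  // msb of S
  int s = 0;
  for (int b = 0; b < 127; ++b) s = ((S >> b) & 1) ? b : s;
  // reciprocal with 6 guard bits: inv ~ 2^(s+F+6) / S
  i128 inv = ct_div_u128((i128)1 << (s + F + 6), S);
  for (int i = 0; i < n; ++i) {
    i128 p = (i128)m[i] * inv;
    m[i] = (int64_t)(p >> (s + 6));
  }
  return normalize_arr(m, n, F, 0);
}

} // namespace dfpc
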