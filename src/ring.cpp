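// Fixed-width ring arithmetic over Z_{2^k}, vectorized over elements.
// Elements are stored as L = ceil(k/32) base-2^32 limbs (little-endian),
// one column per element, each limb held exactly in a double.
// All operations truncate to k bits, i.e. reduce mod 2^k.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#ifdef __GLIBC__
#include <malloc.h>
#endif

using namespace Rcpp;

// Large limb matrices are allocated and freed at high rate; keeping freed
// arenas inside the process (instead of returning pages to the OS) avoids
// refaulting them on every protocol step.
// [[Rcpp::export]]
bool rl_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1 << 30);
  mallopt(M_TRIM_THRESHOLD, 1 << 30);
  return true;
#else
  return false;
#endif
}

static int nlimbs(int k) { return (k + 31) / 32; }

// mask for the top limb
static uint32_t top_mask(int k) {
  int r = k % 32;
  return r == 0 ? 0xffffffffu : ((r == 32) ? 0xffffffffu : ((1u << r) - 1u));
}

static void load_col(const NumericMatrix& A, int j, std::vector<uint64_t>& a) {
  int L = A.nrow();
  for (int i = 0; i < L; ++i) a[i] = (uint64_t)A(i, j);
}

static void store_col(NumericMatrix& R, int j, const std::vector<uint64_t>& r,
                      uint32_t tmask) {
  int L = R.nrow();
  for (int i = 0; i < L; ++i) {
    uint64_t v = r[i] & 0xffffffffu;
    if (i == L - 1) v &= tmask;
    R(i, j) = (double)v;
  }
}

static void check_dims(const NumericMatrix& A, int k) {
  if (A.nrow() != nlimbs(k)) stop("limb matrix has wrong number of rows for k");
}

// broadcast rule: ncol(A)==ncol(B), or either is 1
static int out_cols(int na, int nb) {
  if (na == nb) return na;
  if (na == 1) return nb;
  if (nb == 1) return na;
  stop("incompatible element counts");
}

// [[Rcpp::export]]
int rl_nlimbs(int k) { return nlimbs(k); }

// pointer-based kernels on column-major limb data; pa/pb column strides are
// 0 when that operand has a single (recycled) column
static inline void add_col(const double* a, const double* b, double* r,
                           int L, uint32_t tm) {
  uint64_t carry = 0;
  for (int i = 0; i < L; ++i) {
    uint64_t t = (uint64_t)a[i] + (uint64_t)b[i] + carry;
    r[i] = (double)(uint32_t)t;
    carry = t >> 32;
  }
  r[L - 1] = (double)((uint32_t)r[L - 1] & tm);
}

static inline void sub_col(const double* a, const double* b, double* r,
                           int L, uint32_t tm) {
  int64_t borrow = 0;
  for (int i = 0; i < L; ++i) {
    int64_t t = (int64_t)a[i] - (int64_t)b[i] - borrow;
    if (t < 0) { t += ((int64_t)1 << 32); borrow = 1; } else borrow = 0;
    r[i] = (double)(uint64_t)t;
  }
  r[L - 1] = (double)((uint32_t)r[L - 1] & tm);
}

static inline void mul_col(const double* a, const double* b, double* r,
                           uint64_t* scratch, int L, uint32_t tm) {
  for (int i = 0; i < L; ++i) scratch[i] = 0;
  for (int i = 0; i < L; ++i) {
    uint64_t ai = (uint64_t)a[i];
    if (ai == 0) continue;
    uint64_t carry = 0;
    for (int m = 0; m + i < L; ++m) {
      uint64_t t = ai * (uint64_t)b[m] + scratch[i + m] + carry;
      scratch[i + m] = t & 0xffffffffu;
      carry = t >> 32;
    }
  }
  for (int i = 0; i < L; ++i) r[i] = (double)scratch[i];
  r[L - 1] = (double)((uint32_t)scratch[L - 1] & tm);
}

// [[Rcpp::export]]
NumericMatrix rl_add(const NumericMatrix& A, const NumericMatrix& B, int k) {
  check_dims(A, k); check_dims(B, k);
  int L = nlimbs(k), n = out_cols(A.ncol(), B.ncol());
  uint32_t tm = top_mask(k);
  NumericMatrix R(L, n);
  const double* pa = A.begin(); const double* pb = B.begin();
  double* pr = R.begin();
  size_t sa = A.ncol() == 1 ? 0 : L, sb = B.ncol() == 1 ? 0 : L;
  for (int j = 0; j < n; ++j)
    add_col(pa + sa * j, pb + sb * j, pr + (size_t)L * j, L, tm);
  return R;
}

// [[Rcpp::export]]
NumericMatrix rl_sub(const NumericMatrix& A, const NumericMatrix& B, int k) {
  check_dims(A, k); check_dims(B, k);
  int L = nlimbs(k), n = out_cols(A.ncol(), B.ncol());
  uint32_t tm = top_mask(k);
  NumericMatrix R(L, n);
  const double* pa = A.begin(); const double* pb = B.begin();
  double* pr = R.begin();
  size_t sa = A.ncol() == 1 ? 0 : L, sb = B.ncol() == 1 ? 0 : L;
  for (int j = 0; j < n; ++j)
    sub_col(pa + sa * j, pb + sb * j, pr + (size_t)L * j, L, tm);
  return R;
}

// [[Rcpp::export]]
NumericMatrix rl_neg(const NumericMatrix& A, int k) {
  NumericMatrix zero(nlimbs(k), 1);
  return rl_sub(zero, A, k);
}

// [[Rcpp::export]]
NumericMatrix rl_mul(const NumericMatrix& A, const NumericMatrix& B, int k) {
  check_dims(A, k); check_dims(B, k);
  int L = nlimbs(k), n = out_cols(A.ncol(), B.ncol());
  uint32_t tm = top_mask(k);
  NumericMatrix R(L, n);
  const double* pa = A.begin(); const double* pb = B.begin();
  double* pr = R.begin();
  size_t sa = A.ncol() == 1 ? 0 : L, sb = B.ncol() == 1 ? 0 : L;
  std::vector<uint64_t> scratch(L);
  for (int j = 0; j < n; ++j)
    mul_col(pa + sa * j, pb + sb * j, pr + (size_t)L * j, scratch.data(), L, tm);
  return R;
}

// fused sharing: draw two uniform share matrices and set the third so the
// shares sum to V mod 2^k (one pass, one RNG acquisition)
// [[Rcpp::export]]
List rl_share(const NumericMatrix& V, int k) {
  check_dims(V, k);
  int L = nlimbs(k), n = V.ncol();
  uint32_t tm = top_mask(k);
  NumericMatrix S0(L, n), S1(L, n), S2(L, n);
  double* p0 = S0.begin(); double* p1 = S1.begin(); double* p2 = S2.begin();
  const double* pv = V.begin();
  GetRNGstate();
  for (size_t t = 0; t < (size_t)L * n; ++t) {
    uint32_t hi = (uint32_t)(unif_rand() * 65536.0);
    uint32_t lo = (uint32_t)(unif_rand() * 65536.0);
    if (hi > 65535u) hi = 65535u;
    if (lo > 65535u) lo = 65535u;
    p0[t] = (double)((hi << 16) | lo);
    hi = (uint32_t)(unif_rand() * 65536.0);
    lo = (uint32_t)(unif_rand() * 65536.0);
    if (hi > 65535u) hi = 65535u;
    if (lo > 65535u) lo = 65535u;
    p1[t] = (double)((hi << 16) | lo);
  }
  PutRNGstate();
  for (int j = 0; j < n; ++j) {
    double* c0 = p0 + (size_t)L * j;
    double* c1 = p1 + (size_t)L * j;
    c0[L - 1] = (double)((uint32_t)c0[L - 1] & tm);
    c1[L - 1] = (double)((uint32_t)c1[L - 1] & tm);
    double* c2 = p2 + (size_t)L * j;
    sub_col(pv + (size_t)L * j, c0, c2, L, tm);
    sub_col(c2, c1, c2, L, tm);
  }
  return List::create(S0, S1, S2);
}

// fused Beaver-triple generation: draws alpha, beta implicitly as sums of
// uniform shares, computes gamma = alpha*beta per column on the stack and
// shares it; returns the 9 share matrices (a0..a2, b0..b2, c0..c2)
// [[Rcpp::export]]
List rl_triple(int n, int k) {
  int L = nlimbs(k);
  uint32_t tm = top_mask(k);
  List out(9);
  std::vector<double*> p(9);
  for (int t = 0; t < 9; ++t) {
    NumericMatrix M(L, n);
    out[t] = M;
    p[t] = ((NumericMatrix)out[t]).begin();
  }
  std::vector<double> alpha(L), beta(L), gamma(L), tmp(L);
  std::vector<uint64_t> scratch(L);
  GetRNGstate();
  auto rnd_limb = [&]() -> double {
    uint32_t hi = (uint32_t)(unif_rand() * 65536.0);
    uint32_t lo = (uint32_t)(unif_rand() * 65536.0);
    if (hi > 65535u) hi = 65535u;
    if (lo > 65535u) lo = 65535u;
    return (double)((hi << 16) | lo);
  };
  for (int j = 0; j < n; ++j) {
    size_t off = (size_t)L * j;
    // a0,a1,a2 and b0,b1,b2 uniform; alpha, beta are their sums
    for (int t = 0; t < 6; ++t) {
      double* col = p[t] + off;
      for (int i = 0; i < L; ++i) col[i] = rnd_limb();
      col[L - 1] = (double)((uint32_t)col[L - 1] & tm);
    }
    add_col(p[0] + off, p[1] + off, alpha.data(), L, tm);
    add_col(alpha.data(), p[2] + off, alpha.data(), L, tm);
    add_col(p[3] + off, p[4] + off, beta.data(), L, tm);
    add_col(beta.data(), p[5] + off, beta.data(), L, tm);
    mul_col(alpha.data(), beta.data(), gamma.data(), scratch.data(), L, tm);
    // c0, c1 uniform; c2 = gamma - c0 - c1
    for (int t = 6; t < 8; ++t) {
      double* col = p[t] + off;
      for (int i = 0; i < L; ++i) col[i] = rnd_limb();
      col[L - 1] = (double)((uint32_t)col[L - 1] & tm);
    }
    sub_col(gamma.data(), p[6] + off, tmp.data(), L, tm);
    sub_col(tmp.data(), p[7] + off, p[8] + off, L, tm);
  }
  PutRNGstate();
  return out;
}

// fully fused secure multiplication: per column, draw a fresh Beaver triple
// on the stack (never materialized, never reused), open the masked
// differences and combine. Allocates only the three result share matrices.
// [[Rcpp::export]]
List rl_mul_shared(const List& a_sh, const List& b_sh, int k) {
  int L = nlimbs(k);
  uint32_t tm = top_mask(k);
  NumericMatrix a0 = a_sh[0], a1 = a_sh[1], a2 = a_sh[2];
  NumericMatrix b0 = b_sh[0], b1 = b_sh[1], b2 = b_sh[2];
  int n = out_cols(a0.ncol(), b0.ncol());
  size_t sa = a0.ncol() == 1 ? 0 : L, sb = b0.ncol() == 1 ? 0 : L;
  const double* pa[3] = { a0.begin(), a1.begin(), a2.begin() };
  const double* pb[3] = { b0.begin(), b1.begin(), b2.begin() };
  NumericMatrix R0(L, n), R1(L, n), R2(L, n);
  double* pr[3] = { R0.begin(), R1.begin(), R2.begin() };
  std::vector<double> ta(3 * L), tb(3 * L), tc(3 * L);
  std::vector<double> alpha(L), beta(L), gamma(L), d(L), e(L),
      acc(L), t1(L), t2(L);
  std::vector<uint64_t> scratch(L);
  GetRNGstate();
  auto rnd_limb = []() -> double {
    uint32_t hi = (uint32_t)(unif_rand() * 65536.0);
    uint32_t lo = (uint32_t)(unif_rand() * 65536.0);
    if (hi > 65535u) hi = 65535u;
    if (lo > 65535u) lo = 65535u;
    return (double)((hi << 16) | lo);
  };
  for (int j = 0; j < n; ++j) {
    size_t oa = sa * j, ob = sb * j, ot = (size_t)L * j;
    // dealer: triple shares; alpha, beta implicit as share sums
    for (int t = 0; t < 6; ++t) {
      double* col = (t < 3 ? ta.data() + t * L : tb.data() + (t - 3) * L);
      for (int i = 0; i < L; ++i) col[i] = rnd_limb();
      col[L - 1] = (double)((uint32_t)col[L - 1] & tm);
    }
    add_col(ta.data(), ta.data() + L, alpha.data(), L, tm);
    add_col(alpha.data(), ta.data() + 2 * L, alpha.data(), L, tm);
    add_col(tb.data(), tb.data() + L, beta.data(), L, tm);
    add_col(beta.data(), tb.data() + 2 * L, beta.data(), L, tm);
    mul_col(alpha.data(), beta.data(), gamma.data(), scratch.data(), L, tm);
    for (int t = 0; t < 2; ++t) {
      double* col = tc.data() + t * L;
      for (int i = 0; i < L; ++i) col[i] = rnd_limb();
      col[L - 1] = (double)((uint32_t)col[L - 1] & tm);
    }
    sub_col(gamma.data(), tc.data(), acc.data(), L, tm);
    sub_col(acc.data(), tc.data() + L, tc.data() + 2 * L, L, tm);
    // open d = a - alpha, e = b - beta
    add_col(pa[0] + oa, pa[1] + oa, d.data(), L, tm);
    add_col(d.data(), pa[2] + oa, d.data(), L, tm);
    sub_col(d.data(), alpha.data(), d.data(), L, tm);
    add_col(pb[0] + ob, pb[1] + ob, e.data(), L, tm);
    add_col(e.data(), pb[2] + ob, e.data(), L, tm);
    sub_col(e.data(), beta.data(), e.data(), L, tm);
    for (int h = 0; h < 3; ++h) {
      mul_col(d.data(), tb.data() + h * L, t1.data(), scratch.data(), L, tm);
      mul_col(e.data(), ta.data() + h * L, t2.data(), scratch.data(), L, tm);
      add_col(t1.data(), t2.data(), acc.data(), L, tm);
      add_col(acc.data(), tc.data() + h * L, acc.data(), L, tm);
      if (h == 0) {
        mul_col(d.data(), e.data(), t1.data(), scratch.data(), L, tm);
        add_col(acc.data(), t1.data(), acc.data(), L, tm);
      }
      for (int i = 0; i < L; ++i) pr[h][ot + i] = acc[i];
    }
  }
  PutRNGstate();
  return List::create(R0, R1, R2);
}

// unsigned comparison: -1, 0, 1 per element
// [[Rcpp::export]]
IntegerVector rl_cmp(const NumericMatrix& A, const NumericMatrix& B) {
  if (A.nrow() != B.nrow()) stop("limb count mismatch");
  int L = A.nrow(), n = out_cols(A.ncol(), B.ncol());
  IntegerVector out(n);
  for (int j = 0; j < n; ++j) {
    int ja = A.ncol() == 1 ? 0 : j, jb = B.ncol() == 1 ? 0 : j;
    int c = 0;
    for (int i = L - 1; i >= 0; --i) {
      double ai = A(i, ja), bi = B(i, jb);
      if (ai > bi) { c = 1; break; }
      if (ai < bi) { c = -1; break; }
    }
    out[j] = c;
  }
  return out;
}

// x: numeric vector, |x| < 2^53; negatives mapped to two's complement
// [[Rcpp::export]]
NumericMatrix rl_from_num(const NumericVector& x, int k) {
  int L = nlimbs(k), n = x.size();
  uint32_t tm = top_mask(k);
  NumericMatrix R(L, n);
  std::vector<uint64_t> r(L);
  for (int j = 0; j < n; ++j) {
    double v = x[j];
    if (v != std::floor(v)) stop("non-integer value in ring conversion");
    if (std::abs(v) >= 9007199254740992.0)
      stop("value exceeds exact double range; build it with ring operations");
    bool neg = v < 0;
    uint64_t u = (uint64_t)(neg ? -v : v);
    for (int i = 0; i < L; ++i) { r[i] = u & 0xffffffffu; u >>= 32; }
    if (u != 0 && L * 32 < 64) {
      // value had bits above the ring width; reduce mod 2^k (masking handles it)
    }
    if (neg) {
      // two's complement: 2^k - |v|
      int64_t borrow = 0;
      for (int i = 0; i < L; ++i) {
        int64_t t = 0 - (int64_t)r[i] - borrow;
        if (t < 0) { t += ((int64_t)1 << 32); borrow = 1; } else borrow = 0;
        r[i] = (uint64_t)t;
      }
    }
    store_col(R, j, r, tm);
  }
  return R;
}

// closest double; signed_ interprets top bit as sign (two's complement)
// [[Rcpp::export]]
NumericVector rl_to_num(const NumericMatrix& A, int k, bool signed_ = false) {
  int L = A.nrow(), n = A.ncol();
  if (L != nlimbs(k)) stop("limb matrix has wrong number of rows for k");
  NumericVector out(n);
  int topbit = (k - 1) % 32;
  for (int j = 0; j < n; ++j) {
    bool neg = false;
    if (signed_) {
      uint32_t top = (uint32_t)A(L - 1, j);
      neg = (top >> topbit) & 1u;
    }
    if (!neg) {
      double v = 0, scale = 1;
      for (int i = 0; i < L; ++i) { v += A(i, j) * scale; scale *= 4294967296.0; }
      out[j] = v;
    } else {
      // compute 2^k - value via limb negation for accuracy near the wrap
      std::vector<uint64_t> r(L);
      int64_t borrow = 0;
      for (int i = 0; i < L; ++i) {
        int64_t t = 0 - (int64_t)((uint64_t)A(i, j)) - borrow;
        if (t < 0) { t += ((int64_t)1 << 32); borrow = 1; } else borrow = 0;
        r[i] = (uint64_t)t;
      }
      r[L - 1] &= top_mask(k);
      double v = 0, scale = 1;
      for (int i = 0; i < L; ++i) { v += (double)r[i] * scale; scale *= 4294967296.0; }
      out[j] = -v;
    }
  }
  return out;
}

// exact decimal string per element (unsigned interpretation)
// [[Rcpp::export]]
CharacterVector rl_to_str(const NumericMatrix& A) {
  int L = A.nrow(), n = A.ncol();
  CharacterVector out(n);
  for (int j = 0; j < n; ++j) {
    std::vector<uint64_t> a(L);
    for (int i = 0; i < L; ++i) a[i] = (uint64_t)A(i, j);
    std::string digits;
    bool zero;
    do {
      // divide by 1e9, collect remainder
      uint64_t rem = 0;
      zero = true;
      for (int i = L - 1; i >= 0; --i) {
        uint64_t cur = (rem << 32) | a[i];
        a[i] = cur / 1000000000ull;
        rem = cur % 1000000000ull;
        if (a[i] != 0) zero = false;
      }
      char buf[16];
      snprintf(buf, sizeof(buf), zero ? "%llu" : "%09llu",
               (unsigned long long)rem);
      digits = std::string(buf) + digits;
    } while (!zero);
    out[j] = digits;
  }
  return out;
}

// uniform ring elements using R's RNG (respects set.seed)
// [[Rcpp::export]]
NumericMatrix rl_rand(int n, int k) {
  int L = nlimbs(k);
  uint32_t tm = top_mask(k);
  NumericMatrix R(L, n);
  GetRNGstate();
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < L; ++i) {
      uint32_t hi = (uint32_t)(unif_rand() * 65536.0);
      uint32_t lo = (uint32_t)(unif_rand() * 65536.0);
      if (hi > 65535u) hi = 65535u;
      if (lo > 65535u) lo = 65535u;
      uint32_t v = (hi << 16) | lo;
      if (i == L - 1) v &= tm;
      R(i, j) = (double)v;
    }
  }
  PutRNGstate();
  return R;
}

// bit matrix (k rows, n cols) of each element, LSB first
// [[Rcpp::export]]
IntegerMatrix rl_bits(const NumericMatrix& A, int k) {
  check_dims(A, k);
  int n = A.ncol();
  IntegerMatrix B(k, n);
  for (int j = 0; j < n; ++j)
    for (int b = 0; b < k; ++b) {
      uint32_t limb = (uint32_t)A(b / 32, j);
      B(b, j) = (limb >> (b % 32)) & 1u;
    }
  return B;
}

// sum columns by 1-based group id (local share summation for dot products)
// [[Rcpp::export]]
NumericMatrix rl_sum_groups(const NumericMatrix& A, int k,
                            const IntegerVector& group, int ngroups) {
  check_dims(A, k);
  int L = nlimbs(k), n = A.ncol();
  if (group.size() != n) stop("group vector length mismatch");
  uint32_t tm = top_mask(k);
  NumericMatrix R(L, ngroups);
  std::vector<std::vector<uint64_t> > acc(ngroups, std::vector<uint64_t>(L, 0));
  for (int j = 0; j < n; ++j) {
    int g = group[j] - 1;
    if (g < 0 || g >= ngroups) stop("group id out of range");
    std::vector<uint64_t>& r = acc[g];
    uint64_t carry = 0;
    for (int i = 0; i < L; ++i) {
      uint64_t t = r[i] + (uint64_t)A(i, j) + carry;
      r[i] = t & 0xffffffffu;
      carry = t >> 32;
    }
  }
  for (int g = 0; g < ngroups; ++g) store_col(R, g, acc[g], tm);
  return R;
}
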