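// Negacyclic ring arithmetic mod a composite of one or two NTT-friendly
// primes (< 2^50 each, so residues are exact in doubles and products fit in
// 128-bit integers). The composite modulus q = prod(primes) is the single
// logical coefficient modulus of the toy CKKS scheme; the per-prime residue
// representation is an internal arithmetic device only.
#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <vector>
using namespace Rcpp;

typedef unsigned __int128 u128;
typedef uint64_t u64;

static u64 mulmod(u64 a, u64 b, u64 p) { return (u64)((u128)a * b % p); }
static u64 addmod(u64 a, u64 b, u64 p) { u64 s = a + b; return s >= p ? s - p : s; }
static u64 submod(u64 a, u64 b, u64 p) { return a >= b ? a - b : a + p - b; }

static u64 powmod(u64 a, u64 e, u64 p) {
  u64 r = 1; a %= p;
  while (e) { if (e & 1) r = mulmod(r, a, p); a = mulmod(a, a, p); e >>= 1; }
  return r;
}

// deterministic Miller-Rabin, valid for all 64-bit inputs
static bool is_prime_u64(u64 n) {
  if (n < 2) return false;
  for (u64 p : {2ull, 3ull, 5ull, 7ull, 11ull, 13ull, 17ull, 19ull, 23ull, 29ull, 31ull, 37ull}) {
    if (n % p == 0) return n == p;
  }
  u64 d = n - 1; int s = 0;
  while (!(d & 1)) { d >>= 1; s++; }
  for (u64 a : {2ull, 3ull, 5ull, 7ull, 11ull, 13ull, 17ull, 19ull, 23ull, 29ull, 31ull, 37ull}) {
    u64 x = powmod(a, d, n);
    if (x == 1 || x == n - 1) continue;
    bool comp = true;
    for (int i = 1; i < s; i++) {
      x = mulmod(x, x, n);
      if (x == n - 1) { comp = false; break; }
    }
    if (comp) return false;
  }
  return true;
}

// smallest primitive root mod prime p
static u64 primitive_root(u64 p) {
  u64 phi = p - 1;
  std::vector<u64> fac;
  u64 m = phi;
  for (u64 d = 2; d * d <= m; d++) {
    if (m % d == 0) { fac.push_back(d); while (m % d == 0) m /= d; }
  }
  if (m > 1) fac.push_back(m);
  for (u64 g = 2; g < p; g++) {
    bool ok = true;
    for (u64 f : fac) if (powmod(g, phi / f, p) == 1) { ok = false; break; }
    if (ok) return g;
  }
  return 0;
}

// [[Rcpp::export]]
NumericVector find_ntt_primes_cpp(int total_bits, int n) {
  // one prime if <= 50 bits requested, else two of ~half size (<= 50 each)
  int nprimes = total_bits <= 50 ? 1 : 2;
  std::vector<int> bits(nprimes);
  if (nprimes == 1) bits[0] = std::max(total_bits, 20);
  else {
    int half = (total_bits + 1) / 2;
    if (half > 50) half = 50;
    bits[0] = half; bits[1] = half;
  }
  NumericVector out(nprimes);
  u64 step = 2ull * (u64)n;
  u64 prev = 0;
  for (int i = 0; i < nprimes; i++) {
    u64 base = (1ull << bits[i]);
    u64 cand = base - (base % step) + 1;
    while (cand <= base) cand += step;
    while (!is_prime_u64(cand) || cand == prev) cand += step;
    prev = cand;
    out[i] = (double)cand;
  }
  return out;
}

struct NttTables {
  u64 p;
  int n;
  std::vector<u64> psi_rev, psi_inv_rev; // bit-reversed powers of the 2n-th root
  u64 n_inv;
};

static std::map<std::pair<u64, int>, NttTables> ntt_cache;

static int bitrev(int x, int bits) {
  int r = 0;
  for (int i = 0; i < bits; i++) { r = (r << 1) | (x & 1); x >>= 1; }
  return r;
}

static NttTables &get_tables(u64 p, int n) {
  auto key = std::make_pair(p, n);
  auto it = ntt_cache.find(key);
  if (it != ntt_cache.end()) return it->second;
  NttTables t;
  t.p = p; t.n = n;
  u64 g = primitive_root(p);
  u64 psi = powmod(g, (p - 1) / (2ull * n), p); // primitive 2n-th root
  u64 psi_inv = powmod(psi, p - 2, p);
  int bits = 0;
  while ((1 << bits) < n) bits++;
  t.psi_rev.resize(n); t.psi_inv_rev.resize(n);
  for (int i = 0; i < n; i++) {
    int r = bitrev(i, bits);
    t.psi_rev[i] = powmod(psi, (u64)r, p);
    t.psi_inv_rev[i] = powmod(psi_inv, (u64)r, p);
  }
  t.n_inv = powmod((u64)n, p - 2, p);
  ntt_cache[key] = t;
  return ntt_cache[key];
}

// in-place negacyclic NTT, Longa-Naehrig merged-twist formulation
static void ntt_fwd(std::vector<u64> &a, const NttTables &tb) {
  int n = tb.n; u64 p = tb.p;
  int t = n;
  for (int m = 1; m < n; m <<= 1) {
    t >>= 1;
    for (int i = 0; i < m; i++) {
      int j1 = 2 * i * t, j2 = j1 + t;
      u64 S = tb.psi_rev[m + i];
      for (int j = j1; j < j2; j++) {
        u64 U = a[j], V = mulmod(a[j + t], S, p);
        a[j] = addmod(U, V, p);
        a[j + t] = submod(U, V, p);
      }
    }
  }
}

static void ntt_inv(std::vector<u64> &a, const NttTables &tb) {
  int n = tb.n; u64 p = tb.p;
  int t = 1;
  for (int m = n; m > 1; m >>= 1) {
    int j1 = 0, h = m >> 1;
    for (int i = 0; i < h; i++) {
      int j2 = j1 + t;
      u64 S = tb.psi_inv_rev[h + i];
      for (int j = j1; j < j2; j++) {
        u64 U = a[j], V = a[j + t];
        a[j] = addmod(U, V, p);
        a[j + t] = mulmod(submod(U, V, p), S, p);
      }
      j1 += 2 * t;
    }
    t <<= 1;
  }
  for (int i = 0; i < n; i++) a[i] = mulmod(a[i], tb.n_inv, p);
}

// negacyclic product of two polynomials, per-prime residue columns
// [[Rcpp::export]]
NumericMatrix poly_mul_cpp(NumericMatrix a, NumericMatrix b, NumericVector primes) {
  int n = a.nrow(), L = primes.size();
  NumericMatrix out(n, L);
  for (int l = 0; l < L; l++) {
    u64 p = (u64)primes[l];
    NttTables &t = get_tables(p, n);
    std::vector<u64> x(n), y(n);
    for (int i = 0; i < n; i++) { x[i] = (u64)a(i, l); y[i] = (u64)b(i, l); }
    ntt_fwd(x, t); ntt_fwd(y, t);
    for (int i = 0; i < n; i++) x[i] = mulmod(x[i], y[i], p);
    ntt_inv(x, t);
    for (int i = 0; i < n; i++) out(i, l) = (double)x[i];
  }
  return out;
}

// centered CRT lift of residue columns to signed doubles in (-q/2, q/2]
// [[Rcpp::export]]
NumericVector crt_center_cpp(NumericMatrix a, NumericVector primes) {
  int n = a.nrow(), L = primes.size();
  NumericVector out(n);
  if (L == 1) {
    u64 p = (u64)primes[0];
    for (int i = 0; i < n; i++) {
      u64 x = (u64)a(i, 0);
      out[i] = (x > p / 2) ? -(double)(p - x) : (double)x;
    }
    return out;
  }
  u64 p1 = (u64)primes[0], p2 = (u64)primes[1];
  u64 p1_inv = powmod(p1 % p2, p2 - 2, p2);
  u128 q = (u128)p1 * p2;
  u128 qhalf = q / 2;
  for (int i = 0; i < n; i++) {
    u64 x1 = (u64)a(i, 0), x2 = (u64)a(i, 1);
    u64 d = submod(x2, x1 % p2, p2);
    u64 tt = mulmod(d, p1_inv, p2);
    u128 x = (u128)x1 + (u128)p1 * tt; // in [0, q)
    if (x > qhalf) {
      u128 neg = q - x;
      out[i] = -((double)(u64)(neg >> 60)) * 1152921504606846976.0 - (double)(u64)(neg & ((((u128)1) << 60) - 1));
    } else {
      out[i] = ((double)(u64)(x >> 60)) * 1152921504606846976.0 + (double)(u64)(x & ((((u128)1) << 60) - 1));
    }
  }
  return out;
}

// base-2^w digit decomposition of the CRT lift; returns list of n x L matrices
// [[Rcpp::export]]
List digit_decompose_cpp(NumericMatrix a, NumericVector primes, int base_bits, int ndigits) {
  int n = a.nrow(), L = primes.size();
  u64 mask = (1ull << base_bits) - 1;
  List out(ndigits);
  std::vector<NumericMatrix> digs;
  for (int d = 0; d < ndigits; d++) digs.push_back(NumericMatrix(n, L));
  if (L == 1) {
    for (int i = 0; i < n; i++) {
      u64 x = (u64)a(i, 0);
      for (int d = 0; d < ndigits; d++) { digs[d](i, 0) = (double)(x & mask); x >>= base_bits; }
    }
  } else {
    u64 p1 = (u64)primes[0], p2 = (u64)primes[1];
    u64 p1_inv = powmod(p1 % p2, p2 - 2, p2);
    for (int i = 0; i < n; i++) {
      u64 x1 = (u64)a(i, 0), x2 = (u64)a(i, 1);
      u64 d12 = submod(x2, x1 % p2, p2);
      u64 tt = mulmod(d12, p1_inv, p2);
      u128 x = (u128)x1 + (u128)p1 * tt;
      for (int d = 0; d < ndigits; d++) {
        u64 dig = (u64)(x & mask);
        digs[d](i, 0) = (double)(dig % p1);
        digs[d](i, 1) = (double)(dig % p2);
        x >>= base_bits;
      }
    }
  }
  for (int d = 0; d < ndigits; d++) out[d] = digs[d];
  return out;
}

// exact reduction of (possibly huge) integral double values mod p; R's `%%`
// on doubles loses exactness beyond 2^52, so the reduction goes through
// 128-bit integers (conversion of an integral double below 2^127 is exact)
// [[Rcpp::export]]
NumericMatrix mod_reduce_cpp(NumericVector x, NumericVector primes) {
  int n = x.size(), L = primes.size();
  typedef __int128 i128;
  NumericMatrix out(n, L);
  for (int l = 0; l < L; l++) {
    i128 p = (i128)(u64)primes[l];
    for (int i = 0; i < n; i++) {
      i128 v = (i128)x[i];
      i128 r = v % p;
      if (r < 0) r += p;
      out(i, l) = (double)(u64)r;
    }
  }
  return out;
}
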