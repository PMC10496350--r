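// SHA-256, HMAC-SHA256 and a hash-counter keystream, self-contained.
// Used for authenticated symmetric protection of key shares and partial
// decryptions exchanged through the shared space.
#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
using namespace Rcpp;

typedef uint32_t u32;
typedef uint64_t u64;

static const u32 K[64] = {
  0x428a2f98, 0x71374491, 0xb5c0fbcf, 0xe9b5dba5, 0x3956c25b, 0x59f111f1,
  0x923f82a4, 0xab1c5ed5, 0xd807aa98, 0x12835b01, 0x243185be, 0x550c7dc3,
  0x72be5d74, 0x80deb1fe, 0x9bdc06a7, 0xc19bf174, 0xe49b69c1, 0xefbe4786,
  0x0fc19dc6, 0x240ca1cc, 0x2de92c6f, 0x4a7484aa, 0x5cb0a9dc, 0x76f988da,
  0x983e5152, 0xa831c66d, 0xb00327c8, 0xbf597fc7, 0xc6e00bf3, 0xd5a79147,
  0x06ca6351, 0x14292967, 0x27b70a85, 0x2e1b2138, 0x4d2c6dfc, 0x53380d13,
  0x650a7354, 0x766a0abb, 0x81c2c92e, 0x92722c85, 0xa2bfe8a1, 0xa81a664b,
  0xc24b8b70, 0xc76c51a3, 0xd192e819, 0xd6990624, 0xf40e3585, 0x106aa070,
  0x19a4c116, 0x1e376c08, 0x2748774c, 0x34b0bcb5, 0x391c0cb3, 0x4ed8aa4a,
  0x5b9cca4f, 0x682e6ff3, 0x748f82ee, 0x78a5636f, 0x84c87814, 0x8cc70208,
  0x90befffa, 0xa4506ceb, 0xbef9a3f7, 0xc67178f2};

static inline u32 rotr(u32 x, int c) { return (x >> c) | (x << (32 - c)); }

struct Sha256 {
  u32 h[8];
  u64 len;
  unsigned char buf[64];
  size_t buflen;
  Sha256() { reset(); }
  void reset() {
    static const u32 H0[8] = {0x6a09e667, 0xbb67ae85, 0x3c6ef372, 0xa54ff53a,
                              0x510e527f, 0x9b05688c, 0x1f83d9ab, 0x5be0cd19};
    memcpy(h, H0, sizeof(h));
    len = 0; buflen = 0;
  }
  void block(const unsigned char *p) {
    u32 w[64];
    for (int i = 0; i < 16; i++)
      w[i] = ((u32)p[4 * i] << 24) | ((u32)p[4 * i + 1] << 16) |
             ((u32)p[4 * i + 2] << 8) | (u32)p[4 * i + 3];
    for (int i = 16; i < 64; i++) {
      u32 s0 = rotr(w[i - 15], 7) ^ rotr(w[i - 15], 18) ^ (w[i - 15] >> 3);
      u32 s1 = rotr(w[i - 2], 17) ^ rotr(w[i - 2], 19) ^ (w[i - 2] >> 10);
      w[i] = w[i - 16] + s0 + w[i - 7] + s1;
    }
    u32 a = h[0], b = h[1], c = h[2], d = h[3], e = h[4], f = h[5], g = h[6], hh = h[7];
    for (int i = 0; i < 64; i++) {
      u32 S1 = rotr(e, 6) ^ rotr(e, 11) ^ rotr(e, 25);
      u32 ch = (e & f) ^ (~e & g);
      u32 t1 = hh + S1 + ch + K[i] + w[i];
      u32 S0 = rotr(a, 2) ^ rotr(a, 13) ^ rotr(a, 22);
      u32 maj = (a & b) ^ (a & c) ^ (b & c);
      u32 t2 = S0 + maj;
      hh = g; g = f; f = e; e = d + t1; d = c; c = b; b = a; a = t1 + t2;
    }
    h[0] += a; h[1] += b; h[2] += c; h[3] += d;
    h[4] += e; h[5] += f; h[6] += g; h[7] += hh;
  }
  void update(const unsigned char *p, size_t m) {
    len += m;
    while (m > 0) {
      size_t take = 64 - buflen;
      if (take > m) take = m;
      memcpy(buf + buflen, p, take);
      buflen += take; p += take; m -= take;
      if (buflen == 64) { block(buf); buflen = 0; }
    }
  }
  void final(unsigned char out[32]) {
    u64 bitlen = len * 8;
    unsigned char pad = 0x80;
    update(&pad, 1);
    unsigned char z = 0;
    while (buflen != 56) update(&z, 1);
    unsigned char lenb[8];
    for (int i = 0; i < 8; i++) lenb[i] = (unsigned char)(bitlen >> (56 - 8 * i));
    update(lenb, 8);
    for (int i = 0; i < 8; i++)
      for (int j = 0; j < 4; j++) out[4 * i + j] = (unsigned char)(h[i] >> (24 - 8 * j));
  }
};

static void sha256_buf(const unsigned char *p, size_t n, unsigned char out[32]) {
  Sha256 s; s.update(p, n); s.final(out);
}

// [[Rcpp::export]]
RawVector sha256_cpp(RawVector data) {
  unsigned char out[32];
  sha256_buf(data.size() ? (const unsigned char *)&data[0] : (const unsigned char *)"", data.size(), out);
  RawVector r(32);
  memcpy(&r[0], out, 32);
  return r;
}

static void hmac_sha256(const unsigned char *key, size_t keylen,
                        const unsigned char *msg, size_t msglen,
                        unsigned char out[32]) {
  unsigned char k[64];
  memset(k, 0, 64);
  if (keylen > 64) sha256_buf(key, keylen, k);
  else memcpy(k, key, keylen);
  unsigned char ipad[64], opad[64];
  for (int i = 0; i < 64; i++) { ipad[i] = k[i] ^ 0x36; opad[i] = k[i] ^ 0x5c; }
  unsigned char inner[32];
  Sha256 s;
  s.update(ipad, 64); s.update(msg, msglen); s.final(inner);
  Sha256 s2;
  s2.update(opad, 64); s2.update(inner, 32); s2.final(out);
}

// [[Rcpp::export]]
RawVector hmac_sha256_cpp(RawVector key, RawVector msg) {
  unsigned char out[32];
  hmac_sha256(key.size() ? (const unsigned char *)&key[0] : (const unsigned char *)"", key.size(),
              msg.size() ? (const unsigned char *)&msg[0] : (const unsigned char *)"", msg.size(), out);
  RawVector r(32);
  memcpy(&r[0], out, 32);
  return r;
}

// CTR-mode keystream: block i = SHA256(key || nonce || i)
// [[Rcpp::export]]
RawVector keystream_cpp(RawVector key, RawVector nonce, int nbytes) {
  RawVector out(nbytes);
  std::vector<unsigned char> pre(key.size() + nonce.size() + 8);
  if (key.size()) memcpy(pre.data(), &key[0], key.size());
  if (nonce.size()) memcpy(pre.data() + key.size(), &nonce[0], nonce.size());
  int pos = 0;
  u64 ctr = 0;
  unsigned char blk[32];
  while (pos < nbytes) {
    for (int i = 0; i < 8; i++)
      pre[key.size() + nonce.size() + i] = (unsigned char)(ctr >> (56 - 8 * i));
    sha256_buf(pre.data(), pre.size(), blk);
    int take = nbytes - pos < 32 ? nbytes - pos : 32;
    memcpy(&out[pos], blk, take);
    pos += take;
    ctr++;
  }
  return out;
}
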