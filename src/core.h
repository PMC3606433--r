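// Shared compression engine: byte-wise range coder and the predictor zoo
// (direct frequency models, adaptive bit models, bit-history states, logistic
// mixer, secondary estimation, match model). All arithmetic is integer so
// encoder and decoder are bit-identical across platforms.
#ifndef FQZLITE_CORE_H
#define FQZLITE_CORE_H

#include <cstdint>
#include <cstring>
#include <vector>
#include <memory>
#include <stdexcept>
#include <string>

namespace fqz {

// ---------------------------------------------------------------- range coder
// 32-bit low/range coder with byte-wise renormalisation and carry propagation
// through a cached byte plus a run of 0xFF bytes (carry counting).
static const uint32_t RC_TOP = 1u << 24;

struct RangeEncoder {
  std::vector<uint8_t> buf;
  uint64_t low = 0;
  uint32_t range = 0xFFFFFFFFu;
  uint8_t cache = 0;
  uint64_t cache_size = 1;

  void shift_low() {
    if ((uint32_t)low < 0xFF000000u || (low >> 32) != 0) {
      uint8_t carry = (uint8_t)(low >> 32);
      uint8_t tmp = cache;
      do {
        buf.push_back((uint8_t)(tmp + carry));
        tmp = 0xFF;
      } while (--cache_size != 0);
      cache = (uint8_t)(low >> 24);
    }
    cache_size++;
    low = (low << 8) & 0xFFFFFFFFull;
  }
  // cum/freq on a total scale `tot` <= 2^16
  void encode(uint32_t cum, uint32_t freq, uint32_t tot) {
    range /= tot;
    low += (uint64_t)cum * range;
    range *= freq;
    while (range < RC_TOP) { range <<= 8; shift_low(); }
  }
  // probability p1 that bit==1, 12-bit scale, clamped to [1,4095]
  void encode_bit(int bit, int p1) {
    if (p1 < 1) p1 = 1; else if (p1 > 4095) p1 = 4095;
    if (bit) encode(0, (uint32_t)p1, 4096);
    else     encode((uint32_t)p1, 4096u - p1, 4096);
  }
  void flush() { for (int i = 0; i < 5; i++) shift_low(); }
};

struct RangeDecoder {
  const uint8_t* in;
  size_t len, pos = 0;
  uint32_t range = 0xFFFFFFFFu, code = 0;
  bool overrun = false;

  RangeDecoder(const uint8_t* p, size_t n) : in(p), len(n) {
    for (int i = 0; i < 5; i++) code = (code << 8) | next();
  }
  uint8_t next() {
    if (pos >= len) { overrun = true; return 0; }
    return in[pos++];
  }
  uint32_t get_freq(uint32_t tot) {
    range /= tot;
    uint32_t f = code / range;
    return f >= tot ? tot - 1 : f;
  }
  void decode(uint32_t cum, uint32_t freq) {
    code -= cum * range;
    range *= freq;
    while (range < RC_TOP) { code = (code << 8) | next(); range <<= 8; }
  }
  int decode_bit(int p1) {
    if (p1 < 1) p1 = 1; else if (p1 > 4095) p1 = 4095;
    uint32_t f = get_freq(4096);
    if (f < (uint32_t)p1) { decode(0, (uint32_t)p1); return 1; }
    decode((uint32_t)p1, 4096u - p1); return 0;
  }
};

// ------------------------------------------------------- logistic stretch map
// squash(d) = 4096/(1+e^(-d/256)) via interpolated table; stretch = inverse.
inline int squash(int d) {
  static const int t[33] = {1,2,3,6,10,16,27,45,73,120,194,310,488,747,1101,
    1546,2047,2549,2994,3348,3607,3785,3901,3975,4024,4050,4068,4079,4085,
    4089,4092,4093,4094};
  if (d >  2047) return 4095;
  if (d < -2047) return 1;
  int w = d & 127;
  d = (d >> 7) + 16;
  return (t[d] * (128 - w) + t[d + 1] * w + 64) >> 7;
}

struct StretchTab {
  short t[4096];
  StretchTab() {
    int pi = 0;
    for (int x = -2047; x <= 2047; x++) {
      int v = squash(x);
      for (int p = pi; p <= v; p++) t[p] = (short)x;
      pi = v + 1;
    }
    for (int p = pi; p < 4096; p++) t[p] = 2047;
  }
};
inline int stretch(int p) {
  static StretchTab tab;
  if (p < 0) p = 0; else if (p > 4095) p = 4095;
  return tab.t[p];
}

// ------------------------------------------------- direct multi-symbol model
// 8-bit counters, +4 increment, halve (rounding up) when a counter would pass
// 255. Coding frequency of symbol i is 2*cnt[i]+1 on total 2*sum+A.
inline void sym_update(uint8_t* c, int A, int sym) {
  int v = c[sym] + 4;
  if (v > 255) {
    for (int i = 0; i < A; i++) c[i] = (uint8_t)((c[i] + 1) >> 1);
    v = c[sym] + 4;
  }
  c[sym] = (uint8_t)v;
}

inline void sym_encode(RangeEncoder& rc, uint8_t* c, int A, int sym) {
  uint32_t cum = 0, tot = 0;
  for (int i = 0; i < sym; i++) cum += 2u * c[i] + 1;
  for (int i = 0; i < A;   i++) tot += 2u * c[i] + 1;
  rc.encode(cum, 2u * c[sym] + 1, tot);
  sym_update(c, A, sym);
}

inline int sym_decode(RangeDecoder& rc, uint8_t* c, int A) {
  uint32_t tot = 0;
  for (int i = 0; i < A; i++) tot += 2u * c[i] + 1;
  uint32_t f = rc.get_freq(tot), cum = 0;
  int sym = 0;
  while (sym < A - 1 && cum + 2u * c[sym] + 1 <= f) { cum += 2u * c[sym] + 1; sym++; }
  rc.decode(cum, 2u * c[sym] + 1);
  sym_update(c, A, sym);
  return sym;
}

// --------------------------------------------------------- adaptive bit model
// Direct context-to-prediction map; the step shrinks with the context count so
// early observations move the estimate quickly and later ones refine it.
struct BitModel {
  uint16_t p = 2048;
  uint8_t n = 0;
  int pr() const { return p; }
  void update(int bit) {
    p = (uint16_t)(p + ((bit << 12) - (int)p) / (n + 2));
    if (p < 1) p = 1; else if (p > 4095) p = 4095;
    if (n < 254) n++;
  }
};

// ------------------------------------------------------- bit-history machine
// 8-bit state: (last bit, saturating run length capped at 40). State 0 = no
// history. States: 1 + bit*40 + (run-1), run in 1..40, sticky at 40.
inline uint8_t bh_next(uint8_t s, int bit) {
  if (s == 0) return (uint8_t)(1 + bit * 40);
  int last = (s - 1) / 40, run = (s - 1) % 40 + 1;
  if (bit == last) { if (run < 40) run++; }
  else { last = bit; run = 1; }
  return (uint8_t)(1 + last * 40 + (run - 1));
}
static const int BH_STATES = 81;

// Indirect model: hashed context -> bit history byte; state -> adaptive p.
struct StateMap {
  std::vector<BitModel> m;
  StateMap() : m(BH_STATES) {}
  int pr(uint8_t s) const { return m[s].pr(); }
  void update(uint8_t s, int bit) { m[s].update(bit); }
};

// ------------------------------------------------------------------- mixer
// Integer logistic mixer: weights 16.16 fixed point, one weight vector per
// selector value, inputs are stretched predictions. Learning rate ~0.002 in
// the stretch domain (update shift 13).
struct Mixer {
  int nin, nsel;
  std::vector<int32_t> w;
  int x[16];
  int nx = 0, sel = 0, pr = 2048;
  Mixer(int nin_, int nsel_) : nin(nin_), nsel(nsel_), w((size_t)nin_ * nsel_, 0) {
    for (size_t i = 0; i < w.size(); i++) w[i] = (1 << 16) / nin_;
  }
  void add(int st) { x[nx++] = st; }
  int mix(int selector) {
    sel = selector;
    int64_t dot = 0;
    int32_t* wp = &w[(size_t)sel * nin];
    for (int i = 0; i < nx; i++) dot += (int64_t)x[i] * wp[i];
    pr = squash((int)(dot >> 16));
    if (pr < 1) pr = 1; else if (pr > 4095) pr = 4095;
    return pr;
  }
  void update(int bit) {
    int err = (bit << 12) - pr;
    int32_t* wp = &w[(size_t)sel * nin];
    for (int i = 0; i < nx; i++) wp[i] += (x[i] * err) >> 13;
    nx = 0;
  }
};

// ---------------------------------------------------------------- SSE / APM
// Refines a prediction with an interpolated table keyed by (context, bucket
// of the stretched input prediction).
struct APM {
  std::vector<uint16_t> t;
  int idx = 0;
  explicit APM(int n) : t((size_t)n * 33) {
    for (int cx = 0; cx < n; cx++)
      for (int j = 0; j < 33; j++)
        t[(size_t)cx * 33 + j] = (uint16_t)(squash((j - 16) * 128) * 16);
  }
  int pp(int pr, int cx) {
    int s = stretch(pr);
    int wgt = s & 127;
    idx = cx * 33 + ((s >> 7) + 16);
    int p = (t[idx] * (128 - wgt) + t[idx + 1] * wgt) >> 11;
    if (p < 1) p = 1; else if (p > 4095) p = 4095;
    return p;
  }
  void update(int bit, int rate = 7) {
    int g = (bit << 16) + (bit << rate) - bit - bit;
    t[idx]     = (uint16_t)(t[idx]     + ((g - t[idx])     >> rate));
    t[idx + 1] = (uint16_t)(t[idx + 1] + ((g - t[idx + 1]) >> rate));
  }
};

// -------------------------------------------------------------- match model
// Byte-stream match model: hash of the last MINLEN bytes -> last position in
// the history buffer. While a match is live the next bit of the predicted
// byte is offered with confidence 1 - 1/(match length in bits); a wrong bit
// cancels the match.
inline int match_p12(long len_bits) {
  if (len_bits < 2) return 2048;
  long p = 4096 - 4096 / len_bits;   // floor; clamped on use
  if (p < 2048) p = 2048;
  if (p > 4095) p = 4095;
  return (int)p;
}

struct MatchModel {
  std::vector<uint8_t> hist;
  std::vector<uint32_t> tab;  // hash -> position after the context
  uint32_t mask;
  int minlen;
  size_t mpos = 0;     // position in hist of predicted next byte
  long mlen = 0;       // matched bytes
  int pred_byte = 0;
  MatchModel(int bits, int minlen_) : tab((size_t)1 << bits, 0),
    mask(((uint32_t)1 << bits) - 1), minlen(minlen_) {}

  uint32_t ctx_hash() const {
    uint32_t h = 2166136261u;
    size_t n = hist.size();
    for (int i = 0; i < minlen; i++) { h ^= hist[n - 1 - i]; h *= 16777619u; }
    return h & mask;
  }
  // call at byte boundary before coding the next byte
  void new_byte() {
    if ((long)hist.size() >= minlen) {
      uint32_t h = ctx_hash();
      if (mlen == 0) {
        uint32_t cand = tab[h];
        if (cand > 0 && cand < hist.size()) {
          // verify the context actually matches (no stored checksum)
          bool ok = cand >= (uint32_t)minlen;
          for (int i = 0; ok && i < minlen; i++)
            ok = hist[cand - 1 - i] == hist[hist.size() - 1 - i];
          if (ok) { mpos = cand; mlen = minlen; }
        }
      }
      tab[h] = (uint32_t)hist.size();
    }
    pred_byte = (mlen > 0 && mpos < hist.size()) ? hist[mpos] : -1;
  }
  // prediction for bit `bitpos` (7..0) given partial byte `part`
  // returns stretched input for the mixer
  int st(int bitpos, int part) {
    if (mlen == 0 || pred_byte < 0) return 0;
    int pb = (pred_byte >> bitpos) & 1;
    int p = match_p12(mlen * 8 + (7 - bitpos));
    return pb ? stretch(p) : -stretch(p);
  }
  void upd_bit(int bitpos, int part, int bit) {
    if (mlen > 0 && pred_byte >= 0) {
      int pb = (pred_byte >> bitpos) & 1;
      if (pb != bit) { mlen = 0; pred_byte = -1; }  // misprediction cancels
    }
  }
  void push(uint8_t byte) {
    hist.push_back(byte);
    if (mlen > 0) { mpos++; mlen++; }
  }
};

// ------------------------------------------------------------------ hashing
inline uint32_t hash_u64(uint64_t x) {
  x ^= x >> 33; x *= 0xff51afd7ed558ccdull;
  x ^= x >> 33; x *= 0xc4ceb9fe1a85ec53ull;
  x ^= x >> 33;
  return (uint32_t)x;
}

// -------------------------------------------------------------------- CRC32
inline uint32_t crc32(const uint8_t* p, size_t n, uint32_t crc = 0) {
  static uint32_t tab[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; i++) {
      uint32_t c = i;
      for (int k = 0; k < 8; k++) c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      tab[i] = c;
    }
    init = true;
  }
  crc = ~crc;
  for (size_t i = 0; i < n; i++) crc = tab[(crc ^ p[i]) & 0xFF] ^ (crc >> 8);
  return ~crc;
}

}  // namespace fqz

#endif
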