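// Base-call codec (non-reference): order-k context models over 2-bit base
// codes with optional reverse-complement training and an optional second
// fixed order-7 model. Model selection takes the model with the strongest
// single-symbol bias (no mixing); the choice depends only on model state so
// the decoder repeats it exactly.
#include <Rcpp.h>
#include "core.h"
using namespace Rcpp;
using namespace fqz;

static inline int base_code(char ch) {
  switch (ch) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    case 'N': case 'n': return 0;  // fixed on decode via quality 0
    default: return -1;
  }
}
static const char BASES[] = "ACGT";

struct SeqModel {
  int k;
  bool hashed;
  size_t nctx, mask;
  std::vector<uint8_t> cnt;
  SeqModel(int k_, bool hashed_) : k(k_), hashed(hashed_) {
    if (hashed) nctx = (size_t)1 << 24;
    else nctx = (size_t)1 << (2 * k);
    mask = nctx - 1;
    cnt.assign(nctx * 4, 0);
  }
  size_t slot(uint64_t ctx) const {
    if (!hashed) return (size_t)(ctx & mask) * 4;
    return (size_t)(hash_u64(ctx * 0x9E3779B97F4A7C15ull + k) & mask) * 4;
  }
};

// strongest single-symbol bias = largest maximum frequency (to any base)
static inline int max_freq(const uint8_t* c) {
  int m = c[0];
  for (int i = 1; i < 4; i++) if (c[i] > m) m = c[i];
  return m;
}

// is model a's strongest single-symbol probability strictly larger than b's?
static inline bool stronger_bias(const uint8_t* a, const uint8_t* b) {
  uint32_t ta = 0, tb = 0;
  for (int i = 0; i < 4; i++) { ta += 2u * a[i] + 1; tb += 2u * b[i] + 1; }
  uint64_t pa = (uint64_t)(2u * max_freq(a) + 1) * tb;
  uint64_t pb = (uint64_t)(2u * max_freq(b) + 1) * ta;
  return pa > pb;
}

struct SeqCoder {
  SeqModel mk;
  SeqModel* m7;
  bool revcomp;
  uint64_t kmask;
  SeqCoder(int k, bool use_rc, bool dual7)
      : mk(k, k >= 15), m7(dual7 ? new SeqModel(7, false) : nullptr),
        revcomp(use_rc) {
    kmask = (k >= 32) ? ~0ull : (((uint64_t)1 << (2 * k)) - 1);
  }
  ~SeqCoder() { delete m7; }
};

// Per-read state for the reverse-complement update: ring of last k+1 bases.
struct RcRing {
  std::vector<int> buf;
  size_t n = 0;
  void reset() { n = 0; buf.clear(); }
  void push(int b) { buf.push_back(b); n++; }
};

static void rc_train(SeqCoder& C, const RcRing& ring) {
  int k = C.mk.k;
  if ((long)ring.n < k + 1) return;
  // window of the last k bases; on the opposite strand the base preceding the
  // window predicts its reverse complement context
  uint64_t rctx = 0;
  size_t end = ring.n;             // bases [end-k, end)
  for (size_t i = 0; i < (size_t)k; i++) {
    int b = ring.buf[end - 1 - i];       // newest first
    rctx = (rctx << 2) | (uint64_t)(3 - b);
  }
  int nxt = 3 - ring.buf[end - k - 1];
  sym_update(&C.mk.cnt[C.mk.slot(rctx)], 4, nxt);
}

// [[Rcpp::export(name = ".c_fqz_seq_encode")]]
RawVector c_fqz_seq_encode(CharacterVector seqs, int k, bool use_revcomp,
                           bool dual7) {
  if (k < 1 || k > 24) stop("k must be in 1..24");
  SeqCoder C(k, use_revcomp, dual7);
  RangeEncoder rc;
  RcRing ring;
  for (R_xlen_t r = 0; r < seqs.size(); r++) {
    std::string s = as<std::string>(seqs[r]);
    uint64_t ctx = 0;
    ring.reset();
    for (size_t i = 0; i < s.size(); i++) {
      int b = base_code(s[i]);
      if (b < 0) stop("sequence contains a character outside ACGTN");
      uint8_t* ck = &C.mk.cnt[C.mk.slot(ctx)];
      uint8_t* cu = ck;
      uint8_t* c7 = nullptr;
      if (C.m7) {
        c7 = &C.m7->cnt[C.m7->slot(ctx & ((1ull << 14) - 1))];
        if (stronger_bias(c7, ck)) cu = c7;  // tie prefers order-k
      }
      uint32_t cum = 0, tot = 0;
      for (int j = 0; j < b; j++) cum += 2u * cu[j] + 1;
      for (int j = 0; j < 4; j++) tot += 2u * cu[j] + 1;
      rc.encode(cum, 2u * cu[b] + 1, tot);
      sym_update(ck, 4, b);
      if (c7 && c7 != ck) sym_update(c7, 4, b);
      ctx = ((ctx << 2) | (uint64_t)b) & C.kmask;
      if (C.revcomp) { ring.push(b); rc_train(C, ring); }
    }
  }
  rc.flush();
  return RawVector(rc.buf.begin(), rc.buf.end());
}

// [[Rcpp::export(name = ".c_fqz_seq_decode")]]
CharacterVector c_fqz_seq_decode(RawVector data, IntegerVector lengths, int k,
                                 bool use_revcomp, bool dual7) {
  if (k < 1 || k > 24) stop("k must be in 1..24");
  SeqCoder C(k, use_revcomp, dual7);
  RangeDecoder rc(RAW(data), data.size());
  CharacterVector out(lengths.size());
  RcRing ring;
  for (R_xlen_t r = 0; r < lengths.size(); r++) {
    int L = lengths[r];
    std::string s(L, 'A');
    uint64_t ctx = 0;
    ring.reset();
    for (int i = 0; i < L; i++) {
      uint8_t* ck = &C.mk.cnt[C.mk.slot(ctx)];
      uint8_t* cu = ck;
      uint8_t* c7 = nullptr;
      if (C.m7) {
        c7 = &C.m7->cnt[C.m7->slot(ctx & ((1ull << 14) - 1))];
        if (stronger_bias(c7, ck)) cu = c7;
      }
      uint32_t tot = 0;
      for (int j = 0; j < 4; j++) tot += 2u * cu[j] + 1;
      uint32_t f = rc.get_freq(tot), cum = 0;
      int b = 0;
      while (b < 3 && cum + 2u * cu[b] + 1 <= f) { cum += 2u * cu[b] + 1; b++; }
      rc.decode(cum, 2u * cu[b] + 1);
      sym_update(ck, 4, b);
      if (c7 && c7 != ck) sym_update(c7, 4, b);
      s[i] = BASES[b];
      ctx = ((ctx << 2) | (uint64_t)b) & C.kmask;
      if (C.revcomp) { ring.push(b); rc_train(C, ring); }
    }
    if (rc.overrun) stop("truncated sequence stream");
    out[r] = s;
  }
  return out;
}
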