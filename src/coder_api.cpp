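// R-facing primitives of the coding engine: order-k adaptive arithmetic
// coding of symbol streams, plus small probes used to test the predictor
// machinery (bit histories, per-step model probabilities, CRC32).
#include <Rcpp.h>
#include "core.h"
using namespace Rcpp;
using namespace fqz;

static size_t ctx_table_size(int alphabet, int order) {
  double sz = 1;
  for (int i = 0; i < order; i++) {
    sz *= alphabet;
    if (sz > 1 << 22) stop("context table too large (alphabet^order > 2^22)");
  }
  return (size_t)sz;
}

// [[Rcpp::export(name = ".c_rc_encode")]]
RawVector c_rc_encode(IntegerVector symbols, int alphabet, int order) {
  if (alphabet < 2 || alphabet > 64) stop("alphabet size must be in 2..64");
  size_t nctx = ctx_table_size(alphabet, order);
  std::vector<uint8_t> cnt(nctx * alphabet, 0);
  RangeEncoder rc;
  size_t ctx = 0;
  for (R_xlen_t i = 0; i < symbols.size(); i++) {
    int s = symbols[i];
    if (s < 0 || s >= alphabet) stop("symbol out of range at position %d", (int)(i + 1));
    sym_encode(rc, &cnt[ctx * alphabet], alphabet, s);
    if (order > 0) ctx = (ctx * alphabet + s) % nctx;
  }
  rc.flush();
  return RawVector(rc.buf.begin(), rc.buf.end());
}

// [[Rcpp::export(name = ".c_rc_decode")]]
IntegerVector c_rc_decode(RawVector data, int n, int alphabet, int order) {
  if (alphabet < 2 || alphabet > 64) stop("alphabet size must be in 2..64");
  size_t nctx = ctx_table_size(alphabet, order);
  std::vector<uint8_t> cnt(nctx * alphabet, 0);
  RangeDecoder rc(RAW(data), data.size());
  IntegerVector out(n);
  size_t ctx = 0;
  for (int i = 0; i < n; i++) {
    int s = sym_decode(rc, &cnt[ctx * alphabet], alphabet);
    out[i] = s;
    if (order > 0) ctx = (ctx * alphabet + s) % nctx;
  }
  if (rc.overrun) stop("truncated stream: ran out of coded bytes");
  return out;
}

// Per-step model probabilities for a symbol stream (the probability the model
// assigned to each symbol just before coding it). Used to check that model
// probabilities form a distribution and to compute ideal code lengths.
// [[Rcpp::export(name = ".c_cm_probe")]]
NumericMatrix c_cm_probe(IntegerVector symbols, int alphabet, int order) {
  size_t nctx = ctx_table_size(alphabet, order);
  std::vector<uint8_t> cnt(nctx * alphabet, 0);
  NumericMatrix out(symbols.size(), alphabet);
  size_t ctx = 0;
  for (R_xlen_t i = 0; i < symbols.size(); i++) {
    uint8_t* c = &cnt[ctx * alphabet];
    double tot = 0;
    for (int j = 0; j < alphabet; j++) tot += 2.0 * c[j] + 1;
    for (int j = 0; j < alphabet; j++) out(i, j) = (2.0 * c[j] + 1) / tot;
    int s = symbols[i];
    if (s < 0 || s >= alphabet) stop("symbol out of range");
    sym_update(c, alphabet, s);
    if (order > 0) ctx = (ctx * alphabet + s) % nctx;
  }
  return out;
}

// [[Rcpp::export(name = ".c_bit_history")]]
IntegerVector c_bit_history(IntegerVector bits) {
  IntegerVector out(bits.size());
  uint8_t s = 0;
  for (R_xlen_t i = 0; i < bits.size(); i++) {
    s = bh_next(s, bits[i] != 0);
    out[i] = s;
  }
  return out;
}

// Counter-halving rule exposed for the ordering-preservation property.
// [[Rcpp::export(name = ".c_halve_counts")]]
IntegerVector c_halve_counts(IntegerVector counts) {
  IntegerVector out(counts.size());
  for (R_xlen_t i = 0; i < counts.size(); i++) out[i] = (counts[i] + 1) >> 1;
  return out;
}

// Integer squash/stretch tables (the fixed-point maps the engine itself uses).
// [[Rcpp::export(name = ".c_squash")]]
IntegerVector c_squash(IntegerVector d) {
  IntegerVector out(d.size());
  for (R_xlen_t i = 0; i < d.size(); i++) out[i] = squash(d[i]);
  return out;
}

// [[Rcpp::export(name = ".c_stretch")]]
IntegerVector c_stretch(IntegerVector p) {
  IntegerVector out(p.size());
  for (R_xlen_t i = 0; i < p.size(); i++) out[i] = stretch(p[i]);
  return out;
}

// [[Rcpp::export(name = ".c_crc32")]]
double c_crc32(RawVector data) {
  return (double)crc32(RAW(data), data.size());
}
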