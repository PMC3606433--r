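// Quality-score codec. Canonical symbols are 0..63: ASCII-33 clamped to 62,
// 0 reserved for bases called N, and 63 a sentinel replacing a terminal run
// (length >= 2) of score 2. Symbols are coded under one of three context
// levels combining the previous two scores, the position in the read, the
// running low-quality indicator and a recent-window maximum. Lossy mode
// "within": every value above Q may be replaced by the value within +-Q whose
// current context prediction is strongest.
#include <Rcpp.h>
#include "core.h"
#include "model_nary.h"
using namespace Rcpp;
using namespace fqz;

static const int QA = 64;   // symbol alphabet

// Context key layout (level 3): q1 | q2/4 | pos bucket | max of last 6 /4 | low flag
static const int L3_CTX = 64 * 16 * 16 * 16 * 2;

struct QState {
  int q1 = 0, q2 = 0;
  int pos = 0;
  int low = 0;             // any score so far < 20
  int win[6] = {0, 0, 0, 0, 0, 0};
  void reset() { q1 = q2 = pos = low = 0; for (int i = 0; i < 6; i++) win[i] = 0; }
  int wmax() const { int m = 0; for (int i = 0; i < 6; i++) if (win[i] > m) m = win[i]; return m; }
  size_t key(int level) const {
    if (level <= 1) return (size_t)q1;
    if (level == 2) return (size_t)q1 * 16 + q2 / 4;
    size_t k = (size_t)q1;
    k = k * 16 + q2 / 4;
    k = k * 16 + std::min(pos, 127) / 8;
    k = k * 16 + std::min(wmax(), 63) / 4;
    k = k * 2 + low;
    return k;
  }
  void push(int q) {
    q2 = q1; q1 = q;
    win[pos % 6] = q;
    if (q > 0 && q < 20) low = 1;
    pos++;
  }
};

static size_t n_ctx(int level) {
  return level <= 1 ? 64 : (level == 2 ? 64 * 16 : L3_CTX);
}

// canonicalize one record; returns symbols (possibly ending in sentinel 63)
static std::vector<int> canon(const std::string& qual, const std::string& seq,
                              bool* clamped) {
  size_t L = qual.size();
  if (seq.size() != L) stop("quality and sequence lengths differ");
  std::vector<int> s(L);
  for (size_t i = 0; i < L; i++) {
    int q = (unsigned char)qual[i] - 33;
    if (q < 0 || q > 93) stop("quality character out of Phred+33 range");
    if (q > 62) { q = 62; if (clamped) *clamped = true; }
    if (seq[i] == 'N' || seq[i] == 'n') q = 0;
    s[i] = q;
  }
  size_t run = 0;
  while (run < L && s[L - 1 - run] == 2) run++;
  if (run >= 2) {
    s.resize(L - run);
    s.push_back(63);
  }
  return s;
}

// [[Rcpp::export(name = ".c_canonicalize_quals")]]
IntegerVector c_canonicalize_quals(std::string qual, std::string seq) {
  std::vector<int> s = canon(qual, seq, nullptr);
  return IntegerVector(s.begin(), s.end());
}

// [[Rcpp::export(name = ".c_qual_context")]]
double c_qual_context(IntegerVector history, int level) {
  QState st;
  for (R_xlen_t i = 0; i < history.size(); i++) st.push(history[i]);
  return (double)st.key(level);
}

// [[Rcpp::export(name = ".c_fqz_qual_encode")]]
List c_fqz_qual_encode(CharacterVector quals, CharacterVector seqs, int level,
                       int Q, bool lossy_within) {
  if (level < 1 || level > 3) stop("level must be 1..3");
  if (Q < 1) stop("Q must be >= 1");
  std::vector<uint8_t> cnt(n_ctx(level) * QA, 0);
  RangeEncoder rc;
  bool clamped = false;
  for (R_xlen_t r = 0; r < quals.size(); r++) {
    std::string qs = as<std::string>(quals[r]);
    std::string ss = as<std::string>(seqs[r]);
    std::vector<int> sym = canon(qs, ss, &clamped);
    QState st;
    for (size_t i = 0; i < sym.size(); i++) {
      int v = sym[i];
      uint8_t* c = &cnt[st.key(level) * QA];
      if (lossy_within && Q > 1 && v > Q && v != 63) {
        int lo = std::max(1, v - Q), hi = std::min(62, v + Q);
        int best = v;
        for (int w = lo; w <= hi; w++) {
          if (c[w] > c[best] || (c[w] == c[best] && std::abs(w - v) < std::abs(best - v)))
            best = w;
        }
        v = best;
      }
      sym_encode(rc, c, QA, v);
      if (v != 63) st.push(v);
    }
  }
  rc.flush();
  return List::create(_["data"] = RawVector(rc.buf.begin(), rc.buf.end()),
                      _["clamped"] = clamped);
}

// Decode to quality strings; symbol 0 -> '!', sentinel expands to '#' runs.
// [[Rcpp::export(name = ".c_fqz_qual_decode")]]
CharacterVector c_fqz_qual_decode(RawVector data, IntegerVector lengths, int level) {
  if (level < 1 || level > 3) stop("level must be 1..3");
  std::vector<uint8_t> cnt(n_ctx(level) * QA, 0);
  RangeDecoder rc(RAW(data), data.size());
  CharacterVector out(lengths.size());
  for (R_xlen_t r = 0; r < lengths.size(); r++) {
    int L = lengths[r];
    std::string q(L, '!');
    QState st;
    for (int i = 0; i < L; i++) {
      int v = sym_decode(rc, &cnt[st.key(level) * QA], QA);
      if (v == 63) {
        for (int j = i; j < L; j++) q[j] = (char)(33 + 2);
        break;
      }
      q[i] = (char)(33 + v);
      st.push(v);
    }
    if (rc.overrun) stop("truncated quality stream");
    out[r] = q;
  }
  return out;
}

// ------------------------------------------------- fastqz byte-code packing
// Code space: 0 end-of-2s marker; 1..55 run of score 38 (length 1..55);
// 56..119 triple of scores 35..38; 120..183 pair of scores 31..38;
// 184..246 single score 0..62. 247..255 unused.
static const int C_END = 0, C_RUN = 1, C_TRI = 56, C_PAIR = 120, C_SGL = 184;

// [[Rcpp::export(name = ".c_fastqz_pack_quals")]]
RawVector c_fastqz_pack_quals(IntegerVector symbols) {
  int L = symbols.size();
  std::vector<uint8_t> out;
  // maximal terminal run of score 2 (length >= 2) is replaced by the marker
  int tail = 0;
  while (tail < L && symbols[L - 1 - tail] == 2) tail++;
  int end = (tail >= 2) ? L - tail : L;
  int i = 0;
  while (i < end) {
    int v = symbols[i];
    if (v < 0 || v > 62) stop("quality symbol out of range 0..62");
    if (v == 38) {
      int r = 0;
      while (i + r < end && symbols[i + r] == 38 && r < 55) r++;
      out.push_back((uint8_t)(C_RUN + r - 1));
      i += r;
      continue;
    }
    if (i + 2 < end &&
        v >= 35 && v <= 38 && symbols[i + 1] >= 35 && symbols[i + 1] <= 38 &&
        symbols[i + 2] >= 35 && symbols[i + 2] <= 38) {
      out.push_back((uint8_t)(C_TRI + (v - 35) * 16 + (symbols[i + 1] - 35) * 4 +
                              (symbols[i + 2] - 35)));
      i += 3;
      continue;
    }
    if (i + 1 < end &&
        v >= 31 && v <= 38 && symbols[i + 1] >= 31 && symbols[i + 1] <= 38) {
      out.push_back((uint8_t)(C_PAIR + (v - 31) * 8 + (symbols[i + 1] - 31)));
      i += 2;
      continue;
    }
    out.push_back((uint8_t)(C_SGL + v));
    i++;
  }
  if (tail >= 2) out.push_back(C_END);
  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export(name = ".c_fastqz_unpack_quals")]]
IntegerVector c_fastqz_unpack_quals(RawVector codes, int L) {
  IntegerVector out(L);
  int i = 0;
  R_xlen_t k = 0;
  while (i < L) {
    if (k >= codes.size()) stop("truncated quality codes");
    int b = codes[k++];
    if (b == C_END) {
      for (; i < L; i++) out[i] = 2;
    } else if (b >= C_RUN && b < C_TRI) {
      int r = b - C_RUN + 1;
      if (i + r > L) stop("quality code overruns read");
      for (int j = 0; j < r; j++) out[i++] = 38;
    } else if (b >= C_TRI && b < C_PAIR) {
      int x = b - C_TRI;
      if (i + 3 > L) stop("quality code overruns read");
      out[i++] = 35 + x / 16;
      out[i++] = 35 + (x / 4) % 4;
      out[i++] = 35 + x % 4;
    } else if (b >= C_PAIR && b < C_SGL) {
      int x = b - C_PAIR;
      if (i + 2 > L) stop("quality code overruns read");
      out[i++] = 31 + x / 8;
      out[i++] = 31 + x % 8;
    } else if (b >= C_SGL && b <= C_SGL + 62) {
      out[i++] = b - C_SGL;
    } else {
      stop("invalid quality byte code");
    }
  }
  return out;
}

// Per-record greedy packing of many reads into one byte stream.
// [[Rcpp::export(name = ".c_fastqz_pack_qual_stream")]]
RawVector c_fastqz_pack_qual_stream(CharacterVector quals, CharacterVector seqs) {
  std::vector<uint8_t> out;
  for (R_xlen_t r = 0; r < quals.size(); r++) {
    std::string qs = as<std::string>(quals[r]);
    std::string ss = as<std::string>(seqs[r]);
    IntegerVector sym(qs.size());
    for (size_t i = 0; i < qs.size(); i++) {
      int q = (unsigned char)qs[i] - 33;
      if (q < 0 || q > 93) stop("quality character out of Phred+33 range");
      if (q > 62) q = 62;
      if (i < ss.size() && (ss[i] == 'N' || ss[i] == 'n')) q = 0;
      sym[i] = q;
    }
    RawVector codes = c_fastqz_pack_quals(sym);
    for (R_xlen_t k = 0; k < codes.size(); k++) out.push_back(codes[k]);
  }
  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export(name = ".c_fastqz_unpack_qual_stream")]]
CharacterVector c_fastqz_unpack_qual_stream(RawVector codes, IntegerVector lengths) {
  CharacterVector out(lengths.size());
  size_t k = 0;
  const uint8_t* p = RAW(codes);
  size_t nc = codes.size();
  for (R_xlen_t r = 0; r < lengths.size(); r++) {
    int L = lengths[r];
    std::string q(L, '!');
    int i = 0;
    while (i < L) {
      if (k >= nc) stop("truncated quality codes");
      int b = p[k++];
      if (b == C_END) { for (; i < L; i++) q[i] = (char)(33 + 2); }
      else if (b >= C_RUN && b < C_TRI) {
        int rl = b - C_RUN + 1;
        if (i + rl > L) stop("quality code overruns read");
        for (int j = 0; j < rl; j++) q[i++] = (char)(33 + 38);
      } else if (b >= C_TRI && b < C_PAIR) {
        int x = b - C_TRI;
        if (i + 3 > L) stop("quality code overruns read");
        q[i++] = (char)(33 + 35 + x / 16);
        q[i++] = (char)(33 + 35 + (x / 4) % 4);
        q[i++] = (char)(33 + 35 + x % 4);
      } else if (b >= C_PAIR && b < C_SGL) {
        int x = b - C_PAIR;
        if (i + 2 > L) stop("quality code overruns read");
        q[i++] = (char)(33 + 31 + x / 8);
        q[i++] = (char)(33 + 31 + x % 8);
      } else if (b >= C_SGL && b <= C_SGL + 62) {
        q[i++] = (char)(33 + b - C_SGL);
      } else stop("invalid quality byte code");
    }
    out[r] = q;
  }
  return out;
}
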