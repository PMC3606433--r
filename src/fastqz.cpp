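// Line-delta identifier preprocessing, self-synchronising 3/4-base packing,
// and the bit-wise context-mixing engine used by the slow modes (direct and
// indirect byte-context models, secondary estimation keyed by a bit history,
// a match model, and a logistic mixer).
#include <Rcpp.h>
#include "core.h"
#include "model_nary.h"
using namespace Rcpp;
using namespace fqz;

// ------------------------------------------------------------ line delta
static bool digit(unsigned char c) { return c >= '0' && c <= '9'; }

static size_t lcp(const std::string& a, const std::string& b) {
  size_t n = std::min(a.size(), b.size()), i = 0;
  while (i < n && a[i] == b[i]) i++;
  return i;
}

// render v zero-padded to at least `width` digits
static std::string render_num(unsigned long long v, size_t width) {
  std::string s = std::to_string(v);
  if (s.size() < width) s.insert(0, width - s.size(), '0');
  return s;
}

// apply (column, increment) to prev: add increment to the maximal digit run
// starting at 1-based `column`; column 0 means no adjustment
static std::string delta_adjust(const std::string& prev, int column, int inc) {
  if (column <= 0 || inc <= 0) return prev;
  size_t c = (size_t)column - 1;
  if (c >= prev.size() || !digit(prev[c])) return prev;
  size_t e = c;
  while (e < prev.size() && digit(prev[e]) && e - c < 18) e++;
  unsigned long long v = 0;
  for (size_t i = c; i < e; i++) v = v * 10 + (prev[i] - '0');
  return prev.substr(0, c) + render_num(v + inc, e - c) + prev.substr(e);
}

struct Delta { int column, inc; size_t mlen; std::string lit; };

static Delta fastqz_delta(const std::string& prev, const std::string& cur) {
  Delta best;
  best.column = 0; best.inc = 0; best.mlen = lcp(prev, cur);
  size_t p = best.mlen;  // 0-based first mismatch
  // an adjustment only changes bytes from its column onward, so only digit
  // columns at or before the first mismatch can extend the match; for each
  // such column every increment 1..255 is tried (the rendered digits need
  // only share a prefix with the current line, not equal its whole run)
  for (size_t c = 0; c <= p && c < prev.size(); c++) {
    if (c >= 255) break;
    if (!digit(prev[c])) continue;
    size_t ep = c;
    while (ep < prev.size() && digit(prev[ep]) && ep - c < 18) ep++;
    unsigned long long vp = 0;
    for (size_t i = c; i < ep; i++) vp = vp * 10 + (prev[i] - '0');
    size_t width = ep - c;
    const std::string tailp = prev.substr(ep);
    for (int inc = 1; inc <= 255; inc++) {
      std::string rendered = render_num(vp + inc, width);
      // match length of adjusted = prefix(c) + rendered + tail vs cur
      size_t ml = c;
      size_t i = 0;
      while (i < rendered.size() && c + i < cur.size() &&
             rendered[i] == cur[c + i]) i++;
      ml += i;
      if (i == rendered.size()) {
        size_t off = c + i, j = 0;
        while (j < tailp.size() && off + j < cur.size() &&
               tailp[j] == cur[off + j]) j++;
        ml += j;
      }
      // prefer longer match, then smaller increment, then larger column
      if (ml > best.mlen ||
          (ml == best.mlen && best.column > 0 &&
           (inc < best.inc || (inc == best.inc && (int)c + 1 > best.column)))) {
        best.column = (int)c + 1; best.inc = inc; best.mlen = ml;
      }
    }
  }
  best.lit = cur.substr(std::min(best.mlen, cur.size()));
  return best;
}

// [[Rcpp::export(name = ".c_fastqz_delta")]]
List c_fastqz_delta(std::string prev, std::string cur) {
  Delta d = fastqz_delta(prev, cur);
  return List::create(_["column"] = d.column, _["increment"] = d.inc,
                      _["match_len"] = (int)d.mlen, _["literal"] = d.lit,
                      _["terminator"] = 0);
}

// [[Rcpp::export(name = ".c_fastqz_delta_apply")]]
std::string c_fastqz_delta_apply(std::string prev, int column, int increment,
                                 int match_len, std::string literal) {
  std::string adj = delta_adjust(prev, column, increment);
  if ((size_t)match_len > adj.size()) stop("match length exceeds adjusted line");
  return adj.substr(0, match_len) + literal;
}

// serialized byte form: [col][inc][mlen chunked 255][literal bytes][0]
static void delta_bytes(const Delta& d, std::vector<uint8_t>& out) {
  out.push_back((uint8_t)d.column);
  out.push_back((uint8_t)d.inc);
  size_t m = d.mlen;
  while (m >= 255) { out.push_back(255); m -= 255; }
  out.push_back((uint8_t)m);
  for (char ch : d.lit) out.push_back((uint8_t)ch);
  out.push_back(0);
}

// ------------------------------------------------------------- base packing
// codes A=1, T=2, C=3, G=4; 3-base group values 21..84 (only 63..84 are ever
// emitted), 4-base groups 85..255; escapes 1..4 (one trailing base) and 5..20
// (two trailing bases) close a stream whose length is not a group multiple.
static inline int pcode(char ch) {
  switch (ch) {
    case 'A': case 'a': return 1;
    case 'T': case 't': return 2;
    case 'C': case 'c': return 3;
    case 'G': case 'g': return 4;
    case 'N': case 'n': return 1;  // N carried by the quality stream
    default: return -1;
  }
}
static const char PBASES[] = "?ATCG";

static void pack_seq(const std::string& s, std::vector<uint8_t>& out) {
  size_t i = 0, n = s.size();
  while (n - i >= 3) {
    int c1 = pcode(s[i]), c2 = pcode(s[i + 1]), c3 = pcode(s[i + 2]);
    if (c1 < 0 || c2 < 0 || c3 < 0) stop("sequence contains a character outside ACGTN");
    int v3 = (c1 * 4 + c2) * 4 + c3;
    if (n - i >= 4) {
      int c4 = pcode(s[i + 3]);
      if (c4 < 0) stop("sequence contains a character outside ACGTN");
      if (v3 * 4 + c4 <= 255) { out.push_back((uint8_t)(v3 * 4 + c4)); i += 4; continue; }
    }
    out.push_back((uint8_t)v3);
    i += 3;
  }
  if (n - i == 1) out.push_back((uint8_t)pcode(s[i]));
  else if (n - i == 2)
    out.push_back((uint8_t)(4 + (pcode(s[i]) - 1) * 4 + pcode(s[i + 1])));
}

static std::string unpack_seq(const uint8_t* p, size_t n) {
  std::string s;
  for (size_t k = 0; k < n; k++) {
    int b = p[k];
    if (b >= 85) {
      int c4 = (b - 1) % 4 + 1;
      int v3 = (b - c4) / 4;
      int c3 = (v3 - 1) % 4 + 1;
      int v2 = (v3 - c3) / 4;
      int c2 = (v2 - 1) % 4 + 1;
      int c1 = (v2 - c2) / 4;
      s += PBASES[c1]; s += PBASES[c2]; s += PBASES[c3]; s += PBASES[c4];
    } else if (b >= 21) {
      int c3 = (b - 1) % 4 + 1;
      int v2 = (b - c3) / 4;
      int c2 = (v2 - 1) % 4 + 1;
      int c1 = (v2 - c2) / 4;
      s += PBASES[c1]; s += PBASES[c2]; s += PBASES[c3];
    } else if (b >= 5) {
      int x = b - 4;
      s += PBASES[(x - 1) / 4 + 1]; s += PBASES[(x - 1) % 4 + 1];
    } else if (b >= 1) {
      s += PBASES[b];
    } else {
      throw std::runtime_error("invalid packed base byte");
    }
  }
  return s;
}

// [[Rcpp::export(name = ".c_pack_bases")]]
RawVector c_pack_bases(std::string seq) {
  std::vector<uint8_t> out;
  pack_seq(seq, out);
  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export(name = ".c_unpack_bases")]]
std::string c_unpack_bases(RawVector bytes) {
  return unpack_seq(RAW(bytes), bytes.size());
}

// Group boundaries of the greedy parse (for the self-synchronisation check).
// [[Rcpp::export(name = ".c_pack_groups")]]
CharacterVector c_pack_groups(std::string seq) {
  std::vector<uint8_t> bytes;
  pack_seq(seq, bytes);
  std::vector<std::string> groups;
  for (uint8_t b : bytes) groups.push_back(unpack_seq(&b, 1));
  return wrap(groups);
}

// --------------------------------------------------------------- CM engine
struct CMEngine {
  std::vector<int> dorders, iorders;
  std::vector<std::vector<BitModel>> dtab;
  std::vector<std::vector<uint8_t>> itab;
  std::vector<StateMap> smaps;
  bool use_match, use_sse;
  MatchModel mm;
  int sse_order;
  std::vector<uint8_t> sse_hist;
  APM sse;
  Mixer mx;
  int tbits;
  uint32_t tmask;
  std::vector<uint8_t> hist;
  // per-bit scratch
  std::vector<uint32_t> didx, iidx;
  uint32_t sidx = 0;
  int pmix = 2048, pfin = 2048;

  CMEngine(std::vector<int> d, std::vector<int> ind, bool match, int sseord,
           int nsel, int tbits_)
      : dorders(d), iorders(ind), use_match(match), use_sse(sseord > 0),
        mm(20, 5), sse_order(sseord),
        sse_hist(use_sse ? ((size_t)1 << tbits_) : 0, 0), sse(BH_STATES),
        mx((int)d.size() + (int)ind.size() + (match ? 1 : 0), nsel * 8),
        tbits(tbits_), tmask(((uint32_t)1 << tbits_) - 1) {
    for (size_t i = 0; i < dorders.size(); i++)
      dtab.emplace_back((size_t)1 << tbits, BitModel());
    for (size_t i = 0; i < iorders.size(); i++) {
      itab.emplace_back((size_t)1 << tbits, 0);
      smaps.emplace_back();
    }
  }

  uint32_t ctx(int order, uint32_t xctx, int part, int mid) const {
    uint32_t h = 2166136261u ^ ((uint32_t)mid * 0x9E3779B9u);
    h = (h ^ xctx) * 16777619u;
    size_t n = hist.size();
    for (int j = 1; j <= order; j++) {
      uint8_t b = j <= (int)n ? hist[n - j] : 0;
      h = (h ^ b) * 16777619u;
    }
    h = (h ^ (uint32_t)part) * 16777619u;
    return h & tmask;
  }

  int predict(int bitpos, int part, uint32_t xctx, int sel) {
    didx.clear(); iidx.clear();
    int mi = 0;
    for (size_t i = 0; i < dorders.size(); i++) {
      uint32_t ix = ctx(dorders[i], xctx, part, mi++);
      didx.push_back(ix);
      mx.add(stretch(dtab[i][ix].pr()));
    }
    for (size_t i = 0; i < iorders.size(); i++) {
      uint32_t ix = ctx(iorders[i], xctx, part, mi++);
      iidx.push_back(ix);
      mx.add(stretch(smaps[i].pr(itab[i][ix])));
    }
    if (use_match) mx.add(mm.st(bitpos, part));
    pmix = mx.mix(sel * 8 + (7 - bitpos));
    pfin = pmix;
    if (use_sse) {
      sidx = ctx(sse_order, xctx, part, 97);
      pfin = sse.pp(pmix, sse_hist[sidx]);
      pfin = (pfin * 3 + pmix) >> 2;
      if (pfin < 1) pfin = 1; else if (pfin > 4095) pfin = 4095;
    }
    return pfin;
  }

  void update(int bit, int bitpos, int part) {
    for (size_t i = 0; i < dorders.size(); i++) dtab[i][didx[i]].update(bit);
    for (size_t i = 0; i < iorders.size(); i++) {
      smaps[i].update(itab[i][iidx[i]], bit);
      itab[i][iidx[i]] = bh_next(itab[i][iidx[i]], bit);
    }
    if (use_sse) {
      sse.update(bit);
      sse_hist[sidx] = bh_next(sse_hist[sidx], bit);
    }
    if (use_match) mm.upd_bit(bitpos, part, bit);
    mx.update(bit);
  }

  void encode_byte(RangeEncoder& rc, int byte, uint32_t xctx, int sel) {
    if (use_match) mm.new_byte();
    int part = 1;
    for (int bitpos = 7; bitpos >= 0; bitpos--) {
      int bit = (byte >> bitpos) & 1;
      int p = predict(bitpos, part, xctx, sel);
      rc.encode_bit(bit, p);
      update(bit, bitpos, part);
      part = (part << 1) | bit;
    }
    hist.push_back((uint8_t)byte);
    if (use_match) mm.push((uint8_t)byte);
  }

  int decode_byte(RangeDecoder& rc, uint32_t xctx, int sel) {
    if (use_match) mm.new_byte();
    int part = 1;
    for (int bitpos = 7; bitpos >= 0; bitpos--) {
      int p = predict(bitpos, part, xctx, sel);
      int bit = rc.decode_bit(p);
      update(bit, bitpos, part);
      part = (part << 1) | bit;
    }
    int byte = part & 0xFF;
    hist.push_back((uint8_t)byte);
    if (use_match) mm.push((uint8_t)byte);
    return byte;
  }
};

// profile factories --------------------------------------------------------
static CMEngine* make_engine(const std::string& profile) {
  if (profile == "id")
    return new CMEngine({1, 2}, {3, 4}, false, 0, 64, 18);
  if (profile == "qual")
    return new CMEngine({1, 2, 3}, {}, false, 0, 16, 18);
  if (profile == "seq")
    return new CMEngine({0, 1, 2}, {3}, true, 4, 1, 20);
  if (profile == "order2")  // ablation baseline: a single direct order-2 model
    return new CMEngine({2}, {}, false, 0, 1, 20);
  stop("unknown context-mixing profile");
}

// Generic byte-stream coding under a named profile; xsel supplies the
// per-byte (xctx, selector) pair.
// [[Rcpp::export(name = ".c_cm_encode_bytes")]]
RawVector c_cm_encode_bytes(RawVector bytes, std::string profile) {
  std::unique_ptr<CMEngine> E(make_engine(profile));
  int nsel = E->mx.nsel / 8;
  RangeEncoder rc;
  for (R_xlen_t i = 0; i < bytes.size(); i++) {
    int sel = (int)(i % nsel);
    E->encode_byte(rc, bytes[i], 0, sel);
  }
  rc.flush();
  return RawVector(rc.buf.begin(), rc.buf.end());
}

// [[Rcpp::export(name = ".c_cm_decode_bytes")]]
RawVector c_cm_decode_bytes(RawVector data, double n, std::string profile) {
  std::unique_ptr<CMEngine> E(make_engine(profile));
  int nsel = E->mx.nsel / 8;
  RangeDecoder rc(RAW(data), data.size());
  RawVector out((R_xlen_t)n);
  for (R_xlen_t i = 0; i < (R_xlen_t)n; i++) {
    int sel = (int)(i % nsel);
    out[i] = (uint8_t)E->decode_byte(rc, 0, sel);
  }
  if (rc.overrun) stop("truncated context-mixed stream");
  return out;
}

// ----------------------------------------------------- fastqz id stream
// [[Rcpp::export(name = ".c_fastqz_id_encode")]]
RawVector c_fastqz_id_encode(CharacterVector ids, bool slow) {
  std::vector<uint8_t> bytes;
  std::string prev;
  std::vector<size_t> starts;
  for (R_xlen_t r = 0; r < ids.size(); r++) {
    std::string cur = as<std::string>(ids[r]);
    Delta d = fastqz_delta(prev, cur);
    starts.push_back(bytes.size());
    delta_bytes(d, bytes);
    prev = cur;
  }
  if (!slow) return RawVector(bytes.begin(), bytes.end());
  std::unique_ptr<CMEngine> E(make_engine("id"));
  RangeEncoder rc;
  size_t rec = 0, recstart = 0;
  for (size_t i = 0; i < bytes.size(); i++) {
    if (rec + 1 < starts.size() && i == starts[rec + 1]) { rec++; recstart = i; }
    int col = (int)std::min<size_t>(i - recstart, 63);
    uint8_t prevb = i > recstart ? bytes[i - 1] : 0;
    E->encode_byte(rc, bytes[i], ((uint32_t)col << 8) | prevb, col);
  }
  rc.flush();
  return RawVector(rc.buf.begin(), rc.buf.end());
}

// [[Rcpp::export(name = ".c_fastqz_id_decode")]]
CharacterVector c_fastqz_id_decode(RawVector data, int n, bool slow) {
  CharacterVector out(n);
  std::string prev;
  std::unique_ptr<CMEngine> E(slow ? make_engine("id") : nullptr);
  std::unique_ptr<RangeDecoder> rc(slow ? new RangeDecoder(RAW(data), data.size()) : nullptr);
  size_t k = 0;
  const uint8_t* p = RAW(data);
  size_t nbytes = data.size();
  for (int r = 0; r < n; r++) {
    // parse one serialized delta record byte by byte
    std::vector<uint8_t> recb;
    size_t pos_in_rec = 0;
    auto get = [&]() -> int {
      int b;
      if (slow) {
        int col = (int)std::min<size_t>(pos_in_rec, 63);
        uint8_t prevb = recb.empty() ? 0 : recb.back();
        b = E->decode_byte(*rc, ((uint32_t)col << 8) | prevb, col);
      } else {
        if (k >= nbytes) stop("truncated identifier stream");
        b = p[k++];
      }
      recb.push_back((uint8_t)b);
      pos_in_rec++;
      return b;
    };
    int col = get();
    int inc = get();
    size_t mlen = 0;
    int b;
    while ((b = get()) == 255) mlen += 255;
    mlen += b;
    std::string lit;
    while ((b = get()) != 0) lit += (char)b;
    std::string adj = delta_adjust(prev, col, inc);
    if (mlen > adj.size()) stop("identifier stream corrupt");
    std::string cur = adj.substr(0, mlen) + lit;
    out[r] = cur;
    prev = cur;
  }
  if (slow && rc->overrun) stop("truncated identifier stream");
  return out;
}

// -------------------------------------------------- fastqz seq/qual streams
// [[Rcpp::export(name = ".c_fastqz_seq_encode")]]
RawVector c_fastqz_seq_encode(CharacterVector seqs, bool slow) {
  std::string all;
  for (R_xlen_t r = 0; r < seqs.size(); r++) all += as<std::string>(seqs[r]);
  std::vector<uint8_t> packed;
  pack_seq(all, packed);
  RawVector pk(packed.begin(), packed.end());
  if (!slow) return pk;
  return c_cm_encode_bytes(pk, "seq");
}

// [[Rcpp::export(name = ".c_fastqz_seq_decode")]]
CharacterVector c_fastqz_seq_decode(RawVector data, double npacked,
                                    IntegerVector lengths, bool slow) {
  RawVector pk = slow ? c_cm_decode_bytes(data, npacked, "seq") : data;
  std::string all = unpack_seq(RAW(pk), pk.size());
  CharacterVector out(lengths.size());
  size_t off = 0;
  for (R_xlen_t r = 0; r < lengths.size(); r++) {
    size_t L = (size_t)lengths[r];
    if (off + L > all.size()) stop("sequence stream shorter than read lengths");
    out[r] = all.substr(off, L);
    off += L;
  }
  return out;
}
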