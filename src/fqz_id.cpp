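// Sequence-identifier codec: tokenise each identifier into typed tokens,
// diff against the previous identifier (match / small numeric delta / literal)
// and code each token slot with its own adaptive models. A simple
// prefix+suffix string-delta coder is available as an alternative mode and as
// the per-record fallback when tokenisation overflows the slot budget.
#include <Rcpp.h>
#include "core.h"
#include "model_nary.h"
using namespace Rcpp;
using namespace fqz;

enum TokType { T_ALPHA = 0, T_NUMERIC = 1, T_LZ = 2, T_PUNCT = 3,
               T_MATCH = 4, T_DELTA = 5 };
static const char* TOK_NAMES[] = {"ALPHA", "NUMERIC", "LEADING_ZERO_NUMERIC",
                                  "PUNCT", "MATCH", "DELTA"};
static const int MAX_TOKENS = 32;   // overflow falls back to string delta
static const int MAX_RUN = 255;     // longer runs are chunked

struct Tok {
  int type;
  std::string s;     // literal bytes of the token
  uint64_t v = 0;    // numeric value (NUMERIC only)
};

static bool is_alpha(unsigned char ch) {
  return (ch >= 'A' && ch <= 'Z') || (ch >= 'a' && ch <= 'z');
}
static bool is_digit(unsigned char ch) { return ch >= '0' && ch <= '9'; }

static std::vector<Tok> tokenize(const std::string& id, bool alnum = false) {
  std::vector<Tok> out;
  size_t i = 0, n = id.size();
  while (i < n) {
    unsigned char ch = id[i];
    Tok t;
    size_t j = i;
    if (alnum && is_alpha(ch)) {
      // optional [A-Za-z][A-Za-z0-9]* token type (off by default)
      while (j < n && (is_alpha(id[j]) || is_digit(id[j])) && j - i < MAX_RUN) j++;
      t.type = T_ALPHA;
    } else if (is_alpha(ch)) {
      while (j < n && is_alpha(id[j]) && j - i < MAX_RUN) j++;
      t.type = T_ALPHA;
    } else if (ch == '0') {
      while (j < n && id[j] == '0' && j - i < MAX_RUN) j++;
      t.type = T_LZ;
    } else if (is_digit(ch)) {
      // chunk at 18 digits so values always fit an unsigned 64-bit integer
      while (j < n && is_digit(id[j]) && j - i < 18) j++;
      t.type = T_NUMERIC;
      t.v = 0;
      for (size_t k = i; k < j; k++) t.v = t.v * 10 + (id[k] - '0');
    } else {
      while (j < n && !is_alpha(id[j]) && !is_digit(id[j]) && j - i < MAX_RUN) j++;
      t.type = T_PUNCT;
    }
    t.s = id.substr(i, j - i);
    out.push_back(t);
    i = j;
  }
  return out;
}

static std::string detok(const std::vector<Tok>& toks) {
  std::string out;
  for (const Tok& t : toks) out += t.s;
  return out;
}

// ------------------------------------------------------------- stream models
struct SlotModels {
  NModel<6> type;
  Model256 delta;
  Model256 num[4];   // little-endian bytes of a 32-bit quantity
  BitModel numbig;   // value needs a second 32-bit quantity
  Model256 len;
  Model256 chars;    // order-0 characters of ALPHA/PUNCT tokens in this slot
};

struct IdCoder {
  BitModel fallback;
  NModel<33> ntok;
  std::vector<SlotModels> slot;
  Model256 sd_pfx, sd_len, sd_chr;
  IdCoder() : slot(MAX_TOKENS) {}
};

static void put_chunked(RangeEncoder& rc, Model256& m, size_t v) {
  while (v >= 255) { m.enc(rc, 255); v -= 255; }
  m.enc(rc, (int)v);
}
static size_t get_chunked(RangeDecoder& rc, Model256& m) {
  size_t v = 0;
  int b;
  while ((b = m.dec(rc)) == 255) v += 255;
  return v + b;
}

static void sd_encode(RangeEncoder& rc, IdCoder& C,
                      const std::string& prev, const std::string& cur) {
  size_t p = 0, lim = std::min(prev.size(), cur.size());
  while (p < lim && prev[p] == cur[p]) p++;
  put_chunked(rc, C.sd_pfx, p);
  put_chunked(rc, C.sd_len, cur.size() - p);
  for (size_t i = p; i < cur.size(); i++) C.sd_chr.enc(rc, (unsigned char)cur[i]);
}
static std::string sd_decode(RangeDecoder& rc, IdCoder& C, const std::string& prev) {
  size_t p = get_chunked(rc, C.sd_pfx);
  size_t sl = get_chunked(rc, C.sd_len);
  if (p > prev.size()) throw std::runtime_error("identifier stream corrupt");
  std::string cur = prev.substr(0, p);
  for (size_t i = 0; i < sl; i++) cur += (char)C.sd_chr.dec(rc);
  return cur;
}

static void num_encode(RangeEncoder& rc, SlotModels& S, uint64_t v) {
  int big = v >= (1ull << 32);
  rc.encode_bit(big, S.numbig.pr());
  S.numbig.update(big);
  uint32_t lo = (uint32_t)v;
  for (int b = 0; b < 4; b++) S.num[b].enc(rc, (lo >> (8 * b)) & 0xFF);
  if (big) {
    uint32_t hi = (uint32_t)(v >> 32);
    for (int b = 0; b < 4; b++) S.num[b].enc(rc, (hi >> (8 * b)) & 0xFF);
  }
}
static uint64_t num_decode(RangeDecoder& rc, SlotModels& S) {
  int big = rc.decode_bit(S.numbig.pr());
  S.numbig.update(big);
  uint64_t v = 0;
  for (int b = 0; b < 4; b++) v |= (uint64_t)S.num[b].dec(rc) << (8 * b);
  if (big)
    for (int b = 0; b < 4; b++) v |= (uint64_t)S.num[b].dec(rc) << (32 + 8 * b);
  return v;
}

// ------------------------------------------------------------------ exports

// [[Rcpp::export(name = ".c_tokenize_id")]]
List c_tokenize_id(std::string id, bool alnum = false) {
  std::vector<Tok> toks = tokenize(id, alnum);
  CharacterVector type(toks.size()), value(toks.size());
  IntegerVector slot(toks.size());
  for (size_t i = 0; i < toks.size(); i++) {
    type[i] = TOK_NAMES[toks[i].type];
    value[i] = toks[i].s;
    slot[i] = (int)i + 1;
  }
  return List::create(_["slot"] = slot, _["type"] = type, _["value"] = value);
}

// [[Rcpp::export(name = ".c_diff_tokens")]]
List c_diff_tokens(std::string prev, std::string cur) {
  std::vector<Tok> pt = tokenize(prev), ct = tokenize(cur);
  CharacterVector type(ct.size()), value(ct.size());
  IntegerVector slot(ct.size());
  for (size_t i = 0; i < ct.size(); i++) {
    slot[i] = (int)i + 1;
    if (i < pt.size() && pt[i].type == ct[i].type && pt[i].s == ct[i].s) {
      type[i] = TOK_NAMES[T_MATCH];
      value[i] = "";
    } else if (i < pt.size() && pt[i].type == T_NUMERIC && ct[i].type == T_NUMERIC &&
               ct[i].v >= pt[i].v && ct[i].v - pt[i].v <= 255) {
      type[i] = TOK_NAMES[T_DELTA];
      value[i] = std::to_string(ct[i].v - pt[i].v);
    } else {
      type[i] = TOK_NAMES[ct[i].type];
      value[i] = ct[i].s;
    }
  }
  return List::create(_["slot"] = slot, _["type"] = type, _["value"] = value);
}

// [[Rcpp::export(name = ".c_id_encode")]]
RawVector c_id_encode(CharacterVector ids, bool string_delta) {
  IdCoder C;
  RangeEncoder rc;
  std::string prev;
  std::vector<Tok> prevtoks;
  for (R_xlen_t r = 0; r < ids.size(); r++) {
    std::string cur = as<std::string>(ids[r]);
    if (string_delta) { sd_encode(rc, C, prev, cur); prev = cur; continue; }
    std::vector<Tok> toks = tokenize(cur);
    int fb = toks.size() > MAX_TOKENS;
    rc.encode_bit(fb, C.fallback.pr());
    C.fallback.update(fb);
    if (fb) {
      sd_encode(rc, C, prev, cur);
    } else {
      C.ntok.enc(rc, (int)toks.size());
      for (size_t i = 0; i < toks.size(); i++) {
        SlotModels& S = C.slot[i];
        const Tok& t = toks[i];
        bool havep = i < prevtoks.size();
        if (havep && prevtoks[i].type == t.type && prevtoks[i].s == t.s) {
          S.type.enc(rc, T_MATCH);
        } else if (havep && prevtoks[i].type == T_NUMERIC && t.type == T_NUMERIC &&
                   t.v >= prevtoks[i].v && t.v - prevtoks[i].v <= 255) {
          S.type.enc(rc, T_DELTA);
          S.delta.enc(rc, (int)(t.v - prevtoks[i].v));
        } else if (t.type == T_NUMERIC) {
          S.type.enc(rc, T_NUMERIC);
          num_encode(rc, S, t.v);
        } else if (t.type == T_LZ) {
          S.type.enc(rc, T_LZ);
          S.len.enc(rc, (int)t.s.size());
        } else {
          S.type.enc(rc, t.type);
          S.len.enc(rc, (int)t.s.size());
          for (char ch : t.s) S.chars.enc(rc, (unsigned char)ch);
        }
      }
    }
    prev = cur;
    prevtoks = toks;
  }
  rc.flush();
  return RawVector(rc.buf.begin(), rc.buf.end());
}

// [[Rcpp::export(name = ".c_id_decode")]]
CharacterVector c_id_decode(RawVector data, int n, bool string_delta) {
  IdCoder C;
  RangeDecoder rc(RAW(data), data.size());
  CharacterVector out(n);
  std::string prev;
  std::vector<Tok> prevtoks;
  for (int r = 0; r < n; r++) {
    std::string cur;
    if (string_delta) {
      cur = sd_decode(rc, C, prev);
    } else {
      int fb = rc.decode_bit(C.fallback.pr());
      C.fallback.update(fb);
      if (fb) {
        cur = sd_decode(rc, C, prev);
      } else {
        int nt = C.ntok.dec(rc);
        for (int i = 0; i < nt; i++) {
          SlotModels& S = C.slot[i];
          int ty = S.type.dec(rc);
          if (ty == T_MATCH) {
            if ((size_t)i >= prevtoks.size())
              throw std::runtime_error("identifier stream corrupt (match)");
            cur += prevtoks[i].s;
          } else if (ty == T_DELTA) {
            if ((size_t)i >= prevtoks.size() || prevtoks[i].type != T_NUMERIC)
              throw std::runtime_error("identifier stream corrupt (delta)");
            int d = S.delta.dec(rc);
            cur += std::to_string(prevtoks[i].v + d);
          } else if (ty == T_NUMERIC) {
            cur += std::to_string(num_decode(rc, S));
          } else if (ty == T_LZ) {
            int l = S.len.dec(rc);
            cur.append(l, '0');
          } else {
            int l = S.len.dec(rc);
            for (int k = 0; k < l; k++) cur += (char)S.chars.dec(rc);
          }
        }
      }
    }
    if (rc.overrun) stop("truncated identifier stream");
    out[r] = cur;
    prevtoks = tokenize(cur);
    prev = cur;
  }
  return out;
}
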