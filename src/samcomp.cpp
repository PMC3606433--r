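// SAM base-stream codecs. samcomp1 anchors every called base to a reference
// coordinate via flag/pos/CIGAR and codes it with an adaptive per-coordinate
// model (seeded from the reference when given, otherwise from a low-order
// consensus context); insertions, soft-clips and unmapped reads use their own
// channels. samcomp2 keeps no per-coordinate state: each base codes a
// match/mismatch bit against the reference under a 16-bit match-history
// context, and mismatched bases are coded under the reference base.
// Side fields (flag, pos delta, rname index, mapq, CIGAR text) are coded with
// order-0/order-1 byte models into a separate stream.
#include <Rcpp.h>
#include "core.h"
#include "model_nary.h"
using namespace Rcpp;
using namespace fqz;

static inline int bcode(char ch) {
  switch (ch) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    case 'N': case 'n': return 0;
    default: return -1;
  }
}
static const char BB[] = "ACGT";

// per-coordinate models adapt faster than the generic stream models: the
// increment is one read's worth of evidence at a site
static const int PP_INC = 16;
static inline void pp_update(uint8_t* c, int sym) {
  int v = c[sym] + PP_INC;
  if (v > 255) {
    for (int i = 0; i < 4; i++) c[i] = (uint8_t)((c[i] + 1) >> 1);
    v = c[sym] + PP_INC;
  }
  c[sym] = (uint8_t)v;
}
static inline void pp_encode(fqz::RangeEncoder& rc, uint8_t* c, int sym) {
  uint32_t cum = 0, tot = 0;
  for (int i = 0; i < sym; i++) cum += 2u * c[i] + 1;
  for (int i = 0; i < 4; i++) tot += 2u * c[i] + 1;
  rc.encode(cum, 2u * c[sym] + 1, tot);
  pp_update(c, sym);
}
static inline int pp_decode(fqz::RangeDecoder& rc, uint8_t* c) {
  uint32_t tot = 0;
  for (int i = 0; i < 4; i++) tot += 2u * c[i] + 1;
  uint32_t f = rc.get_freq(tot), cum = 0;
  int sym = 0;
  while (sym < 3 && cum + 2u * c[sym] + 1 <= f) { cum += 2u * c[sym] + 1; sym++; }
  rc.decode(cum, 2u * c[sym] + 1);
  pp_update(c, sym);
  return sym;
}

struct CigOp { char op; long len; };

static std::vector<CigOp> parse_cigar(const std::string& cg, R_xlen_t rec) {
  std::vector<CigOp> ops;
  if (cg == "*") return ops;
  long v = 0;
  bool have = false;
  for (char ch : cg) {
    if (ch >= '0' && ch <= '9') { v = v * 10 + (ch - '0'); have = true; continue; }
    if (!have || std::strchr("MIDNSHP=X", ch) == nullptr)
      stop("malformed CIGAR '%s' in record %d", cg.c_str(), (int)rec + 1);
    ops.push_back({ch, v});
    v = 0; have = false;
  }
  if (have) stop("malformed CIGAR '%s' in record %d", cg.c_str(), (int)rec + 1);
  return ops;
}

static long cigar_read_len(const std::vector<CigOp>& ops) {
  long n = 0;
  for (const CigOp& o : ops)
    if (std::strchr("MIS=X", o.op)) n += o.len;
  return n;
}

// [[Rcpp::export(name = ".c_anchor_bases")]]
List c_anchor_bases(int pos, std::string cigar, std::string seq) {
  std::vector<CigOp> ops = parse_cigar(cigar, 0);
  if (cigar_read_len(ops) != (long)seq.size())
    stop("CIGAR read length does not match sequence length");
  std::vector<double> coord;
  std::vector<std::string> base, channel;
  long rp = 0, refc = pos - 1;
  for (const CigOp& o : ops) {
    if (o.op == 'M' || o.op == '=' || o.op == 'X') {
      for (long j = 0; j < o.len; j++) {
        coord.push_back((double)refc++);
        base.push_back(std::string(1, seq[rp++]));
        channel.push_back("MATCHED");
      }
    } else if (o.op == 'I' || o.op == 'S') {
      for (long j = 0; j < o.len; j++) {
        coord.push_back(NA_REAL);
        base.push_back(std::string(1, seq[rp++]));
        channel.push_back(o.op == 'I' ? "INSERTION" : "SOFTCLIP");
      }
    } else if (o.op == 'D' || o.op == 'N') {
      refc += o.len;
    }  // H, P consume nothing
  }
  return List::create(_["ref_coord"] = wrap(coord), _["base"] = wrap(base),
                      _["channel"] = wrap(channel));
}

// ------------------------------------------------------------- side stream
struct SideModels {
  Model256 flag0, flag1, mapq, rnb[5], posb[5], cigch[64];
  int cig_ctx(int prev) const { return prev & 63; }
};

static void put_varint(RangeEncoder& rc, Model256* m, uint64_t v) {
  int i = 0;
  while (v >= 128) { m[std::min(i, 4)].enc(rc, (int)(v & 127) | 128); v >>= 7; i++; }
  m[std::min(i, 4)].enc(rc, (int)v);
}
static uint64_t get_varint(RangeDecoder& rc, Model256* m) {
  uint64_t v = 0;
  int i = 0, shift = 0, b;
  while ((b = m[std::min(i, 4)].dec(rc)) & 128) {
    v |= (uint64_t)(b & 127) << shift;
    shift += 7; i++;
  }
  return v | ((uint64_t)b << shift);
}

// --------------------------------------------------------------- samcomp1
struct PerPosModels {
  std::vector<uint8_t> cnt;  // 4 counters per coordinate
  void ensure(size_t c) { if (c * 4 + 4 > cnt.size()) cnt.resize((c + 4096) * 4, 0); }
  uint8_t* at(size_t c) { ensure(c); return &cnt[c * 4]; }
  void clear() { cnt.clear(); }
};

struct Sam1State {
  PerPosModels pp;
  // consensus-context seeding when no reference is known; wide counters so
  // a genuinely flat consensus is measured as flat (and then seeds nothing)
  uint32_t cons[16][4];
  std::vector<int8_t> consensus;  // -1 = none yet
  NModel<4> ins[16], clip[16];
  std::vector<uint8_t> unmap;     // order-7 model, 4^7 contexts
  long covered = 0;
  Sam1State() { std::memset(cons, 0, sizeof(cons)); unmap.assign((1 << 14) * 4, 0); }
  void new_chrom() { pp.clear(); consensus.clear(); }
  int cons_at(long c) {
    if (c < 0 || (size_t)c >= consensus.size()) return 0;
    return consensus[c] < 0 ? 0 : consensus[c];
  }
  void seed(uint8_t* m, long c, const std::string& ref) {
    if (!ref.empty() && c >= 0 && (size_t)c < ref.size()) {
      int rb = bcode(ref[c]);
      m[rb < 0 ? 0 : rb] = PP_INC;  // reference base = one prior observation
    } else {
      // consensus-context seeding: give the context's modal base a mass
      // proportional to its excess over a uniform share, so an uninformative
      // (flat) consensus adds nothing and a skewed one seeds its MAP base
      int ctx = cons_at(c - 1) * 4 + cons_at(c - 2);
      long tot = 0, mx = 0;
      int arg = 0;
      for (int i = 0; i < 4; i++) {
        tot += cons[ctx][i];
        if ((long)cons[ctx][i] > mx) { mx = cons[ctx][i]; arg = i; }
      }
      // only trust the consensus context once it has real support; a flat
      // or barely-observed context seeds nothing
      if (tot >= 64) {
        long excess = (PP_INC * (4 * mx - tot)) / (3 * tot);
        if (excess > PP_INC) excess = PP_INC;
        if (excess > 0) m[arg] = (uint8_t)excess;
      }
    }
    covered++;
  }
  void after_code(long c, int b) {
    if ((size_t)c >= consensus.size()) consensus.resize(c + 4096, -1);
    uint8_t* m = pp.at(c);
    int best = 0;
    for (int i = 1; i < 4; i++) if (m[i] > m[best]) best = i;
    consensus[c] = (int8_t)best;
    int ctx = cons_at(c - 1) * 4 + cons_at(c - 2);
    if (++cons[ctx][b] >= (1u << 20))
      for (int i = 0; i < 4; i++) cons[ctx][i] >>= 1;
  }
};

// --------------------------------------------------------------- samcomp2
struct Sam2State {
  std::vector<BitModel> mhist;  // 16-bit match history -> match bit
  NModel<4> lit[4];             // mismatch literal under reference base
  NModel<4> noref[16];          // order-2 fallback when no reference
  NModel<4> ins[16], clip[16];
  std::vector<uint8_t> unmap;
  uint32_t reg = 0xFFFF;
  Sam2State() : mhist(1 << 16) { unmap.assign((1 << 14) * 4, 0); }
};

// shared helpers for the auxiliary channels
static void code_chan(RangeEncoder* enc, RangeDecoder* dec, NModel<4>* mods,
                      int& ctx, int& b) {
  if (enc) mods[ctx].enc(*enc, b);
  else b = mods[ctx].dec(*dec);
  ctx = ((ctx << 2) | b) & 15;
}

// [[Rcpp::export(name = ".c_samcomp_encode")]]
List c_samcomp_encode(IntegerVector flag, IntegerVector pos,
                      IntegerVector rname_idx, IntegerVector mapq,
                      CharacterVector cigar, CharacterVector seq, int variant,
                      CharacterVector refs) {
  R_xlen_t n = flag.size();
  RangeEncoder seqrc, siderc;
  SideModels SM;
  Sam1State* S1 = variant == 1 ? new Sam1State() : nullptr;
  Sam2State* S2 = variant == 2 ? new Sam2State() : nullptr;
  int prev_rname = -1;
  long prev_pos = 0;
  std::string refseq;
  for (R_xlen_t r = 0; r < n; r++) {
    // ---- side fields
    SM.flag0.enc(siderc, flag[r] & 0xFF);
    SM.flag1.enc(siderc, (flag[r] >> 8) & 0xFF);
    SM.mapq.enc(siderc, mapq[r] & 0xFF);
    int rn = rname_idx[r];
    long drn = (long)rn - (prev_rname < 0 ? 0 : prev_rname);
    put_varint(siderc, SM.rnb, drn >= 0 ? (uint64_t)drn << 1
                                        : (((uint64_t)(-drn)) << 1) | 1);
    if (rn != prev_rname) {
      prev_pos = 0;
      if (S1) S1->new_chrom();
      refseq = (rn >= 0 && rn < refs.size() && refs[rn] != NA_STRING)
                   ? as<std::string>(refs[rn]) : std::string();
    }
    long dp = (long)pos[r] - prev_pos;
    if (variant == 1 && (rn < prev_rname || (rn == prev_rname && dp < 0)))
      stop("input is not position sorted at record %d", (int)r + 1);
    uint64_t zz = dp >= 0 ? (uint64_t)dp << 1 : (((uint64_t)(-dp)) << 1) | 1;
    put_varint(siderc, SM.posb, zz);
    prev_pos = pos[r];
    prev_rname = rn;
    // CIGAR text, order-1
    std::string cg = as<std::string>(cigar[r]);
    int cctx = 0;
    for (char ch : cg) {
      SM.cigch[cctx].enc(siderc, (unsigned char)ch);
      cctx = SM.cig_ctx((unsigned char)ch);
    }
    SM.cigch[cctx].enc(siderc, 0);
    // ---- bases
    std::string s = as<std::string>(seq[r]);
    bool unmapped = (flag[r] & 4) || cg == "*";
    if (unmapped) {
      std::vector<uint8_t>* um = S1 ? &S1->unmap : &S2->unmap;
      uint32_t ctx = 0;
      for (char ch : s) {
        int b = bcode(ch);
        if (b < 0) stop("sequence contains a character outside ACGTN");
        sym_encode(seqrc, &(*um)[ctx * 4], 4, b);
        ctx = ((ctx << 2) | b) & ((1 << 14) - 1);
      }
      continue;
    }
    std::vector<CigOp> ops = parse_cigar(cg, r);
    if (cigar_read_len(ops) != (long)s.size())
      stop("CIGAR does not match sequence length in record %d", (int)r + 1);
    long rp = 0, refc = (long)pos[r] - 1;
    int ictx = 0, sctx = 0;
    for (const CigOp& o : ops) {
      if (o.op == 'M' || o.op == '=' || o.op == 'X') {
        for (long j = 0; j < o.len; j++, rp++, refc++) {
          int b = bcode(s[rp]);
          if (b < 0) stop("sequence contains a character outside ACGTN");
          if (variant == 1) {
            uint8_t* m = S1->pp.at(refc);
            bool fresh = !(m[0] | m[1] | m[2] | m[3]);
            if (fresh) S1->seed(m, refc, refseq);
            pp_encode(seqrc, m, b);
            S1->after_code(refc, b);
          } else {
            if (!refseq.empty() && (size_t)refc < refseq.size()) {
              int rb = bcode(refseq[refc]);
              if (rb < 0) rb = 0;
              int match = b == rb;
              BitModel& bm = S2->mhist[S2->reg & 0xFFFF];
              seqrc.encode_bit(match, bm.pr());
              bm.update(match);
              S2->reg = (S2->reg << 1) | (unsigned)match;
              if (!match) S2->lit[rb].enc(seqrc, b);
            } else {
              S2->noref[sctx & 15].enc(seqrc, b);
            }
            sctx = ((sctx << 2) | b) & 15;
          }
        }
      } else if (o.op == 'I') {
        NModel<4>* ch = S1 ? S1->ins : S2->ins;
        for (long j = 0; j < o.len; j++, rp++) {
          int b = bcode(s[rp]);
          if (b < 0) stop("sequence contains a character outside ACGTN");
          code_chan(&seqrc, nullptr, ch, ictx, b);
        }
      } else if (o.op == 'S') {
        NModel<4>* ch = S1 ? S1->clip : S2->clip;
        for (long j = 0; j < o.len; j++, rp++) {
          int b = bcode(s[rp]);
          if (b < 0) stop("sequence contains a character outside ACGTN");
          code_chan(&seqrc, nullptr, ch, sctx, b);
        }
      } else if (o.op == 'D' || o.op == 'N') {
        refc += o.len;
      }
    }
  }
  seqrc.flush();
  siderc.flush();
  long covered = S1 ? S1->covered : 0;
  delete S1;
  delete S2;
  return List::create(
      _["bases"] = RawVector(seqrc.buf.begin(), seqrc.buf.end()),
      _["side"] = RawVector(siderc.buf.begin(), siderc.buf.end()),
      _["n_covered"] = (double)covered);
}

// [[Rcpp::export(name = ".c_samcomp_decode")]]
List c_samcomp_decode(RawVector bases, RawVector side, int n, int variant,
                      CharacterVector refs, IntegerVector lengths) {
  RangeDecoder seqrc(RAW(bases), bases.size());
  RangeDecoder siderc(RAW(side), side.size());
  SideModels SM;
  Sam1State* S1 = variant == 1 ? new Sam1State() : nullptr;
  Sam2State* S2 = variant == 2 ? new Sam2State() : nullptr;
  IntegerVector flag(n), pos(n), rname_idx(n), mapq(n);
  CharacterVector cigar(n), seq(n);
  int prev_rname = -1;
  long prev_pos = 0;
  std::string refseq;
  for (int r = 0; r < n; r++) {
    int f = SM.flag0.dec(siderc) | (SM.flag1.dec(siderc) << 8);
    flag[r] = f;
    mapq[r] = SM.mapq.dec(siderc);
    uint64_t zrn = get_varint(siderc, SM.rnb);
    long drn = (zrn & 1) ? -(long)(zrn >> 1) : (long)(zrn >> 1);
    int rn = (int)((prev_rname < 0 ? 0 : prev_rname) + drn);
    rname_idx[r] = rn;
    if (rn != prev_rname) {
      prev_pos = 0;
      if (S1) S1->new_chrom();
      refseq = (rn >= 0 && rn < refs.size() && refs[rn] != NA_STRING)
                   ? as<std::string>(refs[rn]) : std::string();
    }
    uint64_t zz = get_varint(siderc, SM.posb);
    long dp = (zz & 1) ? -(long)(zz >> 1) : (long)(zz >> 1);
    pos[r] = (int)(prev_pos + dp);
    prev_pos = pos[r];
    prev_rname = rn;
    std::string cg;
    int cctx = 0, ch;
    while ((ch = SM.cigch[cctx].dec(siderc)) != 0) {
      cg += (char)ch;
      cctx = SM.cig_ctx(ch);
    }
    cigar[r] = cg;
    int L = lengths[r];
    std::string s(L, 'A');
    bool unmapped = (f & 4) || cg == "*";
    if (unmapped) {
      std::vector<uint8_t>* um = S1 ? &S1->unmap : &S2->unmap;
      uint32_t ctx = 0;
      for (int i = 0; i < L; i++) {
        int b = sym_decode(seqrc, &(*um)[ctx * 4], 4);
        s[i] = BB[b];
        ctx = ((ctx << 2) | b) & ((1 << 14) - 1);
      }
    } else {
      std::vector<CigOp> ops = parse_cigar(cg, r);
      if (cigar_read_len(ops) != (long)L)
        stop("decoded CIGAR does not match read length in record %d", r + 1);
      long rp = 0, refc = (long)pos[r] - 1;
      int ictx = 0, sctx = 0;
      for (const CigOp& o : ops) {
        if (o.op == 'M' || o.op == '=' || o.op == 'X') {
          for (long j = 0; j < o.len; j++, rp++, refc++) {
            int b;
            if (variant == 1) {
              uint8_t* m = S1->pp.at(refc);
              bool fresh = !(m[0] | m[1] | m[2] | m[3]);
              if (fresh) S1->seed(m, refc, refseq);
              b = pp_decode(seqrc, m);
              S1->after_code(refc, b);
            } else {
              if (!refseq.empty() && (size_t)refc < refseq.size()) {
                int rb = bcode(refseq[refc]);
                if (rb < 0) rb = 0;
                BitModel& bm = S2->mhist[S2->reg & 0xFFFF];
                int match = seqrc.decode_bit(bm.pr());
                bm.update(match);
                S2->reg = (S2->reg << 1) | (unsigned)match;
                b = match ? rb : S2->lit[rb].dec(seqrc);
              } else {
                b = S2->noref[sctx & 15].dec(seqrc);
              }
              sctx = ((sctx << 2) | b) & 15;
            }
            s[rp] = BB[b];
          }
        } else if (o.op == 'I') {
          NModel<4>* chm = S1 ? S1->ins : S2->ins;
          for (long j = 0; j < o.len; j++, rp++) {
            int b = 0;
            code_chan(nullptr, &seqrc, chm, ictx, b);
            s[rp] = BB[b];
          }
        } else if (o.op == 'S') {
          NModel<4>* chm = S1 ? S1->clip : S2->clip;
          for (long j = 0; j < o.len; j++, rp++) {
            int b = 0;
            code_chan(nullptr, &seqrc, chm, sctx, b);
            s[rp] = BB[b];
          }
        } else if (o.op == 'D' || o.op == 'N') {
          refc += o.len;
        }
      }
    }
    seq[r] = s;
  }
  bool bad = seqrc.overrun || siderc.overrun;
  delete S1;
  delete S2;
  if (bad) stop("truncated SAM stream");
  return List::create(_["flag"] = flag, _["pos"] = pos,
                      _["rname_idx"] = rname_idx, _["mapq"] = mapq,
                      _["cigar"] = cigar, _["seq"] = seq);
}
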