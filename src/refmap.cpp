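// Reference-based coding: pack a reference 4 bases/byte (N deleted), index
// non-overlapping 32-base groups in a probed hash table (27-bit pointer +
// 5-bit checksum per slot, linear probe of 8), align reads on both strands by
// rolling hash, rank candidates by the position of the fourth mismatch, and
// code alignment records either raw or under a parse-state context model.
#include <Rcpp.h>
#include "core.h"
#include "model_nary.h"
using namespace Rcpp;
using namespace fqz;

static const int GROUP = 32;
static const int PROBE = 8;
static const uint32_t HMUL = 0x9E3779B1u;  // odd multiplier

static inline int rcode(char ch) {
  switch (ch) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N and anything else
  }
}
static const char RBASES[] = "ACGT";

// ---------------------------------------------------------- pack reference
// [[Rcpp::export(name = ".c_pack_reference")]]
List c_pack_reference(std::string ref) {
  std::vector<uint8_t> codes;
  std::vector<int> nstart, nlen;
  size_t i = 0;
  while (i < ref.size()) {
    int c = rcode(ref[i]);
    if (c < 0) {
      size_t j = i;
      while (j < ref.size() && rcode(ref[j]) < 0) j++;
      nstart.push_back((int)i + 1);
      nlen.push_back((int)(j - i));
      i = j;
    } else {
      codes.push_back((uint8_t)c);
      i++;
    }
  }
  // 4 bases per byte
  std::vector<uint8_t> data((codes.size() + 3) / 4, 0);
  for (size_t k = 0; k < codes.size(); k++)
    data[k / 4] |= codes[k] << (2 * (k % 4));
  return List::create(_["data"] = RawVector(data.begin(), data.end()),
                      _["length"] = (double)codes.size(),
                      _["n_start"] = IntegerVector(nstart.begin(), nstart.end()),
                      _["n_len"] = IntegerVector(nlen.begin(), nlen.end()));
}

// [[Rcpp::export(name = ".c_unpack_reference")]]
std::string c_unpack_reference(RawVector data, double length,
                               IntegerVector n_start, IntegerVector n_len) {
  size_t L = (size_t)length;
  std::string s;
  s.reserve(L);
  for (size_t k = 0; k < L; k++)
    s += RBASES[(data[k / 4] >> (2 * (k % 4))) & 3];
  // reinsert N runs at original coordinates
  for (R_xlen_t i = 0; i < n_start.size(); i++)
    s.insert((size_t)n_start[i] - 1, (size_t)n_len[i], 'N');
  return s;
}

// --------------------------------------------------------------- group hash
static inline uint32_t group_hash(const uint8_t* codes, size_t off) {
  uint32_t h = 0;
  for (int j = 0; j < GROUP; j++) h = h * HMUL + codes[off + j] + 1;
  return h;
}

// insertion with linear probe of 8; returns false when discarded
static inline bool probe_insert(uint32_t* tab, uint32_t mask, uint32_t hfin,
                                uint32_t ptr) {
  uint32_t slot = hfin & mask;
  uint32_t chk = (hfin >> 27) & 31;
  for (int j = 0; j < PROBE; j++) {
    uint32_t s = (slot + j) & mask;
    if (tab[s] == 0) {
      tab[s] = ((ptr + 1) & 0x07FFFFFF) | (chk << 27);
      return true;
    }
  }
  return false;
}

// [[Rcpp::export(name = ".c_build_ref_index")]]
List c_build_ref_index(std::string ref, int table_bits) {
  if (table_bits < 8 || table_bits > 28) stop("table_bits must be in 8..28");
  std::vector<uint8_t> codes;
  codes.reserve(ref.size());
  for (char ch : ref) {
    int c = rcode(ch);
    if (c >= 0) codes.push_back((uint8_t)c);
  }
  size_t ngroups = codes.size() / GROUP;
  if (ngroups > (1ull << 27)) stop("reference too large for 27-bit group pointers");
  std::vector<uint32_t> tab((size_t)1 << table_bits, 0);
  uint32_t mask = ((uint32_t)1 << table_bits) - 1;
  size_t discarded = 0;
  for (size_t g = 0; g < ngroups; g++) {
    uint32_t h = hash_u64(group_hash(codes.data(), g * GROUP));
    if (!probe_insert(tab.data(), mask, h, (uint32_t)g)) discarded++;
  }
  IntegerVector rtab(tab.size());
  std::memcpy(INTEGER(rtab), tab.data(), tab.size() * 4);
  return List::create(
      _["table"] = rtab, _["table_bits"] = table_bits,
      _["codes"] = RawVector(codes.begin(), codes.end()),
      _["n_groups"] = (double)ngroups, _["n_discarded"] = (double)discarded,
      _["discard_fraction"] = ngroups ? (double)discarded / ngroups : 0.0);
}

// Occupancy simulation of the probe-8 insertion scheme with uniform hashes.
// [[Rcpp::export(name = ".c_index_discard_sim")]]
double c_index_discard_sim(int table_bits, double occupancy, int seed) {
  std::vector<uint32_t> tab((size_t)1 << table_bits, 0);
  uint32_t mask = ((uint32_t)1 << table_bits) - 1;
  size_t n = (size_t)(occupancy * ((size_t)1 << table_bits) + 0.5);
  uint64_t state = (uint64_t)seed * 6364136223846793005ull + 1442695040888963407ull;
  size_t disc = 0;
  for (size_t i = 0; i < n; i++) {
    state = state * 6364136223846793005ull + 1442695040888963407ull;
    uint32_t h = (uint32_t)(state >> 32);
    if (!probe_insert(tab.data(), mask, h, (uint32_t)(i & 0x03FFFFFF))) disc++;
  }
  return n ? (double)disc / n : 0.0;
}

// ------------------------------------------------------------------ aligner
struct Cand { uint32_t s; int dir; };

static void gather(const uint32_t* tab, uint32_t mask, const std::vector<uint8_t>& rc,
                   size_t reflen, size_t L, int dir, std::vector<Cand>& cands) {
  // rolling hash over 32-base windows of the (possibly reverse-complemented)
  // read; window ending at i (exclusive) maps group g to read start g*32-(i-32)
  uint32_t h = 0;
  uint32_t mul31 = 1;
  for (int j = 0; j < GROUP - 1; j++) mul31 *= HMUL;
  int found = 0;
  for (size_t i = 0; i < L && found < 16; i++) {
    h = h * HMUL + rc[i] + 1;
    if (i >= GROUP) h -= (rc[i - GROUP] + 1) * mul31 * HMUL;
    if (i + 1 < GROUP) continue;
    uint32_t hf = hash_u64(h);
    uint32_t slot = hf & mask, chk = (hf >> 27) & 31;
    for (int j = 0; j < PROBE; j++) {
      uint32_t t = tab[(slot + j) & mask];
      if (t == 0) break;
      if (((t >> 27) & 31) != chk) continue;
      long g = (long)(t & 0x07FFFFFF) - 1;
      long start = g * GROUP - (long)(i + 1 - GROUP);
      if (start < 0 || (size_t)(start + L) > reflen) continue;
      cands.push_back({(uint32_t)start, dir});
      if (++found >= 16) break;
    }
  }
}

struct Aln {
  bool matched = false;
  int dir = 0;
  uint32_t ptr = 0;
  int m[4];
};

static Aln align_one(const std::vector<uint8_t>& codes, const uint32_t* tab,
                     uint32_t mask, const std::string& read) {
  size_t L = read.size();
  Aln best;
  best.m[0] = best.m[1] = best.m[2] = best.m[3] = (int)L + 1;
  if (L < GROUP || L > 254) return best;
  std::vector<uint8_t> fw(L), rv(L);
  for (size_t j = 0; j < L; j++) {
    int c = rcode(read[j]);
    fw[j] = (uint8_t)(c < 0 ? 0 : c);
  }
  for (size_t j = 0; j < L; j++) rv[j] = (uint8_t)(3 - fw[L - 1 - j]);
  std::vector<Cand> cands;
  gather(tab, mask, fw, codes.size(), L, 0, cands);
  gather(tab, mask, rv, codes.size(), L, 1, cands);
  bool have = false;
  int bm[4];
  for (const Cand& cd : cands) {
    int m[4] = {(int)L + 1, (int)L + 1, (int)L + 1, (int)L + 1};
    int nm = 0;
    for (size_t j = 0; j < L && nm < 4; j++) {
      uint8_t expect = cd.dir ? (uint8_t)(3 - codes[cd.s + L - 1 - j]) : codes[cd.s + j];
      if (fw[j] != expect) m[nm++] = (int)j + 1;
    }
    bool better = !have;
    if (have) {
      for (int i = 3; i >= 0; i--) {
        if (m[i] != bm[i]) { better = m[i] > bm[i]; break; }
      }
    }
    if (better) {
      have = true;
      for (int i = 0; i < 4; i++) bm[i] = m[i];
      best.dir = cd.dir;
      best.ptr = cd.s;
    }
  }
  if (have && 2 * bm[3] >= (int)L) {
    best.matched = true;
    for (int i = 0; i < 4; i++) best.m[i] = bm[i];
  }
  return best;
}

// [[Rcpp::export(name = ".c_align_reads")]]
List c_align_reads(List idx, CharacterVector reads) {
  RawVector rcodes = idx["codes"];
  std::vector<uint8_t> codes(RAW(rcodes), RAW(rcodes) + rcodes.size());
  IntegerVector rtab = idx["table"];
  int tb = idx["table_bits"];
  std::vector<uint32_t> tab((size_t)1 << tb);
  std::memcpy(tab.data(), INTEGER(rtab), tab.size() * 4);
  uint32_t mask = ((uint32_t)1 << tb) - 1;
  int n = reads.size();
  LogicalVector matched(n);
  IntegerVector dir(n), m1(n), m2(n), m3(n), m4(n);
  NumericVector ptr(n);
  for (int r = 0; r < n; r++) {
    Aln a = align_one(codes, tab.data(), mask, as<std::string>(reads[r]));
    matched[r] = a.matched;
    dir[r] = a.dir;
    ptr[r] = (double)a.ptr;
    m1[r] = a.m[0]; m2[r] = a.m[1]; m3[r] = a.m[2]; m4[r] = a.m[3];
  }
  return List::create(_["matched"] = matched, _["dir"] = dir, _["ptr"] = ptr,
                      _["m1"] = m1, _["m2"] = m2, _["m3"] = m3, _["m4"] = m4);
}

// ------------------------------------------------------- alignment records
static void aln_serialize(List aln, std::vector<uint8_t>& out) {
  LogicalVector matched = aln["matched"];
  IntegerVector dir = aln["dir"], m1 = aln["m1"], m2 = aln["m2"],
                m3 = aln["m3"], m4 = aln["m4"];
  NumericVector ptr = aln["ptr"];
  for (R_xlen_t r = 0; r < matched.size(); r++) {
    if (!matched[r]) { out.push_back(0); continue; }
    out.push_back((uint8_t)m1[r]);
    out.push_back((uint8_t)m2[r]);
    out.push_back((uint8_t)m3[r]);
    out.push_back((uint8_t)m4[r]);
    out.push_back((uint8_t)dir[r]);
    uint32_t p = (uint32_t)ptr[r];
    for (int b = 0; b < 4; b++) out.push_back((uint8_t)(p >> (8 * b)));
  }
}

// slow mode: bit-wise direct model; context = parse state, previous bits of
// the current byte, high 6 bits of the previous byte (dropped for the two
// low pointer bytes)
struct AlnCM {
  std::vector<BitModel> t;  // [state][prev6][part]
  AlnCM() : t(9 * 64 * 256) {}
  BitModel& at(int state, int prev6, int part) {
    int p6 = (state == 5 || state == 6) ? 0 : prev6;
    return t[((size_t)state * 64 + p6) * 256 + part];
  }
};

// [[Rcpp::export(name = ".c_code_alignments")]]
RawVector c_code_alignments(List aln, bool slow) {
  std::vector<uint8_t> bytes;
  aln_serialize(aln, bytes);
  if (!slow) return RawVector(bytes.begin(), bytes.end());
  AlnCM cm;
  RangeEncoder rc;
  int state = 0, prev = 0;
  size_t i = 0;
  while (i < bytes.size()) {
    int byte = bytes[i++];
    int part = 1;
    for (int bp = 7; bp >= 0; bp--) {
      int bit = (byte >> bp) & 1;
      BitModel& bm = cm.at(state, prev >> 2, part);
      rc.encode_bit(bit, bm.pr());
      bm.update(bit);
      part = (part << 1) | bit;
    }
    prev = byte;
    if (state == 0) state = byte == 0 ? 0 : 1;
    else if (state == 8) state = 0;
    else state++;
  }
  rc.flush();
  return RawVector(rc.buf.begin(), rc.buf.end());
}

// [[Rcpp::export(name = ".c_decode_alignments")]]
List c_decode_alignments(RawVector data, int n, bool slow) {
  LogicalVector matched(n);
  IntegerVector dir(n), m1(n), m2(n), m3(n), m4(n);
  NumericVector ptr(n);
  AlnCM* cm = slow ? new AlnCM() : nullptr;
  RangeDecoder* rc = slow ? new RangeDecoder(RAW(data), data.size()) : nullptr;
  size_t k = 0;
  int state = 0, prev = 0;
  auto get = [&]() -> int {
    if (!slow) {
      if (k >= (size_t)data.size()) stop("truncated alignment stream");
      int b = data[k++];
      return b;
    }
    int part = 1;
    for (int bp = 7; bp >= 0; bp--) {
      BitModel& bm = cm->at(state, prev >> 2, part);
      int bit = rc->decode_bit(bm.pr());
      bm.update(bit);
      part = (part << 1) | bit;
    }
    return part & 0xFF;
  };
  for (int r = 0; r < n; r++) {
    state = 0;
    int b0 = get();
    prev = b0;
    if (b0 == 0) { matched[r] = false; m1[r] = m2[r] = m3[r] = m4[r] = 0; continue; }
    matched[r] = true;
    state = 1;
    for (int j = 1; j < 9; j++) {
      int b = get();
      prev = b;
      state = (state == 8) ? 0 : state + 1;
      if (j == 1) m2[r] = b;
      else if (j == 2) m3[r] = b;
      else if (j == 3) m4[r] = b;
      else if (j == 4) dir[r] = b;
      else {
        int shift = 8 * (j - 5);
        ptr[r] = ptr[r] + (double)((uint32_t)b << shift);
      }
    }
    m1[r] = b0;
  }
  delete cm;
  delete rc;
  return List::create(_["matched"] = matched, _["dir"] = dir, _["ptr"] = ptr,
                      _["m1"] = m1, _["m2"] = m2, _["m3"] = m3, _["m4"] = m4);
}

// ----------------------------------------- residual stream and reconstruction
// Matched bases are deleted from the sequence stream; mismatch literals are
// coded separately under the expected reference base as context.
// [[Rcpp::export(name = ".c_refmap_residual")]]
List c_refmap_residual(CharacterVector reads, List aln, List idx) {
  RawVector rcodes = idx["codes"];
  const uint8_t* codes = RAW(rcodes);
  LogicalVector matched = aln["matched"];
  IntegerVector dir = aln["dir"], m1 = aln["m1"], m2 = aln["m2"],
                m3 = aln["m3"], m4 = aln["m4"];
  NumericVector ptr = aln["ptr"];
  std::string residual;
  RangeEncoder rc;
  NModel<4> mis[4];
  for (R_xlen_t r = 0; r < reads.size(); r++) {
    std::string s = as<std::string>(reads[r]);
    if (!matched[r]) { residual += s; continue; }
    size_t L = s.size();
    uint32_t p = (uint32_t)ptr[r];
    int mm[4] = {m1[r], m2[r], m3[r], m4[r]};
    for (int i = 0; i < 3; i++) {
      if (mm[i] <= (int)L && mm[i] < mm[3]) {
        size_t j = (size_t)mm[i] - 1;
        uint8_t expect = dir[r] ? (uint8_t)(3 - codes[p + L - 1 - j]) : codes[p + j];
        int c = rcode(s[j]);
        if (c < 0) c = 0;
        mis[expect].enc(rc, c);
      }
    }
    if (mm[3] <= (int)L) residual += s.substr((size_t)mm[3] - 1);
  }
  rc.flush();
  return List::create(_["residual"] = residual,
                      _["mis"] = RawVector(rc.buf.begin(), rc.buf.end()));
}

// [[Rcpp::export(name = ".c_refmap_reconstruct")]]
CharacterVector c_refmap_reconstruct(List aln, std::string residual,
                                     RawVector mis, List idx,
                                     IntegerVector lengths) {
  RawVector rcodes = idx["codes"];
  const uint8_t* codes = RAW(rcodes);
  LogicalVector matched = aln["matched"];
  IntegerVector dir = aln["dir"], m1 = aln["m1"], m2 = aln["m2"],
                m3 = aln["m3"], m4 = aln["m4"];
  NumericVector ptr = aln["ptr"];
  RangeDecoder rc(RAW(mis), mis.size());
  NModel<4> mism[4];
  CharacterVector out(lengths.size());
  size_t off = 0;
  for (R_xlen_t r = 0; r < lengths.size(); r++) {
    size_t L = (size_t)lengths[r];
    std::string s;
    if (!matched[r]) {
      if (off + L > residual.size()) stop("residual sequence stream too short");
      s = residual.substr(off, L);
      off += L;
    } else {
      s.resize(L);
      uint32_t p = (uint32_t)ptr[r];
      for (size_t j = 0; j < L; j++)
        s[j] = RBASES[dir[r] ? (3 - codes[p + L - 1 - j]) : codes[p + j]];
      int mm[4] = {m1[r], m2[r], m3[r], m4[r]};
      for (int i = 0; i < 3; i++) {
        if (mm[i] <= (int)L && mm[i] < mm[3]) {
          size_t j = (size_t)mm[i] - 1;
          uint8_t expect = dir[r] ? (uint8_t)(3 - codes[p + L - 1 - j]) : codes[p + j];
          s[j] = RBASES[mism[expect].dec(rc)];
        }
      }
      if (mm[3] <= (int)L) {
        size_t tl = L - (size_t)mm[3] + 1;
        if (off + tl > residual.size()) stop("residual sequence stream too short");
        for (size_t j = 0; j < tl; j++) s[(size_t)mm[3] - 1 + j] = residual[off + j];
        off += tl;
      }
    }
    out[r] = s;
  }
  return out;
}
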