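// Small adaptive frequency models shared by the stream codecs.
#ifndef FQZLITE_MODEL_NARY_H
#define FQZLITE_MODEL_NARY_H

#include "core.h"

namespace fqz {

// Alphabet <= 128: plain 8-bit counters (total stays under 2^16).
template <int A>
struct NModel {
  uint8_t c[A];
  NModel() { std::memset(c, 0, A); }
  void enc(RangeEncoder& rc, int s) { sym_encode(rc, c, A, s); }
  int dec(RangeDecoder& rc) { return sym_decode(rc, c, A); }
};

// Full byte alphabet: counters halved when the running total would push the
// coding total past the coder's 16-bit precision.
struct Model256 {
  uint8_t c[256];
  uint32_t sum = 0;
  Model256() { std::memset(c, 0, 256); }
  void upd(int s) {
    if (c[s] >= 248 || sum >= 32000) {
      uint32_t ns = 0;
      for (int i = 0; i < 256; i++) { c[i] = (uint8_t)((c[i] + 1) >> 1); ns += c[i]; }
      sum = ns;
    }
    c[s] = (uint8_t)(c[s] + 8);
    sum += 8;
  }
  void enc(RangeEncoder& rc, int s) {
    uint32_t cum = 0;
    for (int i = 0; i < s; i++) cum += 2u * c[i] + 1;
    rc.encode(cum, 2u * c[s] + 1, 2u * sum + 256);
    upd(s);
  }
  int dec(RangeDecoder& rc) {
    uint32_t tot = 2u * sum + 256;
    uint32_t f = rc.get_freq(tot), cum = 0;
    int s = 0;
    while (s < 255 && cum + 2u * c[s] + 1 <= f) { cum += 2u * c[s] + 1; s++; }
    rc.decode(cum, 2u * c[s] + 1);
    upd(s);
    return s;
  }
};

}  // namespace fqz
#endif
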