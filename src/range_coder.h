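// Byte-wise range coder (Subbotin/Shelwien style: 32-bit range, 64-bit low
// with carry propagation and deferred 0xFF runs) and the adaptive
// frequency model shared by the arithmetic codec and the quality codec.
//
// Model discipline: counts start at 1 for every symbol, each coded symbol
// adds 16 to its count, and when the total reaches 2^13 all counts are
// halved flooring at 1.  Encoder and decoder models evolve identically.

#ifndef SEQCODEC_RANGE_CODER_H
#define SEQCODEC_RANGE_CODER_H

#include <Rcpp.h>
#include <cstdint>
#include <vector>

static const uint32_t RC_TOP = 1u << 24;

struct RangeEncoder {
  uint64_t low = 0;
  uint32_t range = 0xFFFFFFFFu;
  uint8_t cache = 0;
  uint64_t ffnum = 0;
  bool started = false;
  std::vector<uint8_t> out;

  void shift_low() {
    uint32_t carry = (uint32_t)(low >> 32);
    if ((uint32_t)low < 0xFF000000u || carry) {
      if (started) out.push_back((uint8_t)(cache + carry));
      while (ffnum) {
        out.push_back((uint8_t)(0xFF + carry));
        --ffnum;
      }
      cache = (uint8_t)(low >> 24);
      started = true;
    } else {
      ++ffnum;
    }
    low = (low << 8) & 0xFFFFFFFFull;
  }

  void encode(uint32_t cum, uint32_t freq, uint32_t tot) {
    range /= tot;
    low += (uint64_t)cum * range;
    range *= freq;
    while (range < RC_TOP) {
      shift_low();
      range <<= 8;
    }
  }

  void finish() {
    for (int i = 0; i < 5; i++) shift_low();
  }
};

struct RangeDecoder {
  uint32_t range = 0xFFFFFFFFu;
  uint32_t code = 0;
  const uint8_t *in;
  size_t pos = 0, len = 0;

  void init(const uint8_t *buf, size_t n) {
    in = buf;
    len = n;
    pos = 0;
    code = 0;
    for (int i = 0; i < 4; i++) code = (code << 8) | next_byte();
  }

  uint8_t next_byte() {
    if (pos >= len) Rcpp::stop("truncated stream: range coder input exhausted");
    return in[pos++];
  }

  uint32_t get_freq(uint32_t tot) {
    range /= tot;
    uint32_t v = code / range;
    return v >= tot ? tot - 1 : v;
  }

  void update(uint32_t cum, uint32_t freq) {
    code -= cum * range;
    range *= freq;
    while (range < RC_TOP) {
      code = (code << 8) | next_byte();
      range <<= 8;
    }
  }
};

// Adaptive model over a contiguous slice of counts (so large model banks
// can live in one flat allocation).
struct ModelView {
  uint16_t *cnt;
  uint32_t *tot;
  int n;

  void update(int s) {
    cnt[s] += 16;
    *tot += 16;
    if (*tot >= 8192) {
      uint32_t t = 0;
      for (int i = 0; i < n; i++) {
        cnt[i] >>= 1;
        if (!cnt[i]) cnt[i] = 1;
        t += cnt[i];
      }
      *tot = t;
    }
  }

  void encode(RangeEncoder &rc, int s) {
    uint32_t cum = 0;
    for (int i = 0; i < s; i++) cum += cnt[i];
    rc.encode(cum, cnt[s], *tot);
    update(s);
  }

  int decode(RangeDecoder &rc) {
    uint32_t df = rc.get_freq(*tot);
    uint32_t cum = 0;
    int s = 0;
    while (cum + cnt[s] <= df) {
      cum += cnt[s];
      ++s;
      if (s >= n) Rcpp::stop("malformed stream: symbol out of range");
    }
    rc.update(cum, cnt[s]);
    update(s);
    return s;
  }
};

// Self-owned model bank: nmodels models of nsym symbols each.
struct ModelBank {
  std::vector<uint16_t> cnt;
  std::vector<uint32_t> tot;
  int nsym;

  ModelBank(int nmodels, int nsym_)
      : cnt((size_t)nmodels * nsym_, 1), tot(nmodels, nsym_), nsym(nsym_) {}

  ModelView view(int m) {
    return ModelView{cnt.data() + (size_t)m * nsym, tot.data() + m, nsym};
  }
};

#endif
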