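// Static-frequency rANS core with 16-bit renormalization and 4- or 32-way
// interleaved states.  Frequency tables are normalized and serialized on the
// R side; this file implements only the payload coding loops.
//
// Layout of a payload produced by rans_enc_core():
//   [nstates x 4 bytes: final states, little-endian, lane 0 first]
//   [16-bit renormalization words, 2 bytes LE each, in reverse emission
//    order so the decoder reads them forward]
//
// Order-0 assigns byte i to lane i % nstates.  Order-1 splits the input
// into nstates contiguous chunks, one lane per chunk; the coding context is
// the previous byte within the chunk and 0 for each chunk's first byte.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static const uint32_t RANS_L = 1u << 15;

// chunk_starts: 0-based start offsets of each lane's chunk (order-1 only;
// empty for order-0).  shift is the frequency precision (12 or 10).
// [[Rcpp::export]]
RawVector rans_enc_core(RawVector data, int nstates, int shift,
                        IntegerMatrix freq, IntegerMatrix cumfreq,
                        IntegerVector chunk_starts) {
  const int L = data.size();
  const int N = nstates;
  const bool o1 = chunk_starts.size() > 0;
  const int shift16 = 31 - shift;

  std::vector<int> lane_of;
  std::vector<uint8_t> is_start;
  if (o1) {
    lane_of.assign(L, 0);
    is_start.assign(L, 0);
    for (int j = 0; j < N; j++) {
      int s = chunk_starts[j];
      int e = (j + 1 < N) ? chunk_starts[j + 1] : L;
      if (s < e) is_start[s] = 1;
      for (int i = s; i < e; i++) lane_of[i] = j;
    }
  }

  std::vector<uint32_t> x(N, RANS_L);
  std::vector<uint16_t> words;
  words.reserve(L / 4 + 16);

  for (int i = L - 1; i >= 0; --i) {
    int lane = o1 ? lane_of[i] : (i % N);
    int ctx = 0;
    if (o1 && !is_start[i]) ctx = data[i - 1];
    int s = data[i];
    uint32_t f = (uint32_t)freq(ctx, s);
    uint32_t c = (uint32_t)cumfreq(ctx, s);
    if (f == 0) stop("internal error: symbol with zero frequency");
    uint32_t xi = x[lane];
    uint32_t x_max = f << shift16;
    while (xi >= x_max) {
      words.push_back((uint16_t)(xi & 0xFFFF));
      xi >>= 16;
    }
    x[lane] = ((xi / f) << shift) + (xi % f) + c;
  }

  RawVector out(4 * (size_t)N + 2 * words.size());
  size_t p = 0;
  for (int j = 0; j < N; j++) {
    uint32_t v = x[j];
    out[p++] = v & 0xFF;
    out[p++] = (v >> 8) & 0xFF;
    out[p++] = (v >> 16) & 0xFF;
    out[p++] = (v >> 24) & 0xFF;
  }
  for (size_t k = words.size(); k-- > 0;) {
    out[p++] = words[k] & 0xFF;
    out[p++] = (words[k] >> 8) & 0xFF;
  }
  return out;
}

// [[Rcpp::export]]
RawVector rans_dec_core(RawVector payload, int len, int nstates, int shift,
                        IntegerMatrix freq, IntegerMatrix cumfreq,
                        IntegerVector chunk_starts) {
  const int N = nstates;
  const bool o1 = chunk_starts.size() > 0;
  const uint32_t mask = (1u << shift) - 1;
  const size_t plen = payload.size();

  // slot -> symbol lookup per context row
  const int nrow = freq.nrow();
  std::vector<uint8_t> lut((size_t)nrow << shift, 0);
  for (int r = 0; r < nrow; r++) {
    size_t pos = 0;
    for (int s = 0; s < 256 && pos < (1u << shift); s++) {
      for (int k = 0; k < freq(r, s); k++) lut[((size_t)r << shift) + pos++] = s;
    }
  }

  if (plen < 4 * (size_t)N) stop("truncated rans stream: missing states");
  std::vector<uint32_t> x(N);
  size_t p = 0;
  for (int j = 0; j < N; j++) {
    uint32_t v = (uint32_t)payload[p] | ((uint32_t)payload[p + 1] << 8) |
                 ((uint32_t)payload[p + 2] << 16) |
                 ((uint32_t)payload[p + 3] << 24);
    p += 4;
    if (v < RANS_L) stop("malformed rans stream: state underflow");
    x[j] = v;
  }

  std::vector<int> lane_of;
  std::vector<uint8_t> is_start;
  if (o1) {
    lane_of.assign(len, 0);
    is_start.assign(len, 0);
    for (int j = 0; j < N; j++) {
      int s = chunk_starts[j];
      int e = (j + 1 < N) ? chunk_starts[j + 1] : len;
      if (s < e) is_start[s] = 1;
      for (int i = s; i < e; i++) lane_of[i] = j;
    }
  }

  RawVector out(len);
  for (int i = 0; i < len; i++) {
    int lane = o1 ? lane_of[i] : (i % N);
    int ctx = 0;
    if (o1 && !is_start[i]) ctx = out[i - 1];
    uint32_t xi = x[lane];
    uint32_t m = xi & mask;
    int s = lut[((size_t)ctx << shift) + m];
    uint32_t f = (uint32_t)freq(ctx, s);
    uint32_t c = (uint32_t)cumfreq(ctx, s);
    if (f == 0 || m < c || m >= c + f)
      stop("malformed rans stream: bad slot");
    xi = f * (xi >> shift) + m - c;
    while (xi < RANS_L) {
      if (p + 2 > plen) stop("truncated rans stream");
      xi = (xi << 16) | ((uint32_t)payload[p] | ((uint32_t)payload[p + 1] << 8));
      p += 2;
    }
    x[lane] = xi;
    out[i] = s;
  }
  return out;
}
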