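// Adaptive byte-wise arithmetic (range) codec payload loops.  Order 0 uses
// one 256-symbol model; order 1 conditions each byte's model on the
// previous byte (context 0 for the first byte).  The RLE variant codes the
// first byte of each maximal run with the literal models and then the
// additional run length with per-symbol run-length models, in chunks of
// 0..255 where a chunk of 255 means "add 255 and continue".

#include <Rcpp.h>
#include "range_coder.h"
using namespace Rcpp;

// [[Rcpp::export]]
RawVector arith_enc_core(RawVector data, int order, bool rle) {
  const int L = data.size();
  RangeEncoder rc;
  ModelBank lit(order == 1 ? 256 : 1, 256);
  if (!rle) {
    int ctx = 0;
    for (int i = 0; i < L; i++) {
      lit.view(order == 1 ? ctx : 0).encode(rc, data[i]);
      ctx = data[i];
    }
  } else {
    ModelBank runs(256, 256);
    int ctx = 0, i = 0;
    while (i < L) {
      int s = data[i];
      int r = 1;
      while (i + r < L && data[i + r] == s) ++r;
      lit.view(order == 1 ? ctx : 0).encode(rc, s);
      int extra = r - 1;
      ModelView rv = runs.view(s);
      while (extra >= 255) {
        rv.encode(rc, 255);
        extra -= 255;
      }
      rv.encode(rc, extra);
      ctx = s;
      i += r;
    }
  }
  rc.finish();
  return RawVector(rc.out.begin(), rc.out.end());
}

// [[Rcpp::export]]
RawVector arith_dec_core(RawVector payload, int len, int order, bool rle) {
  RawVector out(len);
  if (len == 0) return out;
  RangeDecoder rc;
  rc.init(RAW(payload), payload.size());
  ModelBank lit(order == 1 ? 256 : 1, 256);
  if (!rle) {
    int ctx = 0;
    for (int i = 0; i < len; i++) {
      int s = lit.view(order == 1 ? ctx : 0).decode(rc);
      out[i] = s;
      ctx = s;
    }
  } else {
    ModelBank runs(256, 256);
    int ctx = 0, i = 0;
    while (i < len) {
      int s = lit.view(order == 1 ? ctx : 0).decode(rc);
      long run = 1;
      ModelView rv = runs.view(s);
      for (;;) {
        int c = rv.decode(rc);
        run += c;
        if (c < 255) break;
      }
      if (i + run > len) stop("malformed stream: run overflows output");
      for (long k = 0; k < run; k++) out[i + k] = s;
      ctx = s;
      i += run;
    }
  }
  return out;
}
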