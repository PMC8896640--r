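// FQZComp-family quality codec core: adaptive arithmetic coding of quality
// symbols under a <=16-bit context assembled from recent qualities (shifted
// history through a lookup table), read position, a cumulative-difference
// counter and verbatim selector bits, each mapped through a lookup table
// into disjoint bit-fields.  Per-record metadata (length, reverse flag,
// duplicate flag, selector) is coded in the same range-coder stream with
// its own adaptive models.  Parameter-block (de)serialization lives in R;
// this file codes the payload given parsed parameters.

#include <Rcpp.h>
#include "range_coder.h"
using namespace Rcpp;

struct FqzPar {
  int max_sym;
  int qbits, qshift, qloc;
  int pbits, ploc;
  int dbits, dloc;
  int sbits, sloc;
  int fixed_length;  // -1 when lengths vary per record
  bool do_dedup, do_reverse, do_selector;
  std::vector<int> qtab, ptab, dtab;
};

static FqzPar parse_par(List par) {
  FqzPar p;
  p.max_sym = as<int>(par["max_sym"]);
  p.qbits = as<int>(par["qbits"]);
  p.qshift = as<int>(par["qshift"]);
  p.qloc = as<int>(par["qloc"]);
  p.pbits = as<int>(par["pbits"]);
  p.ploc = as<int>(par["ploc"]);
  p.dbits = as<int>(par["dbits"]);
  p.dloc = as<int>(par["dloc"]);
  p.sbits = as<int>(par["sbits"]);
  p.sloc = as<int>(par["sloc"]);
  p.fixed_length = as<int>(par["fixed_length"]);
  p.do_dedup = as<bool>(par["do_dedup"]);
  p.do_reverse = as<bool>(par["do_reverse"]);
  p.do_selector = as<bool>(par["do_selector"]);
  p.qtab = as<std::vector<int>>(par["qtab"]);
  p.ptab = as<std::vector<int>>(par["ptab"]);
  p.dtab = as<std::vector<int>>(par["dtab"]);
  if ((int)p.qtab.size() < 256 || (int)p.ptab.size() < 1024 ||
      (int)p.dtab.size() < 256)
    stop("fqz parameter tables have wrong sizes");
  return p;
}

static inline int fqz_ctx(const FqzPar &p, uint32_t qctx, int pos, int delta,
                          int sel) {
  uint32_t ctx = 0;
  if (p.qbits) ctx |= (qctx & ((1u << p.qbits) - 1)) << p.qloc;
  if (p.pbits) ctx |= (uint32_t)p.ptab[pos > 1023 ? 1023 : pos] << p.ploc;
  if (p.dbits) ctx |= (uint32_t)p.dtab[delta > 255 ? 255 : delta] << p.dloc;
  if (p.sbits) ctx |= (uint32_t)sel << p.sloc;
  return (int)(ctx & 0xFFFF);
}

// [[Rcpp::export]]
List fqz_enc_core(List quals, LogicalVector rev, IntegerVector sel, List par,
                  bool trace) {
  FqzPar p = parse_par(par);
  const int nrec = quals.size();
  RangeEncoder rc;

  ModelBank mqual(1 << 16, p.max_sym);
  ModelBank mlen(4, 256);
  ModelBank mrev(1, 2), mdup(1, 2);
  ModelBank msel(1, p.sbits > 0 ? (1 << p.sbits) : 1);

  LogicalVector dup_out(nrec);
  std::vector<int> ctxs;
  std::vector<int> prevq;

  for (int r = 0; r < nrec; r++) {
    IntegerVector q = quals[r];
    const int len = q.size();
    std::vector<int> qv(q.begin(), q.end());
    for (int i = 0; i < len; i++)
      if (qv[i] < 0 || qv[i] >= p.max_sym)
        stop("quality value out of range for this parameter set");

    if (p.do_dedup) {
      bool dup = r > 0 && qv == prevq;
      mdup.view(0).encode(rc, dup ? 1 : 0);
      dup_out[r] = dup;
      if (dup) continue;
    }
    if (p.fixed_length < 0) {
      for (int b = 0; b < 4; b++)
        mlen.view(b).encode(rc, (len >> (8 * b)) & 0xFF);
    } else if (len != p.fixed_length) {
      stop("record length differs from fixed_length parameter");
    }
    bool rv = p.do_reverse && rev[r];
    if (p.do_reverse) mrev.view(0).encode(rc, rv ? 1 : 0);
    int s = p.do_selector ? sel[r] : 0;
    if (p.do_selector) msel.view(0).encode(rc, s);

    uint32_t qctx = 0;
    int delta = 0, last = 0;
    for (int i = 0; i < len; i++) {
      int qq = rv ? qv[len - 1 - i] : qv[i];
      int ctx = fqz_ctx(p, qctx, i, delta, s);
      if (trace) ctxs.push_back(ctx);
      mqual.view(ctx).encode(rc, qq);
      qctx = (qctx << p.qshift) + p.qtab[qq];
      if (i > 0 && qq != last) delta++;
      last = qq;
    }
    prevq = qv;
  }
  rc.finish();
  return List::create(
      _["payload"] = RawVector(rc.out.begin(), rc.out.end()),
      _["dup"] = dup_out,
      _["ctx"] = IntegerVector(ctxs.begin(), ctxs.end()));
}

// [[Rcpp::export]]
List fqz_dec_core(RawVector payload, List par, int nrec) {
  FqzPar p = parse_par(par);
  RangeDecoder rc;
  if (nrec > 0) rc.init(RAW(payload), payload.size());

  ModelBank mqual(1 << 16, p.max_sym);
  ModelBank mlen(4, 256);
  ModelBank mrev(1, 2), mdup(1, 2);
  ModelBank msel(1, p.sbits > 0 ? (1 << p.sbits) : 1);

  List quals(nrec);
  LogicalVector rev(nrec), dup(nrec);
  IntegerVector sel(nrec);
  std::vector<int> prevq;

  for (int r = 0; r < nrec; r++) {
    if (p.do_dedup) {
      bool d = mdup.view(0).decode(rc) == 1;
      dup[r] = d;
      if (d) {
        if (r == 0) stop("malformed stream: first record marked duplicate");
        quals[r] = IntegerVector(prevq.begin(), prevq.end());
        continue;
      }
    }
    int len;
    if (p.fixed_length < 0) {
      len = 0;
      for (int b = 0; b < 4; b++) len |= mlen.view(b).decode(rc) << (8 * b);
      if (len < 0) stop("malformed stream: negative record length");
    } else {
      len = p.fixed_length;
    }
    bool rv = false;
    if (p.do_reverse) rv = mrev.view(0).decode(rc) == 1;
    rev[r] = rv;
    int s = 0;
    if (p.do_selector) s = msel.view(0).decode(rc);
    sel[r] = s;

    std::vector<int> qv(len);
    uint32_t qctx = 0;
    int delta = 0, last = 0;
    for (int i = 0; i < len; i++) {
      int ctx = fqz_ctx(p, qctx, i, delta, s);
      int qq = mqual.view(ctx).decode(rc);
      qv[i] = qq;
      qctx = (qctx << p.qshift) + p.qtab[qq];
      if (i > 0 && qq != last) delta++;
      last = qq;
    }
    if (rv) std::reverse(qv.begin(), qv.end());
    quals[r] = IntegerVector(qv.begin(), qv.end());
    prevq = qv;
  }
  return List::create(_["quals"] = quals, _["rev"] = rev, _["dup"] = dup,
                      _["sel"] = sel);
}
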