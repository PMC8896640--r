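---
title: "Block codecs for sequencing data: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block codecs for sequencing data: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqcodec)
```

seqcodec implements the family of block-compression codecs used by modern
columnar genomic formats, where each data series — quality values, read
identifiers, auxiliary byte streams — is compressed with an algorithm
matched to its statistics.  This vignette explains the models behind each
codec, the tunable parameters and their defaults, the design choices made
where more than one self-consistent layout exists, and what the synthetic
data generators do and do not emulate.

## The rANS coder and its container

The static-frequency coder is a range Asymmetric Numeral System: symbol
frequencies are normalized to a fixed power-of-two total, written at the
start of the block, and each symbol is folded into a 32-bit state using
integer division and remainder.  Renormalization emits 16 bits at a time,
and either 4 or 32 states are interleaved round-robin (byte `i` on lane
`i mod N` for Order-0).  rANS is last-in-first-out, so the encoder walks
the input backwards and flushes the final states as `N` little-endian
words; 32 lanes therefore cost an extra 112 bytes of flush and only pay
off on large blocks — the file-level front end, not the codec, decides
when to use them.

Choices that the on-wire format fixes, with their rationale:

* **Frequency precision.** Order-0 tables are normalized to 12 bits
  (sum 4096); Order-1 rows to 10 bits (sum 1024).  Smaller rows bound the
  table size, which for Order-1 grows with the square of the alphabet.
  Normalization is largest-remainder apportionment with every observed
  symbol floored at frequency 1 and ties broken by ascending symbol
  value, so tables are a deterministic function of the counts.
* **Order-1 lane layout.** Order-1 splits the input into `N` contiguous
  chunks, one lane per chunk; the coding context is the previous byte
  within the chunk, and each chunk's first byte uses context 0.  A strict
  `i mod N` interleave would make the Order-1 context the byte `N`
  positions back, which destroys exactly the first-order correlation the
  model exists to capture.
* **Table serialization.** Present symbols are stored as runs of
  consecutive byte values, then one varint per frequency.  Order-1 stores
  only rows whose context occurs and wraps the whole serialized table in
  a nested Order-0 container: for dense alphabets (e.g. bit-packed
  qualities, where the byte alphabet is 256) the raw table dominates the
  block, and entropy-coding it recovers a large part of that overhead.
* **Varints and flags.** Block lengths use a most-significant-first
  base-128 varint (1–5 bytes, lexicographically ordered).  Every
  container opens with one flag byte: order in bit 0, 32-state interleave
  in bit 2, STRIPE in bit 3, suppressed length in bit 4, verbatim storage
  in bit 5, RLE in bit 6, PACK in bit 7; bit 1 is reserved.  This is this
  package's own dialect; byte-stream compatibility with other
  implementations is out of scope.

## The data transforms

**PACK** counts distinct symbols and assigns 0, 1, 2 or 4 bits per value
(1, 2, up to 4, up to 16 symbols), packing indices least-significant bits
first.  A one-symbol input needs zero payload bits — a strictly smaller
refinement of the two-symbol one-bit rule.  Inputs with more than 16
distinct symbols are a hard error; automatic fallback is a front-end
decision (`cmd_rans(auto = TRUE)`).

**RLE** is the declared-symbol-set variant: symbols in the set *always*
carry an additional-run-length entry (even zero); other symbols never do.
Literals and lengths form two streams, the lengths entropy-coded in a
nested Order-0 container, each entry chunked in bytes where 255 means
"add 255 and continue" so unbounded runs round-trip.  The selection rule
is exact per-symbol accounting — include a symbol exactly when the
literal bytes saved exceed the length bytes spent.  Because symbols'
contributions are independent, this equals the optimum over all subsets,
which the test suite verifies by exhaustive enumeration on small inputs.

**STRIPE** de-interleaves bytes at positions `Nx + c` into `N` streams,
each recursively framed as its own container (so each lane can pick its
own transforms), with the sub-stream lengths `ceil((L - c)/N)` implied by
the framing.  It exists for fixed-width multi-byte integers, where
per-byte-lane streams are far more predictable.

Composition order is fixed as STRIPE, then PACK, then RLE, then entropy
coding; decode inverts the chain.

## The adaptive arithmetic coder

The byte-wise range coder (32-bit range, 64-bit low with carry
propagation and deferred 0xFF runs) drives adaptive models: every symbol
starts at count 1, each coded occurrence adds 16, and when the total
reaches 2^13 all counts halve, flooring at 1.  The increment/rescale pair
trades steady-state precision for responsiveness on non-stationary data;
any fixed rule round-trips, and this one is part of the stream contract
since the decoder must mirror it exactly.  Order-1 keeps 256 models, one
per preceding byte.  The RLE variant is model-based rather than
stream-splitting: each maximal run codes its first byte with the literal
models, then the additional length with adaptive models indexed by the
run symbol, in 255-continuation chunks so the run alphabet stays at 256.
No models above Order-1 are provided: blocks are kept small for random
access, and higher orders would dilute their statistics.

One consequence worth knowing: on near-uniform wide alphabets (PacBio CLR
qualities span 0–93) the +16 increment deliberately over-weights recent
symbols, so the adaptive coders sit slightly *above* the static coder's
size there.  That data is close to incompressible for every method, which
is itself the expected outcome.

## The quality codec

Quality values are coded by an adaptive arithmetic coder whose model is
selected by a context of at most 16 bits, assembled from four disjoint
bit-fields:

* `qbits` bits of **quality history** at `qloc`: after each symbol `q`,
  the accumulator becomes `(qctx << qshift) + qtab[q]`; the lookup table
  `qtab` can shrink the per-symbol contribution (quantized NovaSeq values
  need 2 bits each, so four previous values fit in 8 bits).
* `pbits` bits of **read position** at `ploc`, via `ptab[min(pos, 1023)]`.
  Wide fields (6 bits and up) track the cycle directly, saturating;
  narrow fields use log-spaced buckets.  Position matters because error
  rates are cycle-dependent, concentrated late in the read.
* `dbits` bits of **cumulative difference** at `dloc`, via
  `dtab[min(delta, 255)]`, where `delta` counts the positions so far
  whose value differed from its predecessor.  Past variability predicts
  future variability, making this a cheap proxy for a read's hidden
  quality regime.
* `sbits` **selector** bits at `sloc`, copied verbatim from the record,
  partitioning records into groups (read 1 vs read 2, clusters by x/y,
  ...).

Disjointness of the four fields is enforced by validation rather than
achieved by hash mixing: it is equally expressive within 16 bits and
makes the context function exactly invertible for testing.  Position
clamps at 1023 and delta at 255 — the lookup-table domains.  Sequence
bases are deliberately not part of the context, which would couple the
quality stream to the sequence stream.

Per-record metadata is coded in the same range-coder stream with its own
adaptive models: the length as four little-endian bytes unless all
records share one length (then it is stored once in the parameter block),
a reverse flag (the record is then coded right-to-left), a duplicate flag
(a record identical to its predecessor contributes nothing else), and the
selector.  The parameter block — field widths, shifts, locations, the
quality-value map and the three lookup tables, the latter stored as
zigzag first-difference run pairs so identity and constant tables cost a
few bytes — is written at the head of the stream, so the decoder always
follows the encoder's model description and presets can evolve freely
without breaking old streams.

Quality values up to Phred 93 are supported; all presets map the observed
values through a stored map, so `max_sym` is the number of distinct
values, at most 94.  The four presets (`generic`, `small_alphabet`,
`position_heavy`, `selector_read12`) are this package's own; they follow
the published design space but no external preset definitions exist to
copy.

## The read-name tokenizer

Names split into maximal digit runs (with a leading-zero flavour), alpha
runs, and single characters; digit runs longer than ten split
left-to-right, and a ten-digit chunk at or above 2^32 splits five-and-five
so every numeric value fits 32 bits.  Each fragment is compared against
the previous name's fragment in the same column: byte-identical fragments
become MATCH; plain numbers whose difference lies in 0..255 become
DDELTA; zero-padded numbers with identical width and leading-zero count
and a difference in 0..255 become DDELTA0; everything else is stored
literally (values as 32-bit little-endian words, zero-padded values with
their width, alpha strings length-prefixed).  Tokens end with END and are
grouped into per-(column, type) streams, each compressed independently —
rANS Order-0 at the `fast` level; at `max`, six candidate methods
(including verbatim storage) are tried per stream and the smallest kept.

Two simplifications relative to the widest possible design, both
lossless: comparison is against the immediately preceding name only, and
the decoder is strictly sequential (name-major, column by column until
END), which makes NOP fill tokens unnecessary — NOP remains in the token
alphabet for completeness but is never emitted.  Negative deltas fall
back to literals; the delta window is 0..255 inclusive on both sides.

## What the synthetic generators emulate

The generators exist so every codec is testable without downloads; their
defaults are frozen as the package's study conditions.

* **novaseq** emulates patterned-flowcell data quantized to
  {2, 12, 23, 37}: each read carries a hidden good/bad cluster state
  (sticky transitions, `P(good to good) = 0.997`,
  `P(bad to bad) = 0.95`), the good state emitting Q37 almost always and
  the bad state a skewed mix centred on Q23, plus a mild late-cycle
  degradation ramp over the final 15% of cycles.  The burstiness this
  produces — long Q37 runs broken by correlated noisy stretches — is what
  makes run-length coding, multi-symbol contexts and the
  cumulative-difference counter genuinely informative, as on real data.
  A plain first-order chain would make the single-previous-symbol model
  optimal by construction and no richer codec could beat it.
* **hiseq** uses 40 observable values (2..41) with a smoothed random-walk
  transition matrix pulled toward the high thirties and a stronger
  late-cycle ramp.
* **pacbio** draws 0..93 independently from a mildly non-uniform weight
  curve: a wide, almost uncorrelated alphabet that no codec should
  compress much.
* **names** follow the `instrument:run:flowcell:lane:tile:x:y` template
  with fixed-width numeric fields; in sorted order y advances by small
  random steps with occasional x bumps (so consecutive names differ in at
  most two numeric fields and the list is lexicographically
  non-decreasing), and the scrambled order is a seeded uniform
  permutation standing in for position sort.

What they do **not** emulate: instrument-specific error models, tile and
flowcell spatial effects, adapter chimeras, duplicate reads from PCR, or
quality/sequence dependence.  Passing tests on this data show the codecs
are lossless and that the qualitative size orderings have the right
causes; they do not predict absolute ratios on real files.

## Problem sizes and numerical choices

Benchmark-style comparisons use a single block of 10 000 reads of 100
cycles (one megabyte of quality values — the block size at which these
codecs are normally operated) and 1000 names per corpus; record-oriented
benchmarks split inputs into blocks of 100 000 records.  Property suites
run on the order of ten thousand randomized round trips with fixed seeds.
The quality codec's calibration check generates 10^5 symbols from a known
first-order model and requires the coded size to be within 5% of the
model's empirical conditional entropy.

Degenerate inputs are defined, not special-cased away: empty blocks are a
header only; one-symbol blocks pack to zero payload bits; Order-1 with
fewer bytes than lanes leaves the spare lanes idle; runs longer than any
one-byte length chunk continue via 255-chunking; all-zero context widths
collapse the quality codec to a single adaptive model.  Decoders validate
frequency-table sums, payload lengths and state bounds, and fail with
`truncated`/`malformed` errors rather than returning wrong bytes.

## Known limitations

* Containers are this package's documented dialect, not a bit-exact match
  for any other implementation of the same codecs.
* The encoder does not auto-tune transform or preset choices beyond the
  `max` tokenizer level and the explicit benchmark harness.
* A single scalar implementation: the 32-state layout permits SIMD
  decoding in principle, but none is provided.
* Lossy quality transforms are intentionally out of scope.
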