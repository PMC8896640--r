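test_that("frequency normalization matches exact apportionment", {
  expect_identical(normalize_frequencies(c(1), 12), 4096L)
  expect_identical(normalize_frequencies(c(1, 1), 12), c(2048L, 2048L))
  expect_identical(normalize_frequencies(c(3, 1), 12), c(3072L, 1024L))
  expect_error(normalize_frequencies(c(0, 0), 12), "empty")
})

test_that("normalized frequencies sum exactly and keep observed symbols", {
  set.seed(3)
  for (rep in 1:50) {
    nsym <- sample(1:256, 1)
    counts <- integer(256)
    counts[sample.int(256, nsym)] <- rpois(nsym, sample(c(2, 50, 5000), 1)) + 1L
    for (bits in c(10, 12)) {
      f <- normalize_frequencies(counts, bits)
      expect_identical(sum(f), as.integer(2^bits))
      expect_true(all(f[counts > 0] >= 1L))
      expect_true(all(f[counts == 0] == 0L))
    }
  }
  # deterministic tie-break: equal counts split evenly, remainder to the
  # lowest symbols first
  f <- normalize_frequencies(rep(1, 3), 12)
  expect_identical(sum(f), 4096L)
  expect_true(max(f) - min(f) <= 1L)
  expect_true(all(diff(f) <= 0L))
})

test_that("rans round-trips across orders, state counts and alphabets", {
  set.seed(21)
  for (order in 0:1) {
    for (ns in c(4L, 32L)) {
      for (rep in 1:25) {
        len <- sample(0:2000, 1)
        if (order == 1L && len == 0L) next
        data <- rand_bytes(len, sample(c(1, 2, 4, 16, 256), 1))
        enc <- rans_encode(data, order, ns)
        expect_identical(rans_decode(enc), data)
      }
    }
  }
  expect_identical(rans_decode(rans_encode(raw(0), 0L)), raw(0))
  expect_error(rans_encode(raw(0), 1L), "non-empty")
})

test_that("single-symbol blocks cost nothing beyond table and state flush", {
  data <- as.raw(rep(0x41, 1000))
  parts <- seqcodec:::rans_block_parts(data, 0L, 4L)
  # payload = 16 bytes of state flush; renormalization never fires at
  # frequency 4096/4096
  expect_lte(length(parts$payload) - 16L, 8L)
  expect_identical(rans_decode(rans_encode(data, 0L)), data)
})

test_that("order-0 payload respects the Shannon lower bound", {
  set.seed(5)
  for (rep in 1:20) {
    data <- rand_bytes(sample(200:5000, 1), sample(c(2, 4, 26, 256), 1),
                       skew = sample(c(1, 3), 1))
    parts <- seqcodec:::rans_block_parts(data, 0L, 4L)
    # the flushed states stay in the payload: they carry the coder's
    # residual information, without which the bound could be undercut
    bound <- ceiling(length(data) * shannon_h0(data) / 8) - 1
    expect_gte(length(parts$payload), bound)
  }
  # near-uniform 4-symbol data sits close to 2 bits/symbol
  data <- rand_bytes(4096, 4L, skew = 0)
  payload <- length(seqcodec:::rans_block_parts(data, 0L, 4L)$payload)
  expect_gte(payload, 1024L)
  expect_lte(payload, 1024L + 192L)
})

test_that("order-1 beats order-0 on strongly Markov data", {
  set.seed(33)
  data <- markov_bytes(65536, syms = c(0x61, 0x71), self = 0.97)
  o0 <- length(rans_encode(data, 0L))
  o1 <- length(rans_encode(data, 1L))
  expect_lt(o1, o0)
})

test_that("4- and 32-state variants agree on content and closely on size", {
  set.seed(13)
  data <- rand_bytes(65536, 256L)
  e4 <- rans_encode(data, 0L, 4L)
  e32 <- rans_encode(data, 0L, 32L)
  expect_identical(rans_decode(e4), rans_decode(e32))
  expect_lte(length(e32), length(e4) * 1.01 + 128)
})

test_that("containers compose transforms and invert every flag set", {
  set.seed(55)
  flag_sets <- list(
    codec_flags(order = 0L),
    codec_flags(order = 1L),
    codec_flags(order = 0L, pack = TRUE),
    codec_flags(order = 1L, rle = TRUE),
    codec_flags(order = 1L, pack = TRUE, rle = TRUE),
    codec_flags(order = 0L, x32 = TRUE, pack = TRUE, rle = TRUE),
    codec_flags(cat = TRUE),
    codec_flags(order = 1L, stripe = TRUE),
    codec_flags(order = 0L, stripe = TRUE, pack = TRUE, rle = TRUE))
  for (fl in flag_sets) {
    for (rep in 1:12) {
      len <- sample(0:1500, 1)
      data <- rand_bytes(len, sample(c(1, 2, 4, 16), 1))
      enc <- encode_container(data, fl, stripe_n = sample(1:4, 1))
      expect_identical(decode_container(enc), data)
    }
  }
})

test_that("striped 16-bit integer data round-trips", {
  set.seed(77)
  vals <- cumsum(sample(-3:3, 3000, replace = TRUE)) + 5000
  data <- writeBin(as.integer(vals), raw(), size = 2, endian = "little")
  enc <- encode_container(data, codec_flags(order = 1L, stripe = TRUE),
                          stripe_n = 2L)
  expect_identical(decode_container(enc), data)
  # de-interleaving separates high and low bytes: each lane compresses
  # better than the interleaved stream
  plain <- encode_container(data, codec_flags(order = 1L))
  expect_lt(length(enc), length(plain))
})

test_that("cat containers store bytes verbatim after the framing", {
  enc <- encode_container(as.raw(c(9, 8, 7)), codec_flags(cat = TRUE))
  expect_identical(enc, as.raw(c(0x20, 3, 9, 8, 7)))
  expect_identical(decode_container(as.raw(c(0x20, 3, 9, 8, 7))),
                   as.raw(c(9, 8, 7)))
})

test_that("no_size containers decode with a caller-supplied length", {
  data <- rand_bytes(100, 4L)
  enc <- encode_container(data, codec_flags(no_size = TRUE))
  expect_identical(decode_container(enc, expected_length = 100), data)
  expect_error(decode_container(enc), "expected_length")
})

test_that("malformed and truncated streams raise informative errors", {
  expect_error(decode_container(as.raw(c(0x02, 0x01, 0x00))), "unsupported")
  data <- rand_bytes(1000, 256L)
  enc <- rans_encode(data, 0L)
  expect_error(rans_decode(enc[1:(length(enc) - 10)]), "truncat")
  expect_error(decode_container(raw(0)), "truncated")
  # corrupt the frequency table so the row no longer sums to 2^12
  enc2 <- rans_encode(as.raw(rep(0x41, 50)), 0L)
  enc2[6] <- as.raw(0x01)
  expect_error(rans_decode(enc2), "malformed|truncat|unsupported")
})

test_that("pack-flagged containers reject unpackable input", {
  expect_error(encode_container(as.raw(0:16),
                                codec_flags(order = 0L, pack = TRUE)),
               "not packable")
})
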