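test_that("pack maps known inputs to the documented payloads", {
  p <- pack("ABABABAB")
  expect_identical(p$packed, as.raw(0xAA))  # LSB-first, 8 values per byte
  expect_identical(p$meta$width_bits, 1L)
  expect_identical(p$meta$symbol_table, charToRaw("AB"))

  p1 <- pack("AAAAAAAA")
  expect_identical(p1$packed, raw(0))
  expect_identical(p1$meta$width_bits, 0L)

  expect_error(pack(as.raw(0:16)), "not packable")
  expect_error(pack(raw(0)), "non-empty")
})

test_that("unpack inverts pack and validates payload lengths", {
  p <- pack("ABABABAB")
  expect_identical(rawToChar(unpack(p$packed, p$meta)), "ABABABAB")
  meta1 <- list(n_symbols = 1L, symbol_table = charToRaw("A"),
                width_bits = 0L, original_length = 5L)
  expect_identical(rawToChar(unpack(raw(0), meta1)), "AAAAA")
  meta2 <- list(n_symbols = 4L, symbol_table = charToRaw("ABCD"),
                width_bits = 2L, original_length = 4L)
  expect_identical(rawToChar(unpack(as.raw(0x0F), meta2)), "DDAA")
  expect_error(unpack(as.raw(c(0x0F, 0x00)), meta2), "length mismatch")
})

test_that("pack payload length follows ceiling(L * width / 8) exactly", {
  set.seed(42)
  for (nsym in c(1L, 2L, 3L, 4L, 5L, 16L)) {
    for (L in c(1L, 7L, 8L, 9L, 100L)) {
      if (L < nsym) next
      data <- as.raw(c(seq_len(nsym) - 1L,
                       sample.int(nsym, L - nsym, replace = TRUE) - 1L))
      p <- pack(data)
      expect_identical(length(p$packed),
                       as.integer(ceiling(L * p$meta$width_bits / 8)))
      expect_identical(unpack(p$packed, p$meta), data)
    }
  }
})

test_that("rle encodes known examples into separate literal/length streams", {
  m <- rle_encode("AAAA", charToRaw("A"))
  expect_identical(m$literals, charToRaw("A"))
  expect_identical(m$lengths, 3L)

  m2 <- rle_encode("AAAA", raw(0))
  expect_identical(m2$literals, charToRaw("AAAA"))
  expect_identical(m2$lengths, integer(0))

  m3 <- rle_encode("ABBBA", charToRaw("B"))
  expect_identical(m3$literals, charToRaw("ABA"))
  expect_identical(m3$lengths, 2L)

  expect_identical(rle_decode(m), charToRaw("AAAA"))
  expect_identical(rle_decode(m3), charToRaw("ABBBA"))
  empty <- rle_encode(raw(0), raw(0))
  expect_identical(rle_decode(empty), raw(0))
})

test_that("rle decode rejects inconsistent streams", {
  bad <- structure(list(literals = charToRaw("AA"), lengths = 3L,
                        run_symbols = charToRaw("A")), class = "rle_meta")
  expect_error(rle_decode(bad), "malformed")
})

test_that("run-symbol selection matches the stated per-symbol accounting", {
  expect_identical(select_run_symbols("AAAABBBBC"), charToRaw("AB"))
  expect_identical(select_run_symbols("ABCABC"), raw(0))
  expect_identical(select_run_symbols(raw(0)), raw(0))
})

test_that("run-symbol selection is optimal against subset enumeration", {
  set.seed(7)
  for (rep in 1:60) {
    nsym <- sample(1:6, 1)
    len <- sample(1:30, 1)
    data <- as.raw(sample(0:(nsym - 1), len, replace = TRUE))
    sel <- select_run_symbols(data)
    oracle <- brute_force_run_symbols(data)
    m <- rle_encode(data, sel)
    cost <- length(m$literals) + sum((m$lengths) %/% 255L + 1L)
    expect_identical(cost, oracle$cost)
    expect_identical(rle_decode(m), data)
  }
})

test_that("stripe de-interleaves by position modulo N", {
  s <- stripe(as.raw(0:7), 4L)
  expect_identical(s, list(as.raw(c(0, 4)), as.raw(c(1, 5)),
                           as.raw(c(2, 6)), as.raw(c(3, 7))))
  expect_identical(stripe(as.raw(1:5), 1L), list(as.raw(1:5)))
  expect_identical(lengths(stripe(as.raw(0:8), 4L)), c(3L, 2L, 2L, 2L))
  expect_error(stripe(as.raw(1), 0L), "n >= 1")
})

test_that("unstripe inverts stripe and rejects inconsistent lengths", {
  expect_identical(unstripe(stripe(as.raw(0:7), 4L)), as.raw(0:7))
  expect_identical(unstripe(list(as.raw(1:3))), as.raw(1:3))
  expect_error(unstripe(list(as.raw(0), as.raw(1), as.raw(2),
                             as.raw(c(3, 99)))), "inconsistent")
})

test_that("all transforms round-trip on randomized inputs", {
  set.seed(11)
  for (rep in 1:200) {
    len <- sample(0:1000, 1)
    nsym <- sample(c(1, 2, 4, 16, 64, 256), 1)
    data <- rand_bytes(len, nsym)
    if (len > 0 && length(unique(data)) <= 16) {
      p <- pack(data)
      expect_identical(unpack(p$packed, p$meta), data)
    }
    rs <- select_run_symbols(data)
    expect_identical(rle_decode(rle_encode(data, rs)), data)
    n <- sample(1:8, 1)
    expect_identical(unstripe(stripe(data, n)), data)
  }
})

test_that("run lengths beyond the one-byte chunk limit round-trip", {
  lens <- c(0L, 1L, 254L, 255L, 256L, 509L, 510L, 70000L)
  bytes <- seqcodec:::chunk_run_lengths(lens)
  expect_identical(seqcodec:::unchunk_run_lengths(bytes), as.numeric(lens))
  long <- as.raw(rep(0x51, 70001))
  m <- rle_encode(long, as.raw(0x51))
  expect_identical(rle_decode(m), long)
  expect_identical(rle_decode(rle_encode(long, raw(0))), long)
})
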