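test_that("context assembly follows the documented bit-field formula", {
  p <- make_fqz_params(16L, qbits = 4L, qshift = 2L, pbits = 2L, ploc = 4L,
                       ptab = pmin(0:1023, 3L))
  # history [3, 1] under qshift 2 gives qctx 13; position 2 maps to field 2
  expect_identical(compute_context(list(qctx = 13, pos = 2, delta = 0), 0L, p),
                   45L)
  p0 <- make_fqz_params(4L)
  expect_identical(compute_context(list(qctx = 99, pos = 7, delta = 3), 0L, p0),
                   0L)
  ps <- make_fqz_params(4L, sbits = 1L, sloc = 15L)
  expect_identical(compute_context(list(qctx = 0, pos = 0, delta = 0), 1L, ps),
                   32768L)
})

test_that("parameter validation enforces the 16-bit disjoint-field budget", {
  expect_error(make_fqz_params(64L, qbits = 12L, pbits = 8L, ploc = 12L),
               "16 context bits")
  expect_error(make_fqz_params(4L, qbits = 4L, pbits = 2L, ploc = 2L),
               "overlapping")
  expect_error(make_fqz_params(4L, pbits = 2L, ploc = 15L), "beyond bit 15")
  for (preset in c("generic", "small_alphabet", "position_heavy",
                   "selector_read12")) {
    p <- build_params(novaseq_fixture(50L), preset)
    expect_lte(p$qbits + p$pbits + p$dbits + p$sbits, 16L)
  }
})

test_that("presets honour their contracts on matching alphabets", {
  nova <- novaseq_fixture(100L)
  p <- build_params(nova, "small_alphabet")
  expect_lte(length(p$qmap), 4L)
  expect_identical(p$qshift, 2L)  # two bits per mapped quality value
  hs <- gen_qualities(quality_profile("hiseq", 100L, 100L, seed = 2))
  ph <- build_params(hs, "position_heavy")
  expect_gte(ph$pbits, 7L)
  # a small-alphabet preset still works when the alphabet turns out wide
  psw <- build_params(hs, "small_alphabet")
  dec <- fqz_decode(fqz_encode(hs, psw))
  expect_identical(dec$quals, hs$quals)
  ps <- build_params(nova, "selector_read12")
  expect_identical(ps$sbits, 1L)
})

test_that("quality records validate their value range", {
  expect_error(quality_records(list(c(1L, 94L))), "0..93")
  expect_error(quality_records(list(-1L)), "0..93")
  expect_silent(quality_records(list(0:93)))
})

test_that("fqz round-trips across alphabets, lengths and flag sets", {
  set.seed(43)
  for (nsym in c(2L, 4L, 8L, 40L, 94L)) {
    vals <- sort(sample(0:93, nsym))
    for (rep in 1:4) {
      n <- sample(5:40, 1)
      quals <- lapply(seq_len(n), function(i)
        vals[sample.int(nsym, sample(1:500, 1), replace = TRUE)])
      # inject exact duplicates to exercise dedup
      if (n > 3) quals[[3]] <- quals[[2]]
      recs <- quality_records(quals,
                              reverse = sample(c(TRUE, FALSE), n, TRUE),
                              selector = sample(0:1, n, TRUE))
      for (preset in c("generic", "selector_read12")) {
        par <- build_params(recs, preset)
        dec <- fqz_decode(fqz_encode(recs, par))
        expect_identical(dec$quals, recs$quals)
        expect_identical(dec$reverse[!dec$duplicate],
                         recs$reverse[!dec$duplicate])
        if (par$do_selector)
          expect_identical(dec$selector[!dec$duplicate],
                           recs$selector[!dec$duplicate])
      }
    }
  }
})

test_that("duplicate records cost only their flag", {
  q <- list(0:60 %% 40L)
  one <- quality_records(q)
  two <- quality_records(c(q, q))
  par1 <- build_params(one, "generic")
  par2 <- build_params(two, "generic")
  s1 <- length(fqz_encode(one, par1))
  s2 <- length(fqz_encode(two, par2))
  expect_lt(s2 - s1, 2L)
  dec <- fqz_decode(fqz_encode(two, par2))
  expect_identical(dec$quals, two$quals)
  expect_identical(dec$duplicate, c(FALSE, TRUE))
})

test_that("selector values survive a round trip", {
  recs <- quality_records(list(c(1L, 2L), c(3L, 4L), c(1L, 1L)),
                          selector = c(0L, 1L, 0L))
  par <- build_params(recs, "selector_read12")
  par$do_dedup <- FALSE
  expect_identical(fqz_decode(fqz_encode(recs, par))$selector, c(0L, 1L, 0L))
})

test_that("reversed records are coded right-to-left and restored", {
  set.seed(47)
  quals <- lapply(1:20, function(i) sample(0:3, 50, replace = TRUE))
  recs <- quality_records(quals, reverse = rep(c(TRUE, FALSE), 10))
  par <- build_params(recs, "generic")
  dec <- fqz_decode(fqz_encode(recs, par))
  expect_identical(dec$quals, recs$quals)
  expect_identical(dec$reverse, recs$reverse)
})

test_that("encoder and decoder visit identical contexts", {
  set.seed(53)
  quals <- lapply(1:5, function(i) sample(0:3, 30, replace = TRUE))
  recs <- quality_records(quals)
  par <- build_params(recs, "generic")
  par$do_dedup <- FALSE
  trace <- seqcodec:::fqz_enc_core(recs$quals, recs$reverse, recs$selector,
                                   seqcodec:::core_params(par), TRUE)$ctx
  # independent replay of the context recurrence through compute_context
  expected <- integer(0)
  for (q in quals) {
    st <- list(qctx = 0, pos = 0, delta = 0)
    last <- 0L
    for (i in seq_along(q)) {
      expected <- c(expected, compute_context(st, 0L, par))
      st$qctx <- (st$qctx * 2^par$qshift + par$qtab[q[i] + 1L]) %% 65536
      if (i > 1L && q[i] != last) st$delta <- st$delta + 1
      last <- q[i]
      st$pos <- i
    }
  }
  expect_identical(trace, expected)
})

test_that("coded size approaches the conditional entropy of a known model", {
  set.seed(101)
  P <- matrix(c(0.70, 0.15, 0.10, 0.05,
                0.10, 0.70, 0.15, 0.05,
                0.05, 0.15, 0.70, 0.10,
                0.05, 0.10, 0.15, 0.70), 4, 4, byrow = TRUE)
  cum <- t(apply(P, 1, cumsum))
  n <- 1000L
  len <- 100L
  quals <- vector("list", n)
  for (i in seq_len(n)) {
    q <- integer(len)
    q[1] <- sample.int(4, 1) - 1L
    u <- runif(len)
    for (j in 2:len) q[j] <- findInterval(u[j], cum[q[j - 1] + 1L, ])
    quals[[i]] <- q
  }
  recs <- quality_records(quals)
  par <- make_fqz_params(4L, qbits = 2L, qshift = 2L, fixed_length = len)
  enc <- fqz_encode(recs, par)
  hdr <- length(seqcodec:::serialize_fqz_params(par, n))
  coded_bits <- (length(enc) - hdr) * 8

  # empirical conditional entropy over the contexts the model actually uses
  ctx <- unlist(lapply(quals, function(q) c(0L, q[-len])))
  sym <- unlist(quals)
  tab <- table(ctx, sym)
  h_bits <- 0
  for (r in seq_len(nrow(tab))) {
    nc <- sum(tab[r, ])
    p <- tab[r, ][tab[r, ] > 0] / nc
    h_bits <- h_bits - nc * sum(p * log2(p))
  }
  expect_lt(abs(coded_bits - h_bits), 0.05 * h_bits)
})

test_that("an informative selector reduces the coded size", {
  set.seed(107)
  n <- 400L
  quals <- vector("list", n)
  sel <- rep(0:1, length.out = n)
  for (i in seq_len(n)) {
    prob <- if (sel[i] == 0L) c(0.85, 0.05, 0.05, 0.05)
            else c(0.05, 0.05, 0.05, 0.85)
    quals[[i]] <- sample(c(2L, 12L, 23L, 37L), 100, TRUE, prob)
  }
  recs <- quality_records(quals, selector = sel)
  base <- make_fqz_params(4L, qbits = 2L, qshift = 2L, fixed_length = 100L,
                          qmap = c(2L, 12L, 23L, 37L))
  with_sel <- make_fqz_params(4L, qbits = 2L, qshift = 2L, sbits = 1L,
                              sloc = 15L, fixed_length = 100L,
                              qmap = c(2L, 12L, 23L, 37L))
  s0 <- length(fqz_encode(recs, base))
  s1 <- length(fqz_encode(recs, with_sel))
  expect_lt(s1, s0)                       # partitioning helps here
  expect_lte(s1, s0 + ceiling(n / 8) + 8) # and can never cost more than
                                          # the per-record selector bit
  dec <- fqz_decode(fqz_encode(recs, with_sel))
  expect_identical(dec$selector, sel)
})

test_that("malformed fqz streams are rejected", {
  recs <- novaseq_fixture(10L)
  enc <- fqz_encode(recs, build_params(recs, "generic"))
  expect_error(fqz_decode(enc[1:8]), "malformed|truncat")
  expect_error(fqz_decode(enc[1:(length(enc) - 20)]), "truncat|malformed")
  bad <- enc
  bad[1] <- as.raw(99)
  expect_error(fqz_decode(bad), "version")
})

test_that("a degenerate all-zero-width context collapses to one model", {
  recs <- quality_records(list(c(3L, 1L, 0L, 2L, 2L, 3L)))
  par <- make_fqz_params(4L)  # qbits = pbits = dbits = sbits = 0
  dec <- fqz_decode(fqz_encode(recs, par))
  expect_identical(dec$quals, recs$quals)
})
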