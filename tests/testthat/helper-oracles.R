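# Shared fixtures and independent oracles used across the suite.

# random raw vector over an alphabet of `nsym` distinct byte values
rand_bytes <- function(n, nsym = 256L, skew = 1) {
  if (n == 0L) return(raw(0))
  syms <- sample.int(256L, nsym) - 1L
  as.raw(syms[sample.int(nsym, n, replace = TRUE, prob = runif(nsym)^skew)])
}

# first-order Markov byte stream with strong self-transitions
markov_bytes <- function(n, syms = c(0x41, 0x42), self = 0.95) {
  k <- length(syms)
  x <- integer(n)
  x[1] <- 1L
  P <- matrix((1 - self) / (k - 1), k, k)
  diag(P) <- self
  u <- runif(n)
  cum <- t(apply(P, 1, cumsum))
  for (i in 2:n) x[i] <- findInterval(u[i], cum[x[i - 1], ]) + 1L
  as.raw(syms[x])
}

# empirical order-0 Shannon entropy in bits per symbol
shannon_h0 <- function(data) {
  if (length(data) == 0L) return(0)
  p <- table(as.integer(data)) / length(data)
  -sum(p * log2(p))
}

# ideal code length (bits) of the adaptive byte model used by the
# arithmetic codec: counts start at 1, +16 per occurrence, halve flooring
# at 1 when the total reaches 2^13; order 0 or 1
adaptive_cost_bits <- function(data, order = 0L) {
  nrowm <- if (order == 0L) 1L else 256L
  cnt <- matrix(1, nrowm, 256)
  tot <- rep(256, nrowm)
  ctx <- 1L
  bits <- 0
  for (b in as.integer(data) + 1L) {
    row <- if (order == 0L) 1L else ctx
    bits <- bits - log2(cnt[row, b] / tot[row])
    cnt[row, b] <- cnt[row, b] + 16
    tot[row] <- tot[row] + 16
    if (tot[row] >= 8192) {
      v <- cnt[row, ] %/% 2
      v[v == 0] <- 1
      cnt[row, ] <- v
      tot[row] <- sum(v)
    }
    ctx <- b
  }
  bits
}

# Independent pure-R range decoder for order-0 adaptive arithmetic
# payloads: re-derives the model from scratch, mirroring the published
# coder contract rather than sharing any code with the implementation.
r_arith_decode_o0 <- function(payload, len) {
  pos <- 1L
  getb <- function() {
    if (pos > length(payload)) stop("oracle: truncated payload")
    b <- as.integer(payload[pos])
    pos <<- pos + 1L
    b
  }
  range <- 2^32 - 1
  code <- 0
  for (i in 1:4) code <- code * 256 + getb()
  cnt <- rep(1, 256)
  tot <- 256
  out <- integer(len)
  for (i in seq_len(len)) {
    range <- floor(range / tot)
    df <- min(floor(code / range), tot - 1)
    cum <- 0
    s <- 1L
    while (cum + cnt[s] <= df) {
      cum <- cum + cnt[s]
      s <- s + 1L
    }
    code <- code - cum * range
    range <- range * cnt[s]
    while (range < 2^24) {
      code <- (code * 256 + getb()) %% 2^32
      range <- range * 256
    }
    cnt[s] <- cnt[s] + 16
    tot <- tot + 16
    if (tot >= 8192) {
      cnt <- cnt %/% 2
      cnt[cnt == 0] <- 1
      tot <- sum(cnt)
    }
    out[i] <- s - 1L
  }
  as.raw(out)
}

# brute-force optimal run-symbol subset: tries every subset and accounts
# literal bytes + chunked length bytes exactly
brute_force_run_symbols <- function(data) {
  syms <- sort(unique(as.integer(data)))
  r <- rle(as.integer(data))
  cost_for <- function(subset) {
    inset <- r$values %in% subset
    lits <- sum(ifelse(inset, 1L, r$lengths))
    lens <- sum((r$lengths[inset] - 1L) %/% 255L + 1L)
    lits + lens
  }
  best <- NULL
  best_cost <- Inf
  for (mask in 0:(2^length(syms) - 1)) {
    subset <- syms[bitwAnd(mask, 2^(seq_along(syms) - 1L)) != 0L]
    cost <- cost_for(subset)
    if (cost < best_cost) {
      best_cost <- cost
      best <- subset
    }
  }
  list(symbols = as.raw(best), cost = best_cost)
}

# random printable read-name-like strings, including pathological shapes
rand_name <- function() {
  pool <- c(LETTERS, letters, 0:9, ":", ".", "_", "-", "#", "/", " ")
  style <- sample(5L, 1L)
  if (style == 1L) {  # Illumina-ish
    sprintf("M%05d:%d:%09d:%d:%d:%d:%d", sample(1e5, 1), sample(9, 1),
            sample(1e9, 1), sample(8, 1), sample(3000, 1), sample(1e5, 1),
            sample(1e6, 1))
  } else if (style == 2L) {  # all digits, possibly very long
    paste(sample(c(0:9), sample(1:25, 1), replace = TRUE), collapse = "")
  } else if (style == 3L) {  # all punctuation
    paste(sample(c(":", ".", "_", "-", "#", "/"), sample(1:8, 1),
                 replace = TRUE), collapse = "")
  } else if (style == 4L) {  # length-1
    sample(pool, 1L)
  } else {
    paste(sample(pool, sample(1:30, 1), replace = TRUE), collapse = "")
  }
}

novaseq_fixture <- function(n_records = 1000L, seed = 1L) {
  gen_qualities(quality_profile("novaseq", n_records, 100L, seed = seed))
}

# hand-assembled FQZComp parameter sets for targeted model tests
make_fqz_params <- function(max_sym, qbits = 0L, qshift = 1L, qloc = 0L,
                            pbits = 0L, ploc = 0L, dbits = 0L, dloc = 0L,
                            sbits = 0L, sloc = 0L, qtab = 0:255,
                            ptab = integer(1024), dtab = integer(256),
                            fixed_length = -1L, do_dedup = FALSE,
                            do_reverse = FALSE, do_selector = sbits > 0L,
                            qmap = seq_len(max_sym) - 1L) {
  p <- structure(list(max_sym = as.integer(max_sym), qmap = as.integer(qmap),
                      qbits = as.integer(qbits), qshift = as.integer(qshift),
                      qloc = as.integer(qloc), pbits = as.integer(pbits),
                      ploc = as.integer(ploc), dbits = as.integer(dbits),
                      dloc = as.integer(dloc), sbits = as.integer(sbits),
                      sloc = as.integer(sloc), qtab = as.integer(qtab),
                      ptab = as.integer(ptab), dtab = as.integer(dtab),
                      fixed_length = as.integer(fixed_length),
                      do_dedup = do_dedup, do_reverse = do_reverse,
                      do_selector = do_selector, store_qmap = TRUE),
                 class = "fqz_params")
  seqcodec:::validate_fqz_params(p)
}
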