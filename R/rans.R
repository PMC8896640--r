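# Static-frequency rANS entropy coder (Order-0 and Order-1, 4 or 32
# interleaved states, 16-bit renormalization) and the self-describing
# container framing that composes the CAT/PACK/RLE/STRIPE transforms with
# entropy coding.

RANS_O0_BITS <- 12L
RANS_O1_BITS <- 10L

#' Normalize symbol counts to a fixed-precision frequency table
#'
#' Scales counts so they sum to exactly `2^precision_bits` by
#' largest-remainder apportionment, with every observed symbol keeping a
#' frequency of at least 1.  Ties are broken by ascending symbol value, so
#' the result is deterministic.
#'
#' @param counts Numeric vector of non-negative counts; element `i` is the
#'   count of symbol `i - 1`.
#' @param precision_bits Target precision; frequencies sum to
#'   `2^precision_bits`.
#' @return Integer vector of the same length as `counts`.
#' @export
normalize_frequencies <- function(counts, precision_bits) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L || all(counts == 0)) stop("empty input: no counts")
  if (any(counts < 0)) stop("negative counts")
  target <- 2^precision_bits
  nz <- which(counts > 0)
  if (length(nz) > target) stop("more symbols than frequency slots")
  ideal <- counts[nz] * target / sum(counts)
  base <- pmax(floor(ideal), 1)
  rem <- ideal - floor(ideal)
  d <- target - sum(base)
  if (d > 0) {
    ord <- order(-rem, nz)
    base[ord[seq_len(d)]] <- base[ord[seq_len(d)]] + 1
  } else if (d < 0) {
    ord <- order(rem, nz)
    i <- 1L
    while (d < 0) {
      j <- ord[i]
      if (base[j] > 1) {
        base[j] <- base[j] - 1
        d <- d + 1
      }
      i <- if (i == length(ord)) 1L else i + 1L
    }
  }
  out <- integer(length(counts))
  out[nz] <- as.integer(base)
  out
}

## ---- frequency-table serialization ----------------------------------------

# Present-symbol lists are stored as runs of consecutive byte values:
# uint7 run count, then (first value, run length - 1) byte pairs.
serialize_symbol_list <- function(syms) {
  if (length(syms) == 0L) return(write_uint7(0))
  breaks <- c(1L, which(diff(syms) > 1L) + 1L)
  ends <- c(breaks[-1L] - 1L, length(syms))
  out <- list(write_uint7(length(breaks)))
  for (i in seq_along(breaks)) {
    out[[length(out) + 1L]] <-
      as.raw(c(syms[breaks[i]], ends[i] - breaks[i]))
  }
  unlist(out)
}

parse_symbol_list <- function(stream, pos) {
  r <- read_uint7_at(stream, pos)
  pos <- r$pos
  syms <- integer(0)
  for (i in seq_len(r$value)) {
    if (pos + 1L > length(stream)) stop("truncated frequency table")
    start <- as.integer(stream[pos])
    len <- as.integer(stream[pos + 1L]) + 1L
    pos <- pos + 2L
    syms <- c(syms, seq.int(start, length.out = len))
  }
  if (is.unsorted(syms, strictly = TRUE) || any(syms > 255L))
    stop("malformed frequency table: bad symbol list")
  list(syms = syms, pos = pos)
}

serialize_freq_row <- function(freq) {
  syms <- which(freq > 0L) - 1L
  c(serialize_symbol_list(syms),
    unlist(lapply(freq[syms + 1L], write_uint7)))
}

parse_freq_row <- function(stream, pos, precision_bits) {
  sl <- parse_symbol_list(stream, pos)
  pos <- sl$pos
  freq <- integer(256)
  for (s in sl$syms) {
    r <- read_uint7_at(stream, pos)
    pos <- r$pos
    freq[s + 1L] <- r$value
  }
  if (sum(freq) != 2^precision_bits)
    stop("malformed frequency table: cumulative frequency overflow")
  list(freq = freq, pos = pos)
}

## ---- entropy block (table + payload) --------------------------------------

o1_chunk_starts <- function(L, nstates) {
  base <- L %/% nstates
  rem <- L %% nstates
  sizes <- base + as.integer(seq_len(nstates) <= rem)
  as.integer(cumsum(c(0L, sizes[-nstates])))
}

cum_from_freq <- function(freqmat) {
  t(apply(freqmat, 1L, function(f) cumsum(c(0L, f[-256L]))))
}

# Returns list(table = raw, payload = raw); payload = state flush + words.
rans_block_parts <- function(data, order, nstates) {
  L <- length(data)
  if (L == 0L) return(list(table = raw(0), payload = raw(0)))
  di <- as.integer(data)
  if (order == 0L) {
    counts <- tabulate(di + 1L, 256L)
    freq <- normalize_frequencies(counts, RANS_O0_BITS)
    fm <- matrix(freq, nrow = 1L)
    payload <- rans_enc_core(data, nstates, RANS_O0_BITS, fm,
                             matrix(cumsum(c(0L, freq[-256L])), nrow = 1L),
                             integer(0))
    list(table = serialize_freq_row(freq), payload = payload)
  } else {
    starts <- o1_chunk_starts(L, nstates)
    prev <- c(0L, di[-L])
    prev[starts[starts < L] + 1L] <- 0L
    counts <- matrix(tabulate(prev * 256L + di + 1L, 65536L),
                     nrow = 256L, byrow = TRUE)
    ctxs <- which(rowSums(counts) > 0L) - 1L
    fm <- matrix(0L, 256L, 256L)
    for (ctx in ctxs) {
      fm[ctx + 1L, ] <- normalize_frequencies(counts[ctx + 1L, ],
                                              RANS_O1_BITS)
    }
    tab <- c(serialize_symbol_list(ctxs),
             unlist(lapply(ctxs, function(ctx)
               serialize_freq_row(fm[ctx + 1L, ]))))
    # order-1 tables can be large for dense alphabets; store them as a
    # nested order-0 container
    tabc <- encode_container(tab, codec_flags(order = 0L))
    payload <- rans_enc_core(data, nstates, RANS_O1_BITS, fm,
                             cum_from_freq(fm), starts)
    list(table = c(write_uint7(length(tabc)), tabc), payload = payload)
  }
}

rans_block_decode <- function(stream, pos, L, order, nstates) {
  if (L == 0L) return(list(data = raw(0), pos = pos))
  if (pos > length(stream)) stop("truncated container: missing entropy block")
  if (order == 0L) {
    fr <- parse_freq_row(stream, pos, RANS_O0_BITS)
    pos <- fr$pos
    fm <- matrix(fr$freq, nrow = 1L)
    data <- rans_dec_core(stream[pos:length(stream)], L, nstates,
                          RANS_O0_BITS, fm,
                          matrix(cumsum(c(0L, fr$freq[-256L])), nrow = 1L),
                          integer(0))
  } else {
    r <- read_uint7_at(stream, pos)
    pos <- r$pos
    if (pos + r$value - 1L > length(stream))
      stop("truncated container: frequency table")
    tab <- decode_container(stream[seq.int(pos, length.out = r$value)])
    pos <- pos + r$value
    sl <- parse_symbol_list(tab, 1L)
    tpos <- sl$pos
    fm <- matrix(0L, 256L, 256L)
    for (ctx in sl$syms) {
      fr <- parse_freq_row(tab, tpos, RANS_O1_BITS)
      tpos <- fr$pos
      fm[ctx + 1L, ] <- fr$freq
    }
    if (pos > length(stream)) stop("truncated container: missing payload")
    data <- rans_dec_core(stream[pos:length(stream)], L, nstates,
                          RANS_O1_BITS, fm, cum_from_freq(fm),
                          o1_chunk_starts(L, nstates))
  }
  list(data = data, pos = NA_integer_)
}

## ---- container framing -----------------------------------------------------

#' Compress a byte sequence into a self-describing codec container
#'
#' The container starts with the one-byte flag field of [codec_flags()],
#' then (unless `no_size`) the uncompressed length as a varint.  `cat`
#' stores the bytes verbatim.  `stripe` de-interleaves into `stripe_n`
#' sub-streams, each stored as a recursively framed sub-container.
#' Otherwise PACK is applied first (when flagged), then RLE — whose
#' run-length stream is stored as a nested Order-0 container — and the
#' remaining literal stream is rANS coded at the flagged order with 4 or 32
#' interleaved states.
#'
#' @param data Raw vector (or single string) to compress.
#' @param flags A [codec_flags()] object.
#' @param stripe_n Number of STRIPE sub-streams when `flags$stripe` is set.
#' @return Raw vector: the compressed container.
#' @export
encode_container <- function(data, flags, stripe_n = 4L) {
  data <- as_raw_input(data)
  stopifnot(inherits(flags, "codec_flags"))
  L <- length(data)
  head <- flags_byte(flags)
  if (!flags$no_size) head <- c(head, write_uint7(L))
  if (L == 0L) return(head)

  if (flags$cat) return(c(head, data))

  if (flags$stripe) {
    n <- as.integer(stripe_n)
    if (is.na(n) || n < 1L) stop("stripe requires n >= 1")
    sub_flags <- flags
    sub_flags$stripe <- FALSE
    sub_flags$no_size <- TRUE
    subs <- lapply(stripe(data, n), encode_container, flags = sub_flags)
    return(c(head, write_uint7(n),
             unlist(lapply(lengths(subs), write_uint7)),
             unlist(subs)))
  }

  cur <- data
  meta <- raw(0)
  if (flags$pack) {
    pk <- pack(cur)  # not-packable error propagates to the caller
    meta <- c(meta, as.raw(pk$meta$n_symbols), pk$meta$symbol_table)
    cur <- pk$packed
  }
  if (flags$rle) {
    rs <- select_run_symbols(cur)
    rm <- rle_encode(cur, rs)
    nested <- encode_container(chunk_run_lengths(rm$lengths),
                               codec_flags(order = 0L))
    meta <- c(meta, write_uint7(length(rs)), rs,
              write_uint7(length(rm$literals)),
              write_uint7(length(nested)), nested)
    cur <- rm$literals
  }
  blk <- rans_block_parts(cur, flags$order, if (flags$x32) 32L else 4L)
  c(head, meta, blk$table, blk$payload)
}

#' Decode a codec container
#'
#' Exact inverse of [encode_container()] for every legal flag combination.
#' Containers written with `no_size` need the caller to supply the
#' uncompressed length.
#'
#' @param stream Raw vector holding one container.
#' @param expected_length Uncompressed length, required only when the
#'   container was written with the `no_size` flag.
#' @return The original raw vector.
#' @export
decode_container <- function(stream, expected_length = NULL) {
  stream <- as.raw(stream)
  if (length(stream) < 1L) stop("truncated container: empty stream")
  flags <- parse_flags(stream[1L])
  pos <- 2L
  if (flags$no_size) {
    if (is.null(expected_length))
      stop("container has no stored size; supply expected_length")
    L <- as.integer(expected_length)
  } else {
    r <- read_uint7_at(stream, pos)
    L <- r$value
    pos <- r$pos
  }
  if (L == 0L) return(raw(0))

  if (flags$cat) {
    if (pos + L - 1L > length(stream)) stop("truncated container: cat data")
    return(stream[pos:(pos + L - 1L)])
  }

  if (flags$stripe) {
    r <- read_uint7_at(stream, pos)
    n <- r$value
    pos <- r$pos
    if (n < 1L) stop("malformed container: stripe with zero streams")
    sub_len <- numeric(n)
    for (j in seq_len(n)) {
      r <- read_uint7_at(stream, pos)
      sub_len[j] <- r$value
      pos <- r$pos
    }
    subs <- vector("list", n)
    for (j in seq_len(n)) {
      if (pos + sub_len[j] - 1L > length(stream))
        stop("truncated container: stripe sub-stream")
      sub <- stream[seq.int(pos, length.out = sub_len[j])]
      pos <- pos + sub_len[j]
      subs[[j]] <- decode_container(sub,
                                    expected_length = ceiling((L - (j - 1L)) / n))
    }
    return(unstripe(subs))
  }

  pack_meta <- NULL
  if (flags$pack) {
    if (pos > length(stream)) stop("truncated container: pack table")
    nsym <- as.integer(stream[pos])
    pos <- pos + 1L
    if (nsym < 1L || nsym > 16L) stop("malformed container: pack table size")
    if (pos + nsym - 1L > length(stream)) stop("truncated container: pack table")
    tab <- stream[seq.int(pos, length.out = nsym)]
    pos <- pos + nsym
    pack_meta <- structure(list(n_symbols = nsym, symbol_table = tab,
                                width_bits = pack_width(nsym),
                                original_length = L),
                           class = "pack_meta")
    target_len <- ceiling(L * pack_meta$width_bits / 8)
  } else {
    target_len <- L
  }

  rle_info <- NULL
  if (flags$rle) {
    r <- read_uint7_at(stream, pos)
    nrs <- r$value
    pos <- r$pos
    rs <- if (nrs > 0L) stream[seq.int(pos, length.out = nrs)] else raw(0)
    pos <- pos + nrs
    r <- read_uint7_at(stream, pos)
    lit_len <- r$value
    pos <- r$pos
    r <- read_uint7_at(stream, pos)
    nested_len <- r$value
    pos <- r$pos
    if (pos + nested_len - 1L > length(stream))
      stop("truncated container: rle length stream")
    nested <- if (nested_len > 0L)
      stream[seq.int(pos, length.out = nested_len)] else raw(0)
    pos <- pos + nested_len
    lengths <- unchunk_run_lengths(decode_container(nested))
    rle_info <- list(run_symbols = rs, lengths = lengths)
    entropy_len <- lit_len
  } else {
    entropy_len <- target_len
  }

  blk <- rans_block_decode(stream, pos, entropy_len, flags$order,
                           if (flags$x32) 32L else 4L)
  cur <- blk$data
  if (flags$rle) {
    cur <- rle_decode(structure(list(literals = cur,
                                     lengths = rle_info$lengths,
                                     run_symbols = rle_info$run_symbols),
                                class = "rle_meta"))
  }
  if (flags$pack) {
    if (length(cur) != ceiling(L * pack_meta$width_bits / 8))
      stop("malformed container: pack payload length mismatch")
    cur <- unpack(cur, pack_meta)
  }
  if (length(cur) != L) stop("malformed container: length mismatch")
  cur
}

#' Compress bytes with the rANS entropy coder
#'
#' Convenience wrapper producing a transform-free self-describing container:
#' a static frequency table (12-bit precision for Order-0, 10-bit rows for
#' Order-1) followed by the interleaved rANS payload.  rANS is
#' last-in-first-out, so input bytes are processed in reverse and the final
#' states are flushed as `n_states` little-endian 32-bit words.
#'
#' @param data Raw vector (or single string).
#' @param order Frequency model order, 0 or 1.
#' @param n_states Number of interleaved coder states, 4 or 32 (32 pays off
#'   only on large blocks because all states are flushed to the stream).
#' @return Raw vector holding the compressed stream.
#' @export
rans_encode <- function(data, order = 0L, n_states = 4L) {
  if (!n_states %in% c(4L, 32L)) stop("n_states must be 4 or 32")
  data <- as_raw_input(data)
  if (order == 1L && length(data) == 0L)
    stop("order-1 rans requires non-empty input")
  encode_container(data, codec_flags(order = order, x32 = n_states == 32L))
}

#' Decompress a rANS stream
#'
#' @param stream Raw vector produced by [rans_encode()] (or any
#'   [encode_container()] output).
#' @return The original raw vector.
#' @export
rans_decode <- function(stream) decode_container(stream)
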