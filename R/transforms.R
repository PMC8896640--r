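# Reversible pre-entropy data transforms: PACK (bit packing of small
# alphabets), RLE (Mespotine-style run-length encoding with a declared
# run-symbol set) and STRIPE (byte de-interleaving).

pack_width <- function(n_symbols) {
  if (n_symbols <= 1L) 0L
  else if (n_symbols == 2L) 1L
  else if (n_symbols <= 4L) 2L
  else if (n_symbols <= 16L) 4L
  else stop("not packable: more than 16 distinct symbols")
}

#' Bit-pack a byte sequence over a small alphabet
#'
#' Counts the distinct symbols in the input: one symbol needs 0 bits, two
#' need 1 bit (8 values per byte), up to four need 2 bits (4 per byte) and
#' up to sixteen need 4 bits (2 per byte).  Each input byte is replaced by
#' its index in the symbol table and indices are packed least-significant
#' bits first within each payload byte.
#'
#' @param data A non-empty raw vector (or single string) with at most 16
#'   distinct byte values.
#' @return A list with `packed` (raw payload of length
#'   `ceiling(length(data) * width_bits / 8)`) and `meta`, a `pack_meta`
#'   list holding `n_symbols`, `symbol_table`, `width_bits` and
#'   `original_length`.
#' @export
pack <- function(data) {
  data <- as_raw_input(data)
  if (length(data) == 0L) stop("pack requires non-empty input")
  tab <- sort(unique(as.integer(data)))
  n <- length(tab)
  width <- pack_width(n)  # errors for > 16 symbols
  idx <- match(as.integer(data), tab) - 1L
  packed <- pack_bits(idx, width)
  meta <- structure(list(n_symbols = n, symbol_table = as.raw(tab),
                         width_bits = width,
                         original_length = length(data)),
                    class = "pack_meta")
  list(packed = packed, meta = meta)
}

pack_bits <- function(idx, width) {
  if (width == 0L) return(raw(0))
  per <- 8L %/% width
  n <- length(idx)
  pad <- (per - n %% per) %% per
  m <- matrix(c(idx, integer(pad)), nrow = per)
  as.raw(colSums(m * 2^(width * (seq_len(per) - 1L))))
}

#' Invert the PACK transform
#'
#' @param packed Raw payload produced by [pack()].
#' @param meta The `pack_meta` metadata from [pack()].
#' @return The original raw vector.
#' @export
unpack <- function(packed, meta) {
  width <- meta$width_bits
  L <- meta$original_length
  if (width == 0L) {
    if (length(packed) != 0L) stop("malformed pack payload: expected empty")
    return(rep(meta$symbol_table[1L], L))
  }
  per <- 8L %/% width
  expect <- ceiling(L * width / 8)
  if (length(packed) != expect)
    stop("malformed pack payload: length mismatch")
  b <- rep(as.integer(packed), each = per)
  sh <- rep.int(width * (seq_len(per) - 1L), length(packed))
  idx <- bitwAnd(bitwShiftR(b, sh), 2L^width - 1L)[seq_len(L)]
  if (any(idx >= meta$n_symbols)) stop("malformed pack payload: bad index")
  meta$symbol_table[idx + 1L]
}

# serialized size in the length stream of one additional-run-length entry
# (chunks of 255-with-continuation)
run_length_bytes <- function(extra) extra %/% 255L + 1L

#' Choose the symbols whose runs the RLE transform should encode
#'
#' A symbol enters the run-symbol set exactly when always attaching a run
#' length to it shrinks the encoded size: the literal bytes saved by
#' collapsing its runs must exceed the bytes spent on its run-length
#' entries.  Because the accounting is independent per symbol this equals
#' the optimum over all symbol subsets.
#'
#' @param data A raw vector (or single string).
#' @return A raw vector of symbols, sorted ascending (possibly empty).
#' @export
select_run_symbols <- function(data) {
  data <- as_raw_input(data)
  if (length(data) == 0L) return(raw(0))
  r <- rle(as.integer(data))
  keep <- integer(0)
  for (s in sort(unique(r$values))) {
    lens <- r$lengths[r$values == s]
    cost_in <- length(lens) + sum(run_length_bytes(lens - 1L))
    cost_out <- sum(lens)
    if (cost_in < cost_out) keep <- c(keep, s)
  }
  as.raw(keep)
}

#' Run-length encode a byte sequence against a declared run-symbol set
#'
#' Scanning left to right, each maximal run of a symbol in `run_symbols`
#' emits one literal plus one length entry holding the additional run
#' length beyond the first occurrence (zero for an isolated occurrence);
#' runs of other symbols are emitted literally with no length entry.
#' Literals and lengths form two separate streams.
#'
#' @param data A raw vector (or single string).
#' @param run_symbols Raw vector of symbols that always carry a run length.
#' @return An `rle_meta` list with `literals` (raw), `lengths` (integer
#'   vector of additional run lengths) and `run_symbols`.
#' @export
rle_encode <- function(data, run_symbols) {
  data <- as_raw_input(data)
  run_symbols <- as.raw(run_symbols)
  if (length(data) == 0L)
    return(structure(list(literals = raw(0), lengths = integer(0),
                          run_symbols = run_symbols), class = "rle_meta"))
  r <- rle(as.integer(data))
  inset <- r$values %in% as.integer(run_symbols)
  counts <- ifelse(inset, 1L, r$lengths)
  structure(list(literals = as.raw(rep.int(r$values, counts)),
                 lengths = r$lengths[inset] - 1L,
                 run_symbols = run_symbols),
            class = "rle_meta")
}

#' Invert the RLE transform
#'
#' @param meta An `rle_meta` list as produced by [rle_encode()].
#' @return The original raw vector.
#' @export
rle_decode <- function(meta) {
  lits <- as.raw(meta$literals)
  if (length(lits) == 0L) {
    if (length(meta$lengths) != 0L) stop("malformed rle: dangling lengths")
    return(raw(0))
  }
  inset <- as.integer(lits) %in% as.integer(meta$run_symbols)
  if (sum(inset) != length(meta$lengths))
    stop("malformed rle: length stream does not match literal stream")
  reps <- rep.int(1L, length(lits))
  reps[inset] <- as.integer(meta$lengths) + 1L
  if (any(reps < 1L)) stop("malformed rle: negative run length")
  rep.int(lits, reps)
}

#' De-interleave a byte stream into N sub-streams
#'
#' Stream `c` (for `0 <= c < n`) receives the bytes at positions
#' `c, c + n, c + 2n, ...`, so fixed-width multi-byte records are split
#' into per-byte-lane streams.
#'
#' @param data A raw vector (or single string).
#' @param n Number of streams, at least 1.
#' @return A list of `n` raw vectors; stream `c` has length
#'   `ceiling((length(data) - c) / n)`.
#' @export
stripe <- function(data, n) {
  data <- as_raw_input(data)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("stripe requires n >= 1")
  lapply(seq_len(n), function(c1) {
    if (c1 > length(data)) raw(0) else data[seq.int(c1, length(data), by = n)]
  })
}

#' Re-interleave STRIPE sub-streams
#'
#' @param streams A list of raw vectors as produced by [stripe()].
#' @return The original raw vector.
#' @export
unstripe <- function(streams) {
  n <- length(streams)
  if (n < 1L) stop("unstripe requires at least one stream")
  streams <- lapply(streams, as.raw)
  L <- sum(lengths(streams))
  expect <- ceiling((L - (seq_len(n) - 1L)) / n)
  if (!all(lengths(streams) == expect))
    stop("malformed stripe streams: inconsistent lengths")
  out <- raw(L)
  for (c1 in seq_len(n)) {
    if (length(streams[[c1]]))
      out[seq.int(c1, L, by = n)] <- streams[[c1]]
  }
  out
}

# Serialize additional-run-length entries as byte chunks where 255 means
# "add 255 and continue"; unbounded run lengths therefore round-trip.
chunk_run_lengths <- function(lengths) {
  if (length(lengths) == 0L) return(raw(0))
  out <- lapply(as.integer(lengths), function(x) {
    chunks <- rep.int(255L, x %/% 255L)
    c(chunks, x %% 255L)
  })
  as.raw(unlist(out))
}

unchunk_run_lengths <- function(bytes) {
  b <- as.integer(bytes)
  if (length(b) == 0L) return(integer(0))
  if (b[length(b)] == 255L) stop("malformed rle length stream: dangling chunk")
  # entries end at every byte < 255
  ends <- which(b < 255L)
  starts <- c(1L, ends[-length(ends)] + 1L)
  vapply(seq_along(ends), function(i) sum(b[starts[i]:ends[i]]), numeric(1))
}
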