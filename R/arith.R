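# Adaptive byte-wise arithmetic (range) codec with Order-0/Order-1 models,
# optional PACK, and an RLE variant that codes per-symbol run lengths with
# their own adaptive models.

#' Compress bytes with the adaptive arithmetic codec
#'
#' A byte-wise range coder with adaptively updated frequencies: every
#' symbol starts with count 1, each coded occurrence adds 16, and all
#' counts are halved (flooring at 1) when the total reaches 2^13, keeping
#' the model responsive to non-stationary data.  Order 1 conditions each
#' byte's model on the preceding byte.  With `rle = TRUE`, only the first
#' byte of each maximal run is coded with the literal models; the
#' additional run length follows, coded with adaptive models indexed by the
#' run symbol in chunks of 0..255 where a chunk of 255 signals
#' continuation.  `pack = TRUE` bit-packs inputs with at most 16 distinct
#' symbols first.
#'
#' @param data Raw vector (or single string).
#' @param order Model order, 0 or 1.
#' @param rle Use the per-symbol run-length variant.
#' @param pack Apply the PACK transform before coding.
#' @return Raw vector: a self-describing container (flag byte, varint
#'   length, optional pack table, coded payload).
#' @export
arith_encode <- function(data, order = 0L, rle = FALSE, pack = FALSE) {
  data <- as_raw_input(data)
  flags <- codec_flags(order = order, rle = rle, pack = pack)
  L <- length(data)
  out <- c(flags_byte(flags), write_uint7(L))
  if (L == 0L) return(out)
  cur <- data
  if (pack) {
    pk <- pack(cur)
    out <- c(out, as.raw(pk$meta$n_symbols), pk$meta$symbol_table)
    cur <- pk$packed
  }
  c(out, arith_enc_core(cur, as.integer(order), isTRUE(rle)))
}

#' Decompress an adaptive arithmetic stream
#'
#' The decoder's models are updated exactly as the encoder's were, so the
#' two evolve in lockstep.
#'
#' @param stream Raw vector produced by [arith_encode()].
#' @return The original raw vector.
#' @export
arith_decode <- function(stream) {
  stream <- as.raw(stream)
  if (length(stream) < 1L) stop("truncated stream: empty")
  flags <- parse_flags(stream[1L])
  r <- read_uint7_at(stream, 2L)
  L <- r$value
  pos <- r$pos
  if (L == 0L) return(raw(0))
  pack_meta <- NULL
  target_len <- L
  if (flags$pack) {
    nsym <- as.integer(stream[pos])
    pos <- pos + 1L
    if (nsym < 1L || nsym > 16L) stop("malformed stream: pack table size")
    if (pos + nsym - 1L > length(stream)) stop("truncated stream: pack table")
    tab <- stream[seq.int(pos, length.out = nsym)]
    pos <- pos + nsym
    pack_meta <- structure(list(n_symbols = nsym, symbol_table = tab,
                                width_bits = pack_width(nsym),
                                original_length = L),
                           class = "pack_meta")
    target_len <- ceiling(L * pack_meta$width_bits / 8)
  }
  payload <- if (pos <= length(stream)) stream[pos:length(stream)] else raw(0)
  if (length(payload) == 0L && target_len > 0L)
    stop("truncated stream: missing payload")
  cur <- arith_dec_core(payload, as.integer(target_len),
                        as.integer(flags$order), flags$rle)
  if (flags$pack) cur <- unpack(cur, pack_meta) else cur
}
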