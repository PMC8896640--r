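# Byte-stream primitives shared by all codecs: variable-length integers and
# the one-byte container flag field.  All byte sequences are raw vectors.

#' Encode a non-negative integer as a variable-length 7-bit integer
#'
#' Values are stored most-significant 7-bit group first, with the
#' continuation bit (0x80) set on every byte except the last.  The encoding
#' is minimal (no redundant leading zero groups) and therefore between 1 and
#' 5 bytes long for values below 2^32; it sorts lexicographically.
#'
#' @param value A single non-negative number below 2^32.
#' @return A raw vector of 1 to 5 bytes.
#' @seealso [read_uint7()]
#' @examples
#' write_uint7(300)   # 0x82 0x2c
#' @export
write_uint7 <- function(value) {
  if (length(value) != 1L || is.na(value) || value < 0 || value >= 2^32 ||
      value != floor(value))
    stop("uint7 value out of range [0, 2^32)")
  value <- as.numeric(value)
  groups <- integer(0)
  repeat {
    groups <- c(value %% 128, groups)
    value <- value %/% 128
    if (value == 0) break
  }
  n <- length(groups)
  if (n > 1L) groups[-n] <- groups[-n] + 128
  as.raw(groups)
}

#' Decode a variable-length 7-bit integer from the head of a byte stream
#'
#' @param stream A raw vector beginning with a [write_uint7()] encoding.
#' @return A list with elements `value` (the decoded number) and `nbytes`
#'   (bytes consumed).
#' @export
read_uint7 <- function(stream) {
  r <- read_uint7_at(stream, 1L)
  list(value = r$value, nbytes = r$pos - 1L)
}

# cursor-based reader used by all container parsers
read_uint7_at <- function(stream, pos) {
  value <- 0
  n <- 0L
  repeat {
    if (pos > length(stream)) stop("truncated uint7: continuation byte missing")
    b <- as.integer(stream[pos])
    pos <- pos + 1L
    n <- n + 1L
    if (n > 5L) stop("malformed uint7: more than 5 bytes")
    value <- value * 128 + (b %% 128)
    if (b < 128L) break
  }
  if (value >= 2^32) stop("malformed uint7: value out of range")
  list(value = value, pos = pos)
}

#' Construct the one-byte flag set describing a codec container
#'
#' Every compressed block starts with a single self-describing flag byte:
#' bit 0 holds the entropy-model order, bit 2 selects 32-way state
#' interleaving, bit 3 the STRIPE transform, bit 4 suppresses the stored
#' uncompressed length, bit 5 marks verbatim (uncompressed) storage, bit 6
#' the RLE transform and bit 7 the PACK transform.  Bit 1 is reserved and
#' always zero.
#'
#' @param order Entropy model order, 0 or 1.
#' @param x32 Use 32 interleaved rANS states instead of 4.
#' @param stripe Apply the STRIPE byte de-interleaving transform.
#' @param no_size Do not store the uncompressed length (the caller must then
#'   supply it at decode time).
#' @param cat Store the data verbatim with no transforms or entropy coding.
#' @param rle Apply the run-length transform before entropy coding.
#' @param pack Apply the bit-packing transform before entropy coding.
#' @return An object of class `codec_flags`.
#' @export
codec_flags <- function(order = 0L, x32 = FALSE, stripe = FALSE,
                        no_size = FALSE, cat = FALSE, rle = FALSE,
                        pack = FALSE) {
  if (!order %in% c(0L, 1L)) stop("order must be 0 or 1")
  if (cat && (order != 0L || rle || pack))
    stop("cat excludes order-1, rle and pack")
  structure(list(order = as.integer(order), x32 = isTRUE(x32),
                 stripe = isTRUE(stripe), no_size = isTRUE(no_size),
                 cat = isTRUE(cat), rle = isTRUE(rle), pack = isTRUE(pack)),
            class = "codec_flags")
}

flags_byte <- function(flags) {
  as.raw(flags$order +
         4L  * flags$x32 +
         8L  * flags$stripe +
         16L * flags$no_size +
         32L * flags$cat +
         64L * flags$rle +
         128L * flags$pack)
}

parse_flags <- function(byte) {
  b <- as.integer(byte)
  if (bitwAnd(b, 2L) != 0L)
    stop("unsupported container format: reserved flag bit set")
  codec_flags(order  = bitwAnd(b, 1L),
              x32    = bitwAnd(b, 4L)   != 0L,
              stripe = bitwAnd(b, 8L)   != 0L,
              no_size = bitwAnd(b, 16L) != 0L,
              cat    = bitwAnd(b, 32L)  != 0L,
              rle    = bitwAnd(b, 64L)  != 0L,
              pack   = bitwAnd(b, 128L) != 0L)
}

#' @export
format.codec_flags <- function(x, ...) {
  on <- c(if (x$x32) "x32", if (x$stripe) "stripe", if (x$no_size) "no_size",
          if (x$cat) "cat", if (x$rle) "rle", if (x$pack) "pack")
  paste0("<codec_flags order=", x$order,
         if (length(on)) paste0(" ", paste(on, collapse = "+")), ">")
}

#' @export
print.codec_flags <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

as_raw_input <- function(data) {
  if (is.character(data) && length(data) == 1L) charToRaw(data) else as.raw(data)
}
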