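# FQZComp-family quality-score codec: adaptive arithmetic coding of Phred
# values under a configurable <=16-bit context built from recent qualities,
# read position, a cumulative-difference counter and selector bits.

#' Bundle quality strings and per-record metadata
#'
#' @param quals A list of integer vectors of Phred values (0..93), one per
#'   read.
#' @param reverse Logical vector: code this record's qualities
#'   right-to-left (e.g. reverse-complemented alignments).
#' @param duplicate Logical vector: record's qualities equal the previous
#'   record's (informational; the encoder recomputes it).
#' @param selector Integer vector of encoder-chosen group labels copied
#'   verbatim into the coding context (e.g. read-1 vs read-2).
#' @return An object of class `quality_records`.
#' @export
quality_records <- function(quals, reverse = FALSE, duplicate = FALSE,
                            selector = 0L) {
  quals <- lapply(quals, as.integer)
  n <- length(quals)
  rec <- structure(list(quals = quals,
                        reverse = rep_len(as.logical(reverse), n),
                        duplicate = rep_len(as.logical(duplicate), n),
                        selector = rep_len(as.integer(selector), n)),
                   class = "quality_records")
  bad <- vapply(quals, function(q) any(is.na(q)) || any(q < 0L | q > 93L),
                logical(1))
  if (any(bad)) stop("quality values must be integers in 0..93")
  rec
}

#' @export
length.quality_records <- function(x) length(x$quals)

#' @export
print.quality_records <- function(x, ...) {
  cat("<quality_records:", length(x), "records,",
      sum(lengths(x$quals)), "values>\n")
  invisible(x)
}

#' Assemble the FQZComp coding context for one position
#'
#' The 16-bit context is the OR of four disjoint bit-fields: the quality
#' history accumulator masked to `qbits` at `qloc`; the position lookup
#' `ptab[min(pos, 1023)]` at `ploc`; the cumulative-difference lookup
#' `dtab[min(delta, 255)]` at `dloc`; and the selector at `sloc`.  After a
#' symbol `q` is coded the history becomes
#' `(qctx << qshift) + qtab[q]`.
#'
#' @param state List with `qctx` (history accumulator), `pos` (0-based
#'   position along the read) and `delta` (count of earlier positions whose
#'   quality differed from its predecessor).
#' @param selector Integer selector value for the current record.
#' @param params An `fqz_params` object (see [build_params()]).
#' @return Integer context in 0..65535.
#' @export
compute_context <- function(state, selector, params) {
  ctx <- 0
  if (params$qbits > 0L)
    ctx <- ctx + (state$qctx %% 2^params$qbits) * 2^params$qloc
  if (params$pbits > 0L)
    ctx <- ctx + params$ptab[min(state$pos, 1023L) + 1L] * 2^params$ploc
  if (params$dbits > 0L)
    ctx <- ctx + params$dtab[min(state$delta, 255L) + 1L] * 2^params$dloc
  if (params$sbits > 0L)
    ctx <- ctx + selector * 2^params$sloc
  as.integer(ctx %% 65536)
}

log2_bucket <- function(i, max_bucket) pmin(floor(log2(i + 1)), max_bucket)

#' Build an FQZComp parameter set from sample records
#'
#' Presets:
#' \describe{
#'   \item{generic}{Two previous qualities (12 history bits), a 2-bit
#'     log-bucketed position field and a 2-bit delta field.}
#'   \item{small_alphabet}{For quantized qualities (e.g. the 4 NovaSeq
#'     values): the quality map shrinks each symbol to `ceil(log2(n))`
#'     bits so four previous qualities fit in 8 history bits, leaving 6
#'     bits of position; widens automatically on larger alphabets.}
#'   \item{position_heavy}{An 8-bit exact position field for data with
#'     strongly cycle-dependent error rates, with 6 history bits.}
#'   \item{selector_read12}{One selector bit at the top of the context to
#'     split records into two groups (e.g. read 1 vs read 2).}
#' }
#' All presets map observed quality values through a stored quality map,
#' so `max_sym` equals the number of distinct values (at most 94, covering
#' Phred 0..93).
#'
#' @param records A `quality_records` sample.
#' @param preset Model preset name.
#' @return An object of class `fqz_params`.
#' @export
build_params <- function(records,
                         preset = c("generic", "small_alphabet",
                                    "position_heavy", "selector_read12")) {
  preset <- match.arg(preset)
  stopifnot(inherits(records, "quality_records"))
  if (length(records) == 0L) stop("empty sample: no records")
  vals <- sort(unique(unlist(records$quals)))
  if (length(vals) == 0L) stop("empty sample: no quality values")
  if (length(vals) > 94L || any(vals > 93L))
    stop("unsupported alphabet: more than 94 distinct quality values")
  max_sym <- length(vals)
  b1 <- max(1L, as.integer(ceiling(log2(max_sym))))

  p <- list(max_sym = max_sym, qmap = vals, preset = preset,
            qshift = b1, qloc = 0L, sbits = 0L, sloc = 0L)
  if (preset == "generic") {
    p$qbits <- min(2L * b1, 12L)
    p$pbits <- 2L
    p$dbits <- 2L
  } else if (preset == "small_alphabet") {
    p$qbits <- min(4L * b1, 12L)
    p$pbits <- min(6L, 14L - p$qbits)
    p$dbits <- 2L
  } else if (preset == "position_heavy") {
    p$qbits <- min(b1, 6L)
    p$pbits <- 8L
    p$dbits <- 2L
  } else {  # selector_read12
    p$qbits <- min(2L * b1, 10L)
    p$pbits <- 3L
    p$dbits <- 2L
    p$sbits <- 1L
    p$sloc <- 15L
  }
  p$ploc <- p$qbits
  p$dloc <- p$qbits + p$pbits

  p$qtab <- seq_len(256L) - 1L  # identity on mapped symbols
  # wide position fields track the cycle exactly (saturating); narrow ones
  # use log-spaced buckets
  p$ptab <- if (p$pbits >= 6L) {
    pmin(0:1023, 2L^p$pbits - 1L)
  } else {
    log2_bucket(0:1023, 2L^p$pbits - 1L)
  }
  p$dtab <- log2_bucket(0:255, 2L^p$dbits - 1L)

  lens <- lengths(records$quals)
  p$fixed_length <- if (length(unique(lens)) == 1L) lens[1L] else -1L
  p$do_dedup <- TRUE
  p$do_reverse <- any(records$reverse)
  p$do_selector <- p$sbits > 0L
  p$store_qmap <- TRUE
  class(p) <- "fqz_params"
  validate_fqz_params(p)
  p
}

validate_fqz_params <- function(p) {
  widths <- c(p$qbits, p$pbits, p$dbits, p$sbits)
  locs <- c(p$qloc, p$ploc, p$dloc, p$sloc)
  if (sum(widths) > 16L)
    stop("invalid fqz params: more than 16 context bits")
  used <- integer(0)
  for (i in seq_along(widths)) {
    if (widths[i] > 0L) {
      bits <- locs[i] + seq_len(widths[i]) - 1L
      if (any(bits > 15L)) stop("invalid fqz params: field beyond bit 15")
      if (any(bits %in% used)) stop("invalid fqz params: overlapping fields")
      used <- c(used, bits)
    }
  }
  if (any(p$ptab >= 2^max(p$pbits, 1L)) || any(p$dtab >= 2^max(p$dbits, 1L)))
    stop("invalid fqz params: lookup output exceeds field width")
  invisible(p)
}

## ---- parameter-block serialization ----------------------------------------

# Lookup tables are stored as first-difference run pairs
# (zigzag(delta) varint, run length - 1 varint), which collapses identity
# and constant tables to a few bytes.
serialize_table <- function(tab) {
  d <- diff(c(0L, as.integer(tab)))
  zz <- ifelse(d >= 0L, 2L * d, -2L * d - 1L)
  r <- rle(zz)
  out <- list(write_uint7(length(r$values)))
  for (i in seq_along(r$values)) {
    out[[length(out) + 1L]] <- c(write_uint7(r$values[i]),
                                 write_uint7(r$lengths[i] - 1L))
  }
  unlist(out)
}

parse_table <- function(stream, pos, n) {
  r <- read_uint7_at(stream, pos)
  pos <- r$pos
  zz <- integer(0)
  for (i in seq_len(r$value)) {
    v <- read_uint7_at(stream, pos)
    l <- read_uint7_at(stream, v$pos)
    pos <- l$pos
    zz <- c(zz, rep.int(v$value, l$value + 1L))
  }
  if (length(zz) != n) stop("malformed fqz parameter table")
  d <- ifelse(zz %% 2 == 0, zz %/% 2, -(zz + 1) %/% 2)
  list(tab = as.integer(cumsum(d)), pos = pos)
}

serialize_fqz_params <- function(p, n_records) {
  flag <- (p$fixed_length >= 0L) + 2L * p$do_dedup + 4L * p$do_reverse +
    8L * p$do_selector + 16L * isTRUE(p$store_qmap)
  out <- c(as.raw(1L),  # format version
           as.raw(flag),
           as.raw(c(p$max_sym, p$qbits, p$qshift, p$qloc, p$pbits, p$ploc,
                    p$dbits, p$dloc, p$sbits, p$sloc)))
  if (p$fixed_length >= 0L) out <- c(out, write_uint7(p$fixed_length))
  if (isTRUE(p$store_qmap)) out <- c(out, as.raw(p$qmap))
  if (p$qbits > 0L) out <- c(out, serialize_table(p$qtab))
  if (p$pbits > 0L) out <- c(out, serialize_table(p$ptab))
  if (p$dbits > 0L) out <- c(out, serialize_table(p$dtab))
  c(out, write_uint7(n_records))
}

parse_fqz_params <- function(stream) {
  if (length(stream) < 12L) stop("malformed fqz stream: short parameter block")
  if (as.integer(stream[1L]) != 1L)
    stop("malformed fqz stream: unknown version")
  flag <- as.integer(stream[2L])
  hdr <- as.integer(stream[3:12])
  p <- list(max_sym = hdr[1L], qbits = hdr[2L], qshift = hdr[3L],
            qloc = hdr[4L], pbits = hdr[5L], ploc = hdr[6L],
            dbits = hdr[7L], dloc = hdr[8L], sbits = hdr[9L],
            sloc = hdr[10L])
  p$do_dedup <- bitwAnd(flag, 2L) != 0L
  p$do_reverse <- bitwAnd(flag, 4L) != 0L
  p$do_selector <- bitwAnd(flag, 8L) != 0L
  p$store_qmap <- bitwAnd(flag, 16L) != 0L
  pos <- 13L
  if (bitwAnd(flag, 1L) != 0L) {
    r <- read_uint7_at(stream, pos)
    p$fixed_length <- r$value
    pos <- r$pos
  } else {
    p$fixed_length <- -1L
  }
  if (p$store_qmap) {
    if (pos + p$max_sym - 1L > length(stream))
      stop("malformed fqz stream: truncated quality map")
    p$qmap <- as.integer(stream[seq.int(pos, length.out = p$max_sym)])
    pos <- pos + p$max_sym
  } else {
    p$qmap <- seq_len(p$max_sym) - 1L
  }
  p$qtab <- seq_len(256L) - 1L
  p$ptab <- integer(1024L)
  p$dtab <- integer(256L)
  if (p$qbits > 0L) {
    r <- parse_table(stream, pos, 256L); p$qtab <- r$tab; pos <- r$pos
  }
  if (p$pbits > 0L) {
    r <- parse_table(stream, pos, 1024L); p$ptab <- r$tab; pos <- r$pos
  }
  if (p$dbits > 0L) {
    r <- parse_table(stream, pos, 256L); p$dtab <- r$tab; pos <- r$pos
  }
  r <- read_uint7_at(stream, pos)
  class(p) <- "fqz_params"
  list(params = p, n_records = r$value, pos = r$pos)
}

core_params <- function(p) {
  list(max_sym = p$max_sym, qbits = p$qbits, qshift = p$qshift,
       qloc = p$qloc, pbits = p$pbits, ploc = p$ploc, dbits = p$dbits,
       dloc = p$dloc, sbits = p$sbits, sloc = p$sloc,
       fixed_length = p$fixed_length, do_dedup = p$do_dedup,
       do_reverse = p$do_reverse, do_selector = p$do_selector,
       qtab = as.integer(p$qtab), ptab = as.integer(p$ptab),
       dtab = as.integer(p$dtab))
}

#' Compress quality records with the FQZComp context-model codec
#'
#' The stream is self-describing: it begins with the serialized parameter
#' block (field widths, shifts and lookup tables), so the decoder follows
#' the model description written by the encoder.  Per-record metadata
#' (length unless fixed, reverse flag, duplicate flag, selector) is coded
#' in the same adaptive arithmetic stream; duplicate records contribute
#' only their flag, and reversed records are coded right-to-left.
#'
#' @param records A [quality_records()] object.
#' @param params An `fqz_params` object from [build_params()].
#' @return Raw vector holding the compressed stream.
#' @export
fqz_encode <- function(records, params) {
  stopifnot(inherits(records, "quality_records"),
            inherits(params, "fqz_params"))
  validate_fqz_params(params)
  mapped <- lapply(records$quals, function(q) {
    m <- match(q, params$qmap) - 1L
    if (anyNA(m)) stop("quality value outside the parameter alphabet")
    m
  })
  if (params$fixed_length >= 0L &&
      !all(lengths(mapped) == params$fixed_length))
    stop("records do not all have the parameter block's fixed length")
  enc <- fqz_enc_core(mapped, records$reverse, records$selector,
                      core_params(params), FALSE)
  c(serialize_fqz_params(params, length(records)), enc$payload)
}

#' Decompress an FQZComp quality stream
#'
#' @param stream Raw vector produced by [fqz_encode()].
#' @return A [quality_records()] object with qualities, reverse and
#'   duplicate flags and selector values restored.
#' @export
fqz_decode <- function(stream) {
  stream <- as.raw(stream)
  hdr <- parse_fqz_params(stream)
  p <- hdr$params
  payload <- if (hdr$pos <= length(stream))
    stream[hdr$pos:length(stream)] else raw(0)
  dec <- fqz_dec_core(payload, core_params(p), hdr$n_records)
  quals <- lapply(dec$quals, function(m) p$qmap[m + 1L])
  quality_records(quals, reverse = dec$rev, duplicate = dec$dup,
                  selector = dec$sel)
}
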