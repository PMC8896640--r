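# Structure-aware read-name tokenizer: identifiers are split into typed
# fragments (alpha runs, digit runs with or without leading zeros, single
# characters), delta-encoded against the previous name, and the resulting
# per-(column, type) streams are entropy coded.

TOKEN_TYPES <- c("CHAR" = 0L, "ALPHA" = 1L, "DIGITS" = 2L, "DIGITS0" = 3L,
                 "MATCH" = 4L, "DDELTA" = 5L, "DDELTA0" = 6L, "NOP" = 7L,
                 "END" = 8L)

leading_zeros <- function(text) nchar(text) - nchar(sub("^0+", "", text))

#' Split a read name into raw fragments
#'
#' Maximal digit runs become numeric fragments (`DIGITS`, or `DIGITS0` when
#' they carry leading zeros), maximal alphabetic runs become `ALPHA`
#' fragments, and every other byte is a single `CHAR` fragment.  Digit runs
#' longer than ten are broken left-to-right into chunks of at most ten
#' digits, and a ten-digit chunk whose value does not fit in 32 bits is
#' split five-and-five, so every numeric fragment's value is below 2^32.
#'
#' @param name A single non-empty string of printable characters.
#' @return A data frame with columns `kind` and `text`, one row per
#'   fragment; concatenating `text` reproduces the name.
#' @export
split_raw <- function(name) {
  if (length(name) != 1L || is.na(name) || !nzchar(name))
    stop("empty name")
  if (grepl("[\n\r]", name)) stop("invalid name: embedded newline")
  m <- regmatches(name, gregexpr("[0-9]+|[A-Za-z]+|[^0-9A-Za-z]", name))[[1]]
  frags <- character(0)
  for (f in m) {
    if (grepl("^[0-9]", f)) {
      while (nchar(f) > 10L) {
        frags <- c(frags, substr(f, 1L, 10L))
        f <- substr(f, 11L, nchar(f))
      }
      frags <- c(frags, f)
    } else {
      frags <- c(frags, f)
    }
  }
  # a 10-digit chunk can still exceed the 32-bit value bound
  out <- character(0)
  for (f in frags) {
    if (grepl("^[0-9]{10}$", f) && as.numeric(f) >= 2^32) {
      out <- c(out, substr(f, 1L, 5L), substr(f, 6L, 10L))
    } else {
      out <- c(out, f)
    }
  }
  kind <- ifelse(grepl("^[0-9]", out),
                 ifelse(nchar(out) > 1L & substr(out, 1L, 1L) == "0",
                        "DIGITS0", "DIGITS"),
                 ifelse(grepl("^[A-Za-z]", out), "ALPHA", "CHAR"))
  data.frame(kind = kind, text = out, stringsAsFactors = FALSE)
}

#' Tokenize a read name against the previous tokenized name
#'
#' Each fragment is compared with the previous name's fragment in the same
#' column: a byte-identical fragment becomes `MATCH`; two plain numbers
#' whose difference lies in 0..255 become `DDELTA`; two zero-padded numbers
#' of identical width and leading-zero count with a difference in 0..255
#' become `DDELTA0`; anything else is stored literally.  The token list is
#' terminated by `END`.
#'
#' @param name A single non-empty string.
#' @param prev The previous name's `tokenized_name`, or `NULL` for the
#'   first name.
#' @return An object of class `tokenized_name` with parallel vectors
#'   `type`, `value` and `text` (one element per token, ending with `END`)
#'   and the fragment table used for comparison by the next name.
#' @export
tokenize_name <- function(name, prev = NULL) {
  fr <- split_raw(name)
  k <- nrow(fr)
  type <- character(k + 1L)
  value <- rep(NA_real_, k + 1L)
  text <- c(fr$text, "")
  for (j in seq_len(k)) {
    kind <- fr$kind[j]
    cur <- fr$text[j]
    pkind <- if (!is.null(prev) && j <= nrow(prev$frags)) prev$frags$kind[j]
    ptext <- if (!is.null(prev) && j <= nrow(prev$frags)) prev$frags$text[j]
    if (!is.null(ptext) && identical(cur, ptext)) {
      type[j] <- "MATCH"
    } else if (kind == "DIGITS" && identical(pkind, "DIGITS")) {
      d <- as.numeric(cur) - as.numeric(ptext)
      if (d >= 0 && d <= 255) {
        type[j] <- "DDELTA"
        value[j] <- d
      } else {
        type[j] <- "DIGITS"
        value[j] <- as.numeric(cur)
      }
    } else if (kind == "DIGITS0" && identical(pkind, "DIGITS0") &&
               nchar(cur) == nchar(ptext) &&
               leading_zeros(cur) == leading_zeros(ptext) &&
               (d <- as.numeric(cur) - as.numeric(ptext)) >= 0 && d <= 255) {
      type[j] <- "DDELTA0"
      value[j] <- d
    } else {
      type[j] <- kind
      if (kind %in% c("DIGITS", "DIGITS0")) value[j] <- as.numeric(cur)
    }
  }
  type[k + 1L] <- "END"
  structure(list(name = name, frags = fr,
                 type = type, value = value, text = text),
            class = "tokenized_name")
}

#' @export
print.tokenized_name <- function(x, ...) {
  lab <- ifelse(is.na(x$value), x$text, paste0(x$text, "(", x$value, ")"))
  cat("<tokenized_name:", paste0(x$type, ifelse(nzchar(lab), ":", ""), lab,
                                 collapse = " "), ">\n")
  invisible(x)
}

le32 <- function(v) {
  v <- as.numeric(v)
  as.raw(c(v %% 256, v %/% 256 %% 256, v %/% 65536 %% 256,
           v %/% 16777216 %% 256))
}

from_le32 <- function(b) {
  sum(as.numeric(b) * c(1, 256, 65536, 16777216))
}

## ---- per-stream entropy layer ---------------------------------------------

TOK_METHODS <- list(
  function(x) encode_container(x, codec_flags(order = 0L)),
  function(x) encode_container(x, codec_flags(order = 1L)),
  function(x) encode_container(x, codec_flags(order = 0L, pack = TRUE,
                                              rle = TRUE)),
  function(x) arith_encode(x, order = 0L),
  function(x) arith_encode(x, order = 1L),
  function(x) encode_container(x, codec_flags(cat = TRUE))
)

tok_compress <- function(x, entropy, level) {
  if (length(x) == 0L) return(write_uint7(0))
  if (level == "fast") {
    method <- if (entropy == "rans") 1L else 4L
    body <- c(as.raw(method - 1L), TOK_METHODS[[method]](x))
  } else {
    cands <- list()
    for (m in seq_along(TOK_METHODS)) {
      if (m == 2L && length(x) == 0L) next
      enc <- tryCatch(TOK_METHODS[[m]](x), error = function(e) NULL)
      if (!is.null(enc)) cands[[length(cands) + 1L]] <- c(as.raw(m - 1L), enc)
    }
    body <- cands[[which.min(vapply(cands, length, integer(1)))]]
  }
  c(write_uint7(length(body)), body)
}

tok_decompress <- function(stream, pos) {
  r <- read_uint7_at(stream, pos)
  pos <- r$pos
  if (r$value == 0L) return(list(data = raw(0), pos = pos))
  if (pos + r$value - 1L > length(stream)) stop("truncated token stream")
  body <- stream[seq.int(pos, length.out = r$value)]
  pos <- pos + r$value
  method <- as.integer(body[1L]) + 1L
  rest <- body[-1L]
  data <- if (method %in% c(4L, 5L)) arith_decode(rest)
          else decode_container(rest)
  list(data = data, pos = pos)
}

#' Compress a list of read names with the structure-aware tokenizer
#'
#' Names are tokenized against their immediate predecessor and the typed
#' tokens are grouped into per-(column, type) byte streams, each entropy
#' coded independently.  `level = "fast"` codes every stream with one fixed
#' method; `level = "max"` tries rANS Order-0/Order-1, PACK+RLE, adaptive
#' arithmetic Order-0/Order-1 and verbatim storage per stream and keeps the
#' smallest.
#'
#' @param names Non-empty character vector of read names (no newlines).
#' @param entropy Preferred entropy coder for `level = "fast"`: `"rans"` or
#'   `"arith"`.
#' @param level `"fast"` or `"max"`.
#' @return Raw vector holding the compressed name block.
#' @export
encode_names <- function(names, entropy = c("rans", "arith"),
                         level = c("fast", "max")) {
  entropy <- match.arg(entropy)
  level <- match.arg(level)
  n <- length(names)
  if (n == 0L) stop("empty name list")
  if (any(is.na(names)) || any(grepl("[\n\r]", names)))
    stop("invalid name: embedded newline")

  toks <- vector("list", n)
  prev <- NULL
  for (i in seq_len(n)) {
    prev <- tokenize_name(names[i], prev)
    toks[[i]] <- prev
  }
  C <- max(vapply(toks, function(t) length(t$type), integer(1)))

  out <- list(write_uint7(n),
              as.raw((entropy == "arith") + 2L * (level == "max")),
              write_uint7(C))
  for (j in seq_len(C)) {
    types <- integer(0)
    s_char <- s_alpha <- s_dig <- s_dig0 <- s_dd <- s_dd0 <- list()
    for (i in seq_len(n)) {
      t <- toks[[i]]
      if (j > length(t$type)) next
      ty <- t$type[j]
      types <- c(types, TOKEN_TYPES[[ty]])
      if (ty == "CHAR") {
        s_char[[length(s_char) + 1L]] <- charToRaw(t$text[j])
      } else if (ty == "ALPHA") {
        b <- charToRaw(t$text[j])
        s_alpha[[length(s_alpha) + 1L]] <- c(write_uint7(length(b)), b)
      } else if (ty == "DIGITS") {
        s_dig[[length(s_dig) + 1L]] <- le32(t$value[j])
      } else if (ty == "DIGITS0") {
        s_dig0[[length(s_dig0) + 1L]] <- c(le32(t$value[j]),
                                           as.raw(nchar(t$text[j])))
      } else if (ty == "DDELTA") {
        s_dd[[length(s_dd) + 1L]] <- as.raw(t$value[j])
      } else if (ty == "DDELTA0") {
        s_dd0[[length(s_dd0) + 1L]] <- as.raw(t$value[j])
      }
    }
    for (s in list(as.raw(types), unlist(s_char), unlist(s_alpha),
                   unlist(s_dig), unlist(s_dig0), unlist(s_dd),
                   unlist(s_dd0))) {
      out[[length(out) + 1L]] <- tok_compress(if (is.null(s)) raw(0) else s,
                                              entropy, level)
    }
  }
  unlist(out)
}

#' Decompress a tokenized name block
#'
#' @param stream Raw vector produced by [encode_names()].
#' @return The original character vector of names, in order.
#' @export
decode_names <- function(stream) {
  stream <- as.raw(stream)
  r <- read_uint7_at(stream, 1L)
  n <- r$value
  pos <- r$pos + 1L  # skip the entropy/level byte (informational)
  r <- read_uint7_at(stream, pos)
  C <- r$value
  pos <- r$pos

  streams <- vector("list", C)
  for (j in seq_len(C)) {
    col <- vector("list", 7L)
    for (k in 1:7) {
      d <- tok_decompress(stream, pos)
      col[[k]] <- d$data
      pos <- d$pos
    }
    streams[[j]] <- list(data = col, cur = rep(1L, 7L))
  }

  take <- function(j, k, nb) {
    s <- streams[[j]]
    i0 <- s$cur[k]
    if (i0 + nb - 1L > length(s$data[[k]])) stop("malformed name block")
    b <- s$data[[k]][seq.int(i0, length.out = nb)]
    streams[[j]]$cur[k] <<- i0 + nb
    b
  }
  type_names <- names(TOKEN_TYPES)

  out <- character(n)
  prev <- NULL  # data.frame kind/text
  for (i in seq_len(n)) {
    kinds <- character(0)
    texts <- character(0)
    j <- 1L
    repeat {
      code <- as.integer(take(j, 1L, 1L))
      ty <- type_names[code + 1L]
      if (is.na(ty)) stop("malformed name block: unknown token type")
      if (ty == "END") break
      if (ty == "NOP") {
        j <- j + 1L
        next
      }
      if (ty == "MATCH") {
        if (is.null(prev) || j > nrow(prev)) stop("malformed name block")
        kinds <- c(kinds, prev$kind[j])
        texts <- c(texts, prev$text[j])
      } else if (ty == "CHAR") {
        kinds <- c(kinds, "CHAR")
        texts <- c(texts, rawToChar(take(j, 2L, 1L)))
      } else if (ty == "ALPHA") {
        s <- streams[[j]]
        r <- read_uint7_at(s$data[[3L]], s$cur[3L])
        streams[[j]]$cur[3L] <- r$pos
        kinds <- c(kinds, "ALPHA")
        texts <- c(texts, rawToChar(take(j, 3L, r$value)))
      } else if (ty == "DIGITS") {
        v <- from_le32(take(j, 4L, 4L))
        kinds <- c(kinds, "DIGITS")
        texts <- c(texts, format(v, scientific = FALSE))
      } else if (ty == "DIGITS0") {
        b <- take(j, 5L, 5L)
        v <- from_le32(b[1:4])
        w <- as.integer(b[5L])
        kinds <- c(kinds, "DIGITS0")
        texts <- c(texts, formatC(v, width = w, flag = "0", format = "d"))
      } else if (ty == "DDELTA") {
        if (is.null(prev) || j > nrow(prev)) stop("malformed name block")
        v <- as.numeric(prev$text[j]) + as.integer(take(j, 6L, 1L))
        kinds <- c(kinds, "DIGITS")
        texts <- c(texts, format(v, scientific = FALSE))
      } else if (ty == "DDELTA0") {
        if (is.null(prev) || j > nrow(prev)) stop("malformed name block")
        v <- as.numeric(prev$text[j]) + as.integer(take(j, 7L, 1L))
        w <- nchar(prev$text[j])
        kinds <- c(kinds, "DIGITS0")
        texts <- c(texts, formatC(v, width = w, flag = "0", format = "d"))
      }
      j <- j + 1L
    }
    out[i] <- paste(texts, collapse = "")
    prev <- data.frame(kind = kinds, text = texts, stringsAsFactors = FALSE)
  }
  out
}
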