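# Line-oriented text interchange: quality strings (Phred+33, one record
# per line), read names (one per line), and minimal FASTQ.

#' Read quality records from a line-oriented Phred+33 file
#'
#' @param path File with one ASCII quality string per line.
#' @return A [quality_records()] object.
#' @export
read_quality_lines <- function(path) {
  lines <- readLines(path)
  quals <- lapply(lines, function(l) {
    q <- as.integer(charToRaw(l)) - 33L
    if (length(q) && (any(q < 0L) || any(q > 93L)))
      stop("input error: quality character outside Phred+33 range")
    q
  })
  quality_records(quals)
}

#' Write quality records as Phred+33 lines
#'
#' @param records A [quality_records()] object.
#' @param path Output path.
#' @export
write_quality_lines <- function(records, path) {
  stopifnot(inherits(records, "quality_records"))
  lines <- vapply(records$quals,
                  function(q) rawToChar(as.raw(q + 33L)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read one identifier per line
#' @param path Input path.
#' @return Character vector of names.
#' @export
read_name_lines <- function(path) readLines(path)

#' Write one identifier per line
#' @param names Character vector.
#' @param path Output path.
#' @export
write_name_lines <- function(names, path) {
  writeLines(names, path)
  invisible(path)
}

#' Write a minimal FASTQ file from names and quality records
#'
#' Sequences are filled with `N`, matching each record's length; the file
#' exists to exercise end-to-end FASTQ extraction, not to simulate bases.
#'
#' @param names Character vector of read names.
#' @param records A [quality_records()] object of the same length.
#' @param path Output path.
#' @export
write_fastq <- function(names, records, path) {
  stopifnot(length(names) == length(records))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(names)) {
    q <- records$quals[[i]]
    writeLines(c(paste0("@", names[i]),
                 strrep("N", length(q)),
                 "+",
                 rawToChar(as.raw(q + 33L))), con)
  }
  invisible(path)
}

read_fastq_lines <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("input error: FASTQ not in 4-line records")
  lines
}

#' Extract the quality column of a FASTQ file
#' @param path FASTQ path (uncompressed, 4 lines per record).
#' @return A [quality_records()] object.
#' @export
fastq_qualities <- function(path) {
  lines <- read_fastq_lines(path)
  qlines <- lines[seq_along(lines) %% 4L == 0L]
  quality_records(lapply(qlines, function(l) as.integer(charToRaw(l)) - 33L))
}

#' Extract the name column of a FASTQ file
#' @param path FASTQ path (uncompressed, 4 lines per record).
#' @return Character vector of names (without the leading `@`).
#' @export
fastq_names <- function(path) {
  lines <- read_fastq_lines(path)
  sub("^@", "", lines[seq_along(lines) %% 4L == 1L])
}
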