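#' Read a FASTQ file
#'
#' Strict 4-line-per-record reader that preserves everything the compressor
#' must reproduce byte-exactly: the identifier line including the leading
#' `@`, whether each `+` line repeats the identifier, and whether the file
#' ends with a newline.
#'
#' @param path FASTQ file path.
#' @return list with `id`, `seq`, `qual` (character vectors), `plus_repeat`
#'   (logical per record) and `final_newline`.
#' @export
read_fastq <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  final_newline <- length(raw) == 0L || raw[length(raw)] == as.raw(10L)
  txt <- rawToChar(raw)
  lines <- if (nchar(txt)) strsplit(txt, "\n", fixed = TRUE)[[1]] else character()
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: line count ", length(lines), " is not a multiple of 4")
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(list(id = character(), seq = character(), qual = character(),
                plus_repeat = logical(), final_newline = final_newline))
  id <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(substr(id, 1L, 1L) != "@")
  if (length(bad))
    stop("malformed FASTQ: record ", bad[1], " does not start with '@'")
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop("malformed FASTQ: record ", bad[1],
         " sequence and quality lengths differ")
  plus_repeat <- plus == paste0("+", substring(id, 2L))
  bad <- which(!plus_repeat & plus != "+")
  if (length(bad))
    stop("malformed FASTQ: record ", bad[1], " has an unsupported '+' line")
  bad <- which(grepl("[^ACGTN]", seq))
  if (length(bad))
    stop("record ", bad[1], ": sequence contains characters outside ACGTN")
  qr <- utf8ToInt(paste(qual, collapse = ""))
  if (length(qr) && (min(qr) < 33L || max(qr) > 126L))
    stop("quality characters outside the Phred+33 range 33..126")
  list(id = id, seq = seq, qual = qual, plus_repeat = plus_repeat,
       final_newline = final_newline)
}

#' @rdname read_fastq
#' @param fq list as returned by [read_fastq()] (or with the same fields).
#' @param path output path.
#' @export
write_fastq <- function(fq, path) {
  n <- length(fq$id)
  plus <- ifelse(rep_len(fq$plus_repeat, n), paste0("+", substring(fq$id, 2L)), "+")
  lines <- character(4L * n)
  if (n) {
    lines[seq(1L, by = 4L, length.out = n)] <- fq$id
    lines[seq(2L, by = 4L, length.out = n)] <- fq$seq
    lines[seq(3L, by = 4L, length.out = n)] <- plus
    lines[seq(4L, by = 4L, length.out = n)] <- fq$qual
  }
  txt <- paste(lines, collapse = "\n")
  if (n && isTRUE(fq$final_newline)) txt <- paste0(txt, "\n")
  writeBin(charToRaw(txt), path)
  invisible(path)
}

#' Read and write FASTA
#'
#' Minimal FASTA handling for reference sequences: multi-sequence files are
#' returned as a named character vector of sequences.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  grp <- cumsum(hdr)
  keep <- grp > 0L & !hdr
  seqs <- vapply(split(lines[keep], grp[keep]),
                 function(x) paste(x, collapse = ""), character(1))
  names(seqs) <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  toupper(seqs)
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    nm <- names(seqs)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("seq", i)
    writeLines(paste0(">", nm), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read and write SAM text
#'
#' Reads the mandatory 11 columns of a SAM file plus the header lines.
#' Auxiliary fields beyond column 11 are dropped with a warning (they are not
#' retained by the SAM codecs).
#'
#' @param path file path.
#' @return list with `header` (character vector of `@` lines) and `records`
#'   (data frame with the 11 mandatory columns).
#' @export
read_sam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  if (!length(body)) {
    rec <- data.frame(qname = character(), flag = integer(), rname = character(),
                      pos = integer(), mapq = integer(), cigar = character(),
                      rnext = character(), pnext = integer(), tlen = integer(),
                      seq = character(), qual = character(),
                      stringsAsFactors = FALSE)
    return(list(header = hdr, records = rec))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L))
    stop("malformed SAM: record ", which(nf < 11L)[1], " has fewer than 11 fields")
  if (any(nf > 11L))
    warning("auxiliary SAM fields present; they are not retained")
  g <- function(i) vapply(parts, `[[`, character(1), i)
  rec <- data.frame(
    qname = g(1), flag = as.integer(g(2)), rname = g(3), pos = as.integer(g(4)),
    mapq = as.integer(g(5)), cigar = g(6), rnext = g(7),
    pnext = as.integer(g(8)), tlen = as.integer(g(9)), seq = g(10), qual = g(11),
    stringsAsFactors = FALSE)
  list(header = hdr, records = rec)
}

#' @rdname read_sam
#' @param sam list as returned by [read_sam()].
#' @export
write_sam <- function(sam, path) {
  r <- sam$records
  body <- if (nrow(r)) {
    paste(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar, r$rnext, r$pnext,
          r$tlen, r$seq, r$qual, sep = "\t")
  } else character()
  writeLines(c(sam$header, body), path)
  invisible(path)
}
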