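# Container format: magic "FQZ1", version byte, mode byte, block count, then
# per-stream blocks. Each block is a 4-byte tag, an 8-byte little-endian
# payload length, the payload, and a CRC-32 of the payload. The META block
# (serialized R list) comes first and carries record counts, read lengths and
# everything else the per-stream decoders need.

MODES <- c(store = 0L, fqz = 1L, fastqz = 2L, samcomp1 = 3L, samcomp2 = 4L)

u32_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, x %/% 256 %% 256, x %/% 65536 %% 256, x %/% 16777216 %% 256))
}
raw_u32 <- function(r) sum(as.numeric(r) * c(1, 256, 65536, 16777216))
u64_raw <- function(x) c(u32_raw(as.numeric(x) %% 4294967296), u32_raw(as.numeric(x) %/% 4294967296))
raw_u64 <- function(r) raw_u32(r[1:4]) + raw_u32(r[5:8]) * 4294967296

write_container <- function(path, mode, blocks) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("FQZ1"), con)
  writeBin(as.raw(c(1L, MODES[[mode]], length(blocks))), con)
  for (tag in names(blocks)) {
    payload <- blocks[[tag]]
    writeBin(charToRaw(formatC(tag, width = 4, flag = " ")), con)
    writeBin(u64_raw(length(payload)), con)
    if (length(payload)) writeBin(payload, con)
    writeBin(u32_raw(.c_crc32(payload)), con)
  }
  invisible(path)
}

read_container <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 7L || rawToChar(raw[1:4]) != "FQZ1")
    stop("not an fqzlite container: ", path)
  if (as.integer(raw[5]) != 1L) stop("unsupported container version")
  mode <- names(MODES)[match(as.integer(raw[6]), MODES)]
  nb <- as.integer(raw[7])
  blocks <- list()
  off <- 8L
  for (i in seq_len(nb)) {
    if (off + 11L > length(raw) + 1L) stop("container truncated")
    tag <- trimws(rawToChar(raw[off:(off + 3L)]))
    len <- raw_u64(raw[(off + 4L):(off + 11L)])
    off <- off + 12L
    payload <- if (len > 0) raw[off:(off + len - 1)] else raw(0)
    off <- off + len
    crc <- raw_u32(raw[off:(off + 3L)])
    off <- off + 4L
    if (.c_crc32(payload) != crc)
      stop("container corrupt: checksum mismatch in block '", tag, "'")
    blocks[[tag]] <- payload
  }
  list(mode = mode, blocks = blocks)
}

meta_pack <- function(meta) serialize(meta, NULL, version = 2)
meta_unpack <- function(raw) unserialize(raw)

# positions where the base-is-N <=> quality-is-0 convention does not hold;
# originals are stored so decoding can restore them
qual_n_exceptions <- function(seqs, quals) {
  cand <- which(grepl("N", seqs, fixed = TRUE) | grepl("!", quals, fixed = TRUE))
  rec <- integer(); pos <- integer(); base <- character(); qch <- character()
  for (r in cand) {
    s <- strsplit(seqs[r], "")[[1]]
    q <- strsplit(quals[r], "")[[1]]
    bad <- which((s == "N") != (q == "!"))
    if (length(bad)) {
      rec <- c(rec, rep(r, length(bad)))
      pos <- c(pos, bad)
      base <- c(base, s[bad])
      qch <- c(qch, q[bad])
    }
  }
  list(rec = rec, pos = pos, base = base, qual = qch)
}

apply_exceptions <- function(seqs, quals, ex) {
  for (i in seq_along(ex$rec)) {
    r <- ex$rec[i]; p <- ex$pos[i]
    substr(seqs[r], p, p) <- ex$base[i]
    if (!is.na(ex$qual[i])) substr(quals[r], p, p) <- ex$qual[i]
  }
  list(seq = seqs, qual = quals)
}

# restore N bases at positions whose decoded quality is 0
restore_n <- function(seqs, quals) {
  has0 <- grepl("!", quals, fixed = TRUE)
  for (r in which(has0)) {
    q <- strsplit(quals[r], "")[[1]]
    s <- strsplit(seqs[r], "")[[1]]
    s[q == "!"] <- "N"
    seqs[r] <- paste(s, collapse = "")
  }
  seqs
}

level_params <- function(level) {
  switch(level,
    fast   = list(k = 12L, revcomp = FALSE, dual7 = FALSE, qlevel = 1L, slow = FALSE),
    medium = list(k = 14L, revcomp = FALSE, dual7 = TRUE,  qlevel = 2L, slow = FALSE),
    slow   = list(k = 16L, revcomp = TRUE,  dual7 = TRUE,  qlevel = 3L, slow = TRUE),
    stop("level must be fast, medium or slow"))
}

#' Compress a FASTQ file
#'
#' Splits the file into identifier, base-call and quality streams and codes
#' each independently. `mode = "fqz"` uses tokenised identifier coding,
#' order-k base models and multi-level quality contexts; `mode = "fastqz"`
#' uses line-delta identifiers, self-synchronising base packing and byte-code
#' quality packing, each followed by a context-mixing stage in slow mode, and
#' can additionally align reads against a reference so that matched bases are
#' replaced by compact alignment records. `mode = "store"` writes the raw
#' streams (8 bits per base and per quality), the uncompressed baseline.
#'
#' @param input FASTQ path.
#' @param output container path.
#' @param mode codec family: `"fqz"`, `"fastqz"` or `"store"`.
#' @param level `"fast"`, `"medium"` or `"slow"` (fastqz has no medium; it is
#'   treated as slow).
#' @param Q lossy quality quantisation factor; 1 (default) is lossless. fqz
#'   mode codes each value above Q within Q of the original; fastqz mode
#'   rounds values above 1 to a multiple of Q.
#' @param ref optional FASTA path enabling reference-based coding (fastqz
#'   mode only); the same reference is required for decompression.
#' @param table_bits log2 size of the reference group index.
#' @return a stream-size breakdown (class `fqz_breakdown`).
#' @export
compress_fastq <- function(input, output, mode = c("fqz", "fastqz", "store"),
                           level = c("medium", "fast", "slow"), Q = 1L,
                           ref = NULL, table_bits = 20L) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  t0 <- proc.time()[["elapsed"]]
  fq <- read_fastq(input)
  n <- length(fq$id)
  lengths <- nchar(fq$seq)
  quals <- fq$qual
  lossy <- if (Q > 1L) (if (mode == "fastqz") "round" else "within") else "none"
  if (lossy == "round") quals <- vapply(quals, lossy_round_line, character(1), Q = Q,
                                        USE.NAMES = FALSE)
  meta <- list(n = n, input_bytes = file.size(input),
               lengths = if (n && length(unique(lengths)) == 1L) lengths[1] else lengths,
               plus_repeat = if (n && length(unique(fq$plus_repeat)) == 1L)
                 fq$plus_repeat[1] else fq$plus_repeat,
               final_newline = fq$final_newline,
               level = level, Q = as.integer(Q), lossy = lossy,
               base_total = sum(lengths))
  blocks <- list()
  if (mode == "store") {
    blocks$ID <- charToRaw(paste(fq$id, collapse = "\n"))
    blocks$SEQ <- charToRaw(paste(fq$seq, collapse = ""))
    blocks$QUAL <- charToRaw(paste(quals, collapse = ""))
  } else if (mode == "fqz") {
    p <- level_params(level)
    ex <- qual_n_exceptions(fq$seq, quals)
    meta$exceptions <- ex
    blocks$ID <- .c_id_encode(fq$id, FALSE)
    blocks$SEQ <- .c_fqz_seq_encode(fq$seq, p$k, p$revcomp, p$dual7)
    qe <- .c_fqz_qual_encode(quals, fq$seq, p$qlevel, as.integer(Q),
                             lossy == "within")
    blocks$QUAL <- qe$data
    meta$qual_clamped <- qe$clamped
  } else {
    slow <- level != "fast"
    ex <- qual_n_exceptions(fq$seq, quals)
    meta$exceptions <- ex
    blocks$ID <- .c_fastqz_id_encode(fq$id, slow)
    qcodes <- .c_fastqz_pack_qual_stream(quals, fq$seq)
    meta$n_qual_codes <- length(qcodes)
    blocks$QUAL <- if (slow) .c_cm_encode_bytes(qcodes, "qual") else qcodes
    if (is.null(ref)) {
      seq_raw <- .c_fastqz_seq_encode(fq$seq, slow)
      meta$n_packed <- if (slow) length(.c_pack_bases(paste(fq$seq, collapse = "")))
                       else length(seq_raw)
      blocks$SEQ <- seq_raw
    } else {
      refseqs <- read_fasta(ref)
      refstr <- paste(refseqs, collapse = "")
      meta$ref_crc <- .c_crc32(charToRaw(refstr))
      meta$ref_len <- nchar(refstr)
      meta$table_bits <- as.integer(table_bits)
      idx <- .c_build_ref_index(refstr, as.integer(table_bits))
      aln <- .c_align_reads(idx, fq$seq)
      blocks$ALN <- .c_code_alignments(aln, slow)
      res <- .c_refmap_residual(fq$seq, aln, idx)
      blocks$MIS <- res$mis
      meta$n_residual <- nchar(res$residual)
      seq_raw <- .c_fastqz_seq_encode(res$residual, slow)
      meta$n_packed <- if (slow) length(.c_pack_bases(res$residual)) else length(seq_raw)
      blocks$SEQ <- seq_raw
    }
  }
  out_blocks <- c(list(META = meta_pack(meta)), blocks)
  write_container(output, mode, out_blocks)
  elapsed <- proc.time()[["elapsed"]] - t0
  breakdown(output, meta, out_blocks, elapsed)
}

breakdown <- function(path, meta, blocks, elapsed = NA_real_) {
  sizes <- vapply(blocks, length, numeric(1))
  n <- meta$n
  bt <- meta$base_total
  seq_bytes <- sum(sizes[names(sizes) %in% c("SEQ", "ALN", "MIS", "SIDE")])
  structure(list(
    n_records = n,
    sizes = sizes,
    file_size = file.size(path),
    input_bytes = meta$input_bytes,
    bits_per_identifier = if (n) 8 * unname(sizes["ID"] %||% sizes["QNAM"]) / n else NA_real_,
    bits_per_base = if (isTRUE(bt > 0)) 8 * seq_bytes / bt else NA_real_,
    bits_per_quality = if (isTRUE(bt > 0)) 8 * unname(sizes["QUAL"]) / bt else NA_real_,
    overall_ratio = file.size(path) / meta$input_bytes,
    compress_rate = if (!is.na(elapsed) && elapsed > 0)
      meta$input_bytes / 1e6 / elapsed else NA_real_
  ), class = "fqz_breakdown")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' @export
print.fqz_breakdown <- function(x, ...) {
  cat("fqzlite stream breakdown\n")
  cat(sprintf("  records:          %d\n", x$n_records))
  for (tag in names(x$sizes))
    cat(sprintf("  %-5s block:      %12.0f bytes\n", tag, x$sizes[[tag]]))
  cat(sprintf("  bits/identifier:  %8.2f\n", x$bits_per_identifier))
  cat(sprintf("  bits/base:        %8.3f\n", x$bits_per_base))
  cat(sprintf("  bits/quality:     %8.3f\n", x$bits_per_quality))
  cat(sprintf("  overall ratio:    %8.4f\n", x$overall_ratio))
  if (!is.na(x$compress_rate))
    cat(sprintf("  compress rate:    %8.1f MB/s\n", x$compress_rate))
  invisible(x)
}

#' Decompress an fqzlite container
#'
#' Reconstructs the original FASTQ or SAM file. Every block checksum is
#' verified before decoding; a container coded against a reference refuses to
#' decode without the identical reference.
#'
#' @param input container path.
#' @param output output path (FASTQ or SAM depending on the container).
#' @param ref reference FASTA path, required when the container was coded
#'   against a reference.
#' @export
decompress <- function(input, output, ref = NULL) {
  ct <- read_container(input)
  meta <- meta_unpack(ct$blocks$META)
  if (ct$mode %in% c("samcomp1", "samcomp2"))
    return(decompress_sam_container(ct, meta, output, ref))
  n <- meta$n
  lengths <- rep_len(meta$lengths, n)
  if (ct$mode == "store") {
    ids <- if (n) strsplit(rawToChar(ct$blocks$ID), "\n", fixed = TRUE)[[1]] else character()
    seqs <- split_concat(rawToChar(ct$blocks$SEQ), lengths)
    quals <- split_concat(rawToChar(ct$blocks$QUAL), lengths)
  } else if (ct$mode == "fqz") {
    p <- level_params(meta$level)
    ids <- .c_id_decode(ct$blocks$ID, n, FALSE)
    seqs <- .c_fqz_seq_decode(ct$blocks$SEQ, lengths, p$k, p$revcomp, p$dual7)
    quals <- .c_fqz_qual_decode(ct$blocks$QUAL, lengths, p$qlevel)
    seqs <- restore_n(seqs, quals)
    fixed <- apply_exceptions(seqs, quals, meta$exceptions)
    seqs <- fixed$seq; quals <- fixed$qual
  } else {
    slow <- meta$level != "fast"
    ids <- .c_fastqz_id_decode(ct$blocks$ID, n, slow)
    qcodes <- if (slow) .c_cm_decode_bytes(ct$blocks$QUAL, meta$n_qual_codes, "qual")
              else ct$blocks$QUAL
    quals <- .c_fastqz_unpack_qual_stream(qcodes, lengths)
    if (is.null(meta$ref_crc)) {
      seqs <- .c_fastqz_seq_decode(ct$blocks$SEQ, meta$n_packed, lengths, slow)
    } else {
      if (is.null(ref))
        stop("this container was coded against a reference; supply it with ref=")
      refstr <- paste(read_fasta(ref), collapse = "")
      if (.c_crc32(charToRaw(refstr)) != meta$ref_crc)
        stop("supplied reference does not match the one used for compression")
      idx <- .c_build_ref_index(refstr, meta$table_bits)
      aln <- .c_decode_alignments(ct$blocks$ALN, n, slow)
      residual <- if (meta$n_residual > 0)
        .c_fastqz_seq_decode(ct$blocks$SEQ, meta$n_packed,
                             as.integer(meta$n_residual), slow)[[1]]
      else ""
      seqs <- .c_refmap_reconstruct(aln, residual, ct$blocks$MIS, idx, lengths)
    }
    seqs <- restore_n(seqs, quals)
    fixed <- apply_exceptions(seqs, quals, meta$exceptions)
    seqs <- fixed$seq; quals <- fixed$qual
  }
  write_fastq(list(id = ids, seq = seqs, qual = quals,
                   plus_repeat = rep_len(meta$plus_repeat, n),
                   final_newline = meta$final_newline), output)
  invisible(output)
}

split_concat <- function(s, lengths) {
  if (!length(lengths)) return(character())
  ends <- cumsum(lengths)
  starts <- c(1, head(ends, -1) + 1)
  substring(s, starts, ends)
}

#' Per-stream size accounting of a container
#'
#' Computes the bits spent per identifier, per base call and per quality
#' value from the container's block sizes, plus the overall compression
#' ratio. A store-mode container reports exactly 8 bits per base and per
#' quality.
#'
#' @param path container path.
#' @return a `fqz_breakdown` object.
#' @export
container_stats <- function(path) {
  ct <- read_container(path)
  meta <- meta_unpack(ct$blocks$META)
  breakdown(path, meta, ct$blocks)
}
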