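#' Canonical quality symbols
#'
#' Maps a Phred+33 quality line to symbols 0..63: ASCII minus 33, clamped to
#' 62; symbol 0 is reserved for bases called `N`; a terminal run (length >= 2)
#' of score 2 is collapsed to the single sentinel 63.
#'
#' @param qual quality line (Phred+33).
#' @param seq matching base-call line.
#' @return integer vector of symbols (shorter than the read when the sentinel
#'   applies).
#' @examples
#' canonicalize_quals("GG####", "ACGTAC")
#' @export
canonicalize_quals <- function(qual, seq) .c_canonicalize_quals(qual, seq)

#' @rdname canonicalize_quals
#' @param symbols canonical symbols.
#' @param length read length.
#' @return `decanonicalize_quals()` returns the quality string (symbol 0 maps
#'   back to `'!'`; the sentinel expands to `'#'`).
#' @export
decanonicalize_quals <- function(symbols, length) {
  out <- integer(length)
  i <- 1L
  for (s in symbols) {
    if (s == 63L) {
      out[i:length] <- 2L
      i <- length + 1L
      break
    }
    out[i] <- s
    i <- i + 1L
  }
  if (i != length + 1L) stop("symbol vector does not cover the read")
  intToUtf8(out + 33L)
}

#' Quality context key
#'
#' The context addressing the quality model, as a pure function of the symbol
#' history: level 1 uses the previous score; level 2 adds the second-previous
#' score quantised by 4; level 3 adds a position bucket, the maximum of the
#' last six scores (quantised) and an indicator that any score so far was
#' below 20.
#'
#' @param history previous symbols of the read (may be empty).
#' @param level context level 1..3.
#' @return the context key (a single number).
#' @export
qual_context <- function(history, level = 3L) {
  .c_qual_context(as.integer(history), as.integer(level))
}

#' Compress quality lines with adaptive context models
#'
#' Canonicalises each line (see [canonicalize_quals()]) and codes the symbols
#' under the selected context level. With `Q > 1` and `lossy = "within"`,
#' every value above `Q` may be replaced by the value within `Q` of the
#' original that the current context model predicts most strongly.
#'
#' @param quals,seqs character vectors of quality and base-call lines.
#' @param level context level 1..3.
#' @param Q quantisation factor (1 = lossless).
#' @param lossy `"none"` or `"within"`.
#' @return list with `data` (raw) and `clamped` (TRUE when any input score
#'   above 62 was clamped).
#' @export
encode_fqz_quals <- function(quals, seqs, level = 3L, Q = 1L,
                             lossy = c("none", "within")) {
  lossy <- match.arg(lossy)
  .c_fqz_qual_encode(quals, seqs, as.integer(level), as.integer(Q),
                     lossy == "within")
}

#' @rdname encode_fqz_quals
#' @param data raw vector from [encode_fqz_quals()].
#' @param lengths integer vector of read lengths.
#' @export
decode_fqz_quals <- function(data, lengths, level = 3L) {
  .c_fqz_qual_decode(data, as.integer(lengths), as.integer(level))
}

#' Byte-code packing of quality scores
#'
#' Greedy left-to-right packing preferring runs of score 38 (up to length 55),
#' then triples in 35..38, then pairs in 31..38, then single scores, with a
#' final marker when the rest of the scores are 2 and can be omitted.
#'
#' @param symbols integer quality symbols 0..62.
#' @return raw vector of byte codes.
#' @export
fastqz_pack_quals <- function(symbols) .c_fastqz_pack_quals(as.integer(symbols))

#' @rdname fastqz_pack_quals
#' @param codes raw vector of byte codes.
#' @param length read length.
#' @export
fastqz_unpack_quals <- function(codes, length) {
  .c_fastqz_unpack_quals(codes, as.integer(length))
}

#' Round quality values to multiples of Q
#'
#' The rounding lossy mode: every value above 1 is replaced by the nearest
#' multiple of `Q` (ties upward, result clamped to 1..62), shrinking the
#' symbol alphabet.
#'
#' @param symbols integer quality values.
#' @param Q quantisation factor.
#' @return quantised values.
#' @export
lossy_round <- function(symbols, Q) {
  stopifnot(Q >= 1)
  v <- as.integer(symbols)
  sel <- v > 1L
  r <- as.integer(Q * floor(v[sel] / Q + 0.5))
  r[r < 1L] <- 1L
  r[r > 62L] <- 62L
  v[sel] <- r
  v
}

# rounding applied to a Phred+33 string, preserving N positions (symbol 0)
lossy_round_line <- function(qual, Q) {
  v <- utf8ToInt(qual) - 33L
  sel <- v > 1L & v <= 62L
  if (any(sel)) {
    r <- as.integer(Q * floor(v[sel] / Q + 0.5))
    r[r < 1L] <- 1L
    r[r > 62L] <- 62L
    v[sel] <- r
  }
  intToUtf8(v + 33L)
}
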