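#' Anchor the bases of a SAM record to reference coordinates
#'
#' Walks the CIGAR string: M/=/X bases advance read and reference and are
#' `MATCHED` to a 0-based coordinate (the first at `pos - 1`); I and S bases
#' are emitted on the `INSERTION` / `SOFTCLIP` channels without a coordinate;
#' D and N advance the reference only; H consumes nothing.
#'
#' @param pos 1-based leftmost mapping position.
#' @param cigar CIGAR string.
#' @param seq read bases.
#' @return data frame with `ref_coord`, `base`, `channel`.
#' @examples
#' anchor_bases(10, "2M1I2M", "ACGTA")
#' @export
anchor_bases <- function(pos, cigar, seq) {
  as.data.frame(.c_anchor_bases(as.integer(pos), cigar, seq),
                stringsAsFactors = FALSE)
}

#' Compress a SAM file
#'
#' `samcomp1` requires input sorted by (rname, pos) and codes every anchored
#' base with an adaptive per-reference-coordinate model, seeded from the
#' reference when one is given; compression improves as coverage accumulates
#' at each coordinate. `samcomp2` accepts records in any order (so the
#' original name order keeps identifiers highly compressible) and codes each
#' base as a match/mismatch bit against the reference under a match-history
#' context; it needs a reference to perform well. Identifiers and qualities
#' are coded with the tokenised identifier codec and the quality context
#' models. Retained columns are qname, flag, rname, pos, mapq, CIGAR, seq and
#' qual; template columns 7-9 are stored as `*`/0/0 and auxiliary fields are
#' dropped. The header is carried verbatim.
#'
#' @param input SAM path (text).
#' @param output container path.
#' @param mode `"samcomp1"` or `"samcomp2"`.
#' @param ref optional FASTA with sequences named as in the SAM rname column.
#' @return a stream-size breakdown (class `fqz_breakdown`).
#' @export
compress_sam <- function(input, output, mode = c("samcomp1", "samcomp2"),
                         ref = NULL) {
  mode <- match.arg(mode)
  t0 <- proc.time()[["elapsed"]]
  sam <- read_sam(input)
  r <- sam$records
  n <- nrow(r)
  if (any(r$seq == "*")) stop("records without stored sequence are not supported")
  rtab <- unique(r$rname)
  rname_idx <- match(r$rname, rtab) - 1L
  refs <- rep(NA_character_, length(rtab))
  if (!is.null(ref)) {
    fa <- read_fasta(ref)
    hit <- match(rtab, names(fa))
    refs[!is.na(hit)] <- unname(fa[hit[!is.na(hit)]])
    miss <- setdiff(rtab[rtab != "*"], names(fa))
    if (length(miss))
      stop("reference is missing sequences named: ", paste(miss, collapse = ", "))
  } else if (mode == "samcomp2") {
    warning("samcomp2 without a reference compresses poorly; ",
            "bases fall back to a low-order context model")
  }
  variant <- if (mode == "samcomp1") 1L else 2L
  enc <- .c_samcomp_encode(r$flag, r$pos, rname_idx, r$mapq, r$cigar, r$seq,
                           variant, refs)
  qstar <- r$qual == "*"
  # exceptions to the base-is-N <=> quality-is-0 convention; records without
  # stored quality list every N position (with NA quality, meaning seq-only)
  ex <- list(rec = integer(), pos = integer(), base = character(),
             qual = character())
  cand <- which(grepl("N", r$seq, fixed = TRUE) |
                  (!qstar & grepl("!", r$qual, fixed = TRUE)))
  for (i in cand) {
    s <- strsplit(r$seq[i], "")[[1]]
    if (qstar[i]) {
      bad <- which(s == "N")
      qch <- rep(NA_character_, length(bad))
    } else {
      q <- strsplit(r$qual[i], "")[[1]]
      bad <- which((s == "N") != (q == "!"))
      qch <- q[bad]
    }
    if (length(bad)) {
      ex$rec <- c(ex$rec, rep(i, length(bad)))
      ex$pos <- c(ex$pos, bad)
      ex$base <- c(ex$base, s[bad])
      ex$qual <- c(ex$qual, qch)
    }
  }
  qe <- .c_fqz_qual_encode(r$qual[!qstar], r$seq[!qstar], 2L, 1L, FALSE)
  meta <- list(n = n, input_bytes = file.size(input),
               lengths = nchar(r$seq), base_total = sum(nchar(r$seq)),
               header = sam$header, rname_table = rtab,
               qual_star = qstar, exceptions = ex,
               ref_used = !is.null(ref),
               ref_crc = if (!is.null(ref))
                 .c_crc32(charToRaw(paste(refs[!is.na(refs)], collapse = ""))) else NA,
               cols789 = list(rnext = r$rnext, pnext = r$pnext, tlen = r$tlen),
               n_covered = enc$n_covered)
  # columns 7-9 are documented losses; store them only when non-default so
  # a normalised file round-trips exactly
  if (all(r$rnext == "*") && all(r$pnext == 0L) && all(r$tlen == 0L))
    meta$cols789 <- NULL
  blocks <- list(META = meta_pack(meta),
                 QNAM = .c_id_encode(r$qname, FALSE),
                 SEQ = enc$bases,
                 QUAL = qe$data,
                 SIDE = enc$side)
  write_container(output, mode, blocks)
  elapsed <- proc.time()[["elapsed"]] - t0
  breakdown(output, meta, blocks, elapsed)
}

decompress_sam_container <- function(ct, meta, output, ref) {
  n <- meta$n
  variant <- if (ct$mode == "samcomp1") 1L else 2L
  rtab <- meta$rname_table
  refs <- rep(NA_character_, length(rtab))
  if (isTRUE(meta$ref_used)) {
    if (is.null(ref))
      stop("this container was coded against a reference; supply it with ref=")
    fa <- read_fasta(ref)
    hit <- match(rtab, names(fa))
    refs[!is.na(hit)] <- unname(fa[hit[!is.na(hit)]])
    if (.c_crc32(charToRaw(paste(refs[!is.na(refs)], collapse = ""))) != meta$ref_crc)
      stop("supplied reference does not match the one used for compression")
  }
  dec <- .c_samcomp_decode(ct$blocks$SEQ, ct$blocks$SIDE, n, variant, refs,
                           as.integer(meta$lengths))
  qname <- .c_id_decode(ct$blocks$QNAM, n, FALSE)
  qstar <- meta$qual_star
  quals <- rep("*", n)
  if (any(!qstar))
    quals[!qstar] <- .c_fqz_qual_decode(ct$blocks$QUAL,
                                        as.integer(meta$lengths[!qstar]), 2L)
  seqs <- dec$seq
  seqs[!qstar] <- restore_n(seqs[!qstar], quals[!qstar])
  fixed <- apply_exceptions(seqs, quals, meta$exceptions)
  seqs <- fixed$seq
  quals[!qstar] <- fixed$qual[!qstar]
  c789 <- meta$cols789
  rec <- data.frame(
    qname = qname, flag = dec$flag, rname = rtab[dec$rname_idx + 1L],
    pos = dec$pos, mapq = dec$mapq, cigar = dec$cigar,
    rnext = if (is.null(c789)) "*" else c789$rnext,
    pnext = if (is.null(c789)) 0L else c789$pnext,
    tlen = if (is.null(c789)) 0L else c789$tlen,
    seq = seqs, qual = quals, stringsAsFactors = FALSE)
  write_sam(list(header = meta$header, records = rec), output)
  invisible(output)
}
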