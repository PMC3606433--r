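#' Order-k base-call compression
#'
#' Codes base calls (2-bit symbols, `N` coded as `A` and restored from the
#' quality stream) under an order-`k` context of the previous bases. The
#' context register is reset at each read start. Optionally every update also
#' trains the reverse-complement context, and a second fixed order-7 model can
#' run alongside, with each base coded by the model holding the strongest
#' single-symbol bias (ties prefer the order-k model; no mixing).
#'
#' @param seqs character vector of reads over `ACGTN`.
#' @param k context order in bases (contexts are hashed for k >= 15).
#' @param use_revcomp also train the reverse-complement context.
#' @param dual7 run the additional fixed order-7 model.
#' @return raw vector.
#' @export
encode_fqz_seqs <- function(seqs, k = 12L, use_revcomp = FALSE, dual7 = FALSE) {
  .c_fqz_seq_encode(seqs, as.integer(k), use_revcomp, dual7)
}

#' @rdname encode_fqz_seqs
#' @param data raw vector from [encode_fqz_seqs()].
#' @param lengths integer vector of read lengths.
#' @export
decode_fqz_seqs <- function(data, lengths, k = 12L, use_revcomp = FALSE,
                            dual7 = FALSE) {
  .c_fqz_seq_decode(data, as.integer(lengths), as.integer(k), use_revcomp, dual7)
}

#' Dual-model selection rule
#'
#' Given the per-base probability distributions of two models, returns the
#' index (1 or 2) of the model with the larger maximum single-symbol
#' probability -- the strongest bias to any base, not just the one being
#' coded -- with ties going to the first (order-k) model. The choice depends
#' only on model state, so encoder and decoder always agree.
#'
#' @param p_orderk,p_order7 numeric probability vectors summing to 1.
#' @return 1L or 2L.
#' @export
select_model <- function(p_orderk, p_order7) {
  stopifnot(abs(sum(p_orderk) - 1) < 1e-6, abs(sum(p_order7) - 1) < 1e-6)
  if (max(p_order7) > max(p_orderk)) 2L else 1L
}

#' Self-synchronising 3/4-base packing
#'
#' Packs bases with codes A=1, T=2, C=3, G=4 into single bytes of three or
#' four bases: after three bases with value `v`, a fourth base `c` is
#' appended iff `4 v + c <= 255`. Any sequence starting with G, CG or CCG is
#' always a 3-base group. Parsers starting at different offsets converge to
#' the same group boundaries, which keeps overlapping reads compressible.
#' A trailing remainder of 1-2 bases is closed with an escape byte below 21.
#'
#' @param seq a base string over `ACGTN` (`N` packs as `A`).
#' @return raw vector of packed bytes.
#' @examples
#' as.integer(pack_bases("TGGA"))  # 209
#' pack_groups("TGGAATCAGATGGAATCA")
#' @export
pack_bases <- function(seq) .c_pack_bases(seq)

#' @rdname pack_bases
#' @param bytes raw vector of packed bytes.
#' @export
unpack_bases <- function(bytes) .c_unpack_bases(bytes)

#' @rdname pack_bases
#' @return `pack_groups()` returns the parsed groups as strings.
#' @export
pack_groups <- function(seq) .c_pack_groups(seq)

#' Context-mixing compression of packed base streams
#'
#' Concatenates the reads, packs them (see [pack_bases()]) and, in slow mode,
#' codes the packed bytes bit-wise under a mix of direct order-0..2 models, an
#' indirect order-3 bit-history model, a match model, and a secondary
#' estimator keyed by the bit history of a hashed order-4 context.
#'
#' @param seqs character vector of reads.
#' @param slow apply the context-mixing stage (otherwise the packed bytes are
#'   returned as-is).
#' @return raw vector.
#' @export
encode_fastqz_seqs <- function(seqs, slow = FALSE) .c_fastqz_seq_encode(seqs, slow)

#' @rdname encode_fastqz_seqs
#' @param data raw vector from [encode_fastqz_seqs()].
#' @param npacked number of packed bytes (needed to drive the slow decoder).
#' @param lengths integer vector of read lengths.
#' @export
decode_fastqz_seqs <- function(data, npacked, lengths, slow = FALSE) {
  .c_fastqz_seq_decode(data, npacked, as.integer(lengths), slow)
}
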