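#' Pack a reference sequence four bases per byte
#'
#' Codes A=0, C=1, G=2, T=3 and deletes `N` runs, recording their original
#' coordinates so [unpack_reference()] can restore the input exactly.
#'
#' @param ref reference sequence string over `ACGTN`.
#' @return list with `data` (raw, 4 bases/byte), `length` (bases retained)
#'   and the `N`-run map (`n_start`, `n_len`).
#' @export
pack_reference <- function(ref) .c_pack_reference(ref)

#' @rdname pack_reference
#' @param packed list as returned by [pack_reference()].
#' @export
unpack_reference <- function(packed) {
  .c_unpack_reference(packed$data, packed$length, packed$n_start, packed$n_len)
}

#' Build the hashed group index of a reference
#'
#' The N-stripped reference is divided into non-overlapping 32-base groups;
#' each group's hash selects a slot holding a 27-bit group pointer and a
#' 5-bit checksum. Insertion probes up to 8 consecutive slots and silently
#' discards the pointer when all are full (coverage loss, never an error).
#'
#' @param ref reference sequence string.
#' @param table_bits log2 of the number of slots.
#' @return an index object (list) including `discard_fraction`.
#' @export
build_ref_index <- function(ref, table_bits = 20L) {
  .c_build_ref_index(ref, as.integer(table_bits))
}

#' Simulated pointer-discard fraction of the group index
#'
#' Inserts `occupancy * 2^table_bits` uniformly hashed groups with the same
#' probe-8 scheme used by [build_ref_index()] and returns the fraction of
#' pointers discarded.
#'
#' @param table_bits log2 of the number of slots.
#' @param occupancy insertions as a fraction of table size.
#' @param seed seed for the simulated hash stream.
#' @export
index_discard_sim <- function(table_bits = 20L, occupancy = 0.34, seed = 1L) {
  .c_index_discard_sim(as.integer(table_bits), occupancy, as.integer(seed))
}

#' Align reads against an indexed reference
#'
#' A rolling hash over every 32-base window of the read (and of its reverse
#' complement) is looked up in the group index, implied start positions are
#' evaluated, and candidates are ranked by the position of the fourth
#' mismatch, breaking ties with the third, second and first. A read whose
#' best fourth mismatch falls before half the read length is left unmatched,
#' as are reads shorter than 32 bases.
#'
#' @param idx index from [build_ref_index()].
#' @param reads character vector of reads.
#' @return data frame with `matched`, `dir` (0 forward / 1 reverse), `ptr`
#'   (0-based reference start), `m1..m4` (1-based mismatch positions, read
#'   length + 1 when unused).
#' @export
align_reads <- function(idx, reads) {
  as.data.frame(.c_align_reads(idx, reads), stringsAsFactors = FALSE)
}

#' @rdname align_reads
#' @param read a single read.
#' @return `align_read()` returns a one-row data frame.
#' @export
align_read <- function(idx, read) align_reads(idx, read)

#' Code alignment records
#'
#' Fast mode serialises each record directly (an unmatched read is a single
#' 0 byte; a matched read is `m1..m4`, the direction byte and a 4-byte
#' pointer). Slow mode codes the same bytes bit-wise under a direct context
#' model of the parse state, the previous bits of the current byte, and the
#' high 6 bits of the previous byte (dropped for the two low pointer bytes).
#'
#' @param aln alignment data frame from [align_reads()].
#' @param slow use the context-modelled coder.
#' @return raw vector.
#' @export
code_alignments <- function(aln, slow = FALSE) .c_code_alignments(aln, slow)

#' @rdname code_alignments
#' @param data raw vector from [code_alignments()].
#' @param n number of records.
#' @export
decode_alignments <- function(data, n, slow = FALSE) {
  as.data.frame(.c_decode_alignments(data, as.integer(n), slow),
                stringsAsFactors = FALSE)
}
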