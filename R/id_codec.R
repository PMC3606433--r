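#' Tokenise a sequence identifier
#'
#' Splits an identifier into typed tokens by maximal munch: letter runs
#' (`ALPHA`), leading-zero runs (`LEADING_ZERO_NUMERIC`), other digit runs
#' (`NUMERIC`) and runs of everything else including spaces (`PUNCT`).
#' Concatenating the token values reproduces the identifier byte for byte.
#'
#' @param id identifier string (no newline).
#' @param alnum also recognise `[A-Za-z][A-Za-z0-9]*` alphanumeric tokens
#'   (off by default).
#' @return data frame with columns `slot`, `type`, `value`.
#' @examples
#' tokenize_id("@SRR062634.3364")
#' @export
tokenize_id <- function(id, alnum = FALSE) {
  as.data.frame(.c_tokenize_id(id, alnum), stringsAsFactors = FALSE)
}

#' @rdname tokenize_id
#' @param tokens data frame as returned by [tokenize_id()].
#' @export
detokenize_id <- function(tokens) paste(tokens$value, collapse = "")

#' Diff an identifier against the previous one, token by token
#'
#' Tokens equal in type and value become `MATCH`; numeric tokens whose value
#' grew by 0..255 become `DELTA` with the difference as value; all other
#' tokens are kept literally.
#'
#' @param prev,cur identifier strings.
#' @return data frame with columns `slot`, `type`, `value`.
#' @export
diff_tokens <- function(prev, cur) {
  as.data.frame(.c_diff_tokens(prev, cur), stringsAsFactors = FALSE)
}

#' Compress a stream of identifiers
#'
#' `tokenized` mode codes token streams against the previous identifier with
#' one model set per token slot; `string_delta` codes a common-prefix length
#' and literal suffix per identifier, which suits base-64 style names whose
#' token structure is unstable.
#'
#' @param ids character vector of identifiers.
#' @param mode `"tokenized"` or `"string_delta"`.
#' @return raw vector.
#' @export
encode_id_stream <- function(ids, mode = c("tokenized", "string_delta")) {
  mode <- match.arg(mode)
  .c_id_encode(ids, mode == "string_delta")
}

#' @rdname encode_id_stream
#' @param data raw vector from [encode_id_stream()].
#' @param n number of identifiers.
#' @export
decode_id_stream <- function(data, n, mode = c("tokenized", "string_delta")) {
  mode <- match.arg(mode)
  .c_id_decode(data, as.integer(n), mode == "string_delta")
}

#' Line-delta encoding of consecutive identifiers
#'
#' Encodes the current identifier against the previous one as: go to `column`
#' (1-based), add `increment` to the decimal string found there, copy the
#' first `match_len` bytes of the adjusted line, then append `literal` and a
#' terminating 0. The `(column, increment)` pair maximising the match length
#' is chosen; increments above 255 are never stored (such lines fall back to
#' plain mismatch coding with `column = 0`).
#'
#' @param prev,cur identifier lines (no newline).
#' @return list with `column`, `increment`, `match_len`, `literal`,
#'   `terminator`.
#' @examples
#' fastqz_delta(
#'   "@SRR062634.2724180 HWI-EAS110_103327062:6:13:11133:11572/1",
#'   "@SRR062634.2724181 HWI-EAS110_103327062:6:13:11133:5630/1")
#' @export
fastqz_delta <- function(prev, cur) .c_fastqz_delta(prev, cur)

#' @rdname fastqz_delta
#' @param delta list as returned by [fastqz_delta()].
#' @return `fastqz_delta_apply()` reconstructs the current line.
#' @export
fastqz_delta_apply <- function(prev, delta) {
  .c_fastqz_delta_apply(prev, delta$column, delta$increment, delta$match_len,
                        delta$literal)
}

#' Line-delta identifier stream coding
#'
#' Serialises the per-line deltas of [fastqz_delta()]; in slow mode the bytes
#' are further coded by a context-mixing model (two direct and two indirect
#' byte-context models combined by a logistic mixer whose weights are selected
#' by the column number).
#'
#' @param ids character vector of identifier lines.
#' @param slow apply the context-mixing stage.
#' @return raw vector.
#' @export
encode_fastqz_ids <- function(ids, slow = FALSE) .c_fastqz_id_encode(ids, slow)

#' @rdname encode_fastqz_ids
#' @param data raw vector from [encode_fastqz_ids()].
#' @param n number of identifiers.
#' @export
decode_fastqz_ids <- function(data, n, slow = FALSE) {
  .c_fastqz_id_decode(data, as.integer(n), slow)
}
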