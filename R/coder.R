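#' Adaptive arithmetic coding of a symbol stream
#'
#' Codes integer symbols `0..alphabet_size-1` with an adaptive frequency model
#' (8-bit counters, +8 increment, halving at 255) addressed by the previous
#' `order` symbols, through a 32-bit byte-wise range coder. The coded length
#' approaches the information content of the stream: about
#' \eqn{\sum_i -\log_2 p_i} bits plus a small flush overhead.
#'
#' @param symbols integer vector of symbols in `0..alphabet_size-1`.
#' @param alphabet_size number of distinct symbols (2..64).
#' @param order context order: how many previous symbols address the model.
#' @return [rc_encode()] returns a raw vector; [rc_decode()] the symbol vector.
#' @examples
#' x <- sample(0:3, 1000, replace = TRUE)
#' stopifnot(identical(rc_decode(rc_encode(x, 4), 1000, 4), x))
#' @export
rc_encode <- function(symbols, alphabet_size, order = 0L) {
  .c_rc_encode(as.integer(symbols), as.integer(alphabet_size), as.integer(order))
}

#' @rdname rc_encode
#' @param data raw vector produced by [rc_encode()] with identical parameters.
#' @param n number of symbols to decode.
#' @export
rc_decode <- function(data, n, alphabet_size, order = 0L) {
  .c_rc_decode(data, as.integer(n), as.integer(alphabet_size), as.integer(order))
}

#' Logistic mixing of bit predictions
#'
#' Combines probabilities by weighted averaging in the logistic domain:
#' `squash(sum(w * stretch(p)))` with `stretch(p) = log(p/(1-p))` and `squash`
#' its inverse. With all inputs equal and weights summing to 1 the mix returns
#' the common input unchanged.
#'
#' @param p probabilities that the next bit is 1, each in (0,1).
#' @param weights mixing weights, one per prediction.
#' @return the mixed probability.
#' @export
mix <- function(p, weights = rep(1 / length(p), length(p))) {
  stopifnot(length(p) >= 1, length(weights) == length(p), all(p > 0 & p < 1))
  squash(sum(weights * stretch(p)))
}

#' @rdname mix
#' @param x log-odds value(s).
#' @export
squash <- function(x) 1 / (1 + exp(-x))

#' @rdname mix
#' @export
stretch <- function(p) log(p / (1 - p))

#' One gradient step of the mixer weights
#'
#' Moves the weights to favour the predictions that were closer to the
#' observed bit (gradient descent on the coding loss in the stretch domain).
#'
#' @inheritParams mix
#' @param bit the observed bit (0 or 1).
#' @param rate learning rate in the stretch domain.
#' @return updated weight vector.
#' @export
mixer_update <- function(weights, p, bit, rate = 0.002) {
  pm <- mix(p, weights)
  weights + rate * (bit - pm) * stretch(p)
}

#' Match-model prediction
#'
#' While a match of `len` bits is live the next bit is predicted with
#' probability `1 - 1/len`; with no match (or a match shorter than 2 bits) the
#' prediction is the uninformed 0.5.
#'
#' @param len current match length in bits (0 for no match).
#' @return probability that the predicted bit is correct.
#' @export
match_predict <- function(len) {
  ifelse(len >= 2, 1 - 1 / len, 0.5)
}

#' Bit-history states
#'
#' Runs a bit sequence through the 8-bit history state machine used by the
#' indirect context models (last bit + saturating run length, capped at 40)
#' and returns the state after each bit.
#'
#' @param bits integer vector of 0/1.
#' @return integer vector of states (at most 256 distinct values).
#' @export
bit_history <- function(bits) .c_bit_history(as.integer(bits))
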