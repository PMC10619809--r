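#' Binary state indexing helpers
#'
#' Network states are encoded as integers in `0:(2^n - 1)`. Throughout the
#' package the *first* node of a node ordering occupies the least significant
#' bit of the state index, the second node the next bit, and so on. All
#' repertoires, TPMs and state records use this single convention.
#'
#' @param state integer state index (scalar), in `0:(2^n - 1)`.
#' @param n number of nodes.
#' @return `state_to_bits()` returns an integer vector of 0/1 of length `n`
#'   (element 1 = least significant bit); `bits_to_state()` its inverse.
#' @examples
#' state_to_bits(5L, 4)        # 1 0 1 0
#' bits_to_state(c(1, 0, 1, 0)) # 5
#' @export
state_to_bits <- function(state, n) {
  stopifnot(length(state) == 1L, state >= 0, state < 2^n)
  as.integer(bitwAnd(bitwShiftR(as.integer(state), 0:(n - 1L)), 1L))
}

#' @rdname state_to_bits
#' @param bits integer vector of 0/1.
#' @export
bits_to_state <- function(bits) {
  stopifnot(all(bits %in% c(0L, 1L)))
  as.integer(sum(as.integer(bits) * 2L^(seq_along(bits) - 1L)))
}

# All 2^n states as an n-column 0/1 matrix, row i = state i-1.
# Column j is node j (LSB first).
state_matrix <- function(n) {
  if (n == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  m <- matrix(0L, nrow = 2^n, ncol = n)
  s <- 0:(2^n - 1)
  for (j in seq_len(n)) m[, j] <- bitwAnd(bitwShiftR(s, j - 1L), 1L)
  m
}
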