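#' Coerce to a bit vector
#'
#' Object representations, codewords and decoded messages are plain integer
#' vectors over \{0, 1\}. `as_bits()` accepts such a vector, a logical vector,
#' or a character string like `"1100"` (whitespace is ignored, so
#' `"111 010 110 011"` also works).
#'
#' @param x Bits as an integer/logical vector or a character string.
#' @return An integer vector of 0s and 1s.
#' @examples
#' as_bits("1100")
#' as_bits(c(1, 0, 1))
#' @export
as_bits <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- strsplit(gsub("\\s", "", x), "")[[1]]
    if (length(x) && !all(x %in% c("0", "1"))) {
      stop("bit strings may only contain 0, 1 and whitespace", call. = FALSE)
    }
    return(as.integer(x))
  }
  if (is.logical(x)) {
    return(as.integer(x))
  }
  x <- as.integer(x)
  if (length(x) && !all(x %in% c(0L, 1L))) {
    stop("bits must all be 0 or 1", call. = FALSE)
  }
  x
}

#' Format a bit vector as a string
#'
#' @param bits Bit vector (see [as_bits()]).
#' @param block Optional block length; blocks are separated by spaces
#'   (e.g. `block = 3` prints a rate-1/3 codeword as `111 010 110 011`).
#' @return A character scalar.
#' @examples
#' format_bits(as_bits("111010110011"), block = 3)
#' @export
format_bits <- function(bits, block = NULL) {
  bits <- as_bits(bits)
  if (is.null(block) || length(bits) == 0L) {
    return(paste(bits, collapse = ""))
  }
  groups <- split(bits, ceiling(seq_along(bits) / block))
  paste(vapply(groups, paste, "", collapse = ""), collapse = " ")
}

#' Alternating object representation
#'
#' The Monte-Carlo studies use as ground truth an alternating sequence of 1s
#' and 0s beginning with 1 (e.g. `101010` for `K = 6`), standing in for the
#' representation a viewed object should evoke at IT.
#'
#' @param K Number of message bits (one bit enters the encoder per time step).
#' @return An integer bit vector of length `K`.
#' @examples
#' make_truth(6)
#' @export
make_truth <- function(K) {
  stopifnot(length(K) == 1L, K >= 1)
  rep_len(c(1L, 0L), K)
}

#' Hamming distance between two equal-length bit vectors
#'
#' The deviation between a decoded message and the representation the object
#' should have evoked: the number of positions at which the two disagree
#' (the zero-"norm" of their XOR).
#'
#' @param a,b Bit vectors of equal length.
#' @return Integer count of disagreeing positions.
#' @examples
#' hamming_distance(as_bits("1100"), as_bits("1110"))
#' @export
hamming_distance <- function(a, b) {
  a <- as_bits(a)
  b <- as_bits(b)
  if (length(a) != length(b)) {
    stop("bit vectors must have equal length", call. = FALSE)
  }
  sum(a != b)
}
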