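#' Build the state-machine trellis of a convolutional encoder
#'
#' The encoder register holds the L most recent message bits; a state is
#' labelled by the integer value of the register written most-recent-bit
#' first, so for L = 2 the labels are S0 = 00, S1 = 01, S2 = 10, S3 = 11
#' (most recent bit is the high-order digit). Each state has exactly two
#' outgoing transitions (input bit 0 or 1), each emitting an N-bit output
#' block, and — for L >= 1 — exactly two incoming transitions.
#'
#' @param spec A `ctor_generator` (or built-in name).
#' @return An object of class `ctor_trellis` with fields:
#'   \describe{
#'     \item{n_states}{2^L.}
#'     \item{next_state}{`n_states x 2` matrix; column u+1 holds the successor
#'       of each state under input bit u.}
#'     \item{output}{`n_states x 2` character matrix of emitted N-bit blocks.}
#'     \item{transitions}{A tibble with one row per transition
#'       (`from`, `input`, `to`, `output`), Fig.-style state diagram in
#'       tabular form.}
#'     \item{inc_prev, inc_input, inc_block}{incoming-transition tables used
#'       by the decoder.}
#'   }
#' @examples
#' build_trellis(simple_encoder())$transitions
#' @export
build_trellis <- function(spec) {
  spec <- ctor_encoder(spec)
  L <- spec$L
  N <- spec$N
  S <- 2L^L
  states <- 0:(S - 1L)

  # register bits of each state, most recent first: r_1 ... r_L
  reg <- if (L > 0) {
    t(matrix(
      vapply(states, function(s) as.integer(s %/% 2^((L - 1):0)) %% 2L,
             integer(L)),
      nrow = L
    ))
  } else {
    matrix(integer(0), nrow = 1L, ncol = 0L)
  }

  next_state <- matrix(0L, S, 2L)
  out_bits <- array(0L, dim = c(S, 2L, N))
  for (u in 0:1) {
    window <- cbind(u, reg) # (input, r_1, ..., r_L) = (b_k, ..., b_{k-L})
    out_bits[, u + 1L, ] <- window %*% t(spec$taps) %% 2L
    next_state[, u + 1L] <- if (L > 0) u * 2L^(L - 1L) + states %/% 2L else 0L
  }
  storage.mode(out_bits) <- "integer"
  output <- matrix("", S, 2L)
  for (u in 0:1) {
    output[, u + 1L] <- apply(
      matrix(out_bits[, u + 1L, ], nrow = S), 1L, paste, collapse = ""
    )
  }

  # incoming transitions per state, ordered by (predecessor label, input):
  # candidate tie-breaks in the decoder follow this ordering
  inc <- lapply(states, function(s) {
    hit <- which(next_state == s + 0L, arr.ind = TRUE)
    hit <- hit[order(hit[, "row"], hit[, "col"]), , drop = FALSE]
    hit
  })
  inc_prev <- t(vapply(inc, function(h) as.integer(h[, "row"] - 1L), integer(2)))
  inc_input <- t(vapply(inc, function(h) as.integer(h[, "col"] - 1L), integer(2)))

  # distinct output blocks and, per incoming transition, the block id
  blocks <- unique(matrix(out_bits, nrow = S * 2L))
  block_id <- matrix(match(
    apply(matrix(out_bits, nrow = S * 2L), 1L, paste, collapse = ","),
    apply(blocks, 1L, paste, collapse = ",")
  ), S, 2L)
  inc_block <- matrix(0L, S, 2L)
  for (j in 1:2) {
    inc_block[, j] <- block_id[cbind(inc_prev[, j] + 1L, inc_input[, j] + 1L)]
  }

  transitions <- tibble::tibble(
    from = rep(states, 2L),
    input = rep(0:1, each = S),
    to = as.integer(next_state),
    output = as.character(output)
  ) |> dplyr::arrange(.data$from, .data$input)

  structure(
    list(
      spec = spec, L = L, N = N, n_states = S,
      next_state = next_state, out_bits = out_bits, output = output,
      inc_prev = inc_prev, inc_input = inc_input,
      inc_block = inc_block, blocks = blocks,
      transitions = transitions
    ),
    class = "ctor_trellis"
  )
}

#' @export
print.ctor_trellis <- function(x, ...) {
  cat(sprintf(
    "<ctor_trellis>  encoder \"%s\": %d states, %d transitions, N = %d\n",
    x$spec$name, x$n_states, 2L * x$n_states, x$N
  ))
  if (x$n_states <= 8L) print(x$transitions)
  invisible(x)
}

#' Walk a trellis over a message
#'
#' Drives the state machine transition-by-transition from S0, returning the
#' visited states and the emitted codeword. Used to cross-check
#' [encode_bits()] (the two must agree on every input) and to recover the
#' state path of a decoded message.
#'
#' @param trellis A `ctor_trellis`.
#' @param message Bit vector.
#' @return A list with `states` (length K + 1, starting at 0) and
#'   `codeword` (length K*N).
#' @examples
#' trellis_path(build_trellis("simple"), "1100")$states # 0 2 3 1 0
#' @export
trellis_path <- function(trellis, message) {
  stopifnot(inherits(trellis, "ctor_trellis"))
  b <- as_bits(message)
  K <- length(b)
  states <- integer(K + 1L)
  cw <- integer(K * trellis$N)
  s <- 0L
  for (k in seq_len(K)) {
    u <- b[k]
    cw[((k - 1L) * trellis$N + 1L):(k * trellis$N)] <-
      trellis$out_bits[s + 1L, u + 1L, ]
    s <- trellis$next_state[s + 1L, u + 1L]
    states[k + 1L] <- s
  }
  list(states = states, codeword = cw)
}
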