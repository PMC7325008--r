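#' Exhaustive MAP decoding by enumeration
#'
#' A brute-force reference decoder: every one of the `2^K` candidate
#' messages is encoded, its full path probability scored (channel
#' log-likelihood of the received sequence plus, in MAP mode, the
#' transition-prior log-probabilities along its state path), and the
#' minimum-total-length candidate returned. Ties are broken toward the
#' message with the smallest value read as a binary integer (first bit most
#' significant). Scoring is direct — no dynamic programming — so the result
#' is an independent check on [viterbi_decode()].
#'
#' @param received Character vector of channel output symbols.
#' @param spec A `ctor_generator` (or built-in name).
#' @param channel A `ctor_channel` (or built-in name).
#' @param priors A `ctor_priors` for MAP scoring, or `NULL` for MLE.
#' @param max_bits Tractability guard: refuse messages longer than this.
#' @return A list with `message` (bit vector), `metric` (its total path
#'   length) and `unique` (`TRUE` if the optimum was strict).
#' @export
exhaustive_map_decode <- function(received, spec, channel, priors = NULL,
                                  max_bits = 16L) {
  spec <- ctor_encoder(spec)
  channel <- ctor_channel(channel)
  sym <- match(as.character(received), channel$alphabet)
  if (anyNA(sym)) {
    stop("received symbols must belong to the channel output alphabet",
      call. = FALSE
    )
  }
  if (length(sym) %% spec$N != 0L) {
    stop("received length must be divisible by N (framing error)",
      call. = FALSE
    )
  }
  K <- length(sym) %/% spec$N
  if (K > max_bits) {
    stop(sprintf("exhaustive search refused for K = %d > %d", K, max_bits),
      call. = FALSE
    )
  }

  # all messages in increasing integer order (first bit = MSB), so the
  # running argmin with strict improvement realises the tie-break
  msgs <- as.matrix(expand.grid(rep(list(0:1), K))[, K:1, drop = FALSE])
  n_msg <- nrow(msgs)

  # codewords via the generator matrix (mod-2 convolution), n_msg x K*N
  L <- spec$L
  N <- spec$N
  G <- matrix(0L, K, K * N)
  for (i in seq_len(K)) {
    for (k in i:min(K, i + L)) {
      G[i, ((k - 1L) * N + 1L):(k * N)] <- spec$taps[, k - i + 1L]
    }
  }
  cw <- (msgs %*% G) %% 2L

  nll0 <- -log(channel$pmf[1L, sym])
  nll1 <- -log(channel$pmf[2L, sym])
  d <- nll1 - nll0
  d[is.nan(d)] <- 0 # Inf - Inf: both bits impossible, handled below
  scores <- as.numeric(sum(nll0) + cw %*% d)
  both_inf <- is.infinite(nll0) & is.infinite(nll1)
  if (any(both_inf)) scores <- rep(Inf, n_msg)

  if (!is.null(priors)) {
    stopifnot(inherits(priors, "ctor_priors"))
    # state after k inputs, label = most recent bit high-order
    states <- matrix(0L, n_msg, K + 1L)
    if (L > 0) {
      for (k in seq_len(K)) {
        lo <- max(1L, k - L + 1L)
        w <- 2L^((k - lo):0)
        states[, k + 1L] <- as.integer(
          msgs[, lo:k, drop = FALSE] %*% rev(w) * 2L^(L - (k - lo + 1L))
        )
      }
    }
    for (k in seq_len(K)) {
      scores <- scores -
        log(priors$probs[cbind(states[, k] + 1L, states[, k + 1L] + 1L)])
    }
  }

  best <- which.min(scores) # first minimum = smallest message integer
  list(
    message = as.integer(msgs[best, ]),
    metric = scores[best],
    unique = sum(abs(scores - scores[best]) < 1e-9) == 1L
  )
}
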