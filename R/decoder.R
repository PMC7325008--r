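#' Branch metric of a trellis transition
#'
#' The length assigned to a candidate transition at one decoding stage:
#' `lambda = -ln P[b_{k+1} | b_k] - sum_j ln P[r_j | output bit j]`. With
#' `priors = NULL` the decoder operates in maximum-likelihood mode and the
#' (constant) uniform-prior term is omitted; pass a [prior_model()] to
#' include the a-priori term of MAP decoding. A zero channel probability
#' yields `Inf` (the transition is effectively forbidden).
#'
#' @param block Received block: `N` symbols from the channel output
#'   alphabet.
#' @param from,to State labels of the transition (integers in
#'   `0..2^L - 1`).
#' @param trellis A `ctor_trellis`.
#' @param channel A `ctor_channel` (or built-in name).
#' @param priors A `ctor_priors`, or `NULL` for MLE mode.
#' @return The branch metric in nats (non-negative, possibly `Inf`).
#' @examples
#' tr <- build_trellis("simple")
#' branch_metric(c("D", "C", "A"), 0, 0, tr, "dispersive") # 4.828...
#' branch_metric(c("D", "C", "A"), 0, 2, tr, "dispersive") # 4.423...
#' @export
branch_metric <- function(block, from, to, trellis, channel, priors = NULL) {
  stopifnot(inherits(trellis, "ctor_trellis"))
  channel <- ctor_channel(channel)
  if (length(block) != trellis$N) {
    stop("received block must contain exactly N symbols", call. = FALSE)
  }
  sym <- match(as.character(block), channel$alphabet)
  if (anyNA(sym)) {
    stop("received symbols must belong to the channel output alphabet",
      call. = FALSE
    )
  }
  input <- which(trellis$next_state[from + 1L, ] == to) - 1L
  if (length(input) == 0L) {
    stop(sprintf("S%d -> S%d is not a valid trellis transition", from, to),
      call. = FALSE
    )
  }
  input <- input[1L]
  out <- trellis$out_bits[from + 1L, input + 1L, ]
  lik <- channel$pmf[cbind(out + 1L, sym)]
  metric <- -sum(log(lik))
  if (!is.null(priors)) {
    stopifnot(inherits(priors, "ctor_priors"))
    metric <- metric - log(priors$probs[from + 1L, to + 1L])
  }
  metric
}

#' Viterbi MAP/MLE sequence estimation
#'
#' Untangles a received symbol sequence into the message most likely to
#' have produced it. The decoder runs the Viterbi algorithm on the encoder
#' trellis: starting from the known initial state S0 (path metric 0, all
#' other states excluded), each stage keeps one survivor per state — the
#' incoming transition minimising the accumulated path length
#' `Gamma(next) = Gamma(prev) + lambda(prev, next)` — and traceback begins
#' from the terminal state with the smallest final metric. Ties (between
#' survivor candidates and between terminal states) are broken toward the
#' smaller predecessor/terminal state label, making decisions reproducible
#' even on a channel that carries no information. The trellis is not
#' terminated: no tail bits are assumed, and all `2^L` terminal states
#' compete.
#'
#' @param received Character vector of channel output symbols, length a
#'   multiple of `N`.
#' @param trellis A `ctor_trellis`.
#' @param channel A `ctor_channel` (or built-in name).
#' @param priors A `ctor_priors` for MAP decoding, or `NULL` for MLE
#'   (uniform priors, constant term omitted).
#' @return An object of class `ctor_decoded`:
#'   \describe{
#'     \item{message}{the decoded K-bit message `b-hat`.}
#'     \item{codeword_estimate}{its re-encoding `s-hat` (length K*N).}
#'     \item{final_metric}{accumulated path length of the winning path.}
#'     \item{path}{visited states S0 -> ... (length K + 1).}
#'     \item{survivor_prev}{K x 2^L matrix of winning predecessors per
#'       stage/state, for trellis-diagram rendering.}
#'     \item{gamma}{K x 2^L matrix of per-stage path metrics.}
#'   }
#' @examples
#' tr <- build_trellis("simple")
#' dec <- viterbi_decode(unlist(strsplit(c("DCA", "DDB", "DDA", "DDD"), "")),
#'   tr, "dispersive"
#' )
#' format_bits(dec$message) # "1100"
#' @export
viterbi_decode <- function(received, trellis, channel, priors = NULL) {
  stopifnot(inherits(trellis, "ctor_trellis"))
  channel <- ctor_channel(channel)
  sym <- match(as.character(received), channel$alphabet)
  if (anyNA(sym)) {
    stop("received symbols must belong to the channel output alphabet",
      call. = FALSE
    )
  }
  if (length(sym) %% trellis$N != 0L) {
    stop("received length must be divisible by N (framing error)",
      call. = FALSE
    )
  }
  res <- viterbi_batch(
    matrix(sym, nrow = 1L), trellis, channel, priors,
    keep_trace = TRUE
  )
  K <- length(sym) %/% trellis$N
  message <- as.integer(res$messages[1L, ])
  structure(
    list(
      message = message,
      codeword_estimate = encode_bits(message, trellis$spec),
      final_metric = res$final_metric[1L],
      terminal_state = res$terminal[1L],
      path = trellis_path(trellis, message)$states,
      survivor_prev = res$survivor_prev,
      gamma = res$gamma,
      mode = if (is.null(priors)) "MLE" else "MAP",
      K = K, trellis = trellis, channel = channel
    ),
    class = "ctor_decoded"
  )
}

#' @export
print.ctor_decoded <- function(x, ...) {
  cat(sprintf(
    "<ctor_decoded>  %s, K = %d, final path metric %.4f\n",
    x$mode, x$K, x$final_metric
  ))
  cat("  b-hat: ", format_bits(x$message), "\n", sep = "")
  cat("  s-hat: ", format_bits(x$codeword_estimate, block = x$trellis$N),
    "\n",
    sep = ""
  )
  cat("  path : ", paste0("S", x$path, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Tidy the per-stage survivor bookkeeping of a decode
#'
#' @param x A `ctor_decoded`.
#' @param ... Unused.
#' @return A tibble with one row per (stage, state): the winning
#'   predecessor and the accumulated path metric, suitable for rendering a
#'   trellis diagram.
#' @method tidy ctor_decoded
#' @export
tidy.ctor_decoded <- function(x, ...) {
  S <- x$trellis$n_states
  tibble::tibble(
    stage = rep(seq_len(x$K), each = S),
    state = rep(0:(S - 1L), x$K),
    survivor_prev = as.integer(t(x$survivor_prev)),
    metric = as.numeric(t(x$gamma)),
    on_path = .data$state == rep(x$path[-1L], each = S)
  )
}

# Vectorised Viterbi over a batch of received sequences.
#
# sym_idx: n_trials x (K*N) matrix of 1-based symbol indices.
# Returns decoded messages (n_trials x K), final metrics and terminal
# states; with keep_trace = TRUE (single-trial use) also per-stage
# survivors and path metrics.
viterbi_batch <- function(sym_idx, trellis, channel, priors = NULL,
                          keep_trace = FALSE) {
  N <- trellis$N
  S <- trellis$n_states
  n <- nrow(sym_idx)
  K <- ncol(sym_idx) %/% N
  nll <- -log(channel$pmf) # 2 x |alphabet|, -log(0) = Inf

  pn <- matrix(0, S, 2L)
  shift <- 0
  if (!is.null(priors)) {
    stopifnot(inherits(priors, "ctor_priors"))
    for (j in 1:2) {
      pn[, j] <- -log(priors$probs[cbind(trellis$inc_prev[, j] + 1L, seq_len(S))])
    }
    # subtract the global minimum prior term: a per-stage constant that
    # cannot change any decision, but keeps exactly-uniform priors bitwise
    # identical to MLE (no float noise on tied paths); restored below
    if (any(is.finite(pn))) {
      shift <- min(pn[is.finite(pn)])
      pn <- pn - shift
    }
  }

  gamma <- matrix(Inf, n, S)
  gamma[, 1L] <- 0
  choices <- array(1L, dim = c(n, S, K))
  trace_prev <- if (keep_trace) matrix(0L, K, S) else NULL
  trace_gamma <- if (keep_trace) matrix(0, K, S) else NULL
  nb <- nrow(trellis$blocks)
  bm <- matrix(0, n, nb)

  for (k in seq_len(K)) {
    cols <- ((k - 1L) * N + 1L):(k * N)
    for (b in seq_len(nb)) {
      acc <- 0
      for (j in seq_len(N)) {
        acc <- acc + nll[trellis$blocks[b, j] + 1L, sym_idx[, cols[j]]]
      }
      bm[, b] <- acc
    }
    new_gamma <- matrix(0, n, S)
    for (s in seq_len(S)) {
      c1 <- gamma[, trellis$inc_prev[s, 1L] + 1L] +
        bm[, trellis$inc_block[s, 1L]] + pn[s, 1L]
      c2 <- gamma[, trellis$inc_prev[s, 2L] + 1L] +
        bm[, trellis$inc_block[s, 2L]] + pn[s, 2L]
      take2 <- c2 < c1 # ties -> candidate 1 (smaller predecessor label)
      new_gamma[, s] <- ifelse(take2, c2, c1)
      choices[, s, k] <- 1L + take2
    }
    gamma <- new_gamma
    if (keep_trace) {
      trace_prev[k, ] <- trellis$inc_prev[cbind(seq_len(S), choices[1L, , k])]
      trace_gamma[k, ] <- gamma[1L, ] + k * shift
    }
  }

  terminal <- max.col(-gamma, ties.method = "first") - 1L
  final_metric <- gamma[cbind(seq_len(n), terminal + 1L)] + K * shift
  messages <- matrix(0L, n, K)
  state <- terminal
  rows <- seq_len(n)
  for (k in rev(seq_len(K))) {
    ch <- choices[cbind(rows, state + 1L, k)]
    messages[, k] <- trellis$inc_input[cbind(state + 1L, ch)]
    state <- trellis$inc_prev[cbind(state + 1L, ch)]
  }

  list(
    messages = messages, final_metric = final_metric, terminal = terminal,
    survivor_prev = trace_prev, gamma = trace_gamma
  )
}
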