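#' Transition-prior model over trellis states
#'
#' The memory circuitry feeds the decoder a-priori probabilities
#' `P[b_{k+1} | b_k]` over trellis state transitions. A prior model stores a
#' `2^L x 2^L` matrix whose row i gives the probabilities of the two valid
#' successors of state i (invalid transitions have probability zero). Rows
#' are floored at `floor` on valid transitions and renormalised, so that a
#' transition never observed in memory remains possible rather than being
#' hard-forbidden.
#'
#' @param probs `2^L x 2^L` matrix of transition probabilities (only entries
#'   on valid trellis transitions may be positive). If `NULL`, uniform
#'   priors (1/2 per valid successor) are returned.
#' @param trellis A `ctor_trellis` defining the valid transitions.
#' @param floor Minimum probability applied to valid transitions before
#'   renormalisation.
#' @return An object of class `ctor_priors` with fields `probs`, `floor`
#'   and `n_states`.
#' @seealso [estimate_priors()], [uniform_priors()]
#' @export
prior_model <- function(probs, trellis, floor = 1e-6) {
  stopifnot(inherits(trellis, "ctor_trellis"), floor >= 0, floor < 0.5)
  S <- trellis$n_states
  valid <- matrix(FALSE, S, S)
  valid[cbind(rep(seq_len(S), 2L), as.integer(trellis$next_state) + 1L)] <- TRUE
  if (is.null(probs)) {
    probs <- matrix(0, S, S)
    probs[valid] <- 0.5
  } else {
    probs <- as.matrix(probs)
    stopifnot(all(dim(probs) == c(S, S)))
    if (any(probs < 0) || any(probs[!valid] != 0)) {
      stop("priors must be non-negative and zero off the valid transitions",
        call. = FALSE
      )
    }
  }
  # floor + renormalise each row over its two valid successors; a row with
  # no mass (unobserved state, floor = 0) falls back to uniform
  probs[valid] <- pmax(probs[valid], floor)
  empty <- rowSums(probs) == 0
  if (any(empty)) probs[valid & matrix(empty, S, S)] <- 0.5
  probs <- probs / rowSums(probs)
  dimnames(probs) <- state_dimnames(S)
  structure(
    list(probs = probs, floor = floor, n_states = S),
    class = "ctor_priors"
  )
}

#' @rdname prior_model
#' @export
uniform_priors <- function(trellis, floor = 1e-6) {
  prior_model(NULL, trellis, floor = floor)
}

state_dimnames <- function(S) {
  labels <- paste0("S", 0:(S - 1L))
  list(from = labels, to = labels)
}

#' @export
print.ctor_priors <- function(x, ...) {
  cat(sprintf(
    "<ctor_priors>  %d states, floor = %g\n", x$n_states, x$floor
  ))
  if (x$n_states <= 8L) print(round(x$probs, 4))
  invisible(x)
}

#' Tidy a prior model into a transition tibble
#'
#' @param x A `ctor_priors`.
#' @param ... Unused.
#' @return A tibble with one row per valid transition
#'   (`from`, `to`, `prior`).
#' @method tidy ctor_priors
#' @export
tidy.ctor_priors <- function(x, ...) {
  idx <- which(x$probs > 0, arr.ind = TRUE)
  tibble::tibble(
    from = idx[, 1L] - 1L,
    to = idx[, 2L] - 1L,
    prior = x$probs[idx]
  ) |> dplyr::arrange(.data$from, .data$to)
}

#' Estimate transition priors from a decoded bit stream
#'
#' Memory estimates the a-priori transition probabilities by sliding an
#' L-bit window along the stream (stride 1) and counting how often each
#' state follows each other state. A stream-order window holds the older
#' bit first; the trellis labels states most-recent-bit first, so each
#' window is reversed before being read as a state label (the stream window
#' `10` is state S1 = 01 for L = 2). Row counts are normalised by the
#' occurrences of the predecessor state among non-terminal positions, then
#' floored and renormalised via [prior_model()]. States never observed get
#' uniform priors over their valid successors.
#'
#' @param stream Bit vector (or bit string) of at least `L + 1` bits.
#' @param trellis A `ctor_trellis` (its `L` sets the window length).
#' @param floor Probability floor on valid transitions.
#' @return A `ctor_priors`.
#' @examples
#' tr <- build_trellis("simple")
#' p <- estimate_priors("11001110", tr, floor = 0)
#' p$probs["S3", "S1"] # 2/3
#' @export
estimate_priors <- function(stream, trellis, floor = 1e-6) {
  stopifnot(inherits(trellis, "ctor_trellis"))
  b <- as_bits(stream)
  L <- trellis$L
  S <- trellis$n_states
  if (length(b) < L + 1L) {
    stop("stream must contain at least L + 1 bits", call. = FALSE)
  }
  # state at window position k: bits b_k..b_{k+L-1}, newest (b_{k+L-1}) as
  # the high-order digit of the register label
  n_win <- length(b) - L + 1L
  states <- integer(n_win)
  if (L > 0) {
    W <- stats::embed(b, L) # row k = (b_{k+L-1}, ..., b_k): newest first
    states <- as.integer(W %*% 2L^((L - 1L):0))
  }
  counts <- matrix(0, S, S)
  if (n_win >= 2L) {
    pairs <- table(
      factor(states[-n_win], levels = 0:(S - 1L)),
      factor(states[-1L], levels = 0:(S - 1L))
    )
    counts <- unclass(pairs)
  }
  seen <- rowSums(counts) > 0
  probs <- matrix(0, S, S)
  probs[seen, ] <- counts[seen, , drop = FALSE] / rowSums(counts)[seen]
  # unseen states: leave zero; prior_model floors valid transitions, giving
  # them a uniform row after renormalisation
  prior_model(zero_off_valid(probs, trellis), trellis, floor = floor)
}

# counted transitions are always valid (consecutive windows share L-1 bits),
# but guard against degenerate L = 0 where every window maps to state 0
zero_off_valid <- function(probs, trellis) {
  S <- trellis$n_states
  valid <- matrix(FALSE, S, S)
  valid[cbind(rep(seq_len(S), 2L), as.integer(trellis$next_state) + 1L)] <- TRUE
  probs[!valid] <- 0
  probs
}
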