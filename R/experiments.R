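derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Monte-Carlo recognition experiment across message lengths and channels
#'
#' For each combination of message length `K` and channel, the alternating
#' truth representation is encoded, transmitted `n_trials` times with fresh
#' channel draws, Viterbi-decoded in MLE mode (uniform priors), and the
#' four recognition metrics computed. One master seed spawns a substream
#' per (encoder, K) cell that is shared across channels, so channel
#' comparisons are matched (common random numbers).
#'
#' @param encoder Encoder name (`"simple"`, `"complex"`) or a
#'   `ctor_generator`.
#' @param channels Character vector of built-in channel names and/or a list
#'   of `ctor_channel` objects.
#' @param K Message lengths to sweep (even values keep the alternating
#'   pattern balanced).
#' @param n_trials Trials per cell.
#' @param seed Master RNG seed.
#' @param c1 Tolerance of the approximate category rate.
#' @param weights Readout weights (default all ones, per K).
#' @return A tibble of class `ctor_experiment`, one row per channel x K:
#'   columns `encoder`, `channel`, `K`, `n_trials`, `seed`, `bcr`, `scr`,
#'   `ccr`, `accr`, `c1`.
#' @examples
#' run_recognition_experiment(K = c(6, 12), n_trials = 200, seed = 42)
#' @export
run_recognition_experiment <- function(encoder = "simple",
                                       channels = c("dispersive", "less_dispersive"),
                                       K = c(6, 12, 24, 36, 48, 60),
                                       n_trials = 1e4,
                                       seed = 1,
                                       c1 = 1,
                                       weights = NULL) {
  spec <- ctor_encoder(encoder)
  trellis <- build_trellis(spec)
  if (!is.list(channels)) channels <- as.list(channels)
  channels <- lapply(channels, ctor_channel)
  cell_seeds <- derive_seeds(seed, length(K))

  rows <- purrr::map(seq_along(K), function(i) {
    k <- K[i]
    truth <- make_truth(k)
    cw <- encode_bits(truth, spec)
    w <- weights %||% rep(1, k)
    purrr::map(channels, function(ch) {
      set.seed(cell_seeds[i]) # same draws for every channel: matched seeds
      sym <- transmit_idx(cw, ch, n_trials = n_trials)
      msgs <- viterbi_batch(sym, trellis, ch)$messages
      trials <- trial_records(truth, msgs, weights = w)
      dplyr::bind_cols(
        tibble::tibble(
          encoder = spec$name, channel = ch$name, K = k,
          seed = seed
        ),
        recognition_metrics(trials, c1 = c1)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  out <- dplyr::relocate(rows, "n_trials", .after = "K")
  class(out) <- c("ctor_experiment", class(out))
  out
}

#' Iterative MLE-versus-MAP decoding comparison
#'
#' Repeatedly transmits the same encoded object and decodes it under two
#' schemes with matched per-iteration channel draws:
#'
#' * MLE — uniform transition priors at every iteration;
#' * MAP — priors start uniform and, from the second iteration on, are
#'   re-estimated (via [estimate_priors()]) from the previous iteration's
#'   decoded stream only (or, optionally, from its compressed memory
#'   representation, or accumulated over all past iterations).
#'
#' Per iteration the trace records the bit correct rate `1 - d/KM`, the
#' exact-recovery indicator, the per-bit correctness (kymograph rows) and,
#' for MAP, the prior matrix in force.
#'
#' @param K Message length (default 60).
#' @param n_trials Number of iterations (default 1000).
#' @param encoder Encoder name or `ctor_generator`.
#' @param channel Channel name or `ctor_channel`.
#' @param seed Master RNG seed.
#' @param prior_floor Probability floor applied to estimated priors.
#' @param prior_source `"decoded"` (default) estimates priors from the raw
#'   decoded stream; `"compressed"` first compresses the stream via
#'   [compress_memory()] with `interleaver`.
#' @param interleaver A `ctor_interleaver`, required for
#'   `prior_source = "compressed"`.
#' @param accumulate If `TRUE`, priors are estimated from the
#'   concatenation of all past decoded streams instead of the previous
#'   iteration only.
#' @param weights Readout weights (default all ones).
#' @param c1 Tolerance of the approximate category rate.
#' @return An object of class `ctor_map_mle` with fields:
#'   \describe{
#'     \item{iterations}{tibble (`scheme`, `iteration`, `bcr`, `scr`).}
#'     \item{bit_correct}{list of two `n_trials x K` logical matrices
#'       (kymographs).}
#'     \item{priors_trace}{tibble of the MAP prior on each valid transition
#'       at each iteration.}
#'     \item{summary}{tibble of scheme-wise mean metrics.}
#'   }
#' @examples
#' run_map_vs_mle(K = 12, n_trials = 50, seed = 7)$summary
#' @export
run_map_vs_mle <- function(K = 60,
                           n_trials = 1000,
                           encoder = "simple",
                           channel = "dispersive",
                           seed = 1,
                           prior_floor = 1e-6,
                           prior_source = c("decoded", "compressed"),
                           interleaver = NULL,
                           accumulate = FALSE,
                           weights = NULL,
                           c1 = 1) {
  prior_source <- match.arg(prior_source)
  if (prior_source == "compressed" && is.null(interleaver)) {
    stop("prior_source = \"compressed\" needs an interleaver", call. = FALSE)
  }
  spec <- ctor_encoder(encoder)
  trellis <- build_trellis(spec)
  ch <- ctor_channel(channel)
  truth <- make_truth(K)
  cw <- encode_bits(truth, spec)
  w <- weights %||% rep(1, K)
  iter_seeds <- derive_seeds(seed, n_trials)

  decode_run <- function(map_mode) {
    msgs <- matrix(0L, n_trials, K)
    prior_rows <- if (map_mode) vector("list", n_trials) else NULL
    priors <- if (map_mode) uniform_priors(trellis, floor = prior_floor)
    history <- integer(0)
    for (t in seq_len(n_trials)) {
      set.seed(iter_seeds[t]) # matched draws across the two schemes
      sym <- transmit_idx(cw, ch, n_trials = 1L)
      msgs[t, ] <- viterbi_batch(
        matrix(sym, nrow = 1L), trellis, ch,
        priors = priors
      )$messages[1L, ]
      if (map_mode) {
        prior_rows[[t]] <- priors$probs
        stream <- if (accumulate) {
          history <- c(history, msgs[t, ])
          history
        } else {
          msgs[t, ]
        }
        if (prior_source == "compressed") {
          stream <- compress_memory(stream, interleaver)$bits
        }
        priors <- estimate_priors(stream, trellis, floor = prior_floor)
      }
    }
    list(msgs = msgs, prior_rows = prior_rows)
  }

  mle <- decode_run(map_mode = FALSE)
  map <- decode_run(map_mode = TRUE)

  per_iter <- function(msgs, scheme) {
    trials <- trial_records(truth, msgs, weights = w)
    tibble::tibble(
      scheme = scheme,
      iteration = trials$trial,
      bcr = 1 - trials$deviation / K,
      scr = as.integer(trials$deviation == 0L),
      decoded_score = trials$decoded_score,
      truth_score = trials$truth_score
    )
  }
  iterations <- dplyr::bind_rows(
    per_iter(mle$msgs, "MLE"),
    per_iter(map$msgs, "MAP")
  )

  truth_mat <- matrix(truth, n_trials, K, byrow = TRUE)
  bit_correct <- list(MLE = mle$msgs == truth_mat, MAP = map$msgs == truth_mat)

  valid <- which(prior_valid_mask(trellis), arr.ind = TRUE)
  valid <- valid[order(valid[, 1L], valid[, 2L]), , drop = FALSE]
  priors_trace <- purrr::map(seq_len(n_trials), function(t) {
    p <- map$prior_rows[[t]]
    tibble::tibble(
      iteration = t,
      from = valid[, 1L] - 1L,
      to = valid[, 2L] - 1L,
      prior = p[valid]
    )
  }) |> purrr::list_rbind()

  summary <- iterations |>
    dplyr::group_by(.data$scheme) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      bcr = mean(.data$bcr),
      scr = mean(.data$scr),
      ccr = mean(.data$decoded_score == .data$truth_score),
      accr = mean(abs(.data$decoded_score - .data$truth_score) <= c1),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$scheme)) # MLE before MAP

  structure(
    list(
      iterations = iterations[, c("scheme", "iteration", "bcr", "scr")],
      bit_correct = bit_correct,
      priors_trace = priors_trace,
      summary = summary,
      config = list(
        K = K, n_trials = n_trials, encoder = spec$name, channel = ch$name,
        seed = seed, prior_floor = prior_floor, prior_source = prior_source,
        accumulate = accumulate, c1 = c1
      )
    ),
    class = "ctor_map_mle"
  )
}

prior_valid_mask <- function(trellis) {
  S <- trellis$n_states
  valid <- matrix(FALSE, S, S)
  valid[cbind(rep(seq_len(S), 2L), as.integer(trellis$next_state) + 1L)] <- TRUE
  valid
}

#' @export
print.ctor_map_mle <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<ctor_map_mle>  K = %d, %d iterations, encoder \"%s\", channel \"%s\", seed %s\n",
    cfg$K, cfg$n_trials, cfg$encoder, cfg$channel, format(cfg$seed)
  ))
  print(x$summary)
  invisible(x)
}

#' @method tidy ctor_map_mle
#' @export
tidy.ctor_map_mle <- function(x, ...) x$iterations

#' @method glance ctor_map_mle
#' @export
glance.ctor_map_mle <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(
      names_from = "scheme",
      values_from = c("bcr", "scr", "ccr", "accr"),
      names_glue = "{tolower(scheme)}_{.value}",
      id_cols = "n_trials"
    )
}

#' Mean MAP prior per transition over a run
#'
#' @param x A `ctor_map_mle`.
#' @param drop_first Drop the (uniform) first-iteration priors.
#' @return A tibble (`from`, `to`, `prior`) of iteration-averaged priors.
#' @export
mean_priors <- function(x, drop_first = TRUE) {
  stopifnot(inherits(x, "ctor_map_mle"))
  tr <- x$priors_trace
  if (drop_first) tr <- dplyr::filter(tr, .data$iteration > 1L)
  tr |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(prior = mean(.data$prior), .groups = "drop")
}
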