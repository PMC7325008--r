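#' Attentional gain modulation of firing rates
#'
#' Attention acts multiplicatively on the resting firing rate of each unit:
#' the modulated rate of unit i at time t is `G_i(t) * s_i_rest(t)` with the
#' gain G strictly positive. Gains are often taken as Gaussian profiles
#' centred on the attended unit.
#'
#' @param rest_rates Numeric matrix (time x unit) of unmodulated firing
#'   rates, or a vector for a single unit.
#' @param gains Positive gain traces, same shape as `rest_rates` (a scalar
#'   or per-unit vector is recycled along time).
#' @return Modulated firing-rate traces, same shape as `rest_rates`.
#' @examples
#' attention_modulate(matrix(10, 5, 2), gains = c(1.5, 1))
#' @export
attention_modulate <- function(rest_rates, gains) {
  if (is.vector(rest_rates)) rest_rates <- matrix(rest_rates, ncol = 1L)
  if (is.vector(gains)) {
    gains <- if (length(gains) %in% c(1L, ncol(rest_rates))) {
      matrix(gains, nrow(rest_rates), ncol(rest_rates), byrow = TRUE)
    } else {
      matrix(gains, ncol = 1L)
    }
  }
  if (!all(dim(gains) == dim(rest_rates))) {
    stop("gain traces must match the shape of the rate traces", call. = FALSE)
  }
  if (any(gains <= 0)) {
    stop("attentional gains must be strictly positive", call. = FALSE)
  }
  gains * rest_rates
}

#' Rate-code a firing-rate trace into a binary symbol
#'
#' A unit contributes a 1 to the codeword if its integrated activity over a
#' time epoch of `duration` seconds exceeds its spike-count threshold
#' `alpha`, and 0 otherwise. The integral is computed by the trapezoidal
#' rule over an evenly sampled trace.
#'
#' @param rate_trace Numeric vector: firing rate (Hz) sampled evenly over
#'   the epoch.
#' @param alpha Positive threshold (expected spike count).
#' @param duration Epoch duration in seconds (e.g. 0.05 for a 50 ms window).
#' @return `1L` or `0L`.
#' @examples
#' rate_code(rep(10, 100), alpha = 0.4, duration = 0.05) # integral 0.5 > 0.4
#' @export
rate_code <- function(rate_trace, alpha, duration) {
  if (length(rate_trace) == 0L) {
    stop("rate trace is empty", call. = FALSE)
  }
  stopifnot(alpha > 0, duration > 0)
  integral <- if (length(rate_trace) == 1L) {
    rate_trace * duration
  } else {
    dt <- duration / (length(rate_trace) - 1L)
    sum((rate_trace[-1] + rate_trace[-length(rate_trace)]) / 2) * dt
  }
  as.integer(integral > alpha)
}

#' Rate-code a population of units
#'
#' Applies [rate_code()] column-wise to a (time x unit) matrix of modulated
#' firing rates, producing one codeword bit per unit.
#'
#' @param rate_traces Numeric matrix (time x unit).
#' @param alpha Per-unit positive thresholds (recycled if scalar).
#' @param duration Epoch duration in seconds.
#' @return Integer bit vector, one element per unit.
#' @export
rate_code_population <- function(rate_traces, alpha, duration) {
  alpha <- rep_len(alpha, ncol(rate_traces))
  vapply(
    seq_len(ncol(rate_traces)),
    function(i) rate_code(rate_traces[, i], alpha[i], duration),
    integer(1)
  )
}
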