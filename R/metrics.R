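#' Build a tibble of trial records
#'
#' One simulated viewing interval per row, holding everything the
#' recognition metrics need: the Hamming deviation between truth and
#' decoded message and the category readout of both. A single pass over
#' the decoded trials feeds all four metrics.
#'
#' @param truth Bit vector: the representation the object should evoke
#'   (recycled across trials).
#' @param decoded Integer matrix of decoded messages, one trial per row
#'   (or a single bit vector).
#' @param weights Readout weights (default all ones).
#' @return A tibble with columns `trial`, `deviation`, `km`,
#'   `truth_score`, `decoded_score`.
#' @export
trial_records <- function(truth, decoded, weights = NULL) {
  truth <- as_bits(truth)
  if (!is.matrix(decoded)) decoded <- matrix(as_bits(decoded), nrow = 1L)
  km <- length(truth)
  stopifnot(ncol(decoded) == km)
  weights <- weights %||% rep(1, km)
  stopifnot(length(weights) == km)
  dev <- as.integer(rowSums(decoded != matrix(truth, nrow(decoded), km,
    byrow = TRUE
  )))
  tibble::tibble(
    trial = seq_len(nrow(decoded)),
    deviation = dev,
    km = km,
    truth_score = sum(weights * truth),
    decoded_score = as.numeric(decoded %*% weights)
  )
}

check_trials <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0L) {
    stop("metrics are undefined on an empty trial set", call. = FALSE)
  }
  trials
}

#' Recognition-performance metrics
#'
#' Four rates summarise `T` simulated trials:
#'
#' * `bcr()` — bit correct rate, `1 - mean(deviation / KM)`; chance 1/2.
#' * `scr()` — symbol correct rate, the fraction of trials with the whole
#'   message recovered exactly; chance `1 / 2^KM`.
#' * `ccr()` — category correct rate, the fraction of trials whose readout
#'   score equals the truth's; nominal chance `1 / KM` (see
#'   [chance_levels()]).
#' * `accr()` — approximate category correct rate, the fraction with
#'   `|score difference| <= c1`; equals `ccr()` at `c1 = 0` and is
#'   non-decreasing in `c1`.
#'
#' @param trials A trial tibble from [trial_records()].
#' @param c1 Non-negative score tolerance for `accr()`.
#' @return A rate in `[0, 1]`.
#' @examples
#' tr <- trial_records("1100", rbind(c(1, 1, 0, 0), c(1, 0, 0, 0)))
#' bcr(tr)
#' scr(tr)
#' @export
bcr <- function(trials) {
  trials <- check_trials(trials)
  1 - mean(trials$deviation / trials$km)
}

#' @rdname bcr
#' @export
scr <- function(trials) {
  trials <- check_trials(trials)
  mean(trials$deviation == 0L)
}

#' @rdname bcr
#' @export
ccr <- function(trials) {
  trials <- check_trials(trials)
  mean(trials$decoded_score == trials$truth_score)
}

#' @rdname bcr
#' @export
accr <- function(trials, c1 = 1) {
  if (c1 < 0) stop("c1 must be non-negative", call. = FALSE)
  trials <- check_trials(trials)
  mean(abs(trials$decoded_score - trials$truth_score) <= c1)
}

#' One-row metric summary of a trial set
#'
#' @param trials A trial tibble from [trial_records()].
#' @param c1 Score tolerance for the approximate category rate.
#' @return A one-row tibble with `n_trials`, `bcr`, `scr`, `ccr`, `accr`
#'   and `c1`.
#' @export
recognition_metrics <- function(trials, c1 = 1) {
  trials <- check_trials(trials)
  tibble::tibble(
    n_trials = nrow(trials),
    bcr = bcr(trials),
    scr = scr(trials),
    ccr = ccr(trials),
    accr = accr(trials, c1),
    c1 = c1
  )
}

#' Chance levels of the recognition metrics
#'
#' Reference chance performance for a KM-bit representation: BCR 1/2,
#' SCR `1 / 2^KM`, and the nominal chance CCR of `1 / KM` (the customary
#' one-over-categories figure; note an all-ones readout on KM bits
#' actually admits KM + 1 distinct score values, so this constant is a
#' label, not an enforced invariant).
#'
#' @param km Number of message bits.
#' @return A one-row tibble with `bcr`, `scr` and `ccr` chance levels.
#' @export
chance_levels <- function(km) {
  tibble::tibble(bcr = 0.5, scr = 1 / 2^km, ccr = 1 / km)
}
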