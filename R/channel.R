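#' Define a binary-input discrete memoryless channel
#'
#' The perturbation of the codeword on its way from V1 to IT is modelled as
#' a discrete memoryless channel: each codeword bit is independently mapped
#' to one of the output symbols according to a conditional pmf
#' `P[r = m | s = n]`. The pmf is a 2 x |r| table (rows: input bit 0 and 1)
#' whose rows must each sum to 1.
#'
#' @param pmf Numeric matrix with 2 rows and at least 2 columns; rows are
#'   validated to sum to 1 within `1e-12` (entries must be non-negative).
#' @param alphabet Output symbol labels (defaults to column names, else
#'   `A`, `B`, `C`, ...).
#' @param name Optional display name.
#' @return An object of class `ctor_channel` with fields `pmf`, `alphabet`
#'   and `name`.
#' @seealso [ctor_channel()] for the built-in channels, [transmit()],
#'   [conditional_entropy()].
#' @examples
#' channel_model(rbind(c(.4, .3, .2, .1), c(.1, .2, .3, .4)))
#' @export
channel_model <- function(pmf, alphabet = NULL, name = NULL) {
  pmf <- as.matrix(pmf)
  if (nrow(pmf) != 2L || ncol(pmf) < 2L) {
    stop("channel pmf must have 2 rows (input bit 0/1) and >= 2 columns",
      call. = FALSE
    )
  }
  if (any(pmf < 0)) {
    stop("channel pmf entries must be non-negative", call. = FALSE)
  }
  if (any(abs(rowSums(pmf) - 1) > 1e-12)) {
    stop("each channel pmf row must sum to 1", call. = FALSE)
  }
  alphabet <- alphabet %||% colnames(pmf) %||% LETTERS[seq_len(ncol(pmf))]
  stopifnot(length(alphabet) == ncol(pmf))
  dimnames(pmf) <- list(input = c("0", "1"), output = alphabet)
  structure(
    list(pmf = pmf, alphabet = alphabet, name = name %||% "custom"),
    class = "ctor_channel"
  )
}

#' Built-in discrete memoryless channels
#'
#' Three binary-input channels over the output alphabet \{A, B, C, D\} are
#' used throughout:
#'
#' * `"dispersive"`: `P[r | s = 0] = (0.4, 0.3, 0.2, 0.1)` and the reverse
#'   for `s = 1`; conditional entropy 1.846 bits.
#' * `"uniform"`: all entries 0.25 — a catastrophically bad channel carrying
#'   no information (conditional entropy 2 bits, its maximum).
#' * `"less_dispersive"`: `P[r | s = 0] = (0.65, 0.2, 0.1, 0.05)` and the
#'   reverse for `s = 1`; conditional entropy 1.416 bits.
#'
#' `identity_channel()` maps bit 0 to symbol `"0"` and bit 1 to `"1"` with
#' probability one (useful for noiseless round-trip checks).
#'
#' @param name `"dispersive"`, `"uniform"` or `"less_dispersive"`; a
#'   `ctor_channel` is passed through unchanged.
#' @return A `ctor_channel`.
#' @examples
#' ctor_channel("dispersive")
#' @export
ctor_channel <- function(name) {
  if (inherits(name, "ctor_channel")) return(name)
  name <- match.arg(name, c("dispersive", "uniform", "less_dispersive"))
  pmf <- switch(name,
    dispersive = rbind(c(0.4, 0.3, 0.2, 0.1), c(0.1, 0.2, 0.3, 0.4)),
    uniform = matrix(0.25, 2, 4),
    less_dispersive = rbind(c(0.65, 0.2, 0.1, 0.05), c(0.05, 0.1, 0.2, 0.65))
  )
  channel_model(pmf, alphabet = c("A", "B", "C", "D"), name = name)
}

#' @rdname ctor_channel
#' @export
identity_channel <- function() {
  channel_model(diag(2), alphabet = c("0", "1"), name = "identity")
}

#' @export
print.ctor_channel <- function(x, ...) {
  cat(sprintf(
    "<ctor_channel \"%s\">  binary input -> {%s}\n",
    x$name, paste(x$alphabet, collapse = ", ")
  ))
  print(x$pmf)
  cat(sprintf(
    "conditional entropy: H(r|s=0) = %.4f, H(r|s=1) = %.4f bits\n",
    conditional_entropy(x, 0), conditional_entropy(x, 1)
  ))
  invisible(x)
}

#' Read/write channel pmf tables as CSV
#'
#' Rows correspond to input bits 0 and 1; columns are named by the output
#' symbols.
#'
#' @param path File path.
#' @param channel A `ctor_channel`.
#' @param name Name for the channel read from file.
#' @return `read_channel_csv()` returns a `ctor_channel`;
#'   `write_channel_csv()` returns `path` invisibly.
#' @export
read_channel_csv <- function(path, name = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE)
  channel_model(as.matrix(tab), alphabet = names(tab),
                name = name %||% basename(path))
}

#' @rdname read_channel_csv
#' @export
write_channel_csv <- function(channel, path) {
  stopifnot(inherits(channel, "ctor_channel"))
  utils::write.csv(as.data.frame(channel$pmf), path, row.names = FALSE)
  invisible(path)
}

#' Conditional entropy of a discrete channel
#'
#' The channel-quality metric for a discrete channel: the equivocation
#' `H(r | s = n) = -sum_m P[r = m | s = n] log2 P[r = m | s = n]` in bits,
#' with the convention `0 * log 0 = 0`. Larger values mean a more
#' dispersive (worse) channel; the uniform channel attains the maximum
#' `log2 |r|`.
#'
#' @param channel A `ctor_channel` (or built-in name).
#' @param input Input bit, 0 or 1.
#' @return Entropy in bits.
#' @examples
#' conditional_entropy(ctor_channel("dispersive"), 0) # 1.846...
#' @export
conditional_entropy <- function(channel, input = 0) {
  channel <- ctor_channel(channel)
  stopifnot(input %in% c(0, 1))
  p <- channel$pmf[input + 1L, ]
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Transmit a codeword through a discrete memoryless channel
#'
#' Each codeword bit independently selects the corresponding pmf row and an
#' output symbol is drawn from it. Sampling uses inversion of a single
#' uniform draw per symbol, so matched `set.seed()` calls give
#' common-random-number coupling across channels with equal alphabet size.
#'
#' @param codeword Bit vector (or bit string).
#' @param channel A `ctor_channel` (or built-in name).
#' @return Character vector of output symbols, same length as the codeword.
#' @examples
#' set.seed(1)
#' transmit(encode_bits("1100", "simple"), "dispersive")
#' @export
transmit <- function(codeword, channel) {
  channel <- ctor_channel(channel)
  s <- as_bits(codeword)
  idx <- transmit_idx(s, channel)
  channel$alphabet[idx]
}

# symbol indices (1-based into the alphabet); internal batch form
transmit_idx <- function(bits, channel, n_trials = 1L) {
  cum <- t(apply(channel$pmf, 1L, cumsum))
  n <- length(bits) * n_trials
  u <- stats::runif(n)
  row <- rep.int(bits, n_trials) + 1L
  idx <- rep.int(1L, n)
  for (j in seq_len(ncol(cum) - 1L)) {
    idx <- idx + (u > cum[row, j])
  }
  if (n_trials == 1L) idx else matrix(idx, nrow = n_trials, byrow = TRUE)
}

#' Additive-noise channel
#'
#' The simplest continuous channel adds zero-location noise to the codeword:
#' `r = s + n`, with the noise law specified only through its second moment
#' `E[n^2]` (the neuronal noise power). The distribution family is
#' configurable; the default is a zero-mean Gaussian with variance
#' `noise_power`.
#'
#' @param noise_power Positive second moment of the noise per component.
#' @param distribution `"gaussian"` (zero-mean normal), `"uniform"`
#'   (symmetric uniform) or `"laplace"`, each scaled to the requested
#'   second moment.
#' @return An object of class `ctor_additive_noise`.
#' @seealso [additive_transmit()], [snr()]
#' @export
additive_noise <- function(noise_power, distribution = c("gaussian", "uniform", "laplace")) {
  stopifnot(noise_power > 0)
  structure(
    list(noise_power = noise_power, distribution = match.arg(distribution)),
    class = "ctor_additive_noise"
  )
}

#' Transmit a codeword through the additive channel
#'
#' @param codeword Bit vector.
#' @param noise A `ctor_additive_noise`.
#' @return Numeric vector `codeword + noise draws`.
#' @export
additive_transmit <- function(codeword, noise) {
  stopifnot(inherits(noise, "ctor_additive_noise"))
  s <- as_bits(codeword)
  n <- length(s)
  draw <- switch(noise$distribution,
    gaussian = stats::rnorm(n, sd = sqrt(noise$noise_power)),
    uniform = stats::runif(n, -1, 1) * sqrt(3 * noise$noise_power),
    laplace = {
      u <- stats::runif(n, -0.5, 0.5)
      b <- sqrt(noise$noise_power / 2)
      -b * sign(u) * log1p(-2 * abs(u))
    }
  )
  s + draw
}

#' Signal-to-noise ratio of the additive channel
#'
#' For binary 0/1 signalling the signal swing `max(s) - min(s)` is 1, so the
#' per-unit SNR reduces to the reciprocal of the noise power. Zero noise
#' power is reported as `Inf`.
#'
#' @param noise A `ctor_additive_noise`, or a non-negative noise power.
#' @return The SNR ratio `1 / noise_power`.
#' @examples
#' snr(additive_noise(0.5)) # 2
#' @export
snr <- function(noise) {
  power <- if (inherits(noise, "ctor_additive_noise")) noise$noise_power else noise
  stopifnot(power >= 0)
  if (power == 0) Inf else 1 / power
}
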