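#' Define a rate-1/N feedforward convolutional encoder
#'
#' The early visual stages (retina, LGN, V1) are modelled as a shift-register
#' convolutional encoder that tangles each message bit into an N-bit codeword
#' block. The encoder is described by N tap vectors over GF(2): entry `j + 1`
#' of a tap vector is the coefficient of the delay monomial D^j, so each
#' vector has length `L + 1` where `L` is the maximal memory order
#' (constraint length) of the register. One bit enters the encoder per time
#' step (`M = 1`).
#'
#' @param taps A list of N equal-length 0/1 vectors (coefficient of D^j at
#'   position j + 1), or a matrix with N rows.
#' @param name Optional display name.
#' @return An object of class `ctor_generator` with fields `taps`
#'   (N x (L+1) matrix), `L`, `N`, `M` and `name`.
#' @seealso [simple_encoder()], [complex_encoder()], [build_trellis()],
#'   [encode_bits()]
#' @examples
#' # G(D) = [1 + D, 1 + D^2, 1 + D + D^2]
#' generator_spec(list(c(1, 1, 0), c(1, 0, 1), c(1, 1, 1)))
#' @export
generator_spec <- function(taps, name = NULL) {
  if (is.matrix(taps)) taps <- asplit(taps, 1)
  taps <- lapply(taps, as_bits)
  N <- length(taps)
  if (N < 1) stop("need at least one tap vector", call. = FALSE)
  len <- lengths(taps)
  if (length(unique(len)) != 1L) {
    stop("all tap vectors must have the same length L + 1", call. = FALSE)
  }
  L <- len[[1]] - 1L
  if (L < 0) stop("tap vectors must be non-empty", call. = FALSE)
  structure(
    list(
      taps = do.call(rbind, taps),
      L = as.integer(L),
      N = as.integer(N),
      M = 1L,
      name = name %||% "custom"
    ),
    class = "ctor_generator"
  )
}

#' @export
print.ctor_generator <- function(x, ...) {
  cat(sprintf(
    "<ctor_generator \"%s\">  rate 1/%d, constraint length L = %d (%d states)\n",
    x$name, x$N, x$L, 2L^x$L
  ))
  terms <- apply(x$taps, 1L, function(g) {
    j <- which(g == 1L) - 1L
    if (!length(j)) return("0")
    paste(ifelse(j == 0L, "1", ifelse(j == 1L, "D", paste0("D^", j))),
          collapse = " + ")
  })
  cat("  G(D) = [", paste(terms, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Built-in encoders
#'
#' Two encoders are used throughout the worked examples and simulations:
#'
#' * `simple_encoder()`: G(D) = \[1 + D, 1 + D^2, 1 + D + D^2\], rate 1/3,
#'   L = 2 (4 trellis states).
#' * `complex_encoder()`: rate 1/3 with maximal memory order L = 8
#'   (256 trellis states),
#'   G(D) = \[1 + D^2 + D^3 + D^5 + D^6 + D^7 + D^8,
#'   1 + D + D^3 + D^4 + D^7 + D^8, 1 + D + D^2 + D^5 + D^8\].
#'
#' @return A `ctor_generator`.
#' @examples
#' simple_encoder()
#' @export
simple_encoder <- function() {
  generator_spec(
    list(c(1, 1, 0), c(1, 0, 1), c(1, 1, 1)),
    name = "simple"
  )
}

#' @rdname simple_encoder
#' @export
complex_encoder <- function() {
  generator_spec(
    list(
      c(1, 0, 1, 1, 0, 1, 1, 1, 1), # 1 + D^2 + D^3 + D^5 + D^6 + D^7 + D^8
      c(1, 1, 0, 1, 1, 0, 0, 1, 1), # 1 + D   + D^3 + D^4 + D^7 + D^8
      c(1, 1, 1, 0, 0, 1, 0, 0, 1)  # 1 + D   + D^2 + D^5 + D^8
    ),
    name = "complex"
  )
}

#' Look up an encoder by name
#'
#' @param name `"simple"`, `"complex"`, or a `ctor_generator` passed through.
#' @return A `ctor_generator`.
#' @export
ctor_encoder <- function(name) {
  if (inherits(name, "ctor_generator")) return(name)
  switch(match.arg(name, c("simple", "complex")),
    simple = simple_encoder(),
    complex = complex_encoder()
  )
}

#' Read/write generator specs as plain text
#'
#' One tap vector per line, D^0 coefficient first, digits separated by
#' optional whitespace. Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @param spec A `ctor_generator`.
#' @param name Name to give the encoder read from file.
#' @return `read_generator_spec()` returns a `ctor_generator`;
#'   `write_generator_spec()` returns `path` invisibly.
#' @export
read_generator_spec <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  generator_spec(lapply(lines, as_bits), name = name %||% basename(path))
}

#' @rdname read_generator_spec
#' @export
write_generator_spec <- function(spec, path) {
  stopifnot(inherits(spec, "ctor_generator"))
  writeLines(apply(spec$taps, 1L, paste, collapse = ""), path)
  invisible(path)
}

#' Encode a message through a convolutional encoder
#'
#' Tangles a K-bit object representation into a K*N-bit codeword. The shift
#' register starts in the all-zero state S0 and no tail/flush bits are
#' appended: exactly K trellis stages are produced. Output block k is, for
#' each tap vector g, the mod-2 sum of g_j times the input delayed by j
#' steps, j = 0..L.
#'
#' @param message Bit vector (or bit string) of message bits.
#' @param spec A `ctor_generator` (or built-in name).
#' @return Integer bit vector of length `N * length(message)`.
#' @examples
#' format_bits(encode_bits("1100", simple_encoder()), block = 3)
#' @export
encode_bits <- function(message, spec) {
  spec <- ctor_encoder(spec)
  b <- as_bits(message)
  K <- length(b)
  if (K == 0L) return(integer(0))
  # windows (b_k, b_{k-1}, ..., b_{k-L}) per stage, zero-padded history
  W <- stats::embed(c(integer(spec$L), b), spec$L + 1L)
  out <- (W %*% t(spec$taps)) %% 2L # K x N
  as.integer(t(out))
}
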