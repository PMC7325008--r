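# shared helpers for the test suite; everything is generated in code

split_symbols <- function(...) {
  unlist(strsplit(c(...), ""))
}

# independent encoding oracle: literal shift-register walk, no reuse of the
# package's convolution or trellis machinery
register_walk_encode <- function(message, taps) {
  taps <- do.call(rbind, lapply(taps, as.integer))
  L <- ncol(taps) - 1L
  reg <- integer(L) # most recent input first
  out <- integer(0)
  for (u in as.integer(message)) {
    window <- c(u, reg)
    out <- c(out, as.integer(taps %*% window) %% 2L)
    if (L > 0) reg <- c(u, reg)[seq_len(L)]
  }
  out
}

# all bit vectors of a given length, ordered by integer value (MSB first)
all_messages <- function(k) {
  lapply(0:(2^k - 1L), function(v) as.integer(intToBits(v))[k:1])
}

random_bits <- function(n) sample(0:1, n, replace = TRUE)
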