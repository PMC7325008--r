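#' Define an importance-ranked feature interleaver
#'
#' After decoding, IT reformats the message into feature groups ranked by
#' importance: an interleaver is an ordered partition of the message bit
#' indices `1..KM` into F groups, the first group holding the indices of
#' the most important feature. Group sizes `M_1..M_F` must sum to `KM`.
#'
#' @param groups A list of integer index vectors (1-based), e.g.
#'   `list(c(1, 3), c(2, 4))`.
#' @return An object of class `ctor_interleaver`.
#' @examples
#' interleaver_spec(list(c(1, 3), c(2, 4)))
#' @export
interleaver_spec <- function(groups) {
  groups <- unname(lapply(groups, function(g) unname(as.integer(g))))
  idx <- unlist(groups)
  km <- length(idx)
  if (km == 0L || !setequal(idx, seq_len(km)) || anyDuplicated(idx)) {
    stop("interleaver groups must form an exact partition of 1..KM",
      call. = FALSE
    )
  }
  structure(
    list(groups = groups, F = length(groups), sizes = lengths(groups),
         km = km),
    class = "ctor_interleaver"
  )
}

#' @export
print.ctor_interleaver <- function(x, ...) {
  cat(sprintf("<ctor_interleaver>  F = %d features over %d bits\n",
              x$F, x$km))
  for (i in seq_len(x$F)) {
    cat(sprintf("  rank %d: indices [%s]\n", i,
                paste(x$groups[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Read/write an interleaver as a JSON-style nested index list
#'
#' The serialised form matches the bracketed notation `[[1,3],[2,4]]`
#' (1-based indices).
#'
#' @param path File path.
#' @param spec A `ctor_interleaver`.
#' @return `read_interleaver()` returns a `ctor_interleaver`;
#'   `write_interleaver()` returns `path` invisibly.
#' @export
read_interleaver <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  txt <- gsub("\\s", "", txt)
  inner <- sub("^\\[\\[", "", sub("\\]\\]$", "", txt))
  groups <- lapply(strsplit(inner, "\\],\\[")[[1]], function(g) {
    as.integer(strsplit(g, ",")[[1]])
  })
  interleaver_spec(groups)
}

#' @rdname read_interleaver
#' @export
write_interleaver <- function(spec, path) {
  stopifnot(inherits(spec, "ctor_interleaver"))
  body <- paste(
    vapply(spec$groups, function(g) {
      paste0("[", paste(g, collapse = ","), "]")
    }, ""),
    collapse = ","
  )
  writeLines(paste0("[", body, "]"), path)
  invisible(path)
}

#' Interleave a decoded message into ranked feature groups
#'
#' @param message Bit vector of length KM.
#' @param spec A `ctor_interleaver`.
#' @return A list of F bit vectors, one per feature in importance order;
#'   their concatenation is a permutation of the message.
#' @examples
#' interleave("1100", interleaver_spec(list(c(1, 3), c(2, 4))))
#' @export
interleave <- function(message, spec) {
  stopifnot(inherits(spec, "ctor_interleaver"))
  b <- as_bits(message)
  if (length(b) != spec$km) {
    stop("message length must equal the interleaver's KM", call. = FALSE)
  }
  lapply(spec$groups, function(g) b[g])
}

#' Invert an interleaving
#'
#' @param groups The list of feature groups produced by [interleave()].
#' @param spec The `ctor_interleaver` that produced them.
#' @return The original message bit vector.
#' @export
deinterleave <- function(groups, spec) {
  stopifnot(inherits(spec, "ctor_interleaver"))
  b <- integer(spec$km)
  for (i in seq_len(spec$F)) {
    b[spec$groups[[i]]] <- as_bits(groups[[i]])
  }
  b
}

#' Compress a stream of decoded blocks into memory
#'
#' Repeated viewings of similar objects are merged before storage: blocks
#' are grouped by the value of their most important feature (rank-1
#' interleaver group), each group is replaced by its most frequent full
#' block (ties keep the earliest-occurring block), and the representatives
#' are concatenated in order of first appearance of each important-feature
#' value. Less-important features are thereby compressed implicitly by the
#' majority rule.
#'
#' @param blocks A list of equal-length bit vectors (or bit strings), one
#'   per viewing interval; a single long bit vector is split into
#'   KM-bit blocks.
#' @param spec A `ctor_interleaver` defining the important feature.
#' @return An object of class `ctor_memory` with fields `blocks` (the
#'   representative bit vectors), `bits` (their concatenation) and
#'   `total_bits`.
#' @examples
#' compress_memory(
#'   list("1100", "1100", "1110", "1101"),
#'   interleaver_spec(list(c(1, 3), c(2, 4)))
#' ) # 1100 1110, 8 bits
#' @export
compress_memory <- function(blocks, spec) {
  stopifnot(inherits(spec, "ctor_interleaver"))
  if (!is.list(blocks)) {
    b <- as_bits(blocks)
    if (length(b) %% spec$km != 0L) {
      stop("stream length must be a multiple of KM", call. = FALSE)
    }
    blocks <- split(b, ceiling(seq_along(b) / spec$km))
  }
  blocks <- lapply(blocks, as_bits)
  if (length(blocks) == 0L) {
    return(structure(
      list(blocks = list(), bits = integer(0), total_bits = 0L),
      class = "ctor_memory"
    ))
  }
  if (any(lengths(blocks) != spec$km)) {
    stop("all blocks must have length KM", call. = FALSE)
  }
  key <- vapply(blocks, function(b) {
    paste(b[spec$groups[[1L]]], collapse = "")
  }, "")
  full <- vapply(blocks, paste, "", collapse = "")
  reps <- lapply(unique(key), function(k) {
    in_group <- full[key == k]
    counts <- table(factor(in_group, levels = unique(in_group)))
    as_bits(names(counts)[which.max(counts)]) # ties: earliest occurrence
  })
  bits <- unlist(reps)
  structure(
    list(blocks = reps, bits = as.integer(bits),
         total_bits = length(bits)),
    class = "ctor_memory"
  )
}

#' @export
print.ctor_memory <- function(x, ...) {
  cat(sprintf("<ctor_memory>  %d block(s), %d bits\n",
              length(x$blocks), x$total_bits))
  if (length(x$blocks)) {
    cat("  ", paste(vapply(x$blocks, format_bits, ""), collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Linear category readout
#'
#' Object category is declared by the inner product of the decoded message
#' with a weight vector, `f(b-hat) = w' b-hat`. With all-ones weights the
#' score is the Hamming weight of the message, so the readout is invariant
#' to any permutation applied jointly to message and weights.
#'
#' @param message Bit vector.
#' @param weights Numeric weight vector of the same length; defaults to
#'   all ones.
#' @return The readout score (numeric scalar).
#' @examples
#' categorize("1100") # 2
#' @export
categorize <- function(message, weights = NULL) {
  b <- as_bits(message)
  weights <- weights %||% rep(1, length(b))
  if (length(weights) != length(b)) {
    stop("weights must match the message length", call. = FALSE)
  }
  sum(weights * b)
}
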