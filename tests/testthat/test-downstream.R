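test_that("interleaving ranks bits into feature groups and is invertible", {
  ivl <- interleaver_spec(list(c(1, 3), c(2, 4)))
  groups <- interleave("1100", ivl)
  expect_equal(groups, list(c(1L, 0L), c(1L, 0L)))

  # identity interleaver returns the message as one group
  ivl_id <- interleaver_spec(list(1:6))
  expect_equal(interleave("110100", ivl_id), list(as_bits("110100")))

  # any spec: outputs are a permutation of the inputs; deinterleave inverts
  set.seed(9)
  for (rep in 1:20) {
    km <- sample(c(4, 6, 8, 12), 1)
    sizes <- diff(sort(c(0, sample(km - 1, sample(1:3, 1)), km)))
    idx <- split(sample(km), rep(seq_along(sizes), sizes))
    spec <- interleaver_spec(idx)
    b <- random_bits(km)
    g <- interleave(b, spec)
    expect_equal(sort(unlist(g)), sort(b))
    expect_identical(deinterleave(g, spec), b)
  }

  expect_error(interleaver_spec(list(c(1, 2), c(2, 3))), "partition")
  expect_error(interleave("110", ivl), "length")
})

test_that("memory compression keeps the majority block per important feature", {
  ivl <- interleaver_spec(list(c(1, 3), c(2, 4)))
  mem <- compress_memory(list("1100", "1100", "1110", "1101"), ivl)
  expect_equal(format_bits(mem$bits), "11001110")
  expect_equal(mem$total_bits, 8L)

  # singleton and all-identical streams
  expect_equal(compress_memory(list("1011"), ivl)$bits, as_bits("1011"))
  expect_equal(
    compress_memory(rep(list("0110"), 4), ivl)$total_bits, 4L
  )

  # frequency tie: the earliest-occurring block wins
  tie <- compress_memory(list("1101", "1100", "1100", "1101"), ivl)
  expect_equal(format_bits(tie$bits), "1101")

  # never more bits than the input; equality iff all feature values distinct
  set.seed(12)
  for (rep in 1:20) {
    blocks <- replicate(sample(1:6, 1), random_bits(4), simplify = FALSE)
    mem <- compress_memory(blocks, ivl)
    expect_lte(mem$total_bits, 4L * length(blocks))
    keys <- vapply(blocks, function(b) paste(b[c(1, 3)], collapse = ""), "")
    expect_equal(mem$total_bits, 4L * length(unique(keys)))
  }

  # a long stream is split into KM-bit viewings
  expect_equal(compress_memory("1100110011101101", ivl)$total_bits, 8L)
  expect_equal(compress_memory(list(), ivl)$total_bits, 0L)
})

test_that("transition priors are counted over overlapping windows", {
  tr <- build_trellis("simple")
  pri <- estimate_priors("11001110", tr, floor = 0)
  expect_equal(unname(pri$probs["S3", "S1"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(pri$probs["S3", "S3"]), 1 / 3, tolerance = 1e-12)

  # constant stream: S0 -> S0 with certainty (before flooring)
  pri0 <- estimate_priors(rep(0, 40), tr, floor = 0)
  expect_equal(unname(pri0$probs["S0", "S0"]), 1)

  # long fair-coin stream: every valid transition near 1/2
  set.seed(31)
  prif <- estimate_priors(random_bits(1e5), tr, floor = 1e-6)
  on <- prif$probs[prif$probs > 0]
  expect_true(all(abs(on - 0.5) < 3 * sqrt(0.25 / (1e5 / 4))))

  # rows over valid successors always renormalise to 1
  set.seed(32)
  for (rep in 1:10) {
    p <- estimate_priors(random_bits(30), tr, floor = 1e-6)
    expect_equal(unname(rowSums(p$probs)), rep(1, 4), tolerance = 1e-12)
    expect_true(all(p$probs[!ctorsim:::prior_valid_mask(tr)] == 0))
  }

  expect_error(estimate_priors("10", tr), "L \\+ 1")
})

test_that("the category readout is a weighted sum invariant to joint permutation", {
  expect_equal(categorize("1100"), 2)
  expect_equal(categorize("1100", c(0, 0, 0, 0)), 0)
  expect_error(categorize("1100", c(1, 1)), "length")

  set.seed(21)
  for (rep in 1:10) {
    b <- random_bits(15)
    w <- stats::rnorm(15)
    perm <- sample(15)
    expect_equal(categorize(b[perm], w[perm]), categorize(b, w))
    # all-ones weights give the Hamming weight, i.e. KM - d(b, all-ones)
    expect_equal(categorize(b), 15 - hamming_distance(b, rep(1, 15)))
  }
})

test_that("interleavers round-trip through the bracketed index notation", {
  path <- withr::local_tempfile(fileext = ".json")
  spec <- interleaver_spec(list(c(1, 3), c(2, 4), c(5, 6)))
  write_interleaver(spec, path)
  expect_equal(readLines(path), "[[1,3],[2,4],[5,6]]")
  back <- read_interleaver(path)
  expect_equal(back$groups, spec$groups)
})
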