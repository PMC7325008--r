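test_that("branch metrics reproduce the printed stage-1 transition lengths", {
  tr <- build_trellis("simple")
  block <- c("D", "C", "A")
  lam00 <- branch_metric(block, 0, 0, tr, "dispersive")
  lam02 <- branch_metric(block, 0, 2, tr, "dispersive")
  expect_equal(lam00, -log(0.1) - log(0.2) - log(0.4), tolerance = 1e-12)
  expect_equal(lam02, -log(0.4) - log(0.3) - log(0.1), tolerance = 1e-12)
  expect_equal(lam00, 4.828314, tolerance = 1e-6)
  expect_equal(lam02, 4.422849, tolerance = 1e-6)

  # uniform channel: every transition has the same length, 3 ln 4
  for (row in 1:8) {
    t_i <- tr$transitions[row, ]
    expect_equal(
      branch_metric(block, t_i$from, t_i$to, tr, "uniform"),
      3 * log(4),
      tolerance = 1e-12
    )
  }

  # MAP mode adds the negative-log prior of the transition
  pri <- estimate_priors("11001110", tr, floor = 1e-6)
  expect_equal(
    branch_metric(block, 3, 1, tr, "dispersive", priors = pri),
    branch_metric(block, 3, 1, tr, "dispersive") - log(pri$probs["S3", "S1"]),
    tolerance = 1e-12
  )

  expect_error(branch_metric(block, 0, 1, tr, "dispersive"), "not a valid")
  expect_error(branch_metric(c("D", "C"), 0, 0, tr, "dispersive"), "N symbols")

  # zero channel probability saturates to +Inf rather than erroring
  expect_identical(
    branch_metric(c("1", "1", "1"), 0, 0, tr, identity_channel()), Inf
  )
})

test_that("the worked received sequence decodes to the transmitted object", {
  tr <- build_trellis("simple")
  r <- split_symbols("DCA", "DDB", "DDA", "DDD")
  dec <- viterbi_decode(r, tr, "dispersive")
  expect_equal(format_bits(dec$message), "1100")
  expect_equal(format_bits(dec$codeword_estimate, block = 3), "111 010 110 011")
  expect_equal(dec$path, c(0L, 2L, 3L, 1L, 0L))

  # stage-1 path metrics: only S0 and S2 reachable, with the printed values
  expect_equal(dec$gamma[1, 1], 4.828314, tolerance = 1e-6)
  expect_equal(dec$gamma[1, 3], 4.422849, tolerance = 1e-6)
  expect_identical(dec$gamma[1, c(2, 4)], c(Inf, Inf))

  # re-encoding invariant and survivor table shape
  expect_identical(dec$codeword_estimate, encode_bits(dec$message, "simple"))
  td <- tidy(dec)
  expect_equal(nrow(td), 4L * 4L)
  expect_equal(sum(td$on_path), 4L)
})

test_that("noiseless round-trips are the identity for both encoders", {
  set.seed(55)
  for (enc in c("simple", "complex")) {
    tr <- build_trellis(enc)
    for (rep in 1:25) {
      b <- random_bits(8)
      r <- transmit(encode_bits(b, enc), identity_channel())
      expect_identical(viterbi_decode(r, tr, identity_channel())$message, b)
    }
  }
})

test_that("the Viterbi path metric attains the exhaustive-search optimum", {
  set.seed(404)
  tr <- build_trellis("simple")
  n_checked <- 0
  for (rep in 1:60) {
    K <- sample(3:10, 1)
    ch <- ctor_channel(sample(c("dispersive", "less_dispersive"), 1))
    pri <- if (rep %% 2 == 0) {
      estimate_priors(random_bits(50), tr, floor = 1e-3)
    }
    r <- transmit(encode_bits(random_bits(K), "simple"), ch)
    v <- viterbi_decode(r, tr, ch, priors = pri)
    o <- exhaustive_map_decode(r, "simple", ch, priors = pri)
    # dynamic-programming optimality: metrics always agree ...
    expect_equal(v$final_metric, o$metric, tolerance = 1e-9)
    # ... and the decisions agree whenever the optimum is unique
    if (o$unique) {
      expect_identical(v$message, o$message)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 40)
})

test_that("uniform priors reduce MAP decoding to MLE decision-for-decision", {
  tr <- build_trellis("simple")
  set.seed(77)
  for (rep in 1:30) {
    r <- transmit(encode_bits(random_bits(12), "simple"), "dispersive")
    mle <- viterbi_decode(r, tr, "dispersive")
    map <- viterbi_decode(r, tr, "dispersive", priors = uniform_priors(tr))
    expect_identical(map$message, mle$message)
    # the uniform prior contributes exactly K ln 2 to the path length
    expect_equal(map$final_metric - mle$final_metric, 12 * log(2),
      tolerance = 1e-9
    )
  }
})

test_that("an information-free channel forces a deterministic arbitrary choice", {
  tr <- build_trellis("simple")
  r <- split_symbols("ABC", "DAB", "CDA", "BCD")
  v <- viterbi_decode(r, tr, "uniform")
  o <- exhaustive_map_decode(r, "simple", "uniform")
  expect_false(o$unique)
  # every path ties at K * N * ln 4; the tie-break representative is the
  # all-zero message (smallest message integer / smallest state labels)
  expect_equal(o$metric, 12 * log(4), tolerance = 1e-12)
  expect_equal(v$final_metric, 12 * log(4), tolerance = 1e-12)
  expect_identical(o$message, rep(0L, 4))
  expect_identical(v$message, rep(0L, 4))
  expect_identical(v$message, viterbi_decode(r, tr, "uniform")$message)
})

test_that("a less dispersive channel never hurts decoding on matched seeds", {
  tr <- build_trellis("simple")
  truth <- make_truth(12)
  cw <- encode_bits(truth, "simple")
  rates <- vapply(c("dispersive", "less_dispersive"), function(chn) {
    ch <- ctor_channel(chn)
    set.seed(1234) # matched draws across the two channels
    sym <- ctorsim:::transmit_idx(cw, ch, n_trials = 1000)
    msgs <- ctorsim:::viterbi_batch(sym, tr, ch)$messages
    bcr(trial_records(truth, msgs))
  }, numeric(1))
  expect_gt(rates["less_dispersive"], rates["dispersive"])
})

test_that("framing and alphabet violations are rejected", {
  tr <- build_trellis("simple")
  expect_error(viterbi_decode(c("A", "B"), tr, "dispersive"), "framing")
  expect_error(viterbi_decode(c("A", "B", "Z"), tr, "dispersive"), "alphabet")
  expect_error(
    exhaustive_map_decode(rep("A", 3 * 17), "simple", "dispersive"),
    "refused"
  )
})
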