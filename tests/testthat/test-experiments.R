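test_that("the truth pattern alternates starting from 1", {
  expect_equal(make_truth(6), c(1L, 0L, 1L, 0L, 1L, 0L))
  expect_equal(make_truth(1), 1L)
  expect_equal(make_truth(4), c(1L, 0L, 1L, 0L))
})

test_that("experiments are byte-for-byte reproducible under a fixed seed", {
  a <- run_recognition_experiment(K = c(6, 12), n_trials = 300, seed = 11)
  b <- run_recognition_experiment(K = c(6, 12), n_trials = 300, seed = 11)
  expect_identical(a, b)
  c <- run_recognition_experiment(K = c(6, 12), n_trials = 300, seed = 12)
  expect_false(identical(a$bcr, c$bcr))

  m1 <- run_map_vs_mle(K = 12, n_trials = 40, seed = 11)
  m2 <- run_map_vs_mle(K = 12, n_trials = 40, seed = 11)
  expect_identical(m1$iterations, m2$iterations)
  expect_identical(m1$priors_trace, m2$priors_trace)
})

test_that("the recognition sweep returns one tidy row per channel and K", {
  res <- run_recognition_experiment(
    K = c(6, 12), n_trials = 300, seed = 5
  )
  expect_s3_class(res, "ctor_experiment")
  expect_s3_class(res, "tbl_df")
  expect_equal(nrow(res), 4L)
  expect_setequal(
    names(res),
    c("encoder", "channel", "K", "n_trials", "seed", "bcr", "scr", "ccr",
      "accr", "c1")
  )
  expect_true(all(res$bcr >= 0 & res$bcr <= 1))
  expect_true(all(res$accr >= res$ccr))
  expect_true(all(res$bcr >= res$scr))
  # matched seeds: the cleaner channel dominates cell-by-cell
  wide <- tidyr::pivot_wider(res[, c("channel", "K", "bcr")],
    names_from = "channel", values_from = "bcr"
  )
  expect_true(all(wide$less_dispersive > wide$dispersive))
})

test_that("scaling up trials leaves metric estimates within Monte-Carlo error", {
  r1 <- run_recognition_experiment(
    channels = "dispersive", K = 12, n_trials = 1000, seed = 21
  )
  r2 <- run_recognition_experiment(
    channels = "dispersive", K = 12, n_trials = 4000, seed = 22
  )
  se <- function(p, n) sqrt(pmax(p * (1 - p), 1e-4) / n)
  for (m in c("bcr", "scr", "ccr", "accr")) {
    tol <- 3 * sqrt(se(r1[[m]], 1000)^2 + se(r2[[m]], 4000)^2)
    expect_lt(abs(r1[[m]] - r2[[m]]), tol)
  }
})

test_that("MAP and MLE coincide at the first (uniform-prior) iteration", {
  res <- run_map_vs_mle(K = 24, n_trials = 30, seed = 13)
  it1 <- dplyr::filter(res$iterations, .data$iteration == 1)
  expect_equal(it1$bcr[it1$scheme == "MLE"], it1$bcr[it1$scheme == "MAP"])
  expect_identical(
    res$bit_correct$MLE[1, ],
    res$bit_correct$MAP[1, ]
  )
  # the first MAP iteration records uniform priors
  p1 <- dplyr::filter(res$priors_trace, .data$iteration == 1)
  expect_true(all(p1$prior == 0.5))
})

test_that("map-vs-mle traces have the documented structure", {
  res <- run_map_vs_mle(K = 12, n_trials = 25, seed = 3)
  expect_equal(dim(res$bit_correct$MAP), c(25L, 12L))
  expect_true(all(res$iterations$scr %in% c(0L, 1L)))
  expect_true(all(res$iterations$bcr >= 0 & res$iterations$bcr <= 1))
  expect_equal(nrow(res$priors_trace), 25L * 8L) # 8 valid transitions
  g <- glance(res)
  expect_equal(nrow(g), 1L)
  expect_true(all(c("mle_bcr", "map_bcr", "mle_scr", "map_scr") %in% names(g)))
  expect_equal(nrow(tidy(res)), 2L * 25L)

  # memory-guided priors help recognition of a repeatedly viewed object
  big <- run_map_vs_mle(K = 24, n_trials = 120, seed = 19)
  s <- tidyr::pivot_wider(big$summary[, c("scheme", "bcr")],
    names_from = "scheme", values_from = "bcr"
  )
  expect_gt(s$MAP, s$MLE)
})

test_that("the worked example recomputes every printed quantity", {
  t0 <- Sys.time()
  we <- worked_example()
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)

  expect_equal(format_bits(we$codeword, block = 3), "111 010 110 011")
  expect_equal(round(ctorsim:::trunc2(we$branch_metrics[["S0->S0"]]), 2), 4.82)
  expect_equal(round(ctorsim:::trunc2(we$branch_metrics[["S0->S2"]]), 2), 4.42)
  expect_equal(format_bits(we$decoded$message), "1100")
  expect_equal(we$features, list(c(1L, 0L), c(1L, 0L)))
  expect_equal(we$readout, 2)
  expect_equal(format_bits(we$memory$bits), "11001110")
  expect_equal(we$memory$total_bits, 8L)
  expect_equal(unname(we$prior_s1_given_s3), 2 / 3, tolerance = 1e-12)
  expect_output(print(we), "1100 1110")
})

test_that("autoplot methods return ggplot objects", {
  res <- run_recognition_experiment(K = c(6, 12), n_trials = 100, seed = 2)
  expect_s3_class(autoplot(res), "ggplot")
  mm <- run_map_vs_mle(K = 12, n_trials = 10, seed = 2)
  expect_s3_class(autoplot(mm, type = "trace"), "ggplot")
  expect_s3_class(autoplot(mm, type = "kymograph"), "ggplot")
  expect_s3_class(autoplot(mm, type = "priors"), "ggplot")
})
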