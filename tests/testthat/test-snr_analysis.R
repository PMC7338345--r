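test_that("larger-is-better S/N matches its closed form", {
  # single observation: 20*log10(y)
  expect_equal(snr_larger_is_better(100), 40)
  expect_equal(round(snr_larger_is_better(81.7), 1), 38.2)
  expect_equal(snr_larger_is_better(5.4), 20 * log10(5.4))
  # constant replicates collapse to the single-value case
  expect_equal(snr_larger_is_better(c(10, 10, 10)), 20)
  # direct evaluation of the replicate form
  y <- c(50, 60, 70)
  expect_equal(snr_larger_is_better(y), -10 * log10(mean(1 / y^2)))
  expect_error(snr_larger_is_better(c(10, 0)), "invalid response")
  expect_error(snr_larger_is_better(-1), "invalid response")
})

test_that("S/N is monotone, bounded by the best replicate, and round-trips", {
  set.seed(42)
  y <- sort(runif(50, 0.5, 120))
  s <- vapply(y, snr_larger_is_better, numeric(1))
  expect_true(all(diff(s) > 0))
  for (i in 1:20) {
    reps <- runif(4, 1, 100)
    expect_lte(snr_larger_is_better(reps), 20 * log10(max(reps)))
  }
  # inverse on singletons to floating tolerance
  for (v in c(0.1, 1, 14.6, 81.7, 250))
    expect_equal(snr_to_response(snr_larger_is_better(v)), v,
                 tolerance = 1e-9)
  expect_equal(snr_to_response(40), 100)
  expect_equal(snr_to_response(0), 1)
})

test_that("scaling responses shifts every S/N by 20*log10(c), fixing deltas and ranks", {
  l9 <- build_l9()
  set.seed(7)
  for (cc in c(0.5, 2, 10)) {
    y <- runif(9, 5, 95)
    s1 <- snr_records(y)$snr
    s2 <- snr_records(cc * y)$snr
    expect_equal(s2, s1 + 20 * log10(cc), tolerance = 1e-12)
    t1 <- response_table(l9, s1)
    t2 <- response_table(l9, s2)
    expect_equal(t2$delta, t1$delta, tolerance = 1e-9)
    expect_equal(t2$rank, t1$rank)
  }
})

test_that("response-table level means equal brute-force row filtering", {
  l9 <- build_l9()
  set.seed(11)
  for (rep in 1:10) {
    s <- rnorm(9, 30, 8)
    rt <- response_table(l9, s)
    expect_equal(unname(rt$level_means), brute_level_means(unclass(l9), s),
                 tolerance = 1e-12)
    expect_equal(unname(rt$delta),
                 apply(rt$level_means, 2, max) - apply(rt$level_means, 2, min),
                 ignore_attr = TRUE)
    expect_setequal(rt$rank, 1:4)
  }
  # constant S/N: all level means equal, all deltas 0
  rt0 <- response_table(l9, rep(5, 9))
  expect_true(all(rt0$level_means == 5))
  expect_equal(unname(rt0$delta), rep(0, 4))
  expect_error(response_table(l9, 1:5), "incomplete design")
})

test_that("the additive optimum prediction follows the response-table algebra", {
  snr <- faee_snr()
  rt <- response_table(build_l9(), snr)
  gm <- mean(snr)
  # empty selection -> grand mean
  p0 <- predict_optimal_snr(rt, factors = character(0))
  expect_equal(p0$predicted_snr, gm)
  # single factor at level k -> that level's mean
  p1 <- predict_optimal_snr(rt, factors = "Time", levels = c(Time = 2))
  expect_equal(p1$predicted_snr, rt$level_means[2, "Time"])
  # all four factors at their best levels: independent spreadsheet-style
  # evaluation from raw run filtering
  oracle <- gm
  cells <- unclass(build_l9())
  best <- c(1, 2, 1, 3)
  for (j in 1:4) oracle <- oracle + (mean(snr[cells[, j] == best[j]]) - gm)
  pa <- predict_optimal_snr(rt)
  expect_equal(unname(pa$selected), best)
  expect_equal(pa$predicted_snr, oracle, tolerance = 1e-12)
  expect_equal(pa$predicted_snr, 43.58426, tolerance = 1e-5)
  expect_equal(pa$predicted_response, snr_to_response(oracle))
  # back-transformed prediction above 100% is flagged, not clipped
  expect_true(pa$exceeds_bound)
  expect_gt(pa$predicted_response, 100)
  expect_error(predict_optimal_snr(rt, factors = "Pressure"),
               "invalid selection")
  expect_error(predict_optimal_snr(rt, factors = "Time",
                                   levels = c(Time = 7)),
               "invalid selection")
})

test_that("the near-tie between temperature levels resolves by full precision", {
  rt <- response_table(build_l9(), faee_snr())
  # L1 and L2 of temperature differ by ~0.1 dB; full-precision argmax is L1
  expect_lt(abs(rt$level_means[1, "Temperature"] -
                rt$level_means[2, "Temperature"]), 0.2)
  expect_equal(unname(optimal_levels(rt)["Temperature"]), 1L)
})
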