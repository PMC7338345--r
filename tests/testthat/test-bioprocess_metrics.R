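test_that("acidity index follows the titration closed form and is linear in volume", {
  expect_equal(acidity_index(titration_record(1, 0.1, 0)), 0)
  expect_equal(acidity_index(titration_record(1, 0.1, 1)), 4.0)
  base <- acidity_index(titration_record(0.3, 0.1, 2.5))
  expect_equal(acidity_index(titration_record(0.3, 0.1, 5.0)), 2 * base)
  expect_error(titration_record(0, 0.1, 1), "invalid mass")
  expect_error(titration_record(1, -0.1, 1), "must be > 0")
})

test_that("FFA conversion interpolates between blank and full neutralization", {
  expect_equal(ffa_conversion(10, 10), 0)
  expect_equal(ffa_conversion(10, 0), 100)
  expect_equal(ffa_conversion(10, 1.83), 81.7)
  # strictly decreasing in the sample acidity
  ai <- seq(0, 12, by = 0.5)
  conv <- suppressWarnings(vapply(ai, function(a) ffa_conversion(10, a),
                                  numeric(1)))
  expect_true(all(diff(conv) < 0))
  expect_warning(ffa_conversion(10, 12), "negative conversion")
  expect_error(ffa_conversion(0, 1), "invalid blank")
})

test_that("hydrolytic activity follows the Beer-Lambert unit chain", {
  expect_equal(hydrolytic_activity(activity_assay(0)), 0)
  # hand evaluation: 0.515/5150 mol/L/min = 0.1 umol/mL/min; x2.6 mL /0.05 mL
  expect_equal(hydrolytic_activity(activity_assay(0.515)), 5.2)
  a1 <- hydrolytic_activity(activity_assay(0.2, dilution = 1))
  a2 <- hydrolytic_activity(activity_assay(0.2, dilution = 2))
  expect_equal(a2, 2 * a1)
  # linearity in the absorbance slope
  expect_equal(hydrolytic_activity(activity_assay(0.3)),
               3 * hydrolytic_activity(activity_assay(0.1)))
  out <- hydrolytic_activity(activity_assay(0.515), support_conc = 0.01)
  expect_equal(unname(out["u_per_g"]), 520)
  expect_error(activity_assay(0.5, extinction_coefficient = -1),
               "invalid assay")
})

test_that("immobilization parameters compose and round-trip", {
  expect_equal(immobilization_yield(100, 0), 100)
  expect_equal(immobilization_yield(100, 100), 0)
  expect_equal(immobilization_yield(100, 5.3), 94.7)
  expect_warning(immobilization_yield(100, 120), "negative retention")
  expect_equal(theoretical_activity(500, 100), 500)
  expect_equal(theoretical_activity(500, 0), 0)
  # offered load back-solved from the bundled biocatalyst, forward-checked
  expect_equal(round(theoretical_activity(483.6, 94.7), 1), 458.0)
  expect_equal(recovered_activity(5, 5), 100)
  # recovered_activity(at_t * r/100, at_t) = r for any r
  for (r in c(10, 40, 74.5, 99)) {
    at_t <- 458
    expect_equal(recovered_activity(at_t * r / 100, at_t), r,
                 tolerance = 1e-12)
  }
  expect_error(recovered_activity(100, 0), "invalid theoretical")
})

test_that("half-life fitting recovers first-order decay", {
  # noiseless exponential: k recovered to 1e-9 relative on any grid
  for (k in c(0.001, 0.01, 0.3)) for (grid in list(c(0, 30, 60, 90),
                                                   c(0, 7, 11, 40, 120))) {
    fit <- half_life(grid, 100 * exp(-k * grid))
    expect_equal(fit$k, k, tolerance = 1e-9)
    expect_equal(fit$t_half, log(2) / k, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
  # two-point series (0,100),(t*,50): half-life is t* by definition
  expect_equal(half_life(c(0, 37), c(100, 50))$t_half, 37, tolerance = 1e-9)
  expect_error(half_life(c(0, 10, 20), c(100, 110, 120)), "no decay")
  expect_error(half_life(c(0, 10, 5), c(100, 80, 60)),
               "strictly increasing")
  expect_error(half_life(c(0, 10), c(100, -5)), "must be > 0")
})

test_that("half-life recovery holds within 10% at 2% noise across seeds", {
  k <- log(2) / 105
  times <- seq(0, 210, by = 15)
  rel_err <- vapply(1:100, function(s) {
    d <- simulate_decay(k, times, noise_sd = 2, seed = s)
    abs(half_life(d$time, d$activity)$t_half - 105) / 105
  }, numeric(1))
  expect_gte(mean(rel_err <= 0.10), 0.95)
  expect_lt(stats::median(rel_err), 0.05)
})

test_that("stabilization factor is the plain half-life ratio", {
  expect_equal(stabilization_factor(12, 12), 1)
  expect_equal(round(stabilization_factor(105, 6.4), 1), 16.4)
  expect_equal(round(stabilization_factor(91, 5.8), 1), 15.7)
  hl <- faee_half_lives()
  ratios <- stabilization_factor(hl$immobilized, hl$free)
  expect_equal(round(ratios, 1), c(16.4, 8.4, 15.7))
  expect_error(stabilization_factor(-1, 5), "must be > 0")
})
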