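test_that("the full pipeline reproduces the per-run S/N of the bundled experiment", {
  rep <- run_pipeline(faee_run_sheet())
  # printed S/N values (1 d.p.); the printed conversions are themselves
  # rounded to 0.1%, which moves the S/N by up to ~0.1 dB at small y
  expect_true(all(abs(round(rep$run_snr$snr, 1) - published$snr) <= 0.1))
  expect_gte(sum(round(rep$run_snr$snr, 1) == published$snr), 8)
  expect_s3_class(rep$anova, "taguchi_anova")
  expect_equal(unname(rep$response_table$rank), published$ranking)
})

test_that("pipeline validation emits distinct diagnostics", {
  sheet <- faee_run_sheet()
  bad <- sheet; bad$conversion[3] <- 0
  expect_error(run_pipeline(bad), "invalid response")
  incomplete <- sheet[-2, ]
  expect_error(run_pipeline(incomplete), "balance|incomplete|orthogonality")
  expect_error(run_pipeline(sheet, response_cols = "yield"),
               "missing response")
  nonnum <- sheet; nonnum$conversion <- as.character(nonnum$conversion)
  expect_error(run_pipeline(nonnum), "numeric")
})

test_that("rendered reports are deterministic and brace pooled sources", {
  rep <- run_pipeline(faee_run_sheet())
  r1 <- render_report(rep)
  r2 <- render_report(run_pipeline(faee_run_sheet()))
  expect_identical(r1, r2)   # byte-identical for identical inputs
  expect_match(r1, "\\{2\\}")      # pooled Time df in braces
  expect_match(r1, "\\{20\\.4\\}") # pooled Time SS in braces
  expect_match(r1, "Predicted S/N")
})

test_that("JSON reports carry the same full-precision numbers as the report object", {
  rep <- run_pipeline(faee_run_sheet())
  parsed <- jsonlite::fromJSON(report_json(rep))
  expect_equal(parsed$run_snr$snr, rep$run_snr$snr, tolerance = 1e-12)
  expect_equal(parsed$prediction$predicted_snr,
               rep$prediction$predicted_snr, tolerance = 1e-12)
  expect_equal(parsed$anova$ss, rep$anova$ss, tolerance = 1e-12)
  expect_equal(parsed$response_table$grand_mean,
               rep$response_table$grand_mean, tolerance = 1e-12)
})

test_that("run sheets survive a CSV round trip", {
  sheet <- faee_run_sheet()
  path <- withr::local_tempfile(fileext = ".csv")
  write_run_sheet(sheet, path)
  back <- read_run_sheet(path)
  expect_equal(back$conversion, sheet$conversion)
  expect_equal(names(back), names(sheet))
  rep <- run_pipeline(back)
  expect_equal(rep$run_snr$snr, run_pipeline(sheet)$run_snr$snr)
  suppressWarnings(
    expect_error(read_run_sheet(withr::local_tempfile()), "malformed CSV"))
})

test_that("simulated run sheets flow through the pipeline end to end", {
  sim <- simulate_doe(faee_effect_model(), build_l9(), seed = 42)
  sheet <- decode_design(build_l9(), faee_factor_specs())
  sheet$conversion <- sim$y
  rep <- run_pipeline(sheet)
  expect_s3_class(rep, "taguchi_report")
  # noiseless scenario: the pipeline identifies the planted optimal levels
  mod0 <- planted_model(noise_sd = 0)
  sheet0 <- sheet
  sheet0$conversion <- simulate_doe(mod0, build_l9())$y
  rep0 <- run_pipeline(sheet0)
  expect_equal(unname(rep0$prediction$selected),
               vapply(mod0$offsets, which.max, integer(1),
                      USE.NAMES = FALSE))
  # and the additive prediction is exact when the truth is additive in dB
  # (equivalently multiplicative on the response scale)
  l9 <- build_l9()
  offs_db <- list(c(1, 0, -1), c(-0.5, 0.5, 0), c(2, -1, -1), c(-3, 1, 2))
  snr_true <- 30 + Reduce(`+`, lapply(1:4, function(j)
    offs_db[[j]][unclass(l9)[, j]]))
  sheet_db <- sheet
  sheet_db$conversion <- snr_to_response(snr_true)
  rep_db <- run_pipeline(sheet_db)
  best_db <- 30 + sum(vapply(offs_db, max, numeric(1)))
  expect_equal(rep_db$prediction$predicted_snr, best_db, tolerance = 1e-9)
  expect_equal(rep_db$prediction$predicted_response,
               snr_to_response(best_db), tolerance = 1e-9)
})
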