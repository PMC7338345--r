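# Shared fixtures and independent oracles.

# Per-run S/N of the bundled esterification experiment.
faee_snr <- function() snr_records(faee_run_sheet()$conversion)$snr

# Published values of the bundled experiment (for comparison at printed
# precision).
published <- list(
  snr = c(23.3, 33.1, 33.1, 34.1, 16.8, 38.2, 20.2, 38.0, 14.7),
  level_means = matrix(c(29.8, 29.7, 24.3,
                         25.8, 29.3, 28.7,
                         33.2, 27.3, 23.3,
                         18.3, 30.5, 35.1), nrow = 3),
  delta = c(5.5, 3.5, 9.8, 16.8),
  ranking = c(3L, 4L, 2L, 1L),
  ss = c(Temperature = 59.5, Time = 20.5, `Molar ratio` = 147.2,
         Biocatalyst = 453.9),
  f = c(Temperature = 2.9, `Molar ratio` = 7.2, Biocatalyst = 22.1),
  contribution = c(Temperature = 8.7, Time = 3.0, `Molar ratio` = 21.6,
                   Biocatalyst = 66.6)
)

# Independent oracle: level means of a statistic by brute-force row
# filtering (no reuse of response_table internals).
brute_level_means <- function(cells, values) {
  out <- matrix(NA_real_, 3, ncol(cells))
  for (j in seq_len(ncol(cells)))
    for (k in 1:3) {
      acc <- c()
      for (i in seq_len(nrow(cells)))
        if (cells[i, j] == k) acc <- c(acc, values[i])
      out[k, j] <- sum(acc) / length(acc)
    }
  out
}

# Independent oracle: total sum of squared deviations.
brute_total_ss <- function(values) {
  m <- sum(values) / length(values)
  s <- 0
  for (v in values) s <- s + (v - m)^2
  s
}

# Planted low-noise effect model for ordering properties (noise below the
# smallest offset gap).
planted_model <- function(noise_sd = 0.3) {
  m <- faee_effect_model()
  effect_model(m$grand_mean, m$offsets, noise_sd = noise_sd)
}
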