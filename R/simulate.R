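# Synthetic-data generators emulating the statistical structure the
# analysis assumes: an additive main-effects response surface with Gaussian
# noise on the conversion scale, titration volumes consistent with a chosen
# acidity index, and exponential activity decay.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Additive main-effects model for simulated designed experiments
#'
#' Ground truth for [simulate_doe()]: a grand mean on the response
#' (conversion, %) scale plus one centered offset per factor level, with
#' additive Gaussian noise also on the response scale (the measured
#' quantity is a titration-derived conversion, so noise enters there, not
#' in dB).
#'
#' @param grand_mean Mean response, percent.
#' @param offsets List of numeric length-3 vectors (one per factor, in
#'   array column order); each must sum to 0 (identifiability).
#' @param noise_sd Gaussian noise standard deviation, percent (>= 0).
#' @param replicates Replicate measurements per run (>= 1).
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(grand_mean, offsets, noise_sd = 0, replicates = 1L) {
  if (!is.list(offsets) || !all(lengths(offsets) == 3L))
    stop("invalid model: 'offsets' must be a list of length-3 vectors",
         call. = FALSE)
  bad <- vapply(offsets, function(o) abs(sum(o)) > 1e-8, logical(1))
  if (any(bad))
    stop("invalid model: level offsets must each sum to 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  structure(list(grand_mean = grand_mean, offsets = offsets,
                 noise_sd = noise_sd, replicates = as.integer(replicates)),
            class = "effect_model")
}

#' Default biocatalysis scenario for examples and stochastic tests
#'
#' Plants a biocatalyst-dominated effect structure whose delta ordering
#' (Biocatalyst > Molar ratio > Temperature > Time) mirrors the main-effects
#' ranking seen in the bundled esterification experiment, on a 40% mean
#' conversion with 2% measurement noise.
#'
#' @return An `effect_model` with four factors in the [build_l9()] column
#'   order (Temperature, Time, Molar ratio, Biocatalyst).
#' @export
faee_effect_model <- function() {
  effect_model(
    grand_mean = 40,
    offsets = list(Temperature   = c(4, 3, -7),
                   Time          = c(-5, 4, 1),
                   `Molar ratio` = c(12, -2, -10),
                   Biocatalyst   = c(-25, 5, 20)),
    noise_sd = 2
  )
}

#' Expected (noiseless) responses of an effect model on an array
#'
#' @param model An [effect_model()].
#' @param array An `orthogonal_array`.
#' @return Numeric vector of additive-model responses, one per run.
#' @export
expected_response <- function(model, array) {
  stopifnot(inherits(model, "effect_model"))
  if (!inherits(array, "orthogonal_array")) array <- orthogonal_array(array)
  if (length(model$offsets) != ncol(array))
    stop("invalid model: offset count does not match array factors",
         call. = FALSE)
  model$grand_mean + Reduce(`+`, lapply(seq_len(ncol(array)), function(j)
    model$offsets[[j]][array[, j]]))
}

#' Simulate responses for a designed experiment
#'
#' `y(run) = grand_mean + sum of level offsets + N(0, noise_sd)`, floored
#' at 0.1% so that the log-scale S/N statistic stays defined. Reproducible
#' under a fixed seed; the caller's RNG state is left untouched.
#'
#' @param model An [effect_model()].
#' @param array An `orthogonal_array`.
#' @param seed Optional integer seed.
#' @return Data frame with a `run` column and one response column per
#'   replicate (`y_1`, ...; a single replicate yields column `y`).
#' @examples
#' simulate_doe(faee_effect_model(), build_l9(), seed = 1)
#' @export
simulate_doe <- function(model, array, seed = NULL) {
  mu <- expected_response(model, array)
  n <- length(mu)
  r <- model$replicates
  y <- with_seed(seed,
    matrix(rep(mu, r) + stats::rnorm(n * r, 0, model$noise_sd), nrow = n))
  y <- pmax(y, 0.1)
  colnames(y) <- if (r == 1L) "y" else paste0("y_", seq_len(r))
  cbind(data.frame(run = seq_len(n)), as.data.frame(y))
}

#' Simulate a titration consistent with a known acidity index
#'
#' Back-solves the NaOH volume that a sample with acidity index `true_ai`
#' would consume, then quantizes it to the burette resolution. Reading the
#' resulting record with [acidity_index()] recovers `true_ai` within one
#' resolution step (`molar_mass * molarity * f * resolution / mass`).
#'
#' @param true_ai Planted acidity index, mg/g (>= 0).
#' @param rec_template A [titration_record()] supplying mass, molarity,
#'   correction factor and molar mass (its volume is ignored).
#' @param volume_resolution Burette resolution, mL; 0 keeps the exact
#'   volume.
#' @param volume_sd Optional Gaussian reading noise on the volume, mL.
#' @param seed Optional integer seed (used only when `volume_sd > 0`).
#' @return A `titration_record` with the simulated volume.
#' @export
simulate_titration <- function(true_ai, rec_template, volume_resolution = 0,
                               volume_sd = 0, seed = NULL) {
  stopifnot(inherits(rec_template, "titration_record"))
  if (true_ai < 0) stop("true_ai must be >= 0", call. = FALSE)
  v <- true_ai * rec_template$sample_mass /
    (rec_template$molar_mass * rec_template$titrant_molarity *
       rec_template$correction_factor)
  if (volume_sd > 0)
    v <- v + with_seed(seed, stats::rnorm(1, 0, volume_sd))
  if (volume_resolution > 0)
    v <- round(v / volume_resolution) * volume_resolution
  v <- max(v, 0)
  titration_record(rec_template$sample_mass, rec_template$titrant_molarity,
                   v, rec_template$correction_factor,
                   rec_template$molar_mass)
}

#' Simulate a thermal-deactivation time series
#'
#' `A(t) = a0 * exp(-k t) + N(0, noise_sd)`, floored at 0.1% so the
#' log-linear half-life fit stays defined.
#'
#' @param k First-order deactivation rate constant, /min (> 0).
#' @param times Sampling times, minutes; strictly increasing from 0, >= 3
#'   points (downstream fitting needs a residual degree of freedom).
#' @param a0 Initial activity, percent (default 100).
#' @param noise_sd Gaussian noise standard deviation, percent of initial.
#' @param seed Optional integer seed.
#' @return Data frame with columns `time` (min) and `activity` (%).
#' @examples
#' simulate_decay(k = log(2) / 105, times = seq(0, 210, 15), seed = 1)
#' @export
simulate_decay <- function(k, times, a0 = 100, noise_sd = 0, seed = NULL) {
  if (k <= 0) stop("rate constant k must be > 0", call. = FALSE)
  if (length(times) < 3L)
    stop("need >= 3 sampling times for a downstream fit", call. = FALSE)
  if (times[1L] != 0 || any(diff(times) <= 0))
    stop("times must start at 0 and be strictly increasing", call. = FALSE)
  a <- a0 * exp(-k * times)
  if (noise_sd > 0)
    a <- a + with_seed(seed, stats::rnorm(length(times), 0, noise_sd))
  data.frame(time = times, activity = pmax(a, 0.1))
}
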