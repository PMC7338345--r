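# Larger-is-better signal-to-noise analysis: per-run S/N ratios, the
# main-effects response table with delta ranking, and the additive
# predicted-optimum S/N with back-transformation to the response scale.

#' Larger-is-better signal-to-noise ratio
#'
#' The quality statistic maximized when the response is both large and
#' consistent:
#' \deqn{S/N = -10 \log_{10}\left(\frac{1}{n}\sum_{i=1}^n \frac{1}{y_i^2}\right)}
#' For a single observation this reduces to `20 * log10(y)`.
#'
#' @param y Numeric vector of strictly positive replicate responses
#'   (percent conversion in the esterification application).
#' @return S/N ratio in decibels.
#' @examples
#' snr_larger_is_better(81.7)   # 38.24 dB
#' snr_larger_is_better(c(10, 10, 10))  # 20 dB
#' @export
snr_larger_is_better <- function(y) {
  if (!is.numeric(y) || length(y) == 0L || anyNA(y))
    stop("responses must be a non-empty numeric vector", call. = FALSE)
  if (any(y <= 0))
    stop("invalid response: all responses must be > 0 (log-scale statistic)",
         call. = FALSE)
  -10 * log10(mean(1 / y^2))
}

#' Back-transform an S/N ratio to the response scale
#'
#' Inverse of the single-observation larger-is-better statistic:
#' `10^(snr/20)`, so that `snr_to_response(snr_larger_is_better(y)) == y`
#' for scalar `y`.
#'
#' @param snr S/N ratio in decibels.
#' @return Response in the original units.
#' @export
snr_to_response <- function(snr) 10^(snr / 20)

#' Per-run S/N ratios for a designed experiment
#'
#' @param responses Either a numeric vector (one response per run), a matrix
#'   or data frame of replicate columns (one row per run), or a list of
#'   replicate vectors.
#' @return Data frame with columns `run` and `snr` (dB).
#' @export
snr_records <- function(responses) {
  reps <- if (is.list(responses) && !is.data.frame(responses)) responses
          else if (is.matrix(responses) || is.data.frame(responses))
            lapply(seq_len(nrow(responses)), function(i)
              as.numeric(responses[i, , drop = TRUE]))
          else as.list(as.numeric(responses))
  data.frame(run = seq_along(reps),
             snr = vapply(reps, snr_larger_is_better, numeric(1)))
}

#' Main-effects response table of S/N ratios
#'
#' For each factor, the level mean is the arithmetic mean of the per-run S/N
#' over the runs where that factor sits at that level; delta is the range of
#' the three level means and factors are ranked by delta (rank 1 = largest;
#' ties broken by column order, leftmost first).
#'
#' @param array An `orthogonal_array` (must pass [check_orthogonality()]).
#' @param snr Per-run S/N: a numeric vector in run order or the data frame
#'   from [snr_records()].
#' @return An object of class `snr_response_table`: list with `level_means`
#'   (3 x n_factors matrix, dB), `delta`, `rank`, `grand_mean` and `n_runs`.
#' @examples
#' sheet <- faee_run_sheet()
#' rt <- response_table(build_l9(), snr_records(sheet$conversion)$snr)
#' print(rt)
#' @export
response_table <- function(array, snr) {
  if (!inherits(array, "orthogonal_array")) array <- orthogonal_array(array)
  if (is.data.frame(snr)) snr <- snr$snr[order(snr$run)]
  if (length(snr) != nrow(array))
    stop("incomplete design: need one S/N value per run (", nrow(array),
         "), got ", length(snr), call. = FALSE)
  chk <- check_orthogonality(array)
  if (!chk$pass)
    stop("array fails balance/orthogonality; response-table means would be biased",
         call. = FALSE)
  lm_ <- vapply(seq_len(ncol(array)), function(j)
    vapply(1:3, function(k) mean(snr[array[, j] == k]), numeric(1)),
    numeric(3))
  dimnames(lm_) <- list(level = 1:3, factor = colnames(array))
  delta <- apply(lm_, 2L, function(x) max(x) - min(x))
  # rank 1 = largest delta; ties to the leftmost column
  rk <- rank(-delta, ties.method = "first")
  structure(list(level_means = lm_,
                 delta = delta,
                 rank = stats::setNames(as.integer(rk), colnames(array)),
                 grand_mean = mean(snr),
                 n_runs = nrow(array)),
            class = "snr_response_table")
}

#' @export
print.snr_response_table <- function(x, digits = 1, ...) {
  tab <- rbind(formatC(round(x$level_means, digits), format = "f",
                       digits = digits),
               Delta = formatC(round(x$delta, digits), format = "f",
                               digits = digits),
               Ranking = as.character(x$rank))
  cat("S/N ratios response (dB)\n")
  print(tab, quote = FALSE, right = TRUE)
  cat(sprintf("Grand mean S/N: %.*f dB over %d runs\n",
              digits, x$grand_mean, x$n_runs))
  invisible(x)
}

#' Best level of each factor under the larger-is-better objective
#'
#' @param table An `snr_response_table`.
#' @return Named integer vector: argmax level (full precision) per factor.
#' @export
optimal_levels <- function(table) {
  stopifnot(inherits(table, "snr_response_table"))
  apply(table$level_means, 2L, which.max)
}

#' Predicted optimum S/N under the additive main-effects model
#'
#' The expected S/N at a chosen level combination is the grand mean plus the
#' sum of the selected factors' level-mean deviations:
#' \deqn{S/N_{pred} = \overline{S/N} + \sum_j (S/N_j - \overline{S/N})}
#' With an empty selection the prediction is the grand mean. The prediction
#' is additive in dB and can back-transform above the 100% physical bound of
#' a conversion; such values are reported as-is with `exceeds_bound = TRUE`
#' rather than clipped, so that lack of fit of the additive model stays
#' visible.
#'
#' @param table An `snr_response_table`.
#' @param factors Character vector of factors entering the sum; defaults to
#'   all factors in the table.
#' @param levels Named integer vector of chosen levels for `factors`;
#'   defaults to each factor's argmax level ([optimal_levels()]).
#' @return An object of class `snr_prediction`: list with `predicted_snr`
#'   (dB), `predicted_response` (response units via [snr_to_response()]),
#'   `selected` (named levels used) and `exceeds_bound`.
#' @export
predict_optimal_snr <- function(table, factors = colnames(table$level_means),
                                levels = NULL) {
  stopifnot(inherits(table, "snr_response_table"))
  known <- colnames(table$level_means)
  if (!all(factors %in% known))
    stop("invalid selection: unknown factor(s) ",
         paste(setdiff(factors, known), collapse = ", "), call. = FALSE)
  if (is.null(levels)) {
    levels <- optimal_levels(table)[factors]
  } else {
    if (is.null(names(levels))) names(levels) <- factors
    if (!all(factors %in% names(levels)))
      stop("invalid selection: 'levels' must name every selected factor",
           call. = FALSE)
    levels <- levels[factors]
  }
  if (length(factors) && !all(levels %in% 1:3))
    stop("invalid selection: levels must be in {1, 2, 3}", call. = FALSE)
  gm <- table$grand_mean
  dev <- if (length(factors))
    sum(table$level_means[cbind(levels, match(factors, known))] - gm)
  else 0
  pred <- gm + dev
  resp <- snr_to_response(pred)
  structure(list(predicted_snr = pred,
                 predicted_response = resp,
                 selected = stats::setNames(as.integer(levels), factors),
                 exceeds_bound = resp > 100),
            class = "snr_prediction")
}

#' @export
print.snr_prediction <- function(x, digits = 1, ...) {
  sel <- if (length(x$selected))
    paste(names(x$selected), "=L", x$selected, sep = "", collapse = ", ")
  else "(none; grand mean)"
  cat(sprintf("Predicted S/N: %.*f dB at %s\n", digits, x$predicted_snr, sel))
  cat(sprintf("Back-transformed response: %.*f%s\n", digits,
              x$predicted_response,
              if (x$exceeds_bound)
                "  [exceeds 100%: additive-model extrapolation]" else ""))
  invisible(x)
}
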