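# Taguchi-style ANOVA of S/N ratios: between-level sums of squares, pooling
# of near-null factors into the residual, F and p statistics, and percent
# contribution.

#' Between-level sum of squares of S/N for one factor
#'
#' \deqn{SS_f = \sum_{k=1}^{3} n_k (\bar{s}_{fk} - \bar{s})^2}
#' where \eqn{n_k} is the number of runs at level `k` (3 for an L9),
#' \eqn{\bar{s}_{fk}} the level-mean S/N and \eqn{\bar{s}} the grand mean.
#' For a complete single-replicate L9 the four factor SS sum exactly to the
#' total SS of the nine S/N values (the design is saturated).
#'
#' @param array An `orthogonal_array`.
#' @param snr Per-run S/N values in run order (vector or [snr_records()]
#'   data frame).
#' @param factor Factor name or column index.
#' @return Sum of squares in dB^2.
#' @export
factor_ss <- function(array, snr, factor) {
  if (!inherits(array, "orthogonal_array")) array <- orthogonal_array(array)
  if (is.data.frame(snr)) snr <- snr$snr[order(snr$run)]
  if (length(snr) != nrow(array))
    stop("incomplete design: need one S/N value per run", call. = FALSE)
  j <- if (is.character(factor)) match(factor, colnames(array)) else factor
  if (is.na(j) || j < 1L || j > ncol(array))
    stop("invalid selection: unknown factor '", factor, "'", call. = FALSE)
  gm <- mean(snr)
  lv <- split(snr, array[, j])
  sum(vapply(lv, function(v) length(v) * (mean(v) - gm)^2, numeric(1)))
}

#' Choose factors to pool into the residual
#'
#' A saturated design (such as a single-replicate L9 with four factors) has
#' no residual degrees of freedom; F tests require pooling the sum of
#' squares of (near-)null factors into an error term. Strategy
#' `"smallest-ss"` pools factors in increasing order of SS until the
#' residual has at least `target_df` degrees of freedom; `"explicit"`
#' returns `pool` unchanged.
#'
#' @param array An `orthogonal_array`.
#' @param snr Per-run S/N values.
#' @param strategy `"smallest-ss"` or `"explicit"`.
#' @param pool Factor names for `strategy = "explicit"`.
#' @param target_df Minimum residual degrees of freedom (default 2).
#' @return Character vector of pooled factor names.
#' @export
auto_pool <- function(array, snr, strategy = c("smallest-ss", "explicit"),
                      pool = NULL, target_df = 2L) {
  strategy <- match.arg(strategy)
  if (strategy == "explicit") return(as.character(pool))
  if (!inherits(array, "orthogonal_array")) array <- orthogonal_array(array)
  fx <- colnames(array)
  ss <- vapply(fx, function(f) factor_ss(array, snr, f), numeric(1))
  ord <- fx[order(ss)]
  pooled <- character(0)
  df <- 0L
  for (f in ord) {
    if (df >= target_df) break
    pooled <- c(pooled, f)
    df <- df + 2L   # three-level factor: df = 2
  }
  pooled
}

#' Pooled ANOVA of S/N ratios with percent contribution
#'
#' Decomposes the S/N variation of a complete three-level design into
#' per-factor between-level sums of squares, pools the chosen factors into
#' the residual, and reports mean squares, F ratios against the residual
#' mean square, upper-tail F probabilities, and each factor's percent
#' contribution. The contribution denominator is the sum of SS over *all*
#' factors (pooled included), so contributions total 100%.
#'
#' Degenerate inputs with zero total SS (constant S/N) yield `NA`
#' contributions and F statistics rather than an error.
#'
#' @param array An `orthogonal_array`.
#' @param snr Per-run S/N values (vector or [snr_records()] data frame).
#' @param pool Factors pooled into the residual: character vector, or
#'   `"auto"` for [auto_pool()]'s smallest-SS rule. Must be non-empty for a
#'   saturated design.
#' @param alpha Significance level for flagging (default 0.05).
#' @return A data frame of class `taguchi_anova` with columns `source`,
#'   `df`, `ss`, `ms`, `f_value`, `p_value`, `contribution`, `pooled`,
#'   `significant`, ending in `Residual` and `Total` rows. The grand mean
#'   is attached as attribute `grand_mean`.
#' @examples
#' sheet <- faee_run_sheet()
#' snr <- snr_records(sheet$conversion)
#' anova_snr(build_l9(), snr, pool = "auto")
#' @export
anova_snr <- function(array, snr, pool = "auto", alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("invalid parameter: alpha must lie in (0, 1)", call. = FALSE)
  if (!inherits(array, "orthogonal_array")) array <- orthogonal_array(array)
  if (is.data.frame(snr)) snr <- snr$snr[order(snr$run)]
  if (length(snr) != nrow(array))
    stop("incomplete design: need one S/N value per run", call. = FALSE)
  fx <- colnames(array)
  if (identical(pool, "auto")) pool <- auto_pool(array, snr)
  pool <- as.character(pool)
  if (!all(pool %in% fx))
    stop("invalid selection: unknown pooled factor(s) ",
         paste(setdiff(pool, fx), collapse = ", "), call. = FALSE)
  n <- nrow(array)
  total_df <- n - 1L
  saturated <- sum(rep(2L, length(fx))) == total_df
  if (saturated && length(pool) == 0L)
    stop("no residual: the design is saturated; pool at least one factor",
         call. = FALSE)

  ss <- vapply(fx, function(f) factor_ss(array, snr, f), numeric(1))
  df <- rep(2L, length(fx))
  total_ss <- sum((snr - mean(snr))^2)
  pooled <- fx %in% pool
  res_ss <- sum(ss[pooled]) + (total_ss - sum(ss))  # + pure error if any
  res_df <- sum(df[pooled]) + (total_df - sum(df))
  res_ms <- if (res_df > 0L) res_ss / res_df else NA_real_

  ms <- ss / df
  f_val <- ifelse(pooled, NA_real_, ms / res_ms)
  p_val <- ifelse(is.na(f_val), NA_real_,
                  stats::pf(f_val, df, res_df, lower.tail = FALSE))
  denom <- sum(ss)
  contrib <- if (denom > 0) 100 * ss / denom else rep(NA_real_, length(ss))
  if (denom == 0) {
    f_val[] <- NA_real_
    p_val[] <- NA_real_
  }

  out <- data.frame(
    source = c(fx, "Residual", "Total"),
    df = c(df, res_df, total_df),
    ss = c(ss, res_ss, total_ss),
    ms = c(ms, res_ms, NA_real_),
    f_value = c(f_val, NA_real_, NA_real_),
    p_value = c(p_val, NA_real_, NA_real_),
    contribution = c(contrib, NA_real_,
                     if (denom > 0) sum(contrib) else NA_real_),
    pooled = c(pooled, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  structure(out, class = c("taguchi_anova", "data.frame"),
            grand_mean = mean(snr), alpha = alpha)
}

#' @export
print.taguchi_anova <- function(x, digits = 1, ...) {
  fmt <- function(v, d = digits) ifelse(is.na(v), "-", formatC(v, format = "f",
                                                               digits = d))
  disp <- data.frame(
    Factor = x$source,
    DF = ifelse(x$pooled, sprintf("{%d}", x$df), as.character(x$df)),
    SS = ifelse(x$pooled, sprintf("{%s}", fmt(x$ss)), fmt(x$ss)),
    MS = ifelse(x$pooled, "-", fmt(x$ms)),
    `F-value` = fmt(x$f_value),
    `p-value` = paste0(fmt(x$p_value, 3),
                       ifelse(x$significant, " *", "")),
    `Contribution (%)` = fmt(x$contribution),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  cat("ANOVA of S/N ratios (pooled sources in braces; * p <",
      attr(x, "alpha"), ")\n")
  print(disp, row.names = FALSE)
  invisible(x)
}
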