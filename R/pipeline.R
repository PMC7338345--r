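# End-to-end pipeline: run-sheet I/O, the full S/N -> response-table ->
# ANOVA -> prediction analysis, and deterministic text/JSON report
# rendering.

#' Read a run sheet from CSV
#'
#' Comma-separated, UTF-8, decimal point, header row mandatory. Expected
#' columns: `run`, one column per factor (coded levels or physical values)
#' and one or more response columns.
#'
#' @param path Path to the CSV file.
#' @return Data frame.
#' @export
read_run_sheet <- function(path) {
  sheet <- tryCatch(
    utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("malformed CSV: ", conditionMessage(e),
                             call. = FALSE))
  if (!"run" %in% names(sheet))
    stop("malformed CSV: a 'run' column is required", call. = FALSE)
  sheet
}

#' Write a run sheet (or any result table) to CSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_sheet <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full Taguchi S/N analysis pipeline
#'
#' From a complete run sheet for a three-level orthogonal design: per-run
#' larger-is-better S/N ratios, the main-effects response table with delta
#' ranking, the pooled ANOVA with percent contribution, and the additive
#' predicted optimum with back-transformed response.
#'
#' @param run_sheet Data frame with a `run` column, factor columns (coded
#'   or physical) and the response column(s); see [faee_run_sheet()] for
#'   the bundled example.
#' @param specs List of [factor_spec()]s; defaults to the FAEE experiment's
#'   factors. Used to encode physical values; ignored when `array` is
#'   given.
#' @param response_cols Names of the replicate response columns (default
#'   `"conversion"`).
#' @param array Optional `orthogonal_array` overriding the encoding of the
#'   run sheet.
#' @param pool Factors pooled into the ANOVA residual (`"auto"` or names).
#' @param alpha Significance level.
#' @return An object of class `taguchi_report`: list with `run_snr` (run
#'   sheet + `snr` column), `response_table`, `anova`, `prediction`, and
#'   `config`.
#' @examples
#' rep <- run_pipeline(faee_run_sheet())
#' print(rep)
#' @export
run_pipeline <- function(run_sheet, specs = faee_factor_specs(),
                         response_cols = "conversion", array = NULL,
                         pool = "auto", alpha = 0.05) {
  missing_cols <- setdiff(response_cols, names(run_sheet))
  if (length(missing_cols))
    stop("malformed run sheet: missing response column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  responses <- as.matrix(run_sheet[, response_cols, drop = FALSE])
  if (!is.numeric(responses) || anyNA(responses))
    stop("malformed run sheet: responses must be numeric and complete",
         call. = FALSE)
  if (any(responses <= 0))
    stop("invalid response: all responses must be > 0 ",
         "(run(s) ", paste(run_sheet$run[apply(responses <= 0, 1, any)],
                           collapse = ", "), ")", call. = FALSE)
  if (is.null(array)) array <- encode_design(run_sheet, specs)
  if (nrow(array) != nrow(run_sheet))
    stop("incomplete design: run sheet and array disagree on run count",
         call. = FALSE)

  rec <- snr_records(responses)
  run_snr <- cbind(run_sheet, snr = rec$snr)
  rt <- response_table(array, rec$snr)
  an <- anova_snr(array, rec$snr, pool = pool, alpha = alpha)
  pred <- predict_optimal_snr(rt)

  structure(list(run_snr = run_snr,
                 response_table = rt,
                 anova = an,
                 prediction = pred,
                 config = list(response_cols = response_cols, pool = pool,
                               alpha = alpha,
                               factors = colnames(array))),
            class = "taguchi_report")
}

#' @export
print.taguchi_report <- function(x, digits = 1, ...) {
  cat(render_report(x, digits = digits))
  invisible(x)
}

#' Render a pipeline report as deterministic text
#'
#' Byte-identical output for identical inputs; pooled ANOVA sources are
#' shown in braces. Rounding is presentation-only: the underlying report
#' object (and [report_json()]) carries full precision.
#'
#' @param report A `taguchi_report` from [run_pipeline()].
#' @param digits Rounding digits for display (default 1).
#' @return A single character string.
#' @export
render_report <- function(report, digits = 1) {
  stopifnot(inherits(report, "taguchi_report"))
  out <- utils::capture.output({
    cat("== Per-run S/N (dB) ==\n")
    disp <- report$run_snr
    num <- vapply(disp, is.numeric, logical(1))
    disp[num] <- lapply(disp[num], round, digits)
    print(disp, row.names = FALSE)
    cat("\n== Response table ==\n")
    print(report$response_table, digits = digits)
    cat("\n== ANOVA ==\n")
    print(report$anova, digits = digits)
    cat("\n== Predicted optimum ==\n")
    print(report$prediction, digits = digits)
  })
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Serialize a pipeline report to JSON at full precision
#'
#' The JSON carries the same numbers as the report object before any
#' display rounding.
#'
#' @param report A `taguchi_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly, when `path` is given).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "taguchi_report"))
  rt <- report$response_table
  x <- list(
    run_snr = report$run_snr,
    response_table = list(
      level_means = as.data.frame(rt$level_means),
      delta = as.list(rt$delta),
      rank = as.list(rt$rank),
      grand_mean = rt$grand_mean
    ),
    anova = as.data.frame(unclass(report$anova)[
      c("source", "df", "ss", "ms", "f_value", "p_value",
        "contribution", "pooled", "significant")]),
    prediction = list(
      predicted_snr = report$prediction$predicted_snr,
      predicted_response = report$prediction$predicted_response,
      selected = as.list(report$prediction$selected),
      exceeds_bound = report$prediction$exceeds_bound
    ),
    config = report$config
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path, useBytes = TRUE)
  invisible(js)
}
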