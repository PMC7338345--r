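# Three-level orthogonal-array experiment design: construction, validation,
# and coding/decoding between coded levels {1,2,3} and physical factor values.

#' Define an experimental factor with three levels
#'
#' A factor specification carries the name, measurement unit and the three
#' physical values (or labels) behind coded levels 1, 2 and 3. Levels may be
#' numeric (temperature, time) or character labels (a molar-ratio label such
#' as `"1:3"`, which is categorical in the analysis).
#'
#' @param name Factor name; must be unique within a design.
#' @param levels Vector of exactly 3 distinct physical values or labels,
#'   ordered so that `levels[k]` is coded level `k`.
#' @param unit Measurement unit label (e.g. `"°C"`, `"h"`, `"%m/m"`).
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("Temperature", c(30, 40, 50), unit = "°C")
#' @export
factor_spec <- function(name, levels, unit = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string", call. = FALSE)
  if (length(levels) != 3L || anyDuplicated(levels))
    stop("a factor_spec requires exactly 3 distinct levels", call. = FALSE)
  structure(list(name = name, unit = unit, levels = levels),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  unit <- if (nzchar(x$unit)) paste0(" [", x$unit, "]") else ""
  cat(sprintf("Factor %s%s: L1=%s  L2=%s  L3=%s\n", x$name, unit,
              x$levels[1], x$levels[2], x$levels[3]))
  invisible(x)
}

#' Construct an orthogonal array of coded levels
#'
#' Wraps a runs-by-factors matrix of coded levels in `{1, 2, 3}` after
#' checking its alphabet and shape. Balance and pairwise orthogonality are
#' *not* enforced here; use [check_orthogonality()] to audit them.
#'
#' @param cells Integer matrix (runs x factors) with entries in `{1, 2, 3}`.
#' @param factor_names Optional column names; defaults to existing colnames
#'   or `F1..Fk`.
#' @return An object of class `orthogonal_array` (a classed integer matrix).
#' @seealso [build_l9()], [check_orthogonality()]
#' @export
orthogonal_array <- function(cells, factor_names = NULL) {
  cells <- as.matrix(cells)
  if (!is.numeric(cells) || anyNA(cells) || !all(cells %in% c(1, 2, 3)))
    stop("array cells must all be coded levels in {1, 2, 3}", call. = FALSE)
  storage.mode(cells) <- "integer"
  if (is.null(factor_names)) factor_names <- colnames(cells)
  if (is.null(factor_names)) factor_names <- paste0("F", seq_len(ncol(cells)))
  if (length(factor_names) != ncol(cells) || anyDuplicated(factor_names))
    stop("factor names must be unique and match the number of columns",
         call. = FALSE)
  dimnames(cells) <- list(run = seq_len(nrow(cells)), factor = factor_names)
  class(cells) <- c("orthogonal_array", class(cells))
  cells
}

#' @export
print.orthogonal_array <- function(x, ...) {
  cat(sprintf("Orthogonal array: %d runs x %d factors (coded levels 1..3)\n",
              nrow(x), ncol(x)))
  print(unclass(x))
  invisible(x)
}

#' The L9 orthogonal array (9 runs, 4 three-level factors)
#'
#' Returns the standard L9 design in the canonical run order used throughout
#' this package: run 1 is all-level-1 and run 6 is coded (2, 3, 1, 2). Every
#' column contains each level exactly three times and every pair of columns
#' contains each of the nine ordered level pairs exactly once.
#'
#' @param factor_names Column names for the four factors.
#' @return An `orthogonal_array` with 9 runs and 4 factors.
#' @examples
#' l9 <- build_l9()
#' check_orthogonality(l9)$pass
#' @export
build_l9 <- function(factor_names = c("Temperature", "Time",
                                      "Molar ratio", "Biocatalyst")) {
  cells <- matrix(c(1L, 1L, 1L, 1L,
                    1L, 2L, 2L, 2L,
                    1L, 3L, 3L, 3L,
                    2L, 1L, 2L, 3L,
                    2L, 2L, 3L, 1L,
                    2L, 3L, 1L, 2L,
                    3L, 1L, 3L, 2L,
                    3L, 2L, 1L, 3L,
                    3L, 3L, 2L, 1L),
                  ncol = 4L, byrow = TRUE)
  orthogonal_array(cells, factor_names)
}

#' Audit balance and pairwise orthogonality of a coded array
#'
#' A three-level array is balanced when each level appears `n_runs/3` times
#' in every column, and pairwise orthogonal when for every pair of columns
#' each of the 9 ordered level pairs appears `n_runs/9` times (exactly once
#' for an L9). The report lists every violating column and column pair.
#'
#' @param array An `orthogonal_array` or a plain matrix of levels in
#'   `{1, 2, 3}`.
#' @return A list of class `oa_check` with elements `pass` (logical),
#'   `unbalanced_columns` (character) and `nonorthogonal_pairs` (two-column
#'   character matrix of offending factor pairs).
#' @export
check_orthogonality <- function(array) {
  if (!inherits(array, "orthogonal_array")) array <- orthogonal_array(array)
  n <- nrow(array)
  fx <- colnames(array)
  bal_bad <- fx[vapply(seq_along(fx), function(j) {
    cnt <- tabulate(array[, j], nbins = 3L)
    n %% 3L != 0L || any(cnt != n / 3L)
  }, logical(1))]
  pairs <- utils::combn(seq_along(fx), 2L)
  bad_pair <- matrix(character(0), ncol = 2L,
                     dimnames = list(NULL, c("factor_a", "factor_b")))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1L, p]; b <- pairs[2L, p]
    # frequency of each ordered level pair (a-level, b-level)
    freq <- table(factor(array[, a], 1:3), factor(array[, b], 1:3))
    if (n %% 9L != 0L || any(freq != n / 9L))
      bad_pair <- rbind(bad_pair, c(fx[a], fx[b]))
  }
  structure(list(pass = length(bal_bad) == 0L && nrow(bad_pair) == 0L,
                 unbalanced_columns = bal_bad,
                 nonorthogonal_pairs = bad_pair),
            class = "oa_check")
}

#' @export
print.oa_check <- function(x, ...) {
  cat("Orthogonality check:", if (x$pass) "PASS" else "FAIL", "\n")
  if (length(x$unbalanced_columns))
    cat("  unbalanced columns:",
        paste(x$unbalanced_columns, collapse = ", "), "\n")
  if (nrow(x$nonorthogonal_pairs))
    cat("  non-orthogonal pairs:",
        paste(apply(x$nonorthogonal_pairs, 1L, paste, collapse = " x "),
              collapse = "; "), "\n")
  invisible(x)
}

#' Decode a coded array into a run sheet of physical values
#'
#' Replaces each coded level `k` in column `f` by `specs[[f]]$levels[k]`.
#'
#' @param array An `orthogonal_array`.
#' @param specs List of [factor_spec()] objects, one per array column.
#' @return A data frame with a `run` column followed by one column of
#'   physical values per factor.
#' @examples
#' decode_design(build_l9(), faee_factor_specs())
#' @export
decode_design <- function(array, specs) {
  if (!inherits(array, "orthogonal_array")) array <- orthogonal_array(array)
  if (length(specs) != ncol(array))
    stop("need one factor_spec per array column (got ", length(specs),
         " for ", ncol(array), " columns)", call. = FALSE)
  cols <- lapply(seq_along(specs), function(j) specs[[j]]$levels[array[, j]])
  names(cols) <- vapply(specs, `[[`, "", "name")
  cbind(data.frame(run = seq_len(nrow(array))),
        as.data.frame(cols, check.names = FALSE))
}

#' Encode a physical run sheet back to coded levels
#'
#' Inverse of [decode_design()]: each physical value is looked up in its
#' factor's level list. Values absent from the declared levels are an error.
#'
#' @param run_sheet Data frame with one column per factor, named as in
#'   `specs` (a `run` column, if present, is ignored).
#' @param specs List of [factor_spec()] objects.
#' @return An `orthogonal_array` of coded levels.
#' @export
encode_design <- function(run_sheet, specs) {
  coded <- lapply(specs, function(sp) {
    if (!sp$name %in% names(run_sheet))
      stop("run sheet lacks a column for factor '", sp$name, "'",
           call. = FALSE)
    idx <- match(run_sheet[[sp$name]], sp$levels)
    if (anyNA(idx))
      stop("values in column '", sp$name,
           "' do not all match the declared levels", call. = FALSE)
    as.integer(idx)
  })
  orthogonal_array(matrix(unlist(coded), ncol = length(specs)),
                   vapply(specs, `[[`, "", "name"))
}
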