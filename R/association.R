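#' @title Association between unit-level indices
#' @description Pairwise product-moment correlations between the efficiency
#'   indices, the risk index and the composite effectiveness index across
#'   care units, with two-sided p-values from the t transform. The source
#'   analyses report pairwise coefficients with raw (uncorrected) p-values;
#'   a rank-based option and Holm adjustment are available but off by
#'   default.
#' @name association_report
NULL

#' Product-moment correlation with input validation
#'
#' @param x,y Numeric vectors of equal length (at least 3), neither constant.
#' @return The Pearson correlation at full precision.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have the same length", class = "casemixr_validation_error")
  }
  if (length(x) < 3) {
    abort("at least 3 paired observations are required", class = "casemixr_validation_error")
  }
  if (anyNA(x) || anyNA(y)) {
    abort("missing values are not allowed", class = "casemixr_validation_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for a constant vector",
          class = "casemixr_computation_error")
  }
  cor(x, y, method = "pearson")
}

#' Two-sided p-value for a correlation coefficient
#'
#' Uses the exact-null t transform `t = r * sqrt((n - 2) / (1 - r^2))` with
#' `n - 2` degrees of freedom. For `|r| = 1` the limit 0 is returned with a
#' warning (the transform degenerates).
#'
#' @param r Correlation coefficient.
#' @param n Number of paired observations (at least 3).
#' @return Two-sided p-value in (0, 1\].
#' @export
#' @examples
#' correlation_pvalue(0, 20)          # 1
#' correlation_pvalue(0.59, 187)      # far below 0.0001
correlation_pvalue <- function(r, n) {
  if (n < 3) {
    abort("n must be at least 3", class = "casemixr_validation_error")
  }
  if (abs(r) > 1 + 1e-12) {
    abort("|r| cannot exceed 1", class = "casemixr_validation_error")
  }
  if (abs(r) >= 1) {
    warn("|r| = 1: returning the degenerate limit p = 0",
         class = "casemixr_degenerate_correlation")
    return(0)
  }
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
}

#' Pairwise correlations among unit-level indices
#'
#' All pairwise correlations among the five indices (visits, episodes and
#' cost efficiency indices, risk index, composite effectiveness index) across
#' units, with p-values and a significance flag at `alpha` (strict
#' inequality).
#'
#' @param unit_table A tibble with one row per unit containing the `vars`
#'   columns (typically [unit_index_table()] joined with [si_table()]).
#' @param vars Columns to correlate.
#' @param alpha Significance level (strict `p < alpha`).
#' @param method `"pearson"` (default) or `"spearman"` (rank-transformed
#'   before the same machinery).
#' @param adjust `"none"` (default, matching raw reporting) or `"holm"`.
#' @return A tibble with `var1`, `var2`, `r`, `p_value`, `n`, `significant`,
#'   one row per unordered pair.
#' @export
correlation_matrix <- function(unit_table,
                               vars = c("visits_ei", "costs_ei", "episodes_ei",
                                        "ri", "si"),
                               alpha = 0.05,
                               method = c("pearson", "spearman"),
                               adjust = c("none", "holm")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  if (!(alpha > 0 && alpha < 1)) {
    abort("alpha must lie in (0, 1)", class = "casemixr_config_error")
  }
  check_columns(unit_table, vars, "unit index table")
  if (nrow(unit_table) < 3) {
    abort("at least 3 units are required", class = "casemixr_validation_error")
  }
  dat <- unit_table[, vars, drop = FALSE]
  if (method == "spearman") dat <- as.data.frame(lapply(dat, rank))
  pairs <- utils::combn(vars, 2)
  n <- nrow(dat)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    v1 <- pairs[1, j]; v2 <- pairs[2, j]
    r <- pearson_r(dat[[v1]], dat[[v2]])
    tibble::tibble(var1 = v1, var2 = v2, r = r,
                   p_value = correlation_pvalue(r, n), n = n)
  })
  out <- dplyr::bind_rows(rows)
  if (adjust == "holm") out$p_value <- stats::p.adjust(out$p_value, "holm")
  out$significant <- out$p_value < alpha
  out
}

#' Format a p-value for reports
#'
#' Values below 1e-4 render as `"<0.0001"`; otherwise the value is shown
#' half-away-from-zero rounded. Stored p-values always keep full precision;
#' this affects rendering only.
#'
#' @param p Numeric vector of p-values.
#' @param digits Decimals for rendered values.
#' @return Character vector.
#' @export
format_pvalue <- function(p, digits = 4) {
  ifelse(p < 1e-4, "<0.0001",
         format(round_half_up(p, digits), nsmall = digits, trim = TRUE,
                scientific = FALSE))
}

#' Render the correlation results as a triangular report table
#'
#' Lays the pairwise results out in the conventional triangular layout with
#' `"r (p)"` cells at 2 decimals, rows and columns following the order of
#' `row_vars` / `col_vars`; cells for pairs not covered are left empty.
#'
#' @param correlations Result of [correlation_matrix()].
#' @param row_vars,col_vars Variables to place on rows and columns.
#' @return A tibble with an `index` column and one column per `col_vars`.
#' @export
render_correlation_table <- function(correlations,
                                     row_vars = c("visits_ei", "ri", "si"),
                                     col_vars = c("costs_ei", "episodes_ei", "ri")) {
  cell <- function(v1, v2) {
    hit <- (correlations$var1 == v1 & correlations$var2 == v2) |
      (correlations$var1 == v2 & correlations$var2 == v1)
    if (!any(hit)) return("")
    r <- correlations$r[hit][1]
    p <- correlations$p_value[hit][1]
    sprintf("%s (%s)", format(round_half_up(r, 2), nsmall = 2, trim = TRUE),
            format_pvalue(p, 2))
  }
  out <- tibble::tibble(index = row_vars)
  for (cv in col_vars) {
    out[[cv]] <- vapply(row_vars, function(rv) {
      if (rv == cv) "" else cell(rv, cv)
    }, character(1), USE.NAMES = FALSE)
  }
  out
}
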