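#' @title Composite effectiveness index (SI)
#' @description Scores each of the 20 care-quality indicators on a 0-100
#'   scale and aggregates them per unit into the composite synthetic
#'   effectiveness index. The exact construction used operationally by the
#'   Catalan contract indicators is not public; the scoring rules here are a
#'   documented re-specification that preserves each indicator's direction:
#'   higher-is-better proportions score `100 * compliant / eligible`,
#'   lower-is-better proportions score `100 * (1 - compliant / eligible)`,
#'   and pharmacy-cost indicators score `100 * min(1, benchmark / observed)`.
#'   Aggregation is a weighted mean over the indicators available for the
#'   unit, with equal weights by default.
#' @name effectiveness_si
NULL

#' Score one indicator observation
#'
#' @param obs A one-row list/tibble with `eligible` and `compliant`
#'   (proportion kind) or `observed_cost` (cost kind).
#' @param def The matching one-row indicator definition (see
#'   [default_indicator_definitions()]).
#' @return A score in \[0, 100\], or `NA` (missing) when no patients were
#'   eligible.
#' @export
#' @examples
#' def <- default_indicator_definitions()
#' score_indicator(list(eligible = 200L, compliant = 150L), def[1, ])   # 75
#' score_indicator(list(observed_cost = 0.80), def[17, ])               # 50
score_indicator <- function(obs, def) {
  if (def$kind == "proportion") {
    if (is.na(obs$eligible) || obs$eligible == 0) return(NA_real_)
    if (obs$compliant > obs$eligible) {
      abort("compliant exceeds eligible", class = "casemixr_validation_error")
    }
    prop <- obs$compliant / obs$eligible
    if (def$direction == "higher_better") 100 * prop else 100 * (1 - prop)
  } else {
    if (is.na(obs$observed_cost)) return(NA_real_)
    if (obs$observed_cost <= 0) {
      abort("observed_cost must be positive", class = "casemixr_validation_error")
    }
    100 * min(1, def$benchmark_cost / obs$observed_cost)
  }
}

#' Score a table of indicator observations
#'
#' Vectorized scoring of per-unit indicator observations against their
#' definitions.
#'
#' @param observations Tibble with `unit_id`, `indicator_id`, and the kind's
#'   observation columns (see [read_indicator_observations()]).
#' @param definitions Indicator definition tibble.
#' @return A tibble `unit_id`, `indicator_id`, `score`, `n_eligible`,
#'   `missing`.
#' @export
score_indicators <- function(observations, definitions = default_indicator_definitions()) {
  validate_definitions(definitions)
  check_columns(observations, c("unit_id", "indicator_id"), "indicator observations")
  unknown <- setdiff(observations$indicator_id, definitions$indicator_id)
  if (length(unknown) > 0) {
    abort(paste0("observation(s) for undefined indicator_id: ",
                 paste(sort(unknown), collapse = ", ")),
          class = "casemixr_validation_error")
  }
  idx <- match(observations$indicator_id, definitions$indicator_id)
  kind <- definitions$kind[idx]
  direction <- definitions$direction[idx]
  benchmark <- definitions$benchmark_cost[idx]
  eligible <- if ("eligible" %in% names(observations)) observations$eligible else NA_integer_
  compliant <- if ("compliant" %in% names(observations)) observations$compliant else NA_integer_
  observed_cost <- if ("observed_cost" %in% names(observations)) observations$observed_cost else NA_real_

  is_prop <- kind == "proportion"
  bad <- which(is_prop & !is.na(eligible) & !is.na(compliant) & compliant > eligible)
  if (length(bad) > 0) {
    abort(paste0("indicator row ", bad[1], ": compliant exceeds eligible"),
          class = "casemixr_validation_error")
  }
  bad_cost <- which(!is_prop & !is.na(observed_cost) & observed_cost <= 0)
  if (length(bad_cost) > 0) {
    abort(paste0("indicator row ", bad_cost[1], ": observed_cost must be positive"),
          class = "casemixr_validation_error")
  }

  score <- rep(NA_real_, nrow(observations))
  prop_ok <- is_prop & !is.na(eligible) & eligible > 0 & !is.na(compliant)
  p <- compliant[prop_ok] / eligible[prop_ok]
  score[prop_ok] <- ifelse(direction[prop_ok] == "higher_better",
                           100 * p, 100 * (1 - p))
  cost_ok <- !is_prop & !is.na(observed_cost)
  score[cost_ok] <- 100 * pmin(1, benchmark[cost_ok] / observed_cost[cost_ok])

  tibble::tibble(
    unit_id = observations$unit_id,
    indicator_id = observations$indicator_id,
    score = score,
    n_eligible = ifelse(is_prop, eligible, NA_integer_),
    missing = is.na(score)
  )
}

#' Aggregate indicator scores into the composite index
#'
#' Weighted mean of the non-missing scores, with weights renormalized over
#' the available indicators; equal weights by default. The result always
#' lies between the smallest and largest component score (hence in
#' \[0, 100\]).
#'
#' @param scores Numeric vector of indicator scores (may contain `NA`).
#' @param weights Optional positive weights, one per score.
#' @return A list with `si`, `n_indicators_used`, `weights` (the renormalized
#'   weights actually applied, `NA` for missing scores).
#' @export
#' @examples
#' synthetic_index(c(40, 60))$si            # 50
#' synthetic_index(c(90, 30), c(2, 1))$si   # 70
synthetic_index <- function(scores, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(scores))
  if (length(weights) != length(scores)) {
    abort("weights must match scores in length", class = "casemixr_validation_error")
  }
  if (any(weights <= 0)) {
    abort("weights must be positive", class = "casemixr_validation_error")
  }
  ok <- !is.na(scores)
  if (!any(ok)) {
    abort("all indicator scores are missing", class = "casemixr_computation_error")
  }
  w <- weights
  w[!ok] <- NA_real_
  w[ok] <- w[ok] / sum(w[ok])
  list(
    si = sum(w[ok] * scores[ok]),
    n_indicators_used = sum(ok),
    weights = w
  )
}

#' Per-unit composite effectiveness table
#'
#' Scores all observations and aggregates them to one composite index per
#' unit.
#'
#' @param observations Indicator observation tibble.
#' @param definitions Indicator definition tibble (its `weight` column is
#'   used unless `weights` overrides it).
#' @param weights Optional named or positional weights per indicator_id.
#' @return A tibble `unit_id`, `si`, `n_indicators_used`, sorted by
#'   `unit_id`, with the observed range reported via attributes `si_min` /
#'   `si_max`.
#' @export
si_table <- function(observations, definitions = default_indicator_definitions(),
                     weights = NULL) {
  scored <- score_indicators(observations, definitions)
  if (is.null(weights)) {
    weights <- setNames(definitions$weight, definitions$indicator_id)
  } else if (is.null(names(weights))) {
    if (length(weights) != nrow(definitions)) {
      abort("unnamed weights must have one entry per indicator definition",
            class = "casemixr_validation_error")
    }
    weights <- setNames(weights, definitions$indicator_id)
  }
  out <- scored |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::group_modify(function(df, key) {
      agg <- synthetic_index(df$score, unname(weights[as.character(df$indicator_id)]))
      tibble::tibble(si = agg$si, n_indicators_used = agg$n_indicators_used)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$unit_id)
  attr(out, "si_min") <- min(out$si)
  attr(out, "si_max") <- max(out$si)
  out
}
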