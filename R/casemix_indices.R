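#' @title Indirect standardization of utilization
#' @description The core computation: a per-category reference profile of
#'   mean visits, episodes and cost; indirectly standardized expected means
#'   for each care unit (the unit's own case mix priced at reference rates);
#'   the three efficiency indices (observed / expected); and the case-mix
#'   risk index (expected visits / reference mean visits).
#' @name casemix_indices
NULL

new_reference_profile <- function(per_acg) {
  stopifnot(is.data.frame(per_acg))
  n <- sum(per_acg$n_patients)
  pooled <- list(
    n = n,
    mean_visits   = sum(per_acg$n_patients * per_acg$mean_visits) / n,
    mean_episodes = sum(per_acg$n_patients * per_acg$mean_episodes) / n,
    mean_cost     = sum(per_acg$n_patients * per_acg$mean_cost) / n
  )
  structure(list(per_acg = tibble::as_tibble(per_acg), pooled = pooled),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat("<reference_profile> ", nrow(x$per_acg), " categories, ",
      format(x$pooled$n, big.mark = ","), " patients\n", sep = "")
  cat(sprintf("pooled means: %.2f visits, %.2f episodes, %.2f EUR\n",
              x$pooled$mean_visits, x$pooled$mean_episodes, x$pooled$mean_cost))
  print(x$per_acg, ...)
  invisible(x)
}

#' Build the per-category reference profile from a pooled cohort
#'
#' Arithmetic means of visits, episodes and cost per patient within each
#' morbidity category, taken over the pooled cohort of all centres; this is
#' the standard population against which each unit's expected values are
#' computed. Pooled totals are the patient-weighted averages of the
#' per-category means, identical to the plain cohort means.
#'
#' @param patients Patient tibble (see [read_patients()]).
#' @return A `reference_profile`: per-category tibble (`acg_code`,
#'   `n_patients`, `mean_visits`, `mean_episodes`, `mean_cost`) plus pooled
#'   totals, printable and writable via `$per_acg`.
#' @export
build_reference_profile <- function(patients) {
  if (!is.data.frame(patients) || nrow(patients) == 0) {
    abort("cannot build a reference profile from an empty cohort",
          class = "casemixr_validation_error")
  }
  check_columns(patients, c("acg_code", "n_visits", "n_episodes", "cost"),
                "patient table")
  per_acg <- patients |>
    dplyr::group_by(.data$acg_code) |>
    dplyr::summarise(
      n_patients = dplyr::n(),
      mean_visits = mean(.data$n_visits),
      mean_episodes = mean(.data$n_episodes),
      mean_cost = mean(.data$cost),
      .groups = "drop"
    )
  new_reference_profile(per_acg)
}

#' Reference profile implied by a catalog
#'
#' Uses a catalog's per-category means directly as the standard population,
#' with patient counts proportional to the catalog shares. Useful as an
#' external, noise-free standard when measuring recovery of planted effects
#' in synthetic cohorts.
#'
#' @param catalog Catalog tibble, see [default_acg_catalog()].
#' @return A `reference_profile`.
#' @export
reference_from_catalog <- function(catalog = default_acg_catalog()) {
  validate_catalog(catalog)
  n <- if ("n_patients" %in% names(catalog)) catalog$n_patients
       else round(catalog$share * 1e6)
  new_reference_profile(tibble::tibble(
    acg_code = catalog$acg_code,
    n_patients = as.integer(n),
    mean_visits = catalog$mean_visits,
    mean_episodes = catalog$mean_episodes,
    mean_cost = catalog$mean_cost
  ))
}

#' Indirectly standardized expected means for one unit
#'
#' For each quantity (visits, episodes, cost) the expected total is the sum
#' over categories of the unit's patient count in the category times the
#' reference per-category mean; the expected mean divides by the unit's
#' attended count. This is the "expected" half of each efficiency index.
#'
#' @param patients Patient tibble restricted to one unit.
#' @param reference A `reference_profile`.
#' @return A named list: `n`, `expected_mean_visits`,
#'   `expected_mean_episodes`, `expected_mean_cost`.
#' @export
expected_means <- function(patients, reference) {
  stopifnot(inherits(reference, "reference_profile"))
  if (nrow(patients) == 0) {
    abort("unit has no attended patients", class = "casemixr_validation_error")
  }
  missing_codes <- setdiff(unique(patients$acg_code), reference$per_acg$acg_code)
  if (length(missing_codes) > 0) {
    abort(
      paste0("ACG code(s) absent from the reference profile: ",
             paste(sort(missing_codes), collapse = ", ")),
      class = "casemixr_validation_error"
    )
  }
  counts <- dplyr::count(patients, .data$acg_code, name = "n_acg")
  joined <- dplyr::inner_join(counts, reference$per_acg, by = "acg_code")
  n <- nrow(patients)
  list(
    n = n,
    expected_mean_visits   = sum(joined$n_acg * joined$mean_visits) / n,
    expected_mean_episodes = sum(joined$n_acg * joined$mean_episodes) / n,
    expected_mean_cost     = sum(joined$n_acg * joined$mean_cost) / n
  )
}

#' Efficiency index: observed over expected mean
#'
#' The ratio of a unit's observed mean (cost, visits or episodes per attended
#' patient) to its case-mix expected mean. A value of 1 matches the reference
#' standard; values below 1 indicate greater efficiency (fewer resources than
#' the case mix predicts).
#'
#' @param observed_mean Observed mean per patient.
#' @param expected_mean Expected mean per patient (must be positive).
#' @return The index at full precision.
#' @export
#' @examples
#' efficiency_index(600.87, 752.71)   # 0.80 at 2 dp: an efficient centre
#' efficiency_index(9.87, 8.02)       # 1.23 at 2 dp: more visits than expected
efficiency_index <- function(observed_mean, expected_mean) {
  if (any(!is.finite(expected_mean)) || any(expected_mean <= 0)) {
    abort("efficiency index undefined: expected mean must be positive",
          class = "casemixr_computation_error")
  }
  observed_mean / expected_mean
}

#' Risk index: case-mix complexity of a unit
#'
#' The ratio of a unit's expected mean visits (its own case mix priced at
#' reference visit rates) to the reference population's mean visits. It
#' depends only on the unit's case mix: values above 1 flag a more complex
#' (higher morbidity burden) population, below 1 a less complex one.
#'
#' @param expected_mean_visits Unit expected mean visits per patient.
#' @param reference_mean_visits Reference population mean visits (positive).
#' @return The index at full precision.
#' @export
#' @examples
#' risk_index(6.93, 7.8)   # 0.89: less complex than the standard
#' risk_index(8.49, 7.8)   # 1.09: more complex
risk_index <- function(expected_mean_visits, reference_mean_visits) {
  if (any(!is.finite(reference_mean_visits)) || any(reference_mean_visits <= 0)) {
    abort("risk index undefined: reference mean visits must be positive",
          class = "casemixr_computation_error")
  }
  expected_mean_visits / reference_mean_visits
}

#' Annual coverage (intensity of use)
#'
#' Attended patients as a proportion of the assigned catchment population.
#'
#' @param n_attended Attended patient count (positive).
#' @param assigned_population Assigned population (at least `n_attended`).
#' @return Proportion in (0, 1].
#' @export
#' @examples
#' coverage_ratio(196593, 284013)  # 0.692
coverage_ratio <- function(n_attended, assigned_population) {
  if (any(n_attended <= 0)) {
    abort("n_attended must be positive", class = "casemixr_validation_error")
  }
  if (any(assigned_population < n_attended)) {
    abort("assigned_population cannot be smaller than the attended count",
          class = "casemixr_validation_error")
  }
  n_attended / assigned_population
}

#' Per-unit observed/expected means, efficiency indices and risk index
#'
#' Computes, for every unit at the requested level (centre or basic care
#' team), the observed means, the indirectly standardized expected means, the
#' three efficiency indices, the risk index and (when unit metadata is
#' given) the coverage ratio. When `reference` is omitted it is built from
#' the analyzed cohort itself, in which case the conservation identities
#' hold: pooled efficiency indices and the attended-weighted mean risk index
#' equal 1.
#'
#' @param patients Patient tibble.
#' @param units Optional unit metadata tibble (`level,id,assigned_population`)
#'   used for coverage.
#' @param reference Optional `reference_profile`; defaults to
#'   `build_reference_profile(patients)`.
#' @param level `"phc"` or `"bct"`; both levels use the same code path.
#' @return A tibble with one row per unit: `unit_id`, `level`, `n_attended`,
#'   observed and expected means for visits/episodes/cost, `visits_ei`,
#'   `episodes_ei`, `costs_ei`, `ri`, `coverage`.
#' @export
unit_index_table <- function(patients, units = NULL, reference = NULL,
                             level = c("phc", "bct")) {
  level <- match.arg(level)
  validate_patients(patients)
  if (is.null(reference)) reference <- build_reference_profile(patients)
  stopifnot(inherits(reference, "reference_profile"))
  id_col <- if (level == "phc") "phc_id" else "bct_id"
  ids <- sort(unique(patients[[id_col]]))
  rows <- lapply(ids, function(id) {
    unit_patients <- patients[patients[[id_col]] == id, , drop = FALSE]
    exp <- expected_means(unit_patients, reference)
    obs_visits <- mean(unit_patients$n_visits)
    obs_episodes <- mean(unit_patients$n_episodes)
    obs_cost <- mean(unit_patients$cost)
    tibble::tibble(
      unit_id = id,
      level = toupper(level),
      n_attended = exp$n,
      observed_mean_visits = obs_visits,
      expected_mean_visits = exp$expected_mean_visits,
      observed_mean_episodes = obs_episodes,
      expected_mean_episodes = exp$expected_mean_episodes,
      observed_mean_cost = obs_cost,
      expected_mean_cost = exp$expected_mean_cost,
      visits_ei = efficiency_index(obs_visits, exp$expected_mean_visits),
      episodes_ei = efficiency_index(obs_episodes, exp$expected_mean_episodes),
      costs_ei = efficiency_index(obs_cost, exp$expected_mean_cost),
      ri = risk_index(exp$expected_mean_visits, reference$pooled$mean_visits)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$coverage <- NA_real_
  if (!is.null(units)) {
    lv <- toupper(level)
    meta <- units[units$level == lv, c("id", "assigned_population"), drop = FALSE]
    idx <- match(out$unit_id, meta$id)
    has <- !is.na(idx)
    out$coverage[has] <- coverage_ratio(out$n_attended[has],
                                        meta$assigned_population[idx[has]])
  }
  out
}

#' Descriptive summary of a cohort
#'
#' Mean (SD) and median \[IQR\] of visits, episodes and cost per patient,
#' plus counts and the shares of female and over-65 patients.
#'
#' @param patients Patient tibble.
#' @param digits Rounding used only for the rendered label column.
#' @return A tibble with one row per quantity: `variable`, `mean`, `sd`,
#'   `median`, `q1`, `q3`, and a presentation `label` formatted
#'   `"mean (SD) ; median [q1-q3]"`.
#' @export
descriptive_summary <- function(patients, digits = 1) {
  if (nrow(patients) == 0) {
    abort("cannot summarise an empty cohort", class = "casemixr_validation_error")
  }
  num_row <- function(name, x) {
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    s <- if (length(x) > 1) sd(x) else 0
    tibble::tibble(
      variable = name, mean = mean(x), sd = s,
      median = q[2], q1 = q[1], q3 = q[3],
      label = sprintf("%s (%s) ; %s [%s-%s]",
                      format(round_half_up(mean(x), digits), nsmall = digits),
                      format(round_half_up(s, digits), nsmall = digits),
                      format(round_half_up(q[2], digits), nsmall = digits),
                      format(round_half_up(q[1], digits), nsmall = digits),
                      format(round_half_up(q[3], digits), nsmall = digits))
    )
  }
  scalar_row <- function(name, value, label) {
    tibble::tibble(variable = name, mean = value, sd = NA_real_,
                   median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                   label = label)
  }
  n <- nrow(patients)
  pct_female <- 100 * mean(patients$sex == "female")
  pct_over65 <- 100 * mean(patients$age > 65)
  dplyr::bind_rows(
    scalar_row("n_attended", n, format(n, big.mark = ",")),
    scalar_row("pct_female", pct_female,
               paste0(format(round_half_up(pct_female, digits), nsmall = digits), "%")),
    scalar_row("pct_over_65", pct_over65,
               paste0(format(round_half_up(pct_over65, digits), nsmall = digits), "%")),
    num_row("age", patients$age),
    num_row("n_visits", patients$n_visits),
    num_row("n_episodes", patients$n_episodes),
    num_row("cost", patients$cost)
  )
}

#' Distribution of the cohort over morbidity categories
#'
#' Per-category counts, percentages, cumulative shares and the mean (SD) of
#' episodes, cost and visits, sorted by count descending. The attribute
#' `n_rare` carries the number of categories whose share falls below
#' `share_threshold` (default 0.5%).
#'
#' @param patients Patient tibble.
#' @param share_threshold Share below which a category counts as rare.
#' @return A tibble sorted by `n` descending with columns `acg_code`, `n`,
#'   `pct`, `cum_pct`, and mean/SD columns for episodes, cost and visits;
#'   attributes `n_rare` and `share_threshold`.
#' @export
acg_distribution_table <- function(patients, share_threshold = 0.005) {
  if (nrow(patients) == 0) {
    abort("cannot tabulate an empty cohort", class = "casemixr_validation_error")
  }
  tab <- patients |>
    dplyr::group_by(.data$acg_code) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_episodes = mean(.data$n_episodes), sd_episodes = sd_or_zero(.data$n_episodes),
      mean_cost = mean(.data$cost), sd_cost = sd_or_zero(.data$cost),
      mean_visits = mean(.data$n_visits), sd_visits = sd_or_zero(.data$n_visits),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$acg_code)
  tab$pct <- 100 * tab$n / sum(tab$n)
  tab$cum_pct <- cumsum(tab$pct)
  tab <- tab[, c("acg_code", "n", "pct", "cum_pct",
                 "mean_episodes", "sd_episodes", "mean_cost", "sd_cost",
                 "mean_visits", "sd_visits")]
  attr(tab, "n_rare") <- sum(tab$pct < 100 * share_threshold)
  attr(tab, "share_threshold") <- share_threshold
  tab
}

sd_or_zero <- function(x) if (length(x) > 1) sd(x) else 0

#' Round half away from zero
#'
#' Presentation rounding used by all report renderers: exact halves round
#' away from zero (so 0.885 -> 0.89), unlike [base::round()]'s
#' round-half-to-even. Values are stored at full precision everywhere;
#' this applies only when rendering.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (non-negative integer).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  stopifnot(digits >= 0)
  p <- 10^digits
  # nudge by a relative epsilon so values stored as 0.99999999 halves round up
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps) * abs(x) * p) / p
}

#' Render a per-unit index table in report layout
#'
#' Transposes a [unit_index_table()] result into the conventional report
#' layout (quantities as rows, units as columns) with half-away-from-zero
#' rounding at `digits` decimals.
#'
#' @param index_table Result of [unit_index_table()].
#' @param digits Decimals for the rendered values.
#' @return A tibble with a `measure` column and one column per unit.
#' @export
render_unit_table <- function(index_table, digits = 2) {
  measures <- c(
    "expected_mean_cost", "observed_mean_cost", "costs_ei",
    "expected_mean_episodes", "observed_mean_episodes", "episodes_ei",
    "expected_mean_visits", "observed_mean_visits", "visits_ei",
    "ri"
  )
  out <- tibble::tibble(measure = measures)
  for (i in seq_len(nrow(index_table))) {
    vals <- vapply(measures, function(m) index_table[[m]][i], numeric(1))
    out[[index_table$unit_id[i]]] <-
      format(round_half_up(vals, digits), nsmall = digits, trim = TRUE)
  }
  out
}
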