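#' @title Delimited-text cohort I/O
#' @description Readers and writers for the fixed file dialect shared by all
#'   pipeline stages: comma-separated, header row, UTF-8, `"."` decimal
#'   separator, values stored at full precision (rounding happens only when
#'   rendering reports).
#' @name cohort_io
NULL

patient_cols <- c("patient_id", "age", "sex", "phc_id", "bct_id",
                  "acg_code", "n_visits", "n_episodes", "cost")

check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    abort(
      paste0(what, " is missing required column(s): ", paste(miss, collapse = ", ")),
      class = "casemixr_schema_error"
    )
  }
  invisible(df)
}

#' Validate a patient table against the cohort invariants
#'
#' Every patient in an attended cohort has at least one visit and one episode
#' (a visit records at least one care episode), is older than 14 years, has a
#' non-negative cost, and `sex` is `"female"` or `"male"`.
#'
#' @param patients A tibble with the columns of `patients.csv`
#'   (`patient_id, age, sex, phc_id, bct_id, acg_code, n_visits, n_episodes, cost`).
#' @return `patients`, invisibly, if valid; otherwise an error naming the
#'   first offending row.
#' @export
validate_patients <- function(patients) {
  check_columns(patients, patient_cols, "patient table")
  fail_row <- function(cond, msg) {
    bad <- which(cond)
    if (length(bad) > 0) {
      abort(paste0("patient row ", bad[1], ": ", msg),
            class = "casemixr_validation_error")
    }
  }
  fail_row(!patients$sex %in% c("female", "male"), "sex must be 'female' or 'male'")
  fail_row(is.na(patients$age) | patients$age <= 14, "age must be > 14 years")
  fail_row(is.na(patients$n_visits) | patients$n_visits < 1,
           "an attended patient must have n_visits >= 1")
  fail_row(is.na(patients$n_episodes) | patients$n_episodes < 1,
           "an attended patient must have n_episodes >= 1")
  fail_row(is.na(patients$cost) | patients$cost < 0, "cost must be non-negative")
  # each basic care team belongs to exactly one centre
  map <- unique(patients[, c("bct_id", "phc_id")])
  dup <- unique(map$bct_id[duplicated(map$bct_id)])
  if (length(dup) > 0) {
    abort(
      paste0("bct_id nested in more than one phc_id: ", paste(dup, collapse = ", ")),
      class = "casemixr_structural_error"
    )
  }
  invisible(patients)
}

#' Read a patient-level cohort file
#'
#' @param path Path to a `patients.csv` file (comma-separated, header, UTF-8).
#' @return A validated tibble of patient records.
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "casemixr_io_error")
  }
  patients <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      age = readr::col_integer(),
      sex = readr::col_character(),
      phc_id = readr::col_character(),
      bct_id = readr::col_character(),
      acg_code = readr::col_character(),
      n_visits = readr::col_integer(),
      n_episodes = readr::col_integer(),
      cost = readr::col_double()
    ),
    progress = FALSE
  )
  check_columns(patients, patient_cols, basename(path))
  validate_patients(patients)
  inform(paste0("read ", nrow(patients), " patient records from ", path))
  patients
}

#' @rdname read_patients
#' @param patients A validated patient tibble.
#' @export
write_patients <- function(patients, path) {
  validate_patients(patients)
  write_table(patients, path)
}

#' Write a tabular result as delimited text
#'
#' Values are stored at full precision; report rounding is applied only by
#' the render helpers.
#'
#' @param rows A non-empty data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0) {
    abort("refusing to write an empty table", class = "casemixr_validation_error")
  }
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}

#' Read unit metadata
#'
#' `units.csv` carries one row per care unit: `level` (`"PHC"` or `"BCT"`),
#' `id`, `assigned_population` (residents of the catchment area) and
#' `parent_phc` (empty for PHC rows).
#'
#' @param path Path to `units.csv`.
#' @return A tibble of unit metadata.
#' @export
read_units <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "casemixr_io_error")
  }
  units <- readr::read_csv(
    path,
    col_types = readr::cols(
      level = readr::col_character(),
      id = readr::col_character(),
      assigned_population = readr::col_integer(),
      parent_phc = readr::col_character()
    ),
    progress = FALSE
  )
  check_columns(units, c("level", "id", "assigned_population"), basename(path))
  if (!all(units$level %in% c("PHC", "BCT"))) {
    abort("unit level must be 'PHC' or 'BCT'", class = "casemixr_validation_error")
  }
  if (any(is.na(units$assigned_population) | units$assigned_population <= 0)) {
    abort("assigned_population must be a positive integer", class = "casemixr_validation_error")
  }
  units
}

#' Read per-unit quality-indicator observations
#'
#' @param path Path to `indicators.csv` with columns
#'   `unit_id, indicator_id, eligible, compliant, observed_cost`
#'   (`eligible`/`compliant` for proportion indicators, `observed_cost`
#'   in EUR per DDD for pharmacy-cost indicators).
#' @return A tibble of indicator observations.
#' @export
read_indicator_observations <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "casemixr_io_error")
  }
  obs <- readr::read_csv(
    path,
    col_types = readr::cols(
      unit_id = readr::col_character(),
      indicator_id = readr::col_integer(),
      eligible = readr::col_integer(),
      compliant = readr::col_integer(),
      observed_cost = readr::col_double()
    ),
    progress = FALSE
  )
  check_columns(obs, c("unit_id", "indicator_id"), basename(path))
  bad <- which(!is.na(obs$eligible) & !is.na(obs$compliant) & obs$compliant > obs$eligible)
  if (length(bad) > 0) {
    abort(paste0("indicator row ", bad[1], ": compliant exceeds eligible"),
          class = "casemixr_validation_error")
  }
  obs
}

#' Read an external reference profile
#'
#' An externally supplied standard population: per-category patient counts and
#' mean visits, episodes and cost. When an external reference is used the
#' conservation identities (pooled efficiency indices equal to 1) are not
#' expected to hold for the analyzed cohort.
#'
#' @param path Path to `reference.csv` with columns
#'   `acg_code, n_patients, mean_visits, mean_episodes, mean_cost`.
#' @return A `reference_profile` object (see [build_reference_profile()]).
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "casemixr_io_error")
  }
  per_acg <- readr::read_csv(
    path,
    col_types = readr::cols(
      acg_code = readr::col_character(),
      n_patients = readr::col_integer(),
      mean_visits = readr::col_double(),
      mean_episodes = readr::col_double(),
      mean_cost = readr::col_double()
    ),
    progress = FALSE
  )
  check_columns(per_acg,
                c("acg_code", "n_patients", "mean_visits", "mean_episodes", "mean_cost"),
                basename(path))
  new_reference_profile(per_acg)
}

#' Consistency report for a cohort
#'
#' Reports patient counts per unit, the category codes observed, and any
#' invariant violations, without modifying its inputs. The upstream exclusion
#' rules of the source study (out-of-region patients, transfers,
#' orthodontics-only contacts) are assumed applied before the cohort reaches
#' this package; only unit and category consistency are checked here.
#'
#' @param patients Patient tibble.
#' @param units Optional unit metadata tibble (as from [read_units()]); when
#'   given, attended counts are checked against assigned populations.
#' @return A list with `n_patients`, `counts_per_unit` (tibble), `acg_codes`
#'   (character), and `violations` (character vector, empty when consistent).
#' @export
validate_cohort <- function(patients, units = NULL) {
  validate_patients(patients)
  counts <- dplyr::count(patients, .data$phc_id, .data$bct_id, name = "n_attended")
  violations <- character()
  if (!is.null(units)) {
    bct_units <- units[units$level == "BCT", , drop = FALSE]
    per_bct <- dplyr::count(patients, .data$bct_id, name = "n_attended")
    joined <- dplyr::inner_join(per_bct, bct_units, by = c(bct_id = "id"))
    over <- joined[joined$n_attended > joined$assigned_population, , drop = FALSE]
    if (nrow(over) > 0) {
      violations <- c(violations, paste0(
        "unit ", over$bct_id, ": attended count ", over$n_attended,
        " exceeds assigned population ", over$assigned_population
      ))
    }
    phc_units <- units[units$level == "PHC", , drop = FALSE]
    per_phc <- dplyr::count(patients, .data$phc_id, name = "n_attended")
    joined_p <- dplyr::inner_join(per_phc, phc_units, by = c(phc_id = "id"))
    over_p <- joined_p[joined_p$n_attended > joined_p$assigned_population, , drop = FALSE]
    if (nrow(over_p) > 0) {
      violations <- c(violations, paste0(
        "unit ", over_p$phc_id, ": attended count ", over_p$n_attended,
        " exceeds assigned population ", over_p$assigned_population
      ))
    }
  }
  list(
    n_patients = nrow(patients),
    counts_per_unit = counts,
    acg_codes = sort(unique(patients$acg_code)),
    violations = violations
  )
}
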