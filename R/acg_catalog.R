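#' Default ACG catalog of the reference population
#'
#' Morbidity-burden category (ACG) mixture and per-category utilization
#' moments for a reference population of 196,593 adult primary-care patients
#' attended during one year in 13 Catalan centres. The catalog lists the 17
#' most frequent categories individually plus one pooled `"OTHER"` entry
#' covering the remaining, individually rare, codes. For each category it
#' carries the attended-patient count, the share of the attended population,
#' and the mean and standard deviation of annual care episodes, total direct
#' cost (EUR) and visits per patient.
#'
#' Shares are renormalized to sum to exactly 1 so the catalog can be used
#' directly as a categorical mixture.
#'
#' @return A tibble with one row per category and columns `acg_code`,
#'   `description`, `n_patients`, `share`, `mean_episodes`, `sd_episodes`,
#'   `mean_cost`, `sd_cost`, `mean_visits`, `sd_visits`.
#' @seealso [catalog_pooled_means()], [reference_from_catalog()]
#' @export
#' @examples
#' cat <- default_acg_catalog()
#' sum(cat$share)                    # exactly 1
#' cat[cat$acg_code == "4100", ]     # most frequent category
default_acg_catalog <- function() {
  cat <- tibble::tribble(
    ~acg_code, ~description,                                                      ~n_patients, ~mean_episodes, ~sd_episodes, ~mean_cost, ~sd_cost, ~mean_visits, ~sd_visits,
    "4100", "2-3 other ADG combinations, age 35+",                                      28864L, 3.9, 1.3,  776.3,  828.2,  7.0,  5.2,
    "300",  "Acute minor, age 6+",                                                      23095L, 1.7, 0.9,  173.2,  249.8,  2.9,  2.6,
    "4910", "6-9 other ADG combinations, age 35+, 0-1 major ADGs",                      14876L, 10.2, 2.4, 1624.4, 1092.9, 17.4, 10.3,
    "4410", "4-5 other ADG combinations, age 45+, no major ADGs",                       10551L, 6.6, 1.6, 1025.4,  755.9, 10.8,  6.2,
    "4420", "4-5 other ADG combinations, age 45+, 1 major ADGs",                        10137L, 6.7, 1.6, 1336.2, 1061.6, 12.2,  8.7,
    "2100", "Acute minor/likely to recur, age 6+, w/o allergy",                          9689L, 3.4, 1.4,  310.3,  296.3,  5.3,  3.8,
    "500",  "Likely to recur, w/o allergies",                                            8815L, 1.6, 0.8,  192.6,  274.4,  2.6,  2.3,
    "400",  "Acute major",                                                               7511L, 1.6, 0.8,  243.2,  388.8,  3.0,  2.6,
    "1800", "Acute minor/acute major",                                                   6993L, 3.4, 1.3,  355.9,  393.2,  5.7,  4.0,
    "1600", "Preventive/administrative",                                                 6937L, 1.1, 0.3,  259.7,  540.2,  2.0,  2.2,
    "900",  "Chronic medical: stable",                                                   6175L, 2.0, 0.7,  512.8,  580.5,  4.1,  3.3,
    "3900", "2-3 other ADG combinations, males age 18 to 34",                            5877L, 3.4, 1.0,  341.7,  399.1,  5.6,  4.1,
    "3200", "Acute minor/acute major/likely to recur, age 12+, w/o allergy",             5535L, 5.4, 1.8,  529.0,  477.1,  8.1,  5.2,
    "2300", "Acute minor/chronic medical: stable",                                       5345L, 3.7, 1.3,  634.8,  594.8,  6.8,  5.0,
    "3600", "Acute minor/acute major/likely to recur/chronic medical: stable",           5300L, 7.8, 2.3, 1043.4,  742.9, 12.4,  7.2,
    "4310", "4-5 other ADG combinations, age 18 to 44, no major ADGs",                   4168L, 5.9, 1.3,  554.8,  474.6,  9.3,  5.1,
    "4920", "6-9 other ADG combinations, age 35+, 2 major ADGs",                         4089L, 10.6, 2.5, 2102.5, 1407.8, 20.7, 13.9,
    "OTHER", "Other ACG codes (pooled rare categories)",                                32636L, 5.0, 4.0,  747.8, 1045.4,  9.0, 10.0
  )
  cat$share <- cat$n_patients / sum(cat$n_patients)
  cat[, c("acg_code", "description", "n_patients", "share",
          "mean_episodes", "sd_episodes", "mean_cost", "sd_cost",
          "mean_visits", "sd_visits")]
}

validate_catalog <- function(catalog) {
  req <- c("acg_code", "share", "mean_episodes", "sd_episodes",
           "mean_cost", "sd_cost", "mean_visits", "sd_visits")
  miss <- setdiff(req, names(catalog))
  if (length(miss) > 0) {
    abort(paste0("catalog is missing column(s): ", paste(miss, collapse = ", ")),
          class = "casemixr_schema_error")
  }
  if (anyDuplicated(catalog$acg_code)) {
    abort("catalog has duplicated acg_code entries", class = "casemixr_validation_error")
  }
  if (abs(sum(catalog$share) - 1) > 1e-9) {
    abort("catalog shares must sum to 1 (tolerance 1e-9)", class = "casemixr_validation_error")
  }
  mom <- unlist(catalog[, setdiff(req, c("acg_code", "share"))])
  if (any(!is.finite(mom)) || any(mom < 0)) {
    abort("catalog means/SDs must be finite and non-negative", class = "casemixr_validation_error")
  }
  invisible(catalog)
}

#' Pooled (mixture-implied) means of a catalog
#'
#' Share-weighted means of episodes, cost and visits implied by a catalog's
#' categorical mixture; these are the moments of a population drawn exactly
#' from the catalog.
#'
#' @param catalog A catalog tibble as returned by [default_acg_catalog()].
#' @return A named list with `mean_episodes`, `mean_cost`, `mean_visits`.
#' @export
catalog_pooled_means <- function(catalog = default_acg_catalog()) {
  validate_catalog(catalog)
  w <- catalog$share / sum(catalog$share)
  list(
    mean_episodes = sum(w * catalog$mean_episodes),
    mean_cost     = sum(w * catalog$mean_cost),
    mean_visits   = sum(w * catalog$mean_visits)
  )
}
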