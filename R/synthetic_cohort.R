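#' @title Synthetic cohort generator
#' @description Seeded generation of patient-level cohorts whose
#'   morbidity-category mixture and per-category utilization moments follow a
#'   catalog (by default [default_acg_catalog()]), with plantable unit-level
#'   complexity, efficiency and quality effects. Case mix per unit is a
#'   Dirichlet perturbation of the (optionally tilted) catalog shares; visit
#'   and episode counts are zero-truncated negative binomial (zero-truncated
#'   Poisson when the target is underdispersed), costs are gamma. Count
#'   parameters are solved so the *zero-truncated* mean equals the target
#'   exactly; the dispersion parameter comes from an untruncated moment match.
#' @name synthetic_cohort
NULL

#' Build a unit-effect table
#'
#' One row per basic care team (BCT), nested in centres (PHCs), with neutral
#' effects: all efficiency factors 1, no complexity tilt, quality level 0.5.
#' Assigned populations default to `n_attended / coverage`, rounded up, with
#' `coverage` matching the 69.2% annual coverage of the reference study
#' population.
#'
#' @param n_units Number of BCTs (at least 2).
#' @param patients_per_unit Attended patients per BCT.
#' @param n_phc Number of centres the BCTs are grouped into (contiguous
#'   blocks); defaults to one centre per BCT.
#' @param coverage Attended/assigned ratio used to derive assigned
#'   populations.
#' @return A tibble with columns `bct_id`, `phc_id`, `n_attended`,
#'   `assigned_population`, `complexity_shift`, `eff_visits`, `eff_episodes`,
#'   `eff_costs`, `quality_level`.
#' @export
make_units <- function(n_units, patients_per_unit = 2000, n_phc = n_units,
                       coverage = 0.692) {
  stopifnot(n_units >= 2, patients_per_unit >= 1, n_phc >= 1, n_phc <= n_units)
  phc_of <- rep(seq_len(n_phc), each = ceiling(n_units / n_phc))[seq_len(n_units)]
  tibble::tibble(
    bct_id = sprintf("bct%03d", seq_len(n_units)),
    phc_id = sprintf("phc%02d", phc_of),
    n_attended = as.integer(patients_per_unit),
    assigned_population = as.integer(ceiling(patients_per_unit / coverage)),
    complexity_shift = 0,
    eff_visits = 1,
    eff_episodes = 1,
    eff_costs = 1,
    quality_level = 0.5
  )
}

#' Generator configuration
#'
#' @param units Unit-effect tibble, see [make_units()].
#' @param catalog Category catalog, see [default_acg_catalog()].
#' @param kappa Dirichlet concentration controlling residual case-mix
#'   dispersion across units (larger = less dispersion; `Inf` = every unit
#'   uses its tilted catalog shares exactly).
#' @param seed Master seed; all per-unit and per-stage substreams are derived
#'   from it deterministically.
#' @param sampling `"random"` for iid draws (realistic sampling noise) or
#'   `"balanced"` for quota-allocated case mix with stratified quantile draws
#'   of utilization (a variance-reduction design used by the planted-gradient
#'   calibration scenarios).
#' @return A `generator_config` object (a validated list).
#' @export
generator_config <- function(units, catalog = default_acg_catalog(),
                             kappa = 3000, seed = 1,
                             sampling = c("random", "balanced")) {
  sampling <- match.arg(sampling)
  validate_catalog(catalog)
  req <- c("bct_id", "phc_id", "n_attended", "assigned_population",
           "complexity_shift", "eff_visits", "eff_episodes", "eff_costs",
           "quality_level")
  check_columns(units, req, "unit-effect table")
  if (nrow(units) < 2) {
    abort("at least 2 units are required", class = "casemixr_config_error")
  }
  if (any(units$eff_visits <= 0 | units$eff_episodes <= 0 | units$eff_costs <= 0)) {
    abort("efficiency factors must be positive", class = "casemixr_config_error")
  }
  if (any(units$quality_level < 0 | units$quality_level > 1)) {
    abort("quality_level must lie in [0, 1]", class = "casemixr_config_error")
  }
  if (any(units$n_attended > units$assigned_population)) {
    abort("n_attended cannot exceed assigned_population", class = "casemixr_config_error")
  }
  if (!(is.numeric(kappa) && length(kappa) == 1 && kappa > 0)) {
    abort("kappa must be a positive number (possibly Inf)", class = "casemixr_config_error")
  }
  structure(
    list(units = tibble::as_tibble(units), catalog = catalog,
         kappa = kappa, seed = as.integer(seed), sampling = sampling),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config> ", nrow(x$units), " units, ",
      sum(x$units$n_attended), " patients, kappa = ", x$kappa,
      ", sampling = ", x$sampling, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Plant documented unit-level effect scenarios
#'
#' Returns a copy of `base` whose unit effects encode one of four study
#' scenarios:
#'
#' * `"null"` — no effects: all factors 1, no tilt, quality 0.5; iid
#'   sampling. Used for false-positive-rate calibration.
#' * `"efficiency_gradient"` — visit efficiency factors evenly spaced in
#'   \[0.85, 1.20\] (the span of visit indices observed across centres in the
#'   reference study); balanced sampling, exact case mix.
#' * `"complexity_gradient"` — case-mix tilts solved so the planted risk
#'   index is evenly spaced in \[0.75, 1.25\]; all efficiency factors 1;
#'   balanced sampling, exact case mix.
#' * `"coupled_quality_efficiency"` — quality levels evenly spaced in
#'   \[0.25, 0.90\] with cost factors coupled negatively
#'   (`1.25 - 0.4 * quality`) and episode factors positively
#'   (`0.92 + 0.24 * quality`); iid sampling. Mirrors, qualitatively, the
#'   negative effectiveness-vs-cost and positive effectiveness-vs-episodes
#'   association reported across real care teams.
#'
#' The two gradient scenarios are calibration instruments: they switch to
#' balanced sampling and an exact (non-Dirichlet) case mix so that recovered
#' indices measure the planted effects rather than sampling noise.
#'
#' @param base A `generator_config`.
#' @param scenario Scenario name.
#' @return A modified `generator_config`.
#' @export
plant_unit_effects <- function(base,
                               scenario = c("null", "efficiency_gradient",
                                            "complexity_gradient",
                                            "coupled_quality_efficiency")) {
  stopifnot(inherits(base, "generator_config"))
  scenario <- match.arg(scenario)
  units <- base$units
  n <- nrow(units)
  units$complexity_shift <- 0
  units$eff_visits <- 1
  units$eff_episodes <- 1
  units$eff_costs <- 1
  units$quality_level <- 0.5
  kappa <- base$kappa
  sampling <- base$sampling
  if (scenario == "efficiency_gradient") {
    units$eff_visits <- seq(0.85, 1.20, length.out = n)
    kappa <- Inf
    sampling <- "balanced"
  } else if (scenario == "complexity_gradient") {
    targets <- seq(0.75, 1.25, length.out = n)
    units$complexity_shift <- vapply(targets, solve_complexity_shift,
                                     numeric(1), catalog = base$catalog)
    kappa <- Inf
    sampling <- "balanced"
  } else if (scenario == "coupled_quality_efficiency") {
    q <- seq(0.25, 0.90, length.out = n)
    units$quality_level <- q
    units$eff_costs <- 1.25 - 0.4 * q
    # kept above 1/min(catalog episode mean) so every zero-truncated episode
    # target mean stays >= 1
    units$eff_episodes <- 0.92 + 0.24 * q
    sampling <- "random"
  } else {
    sampling <- "random"
  }
  out <- base
  out$units <- units
  out$kappa <- kappa
  out$sampling <- sampling
  out
}

# ---- case-mix tilting -------------------------------------------------------

# Exponential tilt of catalog shares toward high-burden categories:
# weights proportional to share * exp(shift * standardized mean visits).
tilt_shares <- function(catalog, shift) {
  m <- catalog$mean_visits
  s <- catalog$share
  mbar <- sum(s * m)
  msd <- sqrt(sum(s * (m - mbar)^2))
  w <- s * exp(shift * (m - mbar) / msd)
  w / sum(w)
}

# Shift whose tilted mix has expected catalog-mean visits equal to
# target_ratio times the pooled catalog mean.
solve_complexity_shift <- function(target_ratio, catalog) {
  pooled <- sum(catalog$share * catalog$mean_visits)
  f <- function(shift) {
    w <- tilt_shares(catalog, shift)
    sum(w * catalog$mean_visits) / pooled - target_ratio
  }
  uniroot(f, c(-6, 6), tol = 1e-12)$root
}

# ---- count and cost samplers ------------------------------------------------

# Parameters of the count model for one (category, quantity) cell.
# Dispersion: negative binomial size from an untruncated moment match when
# sd^2 > mean, else zero-truncated Poisson (fallback). The untruncated mean
# `u` is then solved so that the zero-truncated mean equals `mean` exactly.
count_cell_params <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0) {
    abort("infeasible count moments: mean must be positive",
          class = "casemixr_config_error")
  }
  if (mean <= 1) {
    # zero-truncated counts cannot have mean below 1; mean 1 is degenerate
    if (mean < 1) {
      abort("infeasible count moments: a zero-truncated count mean must be >= 1",
            class = "casemixr_config_error")
    }
    return(list(family = "constant", u = 1, size = Inf, p0 = 0,
                zt_mean = 1, zt_var = 0, fallback = FALSE))
  }
  overdispersed <- sd^2 > mean
  size <- if (overdispersed) mean^2 / (sd^2 - mean) else Inf
  p0 <- function(u) {
    if (overdispersed) (size / (size + u))^size else exp(-u)
  }
  zt_mean <- function(u) u / (1 - p0(u))
  u <- uniroot(function(u) zt_mean(u) - mean,
               c(mean * 1e-9, mean), tol = 1e-12)$root
  pz <- p0(u)
  var_u <- if (overdispersed) u + u^2 / size else u
  m2 <- (var_u + u^2) / (1 - pz)
  list(family = if (overdispersed) "nbinom" else "ztpois",
       u = u, size = size, p0 = pz,
       zt_mean = u / (1 - pz), zt_var = m2 - mean^2,
       fallback = !overdispersed)
}

# Zero-truncated draw: rejection for iid sampling, stratified quantiles of
# the truncated distribution for balanced sampling.
draw_zt_counts <- function(n, params, sampling) {
  if (n == 0) return(integer(0))
  if (params$family == "constant") return(rep(1L, n))
  qfun <- function(p) {
    pp <- params$p0 + p * (1 - params$p0)
    if (params$family == "nbinom") {
      qnbinom(pp, mu = params$u, size = params$size)
    } else {
      qpois(pp, lambda = params$u)
    }
  }
  if (sampling == "balanced") {
    p <- (seq_len(n) - runif(n)) / n
    return(as.integer(sample(qfun(p))))
  }
  rfun <- function(k) {
    if (params$family == "nbinom") rnbinom(k, mu = params$u, size = params$size)
    else rpois(k, lambda = params$u)
  }
  x <- rfun(n)
  zero <- which(x == 0L)
  while (length(zero) > 0) {
    x[zero] <- rfun(length(zero))
    zero <- zero[x[zero] == 0L]
  }
  as.integer(x)
}

draw_costs <- function(n, mean, sd, sampling) {
  if (n == 0) return(numeric(0))
  if (!is.finite(mean) || mean <= 0 || sd <= 0) {
    abort("infeasible cost moments: mean and sd must be positive",
          class = "casemixr_config_error")
  }
  shape <- (mean / sd)^2
  rate <- shape / mean
  if (sampling == "balanced") {
    p <- (seq_len(n) - runif(n)) / n
    sample(qgamma(p, shape = shape, rate = rate))
  } else {
    rgamma(n, shape = shape, rate = rate)
  }
}

# Allocate n patients over mixture weights by largest remainder.
quota_allocate <- function(n, weights) {
  raw <- n * weights / sum(weights)
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Deterministic substreams derived from the master seed.
derive_streams <- function(config) {
  n <- nrow(config$units)
  withr::with_seed(config$seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n + 1L)
  })
  list(unit = seeds[seq_len(n)], indicators = seeds[n + 1L])
}

#' Generate a synthetic patient-level cohort
#'
#' For each unit the case mix is a Dirichlet perturbation (concentration
#' `kappa` times the weights) of the catalog shares exponentially tilted by
#' the unit's `complexity_shift`; each patient draws a category from the unit
#' mix, then visit and episode counts from zero-truncated count models whose
#' truncated mean equals `efficiency_factor * catalog mean` exactly, and a
#' cost from a gamma matched to `eff_costs * catalog mean` and the catalog
#' SD. Age and sex are drawn to resemble an adult attended population
#' (normal age, mean 49.9, SD 19.9, truncated at >14; 56.7% female).
#' Identical configuration and seed give identical output.
#'
#' Cells whose target SD squared does not exceed the target mean cannot be
#' matched by a negative binomial; those fall back to a zero-truncated
#' Poisson and a single warning lists them.
#'
#' @param config A `generator_config`.
#' @return A patient tibble with the `patients.csv` columns.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  streams <- derive_streams(config)
  catalog <- config$catalog
  ncat <- nrow(catalog)
  fallback_cells <- character(0)

  unit_tables <- vector("list", nrow(config$units))
  for (i in seq_len(nrow(config$units))) {
    unit <- config$units[i, ]
    unit_tables[[i]] <- withr::with_seed(streams$unit[i], {
      w <- tilt_shares(catalog, unit$complexity_shift)
      mix <- if (is.finite(config$kappa)) {
        g <- rgamma(ncat, shape = config$kappa * w)
        g / sum(g)
      } else w
      n <- unit$n_attended
      cell_n <- if (config$sampling == "balanced") {
        quota_allocate(n, mix)
      } else {
        tabulate(sample.int(ncat, n, replace = TRUE, prob = mix), nbins = ncat)
      }
      acg <- rep(catalog$acg_code, cell_n)
      visits <- integer(0)
      episodes <- integer(0)
      cost <- numeric(0)
      for (k in seq_len(ncat)) {
        nk <- cell_n[k]
        if (nk == 0) next
        pv <- count_cell_params(unit$eff_visits * catalog$mean_visits[k],
                                catalog$sd_visits[k])
        pe <- count_cell_params(unit$eff_episodes * catalog$mean_episodes[k],
                                catalog$sd_episodes[k])
        if (pv$fallback) {
          fallback_cells <- c(fallback_cells,
                              paste0("visits:", catalog$acg_code[k]))
        }
        if (pe$fallback) {
          fallback_cells <- c(fallback_cells,
                              paste0("episodes:", catalog$acg_code[k]))
        }
        visits <- c(visits, draw_zt_counts(nk, pv, config$sampling))
        episodes <- c(episodes, draw_zt_counts(nk, pe, config$sampling))
        cost <- c(cost, draw_costs(nk, unit$eff_costs * catalog$mean_cost[k],
                                   catalog$sd_cost[k], config$sampling))
      }
      age <- numeric(n)
      todo <- seq_len(n)
      while (length(todo) > 0) {
        age[todo] <- round(49.9 + 19.9 * stats::rnorm(length(todo)))
        todo <- todo[age[todo] <= 14 | age[todo] > 105]
      }
      sex <- ifelse(runif(n) < 0.567, "female", "male")
      ord <- sample.int(n)  # decouple row order from the cell blocks
      tibble::tibble(
        patient_id = sprintf("%s-%05d", unit$bct_id, seq_len(n)),
        age = as.integer(age[ord]),
        sex = sex[ord],
        phc_id = unit$phc_id,
        bct_id = unit$bct_id,
        acg_code = acg[ord],
        n_visits = visits[ord],
        n_episodes = episodes[ord],
        cost = cost[ord]
      )
    })
  }
  if (length(fallback_cells) > 0) {
    cells <- sort(unique(fallback_cells))
    warn(
      paste0("SD^2 <= mean for ", length(cells),
             " count cell(s); zero-truncated Poisson used instead of ",
             "negative binomial: ", paste(cells, collapse = ", ")),
      class = "casemixr_moment_fallback"
    )
  }
  dplyr::bind_rows(unit_tables)
}

#' Definitions of the 20 care-quality indicators
#'
#' The composite effectiveness score aggregates 20 process and outcome
#' indicators used in Catalan primary-care management contracts: 15
#' proportion-type indicators where higher compliance is better (blood
#' pressure and diabetes control, screening, vaccination, generic
#' prescribing, ...), one proportion-type indicator where lower is better
#' (use of new medications with limited added value), and four pharmacy-cost
#' indicators (mean cost per defined daily dose, DDD) where lower cost is
#' better. Benchmark DDD costs here are synthetic defaults intended only to
#' anchor the cost-score scale; they are configuration inputs, not
#' historical prices. `eligible_frac` is the fraction of a unit's attended
#' panel eligible for the indicator, used by the synthetic generator.
#'
#' @return A tibble with columns `indicator_id`, `description`, `kind`
#'   (`"proportion"` or `"cost_per_ddd"`), `direction` (`"higher_better"` or
#'   `"lower_better"`), `benchmark_cost` (EUR/DDD, cost kind only), `weight`,
#'   `eligible_frac`.
#' @export
default_indicator_definitions <- function() {
  def <- tibble::tribble(
    ~indicator_id, ~description,                                                     ~kind,         ~direction,      ~benchmark_cost, ~eligible_frac,
    1L,  "Blood pressure at target in treated hypertension",                         "proportion",   "higher_better", NA,   0.22,
    2L,  "HbA1c below 7% in diabetes",                                               "proportion",   "higher_better", NA,   0.09,
    3L,  "Blood pressure screening recorded",                                        "proportion",   "higher_better", NA,   0.60,
    4L,  "Diabetes screening in at-risk adults",                                     "proportion",   "higher_better", NA,   0.35,
    5L,  "Cardiovascular risk assessed when cholesterol is raised (age 35-74)",      "proportion",   "higher_better", NA,   0.18,
    6L,  "Alcohol consumption screening in adults",                                  "proportion",   "higher_better", NA,   0.55,
    7L,  "Smoking cessation sustained at one year",                                  "proportion",   "higher_better", NA,   0.06,
    8L,  "Antiplatelet treatment in ischaemic heart disease",                        "proportion",   "higher_better", NA,   0.04,
    9L,  "LDL cholesterol below 100 mg/dl in ischaemic heart disease",               "proportion",   "higher_better", NA,   0.04,
    10L, "Anticoagulation in atrial fibrillation",                                   "proportion",   "higher_better", NA,   0.03,
    11L, "Home-care reach in the assigned population over 74",                       "proportion",   "higher_better", NA,   0.08,
    12L, "Home-care patients over 74 with a documented assessment",                  "proportion",   "higher_better", NA,   0.07,
    13L, "Influenza vaccination at age 60 or more",                                  "proportion",   "higher_better", NA,   0.30,
    14L, "Pneumococcal vaccination in COPD",                                         "proportion",   "higher_better", NA,   0.05,
    15L, "Generic pharmaceutical prescribing",                                       "proportion",   "higher_better", NA,   0.50,
    16L, "Use of new medications with limited added value",                          "proportion",   "lower_better",  NA,   0.40,
    17L, "Mean cost per DDD, proton pump inhibitors",                                "cost_per_ddd", "lower_better",  0.40, NA,
    18L, "Mean cost per DDD, statins",                                               "cost_per_ddd", "lower_better",  0.55, NA,
    19L, "Mean cost per DDD, ACE inhibitors and angiotensin receptor antagonists",   "cost_per_ddd", "lower_better",  0.50, NA,
    20L, "Mean cost per DDD, SSRI and newer antidepressants",                        "cost_per_ddd", "lower_better",  0.70, NA
  )
  def$weight <- 1
  def
}

validate_definitions <- function(definitions) {
  check_columns(definitions,
                c("indicator_id", "kind", "direction", "weight"),
                "indicator definition table")
  if (!all(definitions$kind %in% c("proportion", "cost_per_ddd"))) {
    abort("indicator kind must be 'proportion' or 'cost_per_ddd'",
          class = "casemixr_validation_error")
  }
  if (!all(definitions$direction %in% c("higher_better", "lower_better"))) {
    abort("indicator direction must be 'higher_better' or 'lower_better'",
          class = "casemixr_validation_error")
  }
  is_cost <- definitions$kind == "cost_per_ddd"
  if (any(is_cost & (is.na(definitions$benchmark_cost) |
                     definitions$benchmark_cost <= 0))) {
    abort("cost_per_ddd indicators need a positive benchmark_cost",
          class = "casemixr_validation_error")
  }
  if (any(definitions$weight <= 0)) {
    abort("indicator weights must be positive", class = "casemixr_validation_error")
  }
  invisible(definitions)
}

# Compliance probability as a logistic function of quality level.
compliance_prob <- function(quality_level, direction) {
  q <- ifelse(direction == "lower_better", 1 - quality_level, quality_level)
  stats::plogis(-1.8 + 3.6 * q)
}

#' Generate per-unit quality-indicator observations
#'
#' For proportion indicators the eligible count is the indicator's
#' `eligible_frac` times the unit's attended panel, and the compliant count
#' is binomial with success probability a logistic function of the unit's
#' `quality_level` (reversed for lower-is-better indicators). For
#' pharmacy-cost indicators the observed cost per DDD is
#' `benchmark * (2 - quality_level)` times mean-one lognormal noise, so a
#' unit at quality 1 sits at the benchmark. `exact = TRUE` removes all
#' noise (expected compliant counts, no cost noise), which is useful for
#' monotonicity checks.
#'
#' @param config A `generator_config` (quality levels come from its units).
#' @param definitions Indicator definitions, see
#'   [default_indicator_definitions()].
#' @param exact Suppress sampling noise.
#' @param cost_noise_sd SD of the lognormal cost noise on the log scale.
#' @return A tibble with columns `unit_id`, `indicator_id`, `eligible`,
#'   `compliant`, `observed_cost`.
#' @export
generate_indicator_observations <- function(config,
                                            definitions = default_indicator_definitions(),
                                            exact = FALSE,
                                            cost_noise_sd = 0.1) {
  stopifnot(inherits(config, "generator_config"))
  validate_definitions(definitions)
  streams <- derive_streams(config)
  withr::with_seed(streams$indicators, {
    rows <- lapply(seq_len(nrow(config$units)), function(i) {
      unit <- config$units[i, ]
      q <- unit$quality_level
      out <- tibble::tibble(
        unit_id = unit$bct_id,
        indicator_id = definitions$indicator_id,
        eligible = NA_integer_,
        compliant = NA_integer_,
        observed_cost = NA_real_
      )
      is_prop <- definitions$kind == "proportion"
      elig <- pmax(1L, as.integer(round(definitions$eligible_frac[is_prop] *
                                          unit$n_attended)))
      p <- compliance_prob(q, definitions$direction[is_prop])
      out$eligible[is_prop] <- elig
      out$compliant[is_prop] <- if (exact) {
        as.integer(round(elig * p))
      } else {
        rbinom(length(elig), elig, p)
      }
      is_cost <- !is_prop
      bench <- definitions$benchmark_cost[is_cost]
      noise <- if (exact) 1 else {
        rlnorm(sum(is_cost), meanlog = -cost_noise_sd^2 / 2, sdlog = cost_noise_sd)
      }
      out$observed_cost[is_cost] <- bench * (2 - q) * noise
      out
    })
    dplyr::bind_rows(rows)
  })
}
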