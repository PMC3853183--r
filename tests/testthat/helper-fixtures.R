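# Shared fixtures and independent oracles used across the suite.

# Generate a population while muffling the documented Poisson-fallback
# warning (several catalog episode cells are underdispersed by design).
quiet_generate <- function(config) {
  withCallingHandlers(
    generate_population(config),
    casemixr_moment_fallback = function(w) invokeRestart("muffleWarning")
  )
}

# A hand-built random cohort, independent of the package generator, for
# oracle tests of the grouped computations.
random_cohort <- function(n, seed, n_units = 4, n_codes = 6) {
  withr::with_seed(seed, {
    units <- sprintf("u%02d", seq_len(n_units))
    tibble::tibble(
      patient_id = sprintf("p%06d", seq_len(n)),
      age = sample(15:95, n, replace = TRUE),
      sex = sample(c("female", "male"), n, replace = TRUE),
      phc_id = "phcA",
      bct_id = sample(units, n, replace = TRUE),
      acg_code = sample(LETTERS[seq_len(n_codes)], n, replace = TRUE),
      n_visits = sample(1:20, n, replace = TRUE),
      n_episodes = sample(1:8, n, replace = TRUE),
      cost = round(stats::rgamma(n, shape = 2, rate = 1 / 300), 2)
    )
  })
}

# Brute-force per-patient loop for expected totals under a reference:
# the oracle the grouped computation must reproduce.
loop_expected_means <- function(patients, reference) {
  lut_v <- stats::setNames(reference$per_acg$mean_visits, reference$per_acg$acg_code)
  lut_e <- stats::setNames(reference$per_acg$mean_episodes, reference$per_acg$acg_code)
  lut_c <- stats::setNames(reference$per_acg$mean_cost, reference$per_acg$acg_code)
  tv <- te <- tc <- 0
  for (i in seq_len(nrow(patients))) {
    code <- patients$acg_code[i]
    tv <- tv + lut_v[[code]]
    te <- te + lut_e[[code]]
    tc <- tc + lut_c[[code]]
  }
  n <- nrow(patients)
  list(expected_mean_visits = tv / n, expected_mean_episodes = te / n,
       expected_mean_cost = tc / n)
}

# Welford online mean/variance: an independent numerical oracle.
streaming_mean_sd <- function(x) {
  m <- 0; m2 <- 0; k <- 0
  for (v in x) {
    k <- k + 1
    d <- v - m
    m <- m + d / k
    m2 <- m2 + d * (v - m)
  }
  list(mean = m, sd = if (k > 1) sqrt(m2 / (k - 1)) else 0)
}

# Two-sided permutation p-value for a correlation coefficient.
permutation_pvalue <- function(x, y, B = 10000, seed = 1) {
  withr::with_seed(seed, {
    r_obs <- abs(stats::cor(x, y))
    hits <- 0L
    for (b in seq_len(B)) {
      if (abs(stats::cor(x, sample(y))) >= r_obs) hits <- hits + 1L
    }
    (1 + hits) / (B + 1)
  })
}

# Small valid patient table for I/O tests.
tiny_patients <- function() {
  tibble::tibble(
    patient_id = c("p1", "p2", "p3"),
    age = c(30L, 45L, 70L),
    sex = c("female", "male", "female"),
    phc_id = c("phc1", "phc1", "phc1"),
    bct_id = c("bct1", "bct1", "bct2"),
    acg_code = c("300", "4100", "300"),
    n_visits = c(2L, 7L, 4L),
    n_episodes = c(1L, 4L, 2L),
    cost = c(120.5, 800.25, 310.75)
  )
}
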