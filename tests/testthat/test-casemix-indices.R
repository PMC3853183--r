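test_that("reference profile means are per-category arithmetic means", {
  p <- tiny_patients()[c(1, 3), ]  # both ACG 300, 2 and 4 visits
  ref <- build_reference_profile(p)
  expect_equal(ref$per_acg$mean_visits, 3)
  expect_equal(ref$pooled$mean_visits, 3)
  expect_error(build_reference_profile(tiny_patients()[0, ]),
               class = "casemixr_validation_error")

  # pooled mean equals the share-weighted per-category means, and the
  # grouped computation matches a per-patient loop on a larger cohort
  cohort <- random_cohort(10000, seed = 14)
  ref2 <- build_reference_profile(cohort)
  shares <- ref2$per_acg$n_patients / sum(ref2$per_acg$n_patients)
  expect_equal(ref2$pooled$mean_cost, sum(shares * ref2$per_acg$mean_cost),
               tolerance = 1e-12)
  for (code in ref2$per_acg$acg_code) {
    x <- cohort$n_visits[cohort$acg_code == code]
    s <- 0
    for (v in x) s <- s + v
    expect_equal(ref2$per_acg$mean_visits[ref2$per_acg$acg_code == code],
                 s / length(x), tolerance = 1e-12)
  }
})

test_that("expected means obey the mixture identity and match the loop oracle", {
  cohort <- random_cohort(2000, seed = 7)
  ref <- build_reference_profile(cohort)

  # the whole cohort has the pooled mix, so expected mean = pooled mean
  em <- expected_means(cohort, ref)
  expect_equal(em$expected_mean_visits, ref$pooled$mean_visits, tolerance = 1e-12)
  expect_equal(em$expected_mean_cost, ref$pooled$mean_cost, tolerance = 1e-12)

  for (unit in unique(cohort$bct_id)) {
    up <- cohort[cohort$bct_id == unit, ]
    got <- expected_means(up, ref)
    want <- loop_expected_means(up, ref)
    expect_equal(got$expected_mean_visits, want$expected_mean_visits, tolerance = 1e-12)
    expect_equal(got$expected_mean_episodes, want$expected_mean_episodes, tolerance = 1e-12)
    expect_equal(got$expected_mean_cost, want$expected_mean_cost, tolerance = 1e-12)
  }

  # unseen categories are an explicit error naming the codes
  alien <- cohort[1:5, ]
  alien$acg_code <- "ZZZ"
  expect_error(expected_means(alien, ref), "ZZZ",
               class = "casemixr_validation_error")
})

test_that("scalar index operations follow their definitions", {
  expect_equal(round_half_up(efficiency_index(600.87, 752.71), 2), 0.80)
  expect_equal(round_half_up(efficiency_index(9.87, 8.02), 2), 1.23)
  expect_equal(efficiency_index(5, 5), 1)
  expect_error(efficiency_index(1, 0), class = "casemixr_computation_error")

  expect_equal(round_half_up(risk_index(6.93, 7.8), 2), 0.89)
  expect_equal(round_half_up(risk_index(8.49, 7.8), 2), 1.09)
  expect_error(risk_index(1, 0), class = "casemixr_computation_error")

  expect_equal(coverage_ratio(1, 4), 0.25)
  expect_equal(coverage_ratio(10, 10), 1)
  expect_error(coverage_ratio(5, 4), class = "casemixr_validation_error")
  expect_error(coverage_ratio(0, 4), class = "casemixr_validation_error")
})

test_that("unit index tables satisfy ratio and conservation invariants", {
  cfg <- generator_config(make_units(13, 500), seed = 17)
  pats <- quiet_generate(cfg)
  tab <- unit_index_table(pats, level = "bct")
  expect_equal(nrow(tab), 13)
  expect_equal(tab$visits_ei, tab$observed_mean_visits / tab$expected_mean_visits,
               tolerance = 1e-12)
  expect_equal(tab$costs_ei, tab$observed_mean_cost / tab$expected_mean_cost,
               tolerance = 1e-12)
  expect_true(all(tab$visits_ei > 0 & tab$episodes_ei > 0 & tab$costs_ei > 0 &
                    tab$ri > 0))

  # with the reference built from the same cohort, expected totals conserve
  # observed totals: pooled EIs and the attended-weighted mean RI are 1
  w <- tab$n_attended
  expect_equal(sum(w * tab$observed_mean_visits) / sum(w * tab$expected_mean_visits),
               1, tolerance = 1e-9)
  expect_equal(sum(w * tab$observed_mean_episodes) / sum(w * tab$expected_mean_episodes),
               1, tolerance = 1e-9)
  expect_equal(sum(w * tab$observed_mean_cost) / sum(w * tab$expected_mean_cost),
               1, tolerance = 1e-9)
  expect_equal(sum(w * tab$ri) / sum(w), 1, tolerance = 1e-9)

  # coverage appears when unit metadata is supplied
  units_meta <- tibble::tibble(level = "BCT", id = cfg$units$bct_id,
                               assigned_population = cfg$units$assigned_population,
                               parent_phc = cfg$units$phc_id)
  tab2 <- unit_index_table(pats, units_meta, level = "bct")
  expect_true(all(tab2$coverage > 0 & tab2$coverage <= 1))
})

test_that("one extra visit raises the unit's visits EI and leaves its RI fixed", {
  cohort <- random_cohort(1500, seed = 3)
  ref <- build_reference_profile(cohort)
  before <- unit_index_table(cohort, reference = ref, level = "bct")
  bumped <- cohort
  idx <- which(bumped$bct_id == before$unit_id[1])[1]
  bumped$n_visits[idx] <- bumped$n_visits[idx] + 1L
  after <- unit_index_table(bumped, reference = ref, level = "bct")
  expect_gt(after$visits_ei[1], before$visits_ei[1])
  expect_equal(after$ri, before$ri, tolerance = 1e-12)
  expect_equal(after$costs_ei, before$costs_ei, tolerance = 1e-12)
})

test_that("cost EI is invariant to rescaling all costs", {
  cohort <- random_cohort(1200, seed = 9)
  tab <- unit_index_table(cohort, level = "bct")
  scaled <- cohort
  scaled$cost <- scaled$cost * 3.7
  tab2 <- unit_index_table(scaled, level = "bct")
  expect_equal(tab2$costs_ei, tab$costs_ei, tolerance = 1e-12)
})

test_that("descriptive summaries match a streaming oracle and the layout contract", {
  one <- tiny_patients()[2, ]
  d1 <- descriptive_summary(one)
  expect_equal(d1$mean[d1$variable == "n_visits"], 7)
  expect_equal(d1$sd[d1$variable == "n_visits"], 0)
  expect_equal(d1$median[d1$variable == "n_visits"], 7)

  cohort <- random_cohort(3000, seed = 5)
  d <- descriptive_summary(cohort)
  oracle <- streaming_mean_sd(cohort$cost)
  expect_equal(d$mean[d$variable == "cost"], oracle$mean, tolerance = 1e-10)
  expect_equal(d$sd[d$variable == "cost"], oracle$sd, tolerance = 1e-10)
  expect_match(d$label[d$variable == "n_visits"],
               "^[0-9.]+ \\([0-9.]+\\) ; [0-9.]+ \\[[0-9.]+-[0-9.]+\\]$")
})

test_that("the category distribution table is complete, ordered and thresholded", {
  cohort <- random_cohort(4000, seed = 12, n_codes = 10)
  tab <- acg_distribution_table(cohort, share_threshold = 0.08)
  expect_equal(sum(tab$pct), 100, tolerance = 1e-9)
  expect_false(is.unsorted(rev(tab$n)))
  expect_equal(tab$cum_pct, cumsum(tab$pct), tolerance = 1e-12)
  # threshold count equals a brute-force filter on shares
  brute <- sum(table(cohort$acg_code) / nrow(cohort) < 0.08)
  expect_equal(attr(tab, "n_rare"), brute)
})

test_that("report rounding is half away from zero", {
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(-2.5, 0), -3)
  expect_equal(round_half_up(0.885, 2), 0.89)
  expect_equal(round_half_up(1.005, 2), 1.01)
  expect_equal(round_half_up(69.15, 1), 69.2)
  expect_equal(round_half_up(0.79827, 2), 0.8)
})
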