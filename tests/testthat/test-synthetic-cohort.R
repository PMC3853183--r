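test_that("generation is deterministic and zero-truncated", {
  cfg <- generator_config(make_units(3, 400), seed = 5)
  a <- quiet_generate(cfg)
  b <- quiet_generate(cfg)
  expect_identical(a, b)
  expect_true(all(a$n_visits >= 1))
  expect_true(all(a$n_episodes >= 1))
  expect_true(all(a$cost > 0))
  expect_true(all(a$age > 14))
  expect_equal(nrow(a), 1200)

  # a different seed changes the cohort
  cfg2 <- generator_config(make_units(3, 400), seed = 6)
  expect_false(identical(quiet_generate(cfg2), a))
})

test_that("empirical case-mix shares track the catalog at scale", {
  cfg <- generator_config(make_units(2, 25000), kappa = Inf, seed = 11)
  pats <- quiet_generate(cfg)
  catg <- default_acg_catalog()
  shares <- as.numeric(table(factor(pats$acg_code, levels = catg$acg_code))) /
    nrow(pats)
  expect_lt(max(abs(shares - catg$share)), 0.01)
})

test_that("cell moments are recovered: truncated means exact, SDs as implied", {
  cfg <- generator_config(make_units(2, 25000), kappa = Inf, seed = 11)
  pats <- quiet_generate(cfg)
  catg <- default_acg_catalog()
  pm <- catalog_pooled_means()

  # pooled mean visits within Monte-Carlo error of the mixture-implied mean
  se <- stats::sd(pats$n_visits) / sqrt(nrow(pats))
  expect_lt(abs(mean(pats$n_visits) - pm$mean_visits), 3 * se)

  for (code in c("4100", "300", "4910", "OTHER")) {
    row <- catg[catg$acg_code == code, ]
    x <- pats$n_visits[pats$acg_code == code]
    n <- length(x)
    pv <- casemixr:::count_cell_params(row$mean_visits, row$sd_visits)
    # truncated-mean matching is exact, so the target is the catalog mean
    expect_lt(abs(mean(x) - row$mean_visits), 4 * sqrt(pv$zt_var / n))
    # the SD target is the implied zero-truncated SD
    expect_lt(abs(stats::sd(x) - sqrt(pv$zt_var)),
              4 * sqrt(pv$zt_var) / sqrt(2 * (n - 1)))
    y <- pats$cost[pats$acg_code == code]
    expect_lt(abs(mean(y) - row$mean_cost), 4 * row$sd_cost / sqrt(n))
  }
})

test_that("underdispersed count targets fall back to truncated Poisson with a warning", {
  cfg <- generator_config(make_units(2, 50), seed = 3)
  expect_warning(generate_population(cfg), "episodes:4100",
                 class = "casemixr_moment_fallback")
  p <- casemixr:::count_cell_params(3.9, 1.3)   # sd^2 < mean
  expect_identical(p$family, "ztpois")
  expect_true(p$fallback)
  p2 <- casemixr:::count_cell_params(7.0, 5.2)  # sd^2 > mean
  expect_identical(p2$family, "nbinom")
  expect_equal(p2$zt_mean, 7.0, tolerance = 1e-9)
})

test_that("infeasible moment targets are config errors", {
  expect_error(casemixr:::count_cell_params(0.8, 1.0),
               class = "casemixr_config_error")
  expect_error(casemixr:::draw_costs(5, -1, 2, "random"),
               class = "casemixr_config_error")
})

test_that("case-mix tilt monotonically raises the implied visit burden", {
  catg <- default_acg_catalog()
  shifts <- seq(-1.5, 1.5, by = 0.25)
  implied <- vapply(shifts, function(s) {
    sum(casemixr:::tilt_shares(catg, s) * catg$mean_visits)
  }, numeric(1))
  expect_false(is.unsorted(implied, strictly = TRUE))
  expect_equal(sum(casemixr:::tilt_shares(catg, 0) * catg$mean_visits),
               catalog_pooled_means()$mean_visits, tolerance = 1e-12)
})

test_that("planted scenarios encode the documented effect structure", {
  base <- generator_config(make_units(13, 100), seed = 1)

  null <- plant_unit_effects(base, "null")
  expect_true(all(null$units$eff_visits == 1))
  expect_true(all(null$units$complexity_shift == 0))

  eg <- plant_unit_effects(base, "efficiency_gradient")
  expect_length(unique(eg$units$eff_visits), 13)
  expect_equal(range(eg$units$eff_visits), c(0.85, 1.20))
  expect_identical(eg$sampling, "balanced")

  cg <- plant_unit_effects(base, "complexity_gradient")
  expect_false(is.unsorted(cg$units$complexity_shift, strictly = TRUE))

  cq <- plant_unit_effects(base, "coupled_quality_efficiency")
  expect_lt(cor(cq$units$eff_costs, cq$units$quality_level), 0)
  expect_gt(cor(cq$units$eff_episodes, cq$units$quality_level), 0)

  expect_error(plant_unit_effects(base, "not_a_scenario"))
})

test_that("generator configuration is validated", {
  u <- make_units(3, 100)
  expect_error(generator_config(u[1, , drop = FALSE]), class = "casemixr_config_error")
  expect_error(generator_config(u, kappa = 0), class = "casemixr_config_error")
  bad <- u; bad$eff_costs[1] <- -1
  expect_error(generator_config(bad), class = "casemixr_config_error")
  bad2 <- u; bad2$n_attended[1] <- bad2$assigned_population[1] + 1L
  expect_error(generator_config(bad2), class = "casemixr_config_error")
})

test_that("indicator observations respect binomial support and quality limits", {
  cfg <- generator_config(make_units(4, 1500), seed = 21)
  obs <- generate_indicator_observations(cfg)
  prop <- obs[!is.na(obs$eligible), ]
  expect_true(all(prop$compliant <= prop$eligible))
  expect_true(all(prop$compliant >= 0))
  expect_equal(nrow(obs), 4 * 20)

  # exact mode at quality 1: proportions at the upper compliance bound,
  # pharmacy costs exactly at benchmark
  u <- make_units(2, 1000)
  u$quality_level <- 1
  top <- generate_indicator_observations(generator_config(u, seed = 1), exact = TRUE)
  defs <- default_indicator_definitions()
  costs <- top$observed_cost[!is.na(top$observed_cost)]
  expect_equal(costs, rep(defs$benchmark_cost[defs$kind == "cost_per_ddd"], 2),
               tolerance = 1e-12)
  hb <- dplyr::inner_join(top, defs, by = "indicator_id")
  hb <- hb[hb$direction == "higher_better" & !is.na(hb$eligible), ]
  expect_equal(hb$compliant / hb$eligible,
               rep(stats::plogis(1.8), nrow(hb)), tolerance = 0.02)

  # higher quality level gives the larger composite score
  u2 <- make_units(2, 5000)
  u2$quality_level <- c(0.2, 0.9)
  obs2 <- generate_indicator_observations(generator_config(u2, seed = 8))
  si <- si_table(obs2)
  expect_gt(si$si[si$unit_id == u2$bct_id[2]], si$si[si$unit_id == u2$bct_id[1]])
})
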