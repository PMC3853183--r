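defs <- default_indicator_definitions()

test_that("indicator definitions encode the contract semantics", {
  expect_equal(nrow(defs), 20)
  expect_true(all(defs$kind[1:15] == "proportion" &
                    defs$direction[1:15] == "higher_better"))
  expect_identical(defs$kind[16], "proportion")
  expect_identical(defs$direction[16], "lower_better")
  expect_true(all(defs$kind[17:20] == "cost_per_ddd" &
                    defs$direction[17:20] == "lower_better"))
  expect_true(all(defs$benchmark_cost[17:20] > 0))
})

test_that("scoring formulas follow each indicator's direction", {
  expect_equal(score_indicator(list(eligible = 200L, compliant = 150L), defs[1, ]), 75)
  expect_equal(score_indicator(list(eligible = 200L, compliant = 150L), defs[16, ]), 25)
  b <- defs$benchmark_cost[17]
  expect_equal(score_indicator(list(observed_cost = b), defs[17, ]), 100)
  expect_equal(score_indicator(list(observed_cost = 2 * b), defs[17, ]), 50)
  expect_equal(score_indicator(list(observed_cost = b / 2), defs[17, ]), 100)

  # no eligible patients means a missing score, not a zero
  expect_true(is.na(score_indicator(list(eligible = 0L, compliant = 0L), defs[1, ])))
  expect_error(score_indicator(list(observed_cost = 0), defs[17, ]),
               class = "casemixr_validation_error")
  expect_error(score_indicator(list(eligible = 10L, compliant = 11L), defs[1, ]),
               class = "casemixr_validation_error")

  # vectorized scoring equals the scalar formula on random observations
  withr::with_seed(31, {
    obs <- tibble::tibble(
      unit_id = "u1",
      indicator_id = sample(defs$indicator_id, 50, replace = TRUE)
    )
    d <- defs[match(obs$indicator_id, defs$indicator_id), ]
    obs$eligible <- ifelse(d$kind == "proportion", sample(10:500, 50, TRUE), NA_integer_)
    obs$compliant <- ifelse(d$kind == "proportion",
                            floor(obs$eligible * runif(50)), NA_integer_)
    obs$observed_cost <- ifelse(d$kind == "cost_per_ddd",
                                runif(50, 0.2, 1.5), NA_real_)
  })
  got <- score_indicators(obs, defs)$score
  want <- vapply(seq_len(nrow(obs)), function(i) {
    score_indicator(obs[i, ], defs[defs$indicator_id == obs$indicator_id[i], ])
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("the composite index is a renormalized weighted mean", {
  expect_equal(synthetic_index(c(40, 60))$si, 50)
  expect_equal(synthetic_index(rep(100, 20))$si, 100)
  expect_equal(synthetic_index(c(90, 30), c(2, 1))$si, 70)
  agg <- synthetic_index(c(NA, 80, 20))
  expect_equal(agg$si, 50)
  expect_equal(agg$n_indicators_used, 2)
  expect_error(synthetic_index(c(NA_real_, NA_real_)),
               class = "casemixr_computation_error")
  expect_error(synthetic_index(c(1, 2), c(1, -1)), class = "casemixr_validation_error")
})

test_that("composite index bounds, symmetry and monotonicity hold over random tables", {
  withr::with_seed(77, {
    for (i in seq_len(1000)) {
      k <- sample(2:20, 1)
      scores <- runif(k, 0, 100)
      scores[runif(k) < 0.15] <- NA
      if (all(is.na(scores))) scores[1] <- runif(1, 0, 100)
      w <- runif(k, 0.5, 2)
      si <- synthetic_index(scores, w)$si

      expect_gte(si, min(scores, na.rm = TRUE) - 1e-9)
      expect_lte(si, max(scores, na.rm = TRUE) + 1e-9)
      expect_gte(si, 0)
      expect_lte(si, 100)

      # permutation invariance
      perm <- sample(k)
      expect_equal(synthetic_index(scores[perm], w[perm])$si, si, tolerance = 1e-9)

      # duplicating an indicator with its weight split in half changes nothing
      j <- which(!is.na(scores))[1]
      scores2 <- c(scores, scores[j])
      w2 <- c(w, w[j] / 2)
      w2[j] <- w[j] / 2
      expect_equal(synthetic_index(scores2, w2)$si, si, tolerance = 1e-9)

      # raising one available score cannot lower the composite
      bump <- scores
      bump[j] <- min(100, bump[j] + 5)
      expect_gte(synthetic_index(bump, w)$si, si - 1e-9)
    }
  })
})

test_that("per-unit composite table is monotone in planted quality and order-free", {
  u <- make_units(13, 2000)
  u$quality_level <- seq(0.1, 0.95, length.out = 13)
  cfg <- generator_config(u, seed = 2)
  obs <- generate_indicator_observations(cfg, exact = TRUE)
  tab <- si_table(obs)
  tab <- tab[match(u$bct_id, tab$unit_id), ]
  expect_false(is.unsorted(tab$si, strictly = TRUE))
  expect_true(all(tab$n_indicators_used == 20))

  shuffled <- obs[withr::with_seed(4, sample(nrow(obs))), ]
  expect_equal(si_table(shuffled)$si, si_table(obs)$si, tolerance = 1e-12)

  # a unit missing one indicator still aggregates over the remaining 19
  obs19 <- obs[!(obs$unit_id == u$bct_id[1] & obs$indicator_id == 20), ]
  t19 <- si_table(obs19)
  expect_equal(t19$n_indicators_used[t19$unit_id == u$bct_id[1]], 19)
})
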