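test_that("agent sampling reproduces the configured trait and parameter moments", {
  ag <- sample_agents(10000, "low", seed = 21)
  expect_equal(mean(ag$trait_anxiety), 0.165, tolerance = 0.01)
  expect_equal(mean(ag$trait_depression), 0.282, tolerance = 0.01)
  expect_equal(sd(ag$trait_anxiety), 0.149, tolerance = 0.01)
  expect_true(all(ag$trait_anxiety >= 0 & ag$trait_anxiety <= 1))
  expect_true(all(ag$trait_depression >= 0 & ag$trait_depression <= 1))
  # parameter means sit at the configured cohort means (MC error ~0.01)
  expect_equal(mean(ag$rho), 1.217, tolerance = 0.015)
  expect_equal(mean(ag$lambda), 2.361, tolerance = 0.06)
  expect_equal(mean(ag$alpha_RG), 1.447, tolerance = 0.04)
  expect_true(all(ag[, c("mu", "rho", "lambda", "alpha_RG", "alpha_SG",
                         "alpha_RL", "alpha_SL")] > 0))
})

test_that("traits are correlated as configured (VIF-scale coupling)", {
  ag <- sample_agents(8000, "high", seed = 22)
  r <- cor(ag$trait_anxiety, ag$trait_depression)
  expect_gt(r, 0.70)
  expect_lt(r, 0.85)
})

test_that("edge cases and determinism", {
  expect_equal(nrow(sample_agents(0, "high")), 0)
  a1 <- sample_agents(25, "high", seed = 5)
  expect_identical(a1, sample_agents(25, "high", seed = 5))
  expect_false(identical(a1, sample_agents(25, "high", seed = 6)))
  bad <- default_param_distributions("high")
  bad$rho["mean"] <- -1
  expect_error(sample_agents(5, "high", param_distributions = bad),
               "positive-support")
})

test_that("trait-parameter linkage shifts parameters in the stated direction", {
  lk <- list(rho = c(anxiety = 2, depression = 0))
  ag <- sample_agents(3000, "high", linkage = lk, seed = 23)
  expect_gt(cor(log(ag$rho), ag$trait_anxiety), 0.2)
  # default linkage is null
  ag0 <- sample_agents(3000, "high", seed = 23)
  expect_lt(abs(cor(log(ag0$rho), ag0$trait_anxiety)), 0.05)
})

test_that("cohort simulation matches analytic choice probabilities", {
  dc <- design_constants("high")
  sched <- generate_schedule("high", 10000, seed = 29)
  par <- parameter_set(mu = 1)   # rational risk-neutral agent, moderate noise
  ch <- simulate_choices(par, sched, dc, seed = 36)
  p <- predict_p_gamble(sched, par, dc)
  for (cc in 1:8) {
    i <- sched$condition == cc
    expect_lt(abs(mean(ch$chose_gamble[i]) - mean(p[i])), 0.02)
  }
})

test_that("simulation limits: deterministic and indifferent agents", {
  dc <- design_constants("high")
  sched <- generate_schedule("high", 400, seed = 31)
  # huge mu: every choice follows the utility sign
  par <- parameter_set(mu = 1e6, rho = 1.1, lambda = 2)
  ch <- simulate_choices(par, sched, dc, seed = 32)
  p <- predict_p_gamble(sched, par, dc)
  expect_true(all(ch$chose_gamble[p > 0.999] == 1))
  expect_true(all(ch$chose_gamble[p < 0.001] == 0))
  # mu = 0: long-run gamble rate 50%
  ch0 <- simulate_choices(parameter_set(mu = 0), sched, dc, seed = 33)
  expect_lt(abs(mean(ch0$chose_gamble) - 0.5), 0.06)
})

test_that("missing responses are generated at the configured rate", {
  dc <- design_constants("high")
  sched <- generate_schedule("high", 4000, seed = 34)
  ch <- simulate_choices(parameter_set(mu = 0.5), sched, dc, seed = 35,
                         missing_rate = 0.1)
  expect_lt(abs(mean(is.na(ch$chose_gamble)) - 0.1), 0.02)
})

test_that("cohort container round-trips through delimited text", {
  co <- tiny_cohort
  expect_equal(nrow(co$choices), 6 * 96)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$choices), nrow(co$choices))
  expect_equal(back$agents$rho, co$agents$rho, tolerance = 1e-12)
  expect_equal(back$choices$chose_gamble, co$choices$chose_gamble)
})
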