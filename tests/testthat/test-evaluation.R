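test_that("pseudo-R2 and AIC algebra", {
  expect_equal(pseudo_r2(-230.2, -230.2), 0)
  expect_equal(pseudo_r2(-115.1, -230.2), 0.5)
  expect_equal(aic(0, -230.2), 460.4)
  expect_equal(aic(7, -103.25), 220.5)
  expect_equal(aic(0, 0), 0)
  expect_error(pseudo_r2(-1, 0.1), "negative")
  expect_error(aic(-1, -10))
  # AIC strictly increases with k at fixed loglik
  expect_true(all(diff(aic(0:7, -100)) > 0))
})

test_that("accuracy scoring and the 0.5 tie convention", {
  expect_equal(accuracy(rep(0.5, 20), rbinom(20, 1, 0.5)), 50)
  expect_equal(accuracy(rep(1, 10), rep(1, 10)), 100)
  expect_equal(accuracy(c(0.9, 0.2), c(1, 1)), 50)
  expect_equal(accuracy(c(0.9, 0.2, NA_real_), c(1, 0, NA)), 100)
  expect_error(accuracy(numeric(0), numeric(0)), "non-missing")
})

test_that("within-subject CV: predictable and unpredictable limits", {
  dc <- design_constants("high")
  sched <- generate_schedule("high", 120, seed = 71)
  # near-deterministic agent: choices are perfectly predictable
  chd <- simulate_choices(parameter_set(mu = 50, rho = 1.1, lambda = 2),
                          sched, dc, seed = 72)
  acc <- within_subject_cv(chd, "M1", dc, quick_opts, n_repeats = 2, seed = 73)
  expect_gt(acc, 95)
  # indifferent agent: nothing to predict
  ch0 <- simulate_choices(parameter_set(mu = 0), sched, dc, seed = 74)
  acc0 <- within_subject_cv(ch0, "M1", dc, quick_opts, n_repeats = 2, seed = 75)
  expect_lt(abs(acc0 - 50), 12)
  # bit-for-bit reproducible given seed
  expect_identical(acc, within_subject_cv(chd, "M1", dc, quick_opts,
                                          n_repeats = 2, seed = 73))
})

test_that("between-subject CV: boundary cases and homogeneous cohorts", {
  # homogeneous cohort: shared parameters, so no heterogeneity penalty
  dc <- design_constants("high")
  sched <- generate_schedule("high", 150, seed = 76)
  par <- parameter_set(mu = 2, rho = 1.1, lambda = 2)
  rows <- lapply(1:6, function(i) {
    ch <- simulate_choices(par, sched, dc, seed = 80 + i)
    tibble::add_column(ch, agent_id = sprintf("agent%03d", i), .before = 1)
  })
  ds <- list(choices = dplyr::bind_rows(rows), constants = dc)
  # leave-one-subject-out special case runs
  acc_b <- between_subject_cv(ds, "M1", quick_opts, n_groups = 6,
                              n_repeats = 1, seed = 77)
  fits <- fit_cohort(ds, "M1", quick_opts, seed = 78)
  acc_w <- mean(vapply(unique(ds$choices$agent_id), function(id) {
    within_subject_cv(ds$choices[ds$choices$agent_id == id, ], "M1", dc,
                      quick_opts, n_repeats = 1, seed = 79)
  }, numeric(1)))
  expect_lt(abs(acc_b - acc_w), 6)
  expect_error(between_subject_cv(ds, "M1", quick_opts, n_groups = 7),
               "fewer subjects")
})

test_that("comparison table: shapes, null rows exact, winner flag", {
  co <- tiny_cohort
  tab <- comparison_table(co, c("null1", "null2", "M1"), quick_opts, seed = 81)
  expect_equal(nrow(tab), 3)
  n1 <- tab[tab$variant == "null1", ]
  expect_equal(n1$pseudo_r2, 0)
  expect_equal(n1$acc_within, 50)
  expect_equal(n1$k, 0)
  expect_equal(sum(tab$winner), 1)
  # agents gamble non-randomly, so the utility model beats the coin flip
  expect_lt(tab$aic[tab$variant == "M1"], n1$aic)
  expect_gt(tab$pseudo_r2[tab$variant == "null2"], 0)
})
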