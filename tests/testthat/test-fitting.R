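dc <- design_constants("high")

test_that("null variants return closed-form fit results", {
  ch <- fixture_subject$choices
  f <- fit_subject(ch, "null1", dc)
  n <- sum(!is.na(ch$chose_gamble))
  expect_equal(f$k, 0)
  expect_equal(f$loglik, n * log(0.5))
  expect_true(f$converged)
})

test_that("fitting is deterministic given seed and data", {
  ch <- fixture_subject$choices
  f1 <- fit_subject(ch, "M2", dc, quick_opts, seed = 44)
  f2 <- fit_subject(ch, "M2", dc, quick_opts, seed = 44)
  expect_identical(f1, f2)
})

test_that("more starts never worsen the returned log-likelihood", {
  sched <- generate_schedule("high", 150, seed = 51)
  ch <- simulate_choices(parameter_set(mu = 0.5, rho = 1.2, lambda = 2.5,
                                       alpha_RG = 0.6, alpha_SG = 1.4,
                                       alpha_RL = 1.2, alpha_SL = 0.7),
                         sched, dc, seed = 52)
  ll <- vapply(c(1, 3, 6), function(ns) {
    fit_subject(ch, "M5", dc, fit_options(n_starts = ns, maxit = 200),
                seed = 53)$loglik
  }, numeric(1))
  expect_true(all(diff(ll) >= -1e-8))
})

test_that("restricted one-parameter fit matches a grid-search oracle", {
  sched <- generate_schedule("high", 200, seed = 54)
  ch <- simulate_choices(parameter_set(mu = 0.4), sched, dc, seed = 55)
  # pin rho and lambda so mu is the only free parameter of M1
  opts <- fit_options(n_starts = 4,
                      bounds = list(rho = c(1, 1), lambda = c(1, 1)))
  f <- fit_subject(ch, "M1", dc, opts, seed = 56)
  mu_grid <- exp(seq(log(0.001), log(30), length.out = 3000))
  ll_grid <- vapply(mu_grid, function(m) {
    log_likelihood(ch, parameter_set(mu = m), "M1", dc)
  }, numeric(1))
  expect_gte(f$loglik, max(ll_grid) - 1e-8)
  expect_lte(f$loglik, max(ll_grid) + 1e-3)
  expect_equal(f$mu, mu_grid[which.max(ll_grid)], tolerance = 0.01)
})

test_that("nested variants are monotone in likelihood on shared data", {
  sched <- generate_schedule("high", 333, seed = 57)
  ch <- simulate_choices(parameter_set(mu = 0.5, rho = 1.1, lambda = 2.2,
                                       alpha_RG = 0.7, alpha_SG = 1.2,
                                       alpha_RL = 1.1, alpha_SL = 0.8),
                         sched, dc, seed = 58)
  opts <- fit_options(n_starts = 6)
  ll <- vapply(c("M1", "M2", "M3", "M4", "M5"), function(v) {
    fit_subject(ch, v, dc, opts, seed = 59)$loglik
  }, numeric(1))
  tol <- 1e-4
  expect_gte(ll[["M5"]], ll[["M3"]] - tol)
  expect_gte(ll[["M3"]], ll[["M2"]] - tol)
  expect_gte(ll[["M2"]], ll[["M1"]] - tol)
  expect_gte(ll[["M5"]], ll[["M4"]] - tol)
  expect_gte(ll[["M4"]], ll[["M2"]] - tol)
})

test_that("fit_cohort shapes: cardinality, empty case, order independence", {
  co <- tiny_cohort
  two <- list(choices = co$choices[co$choices$agent_id %in%
                                     c("agent001", "agent002"), ],
              constants = co$constants)
  fits <- fit_cohort(two, c("null1", "M1"), quick_opts, seed = 60)
  expect_equal(nrow(fits), 4)
  expect_setequal(fits$variant, c("null1", "M1"))
  empty <- list(choices = co$choices[0, ], constants = co$constants)
  expect_equal(nrow(fit_cohort(empty, "M1", quick_opts)), 0)
  # per-subject seeds are derived, so subject order does not matter
  rev2 <- list(choices = two$choices[rev(seq_len(nrow(two$choices))), ],
               constants = co$constants)
  fits_rev <- fit_cohort(rev2, c("null1", "M1"), quick_opts, seed = 60)
  key <- function(d) d[order(d$agent_id, d$variant), c("agent_id", "variant", "loglik")]
  expect_equal(key(as.data.frame(fits)), key(as.data.frame(fits_rev)),
               ignore_attr = TRUE)
})

test_that("estimates recover generating parameters on a small cohort", {
  co <- simulate_cohort(8, "high", n_trials = 333, seed = 61)
  fits <- fit_cohort(co, "M5", fit_options(n_starts = 4), seed = 62)
  expect_true(all(fits$converged))
  m <- merge(fits, co$agents, by = "agent_id", suffixes = c("_hat", "_true"))
  expect_gt(cor(m$rho_hat, m$rho_true), 0.6)
  expect_gt(cor(m$lambda_hat, m$lambda_true), 0.6)
})

test_that("all-missing subjects error; failures are reported not silent", {
  ch <- fixture_subject$choices
  ch$chose_gamble <- NA_integer_
  expect_error(fit_subject(ch, "M1", dc), "non-missing")
})
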