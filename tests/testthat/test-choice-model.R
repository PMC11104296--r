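dc_high <- design_constants("high")

trial_row <- function(condition, gamble_high = NA, gamble_low = NA,
                      sure_value = NA) {
  tibble::tibble(condition = condition, gamble_high = gamble_high,
                 gamble_low = gamble_low, sure_value = sure_value)
}

test_that("utilities match hand-evaluated condition equations", {
  # C1 at rho=1, lambda=2, gain = 2*loss: utilities cancel
  u <- subjective_utilities(trial_row(1, gamble_high = 10, gamble_low = -5,
                                      sure_value = 0),
                            parameter_set(lambda = 2), dc_high)
  expect_equal(u$u_gamble, 0)
  expect_equal(u$u_sure, 0)
  # C2 high stakes at unit parameters, gain $10: 0.5*10 - 0.5*8.15
  u <- subjective_utilities(trial_row(2, gamble_high = 10, sure_value = 0),
                            parameter_set(), dc_high)
  expect_equal(u$u_gamble, 0.925)
  expect_equal(u$u_sure, 0)
  # C7: ambiguous sure gain (mean 7) vs sure $6 at unit parameters
  u <- subjective_utilities(trial_row(7, sure_value = 6), parameter_set(),
                            dc_high)
  expect_equal(u$u_gamble, 7)
  expect_equal(u$u_sure, 6)
  # C8: lambda multiplies both options
  u <- subjective_utilities(trial_row(8, sure_value = -5),
                            parameter_set(lambda = 2, alpha_SL = 1.5),
                            dc_high)
  expect_equal(u$u_gamble, -2 * 1.5 * 7)
  expect_equal(u$u_sure, -2 * 5)
})

test_that("utilities agree with the scalar oracle on random trials and params", {
  set.seed(31)
  sched <- generate_schedule("high", 64, seed = 13)
  for (rep in 1:5) {
    par <- parameter_set(mu = runif(1, 0, 2), rho = runif(1, 0.5, 1.8),
                         lambda = runif(1, 0.5, 4),
                         alpha_RG = runif(1, 0.3, 2),
                         alpha_SG = runif(1, 0.3, 2),
                         alpha_RL = runif(1, 0.3, 2),
                         alpha_SL = runif(1, 0.3, 2))
    u <- subjective_utilities(sched, par, dc_high)
    for (i in seq_len(nrow(sched))) {
      uo <- oracle_utilities(sched[i, ], par, dc_high$ambiguous_mean)
      expect_equal(u$u_gamble[i], uo[["u_gamble"]], tolerance = 1e-12)
      expect_equal(u$u_sure[i], uo[["u_sure"]], tolerance = 1e-12)
    }
  }
})

test_that("at unit parameters the model is risk-neutral expected value on
           unambiguous trials", {
  sched <- generate_schedule("high", 120, seed = 17)
  unamb <- sched[sched$condition %in% c(1, 4), ]
  u <- subjective_utilities(unamb, parameter_set(), dc_high)
  ev <- 0.5 * unamb$gamble_high + 0.5 * unamb$gamble_low
  expect_equal(u$u_gamble, ev)
  expect_equal(u$u_sure, unamb$sure_value)
})

test_that("parameter-role monotonicities hold", {
  sched <- generate_schedule("high", 160, seed = 19)
  base <- parameter_set(rho = 1.2, lambda = 2, alpha_RG = 1.1,
                        alpha_SG = 0.9, alpha_RL = 1.2, alpha_SL = 0.8)
  bump <- function(p, nm, by) {
    v <- as.numeric(p); names(v) <- names(unclass(p))
    v[nm] <- v[nm] + by
    do.call(parameter_set, as.list(v))
  }
  u0 <- subjective_utilities(sched, base, dc_high)
  # more loss aversion never increases gamble utility on loss-bearing trials
  u1 <- subjective_utilities(sched, bump(base, "lambda", 1), dc_high)
  lossy <- sched$condition %in% c(1, 2, 3, 8)
  expect_true(all(u1$u_gamble[lossy] <= u0$u_gamble[lossy]))
  # ambiguous-gain weights never decrease the ambiguous-gain utility
  u2 <- subjective_utilities(sched, bump(base, "alpha_RG", 0.5), dc_high)
  rg <- sched$condition %in% c(3, 5)
  expect_true(all(u2$u_gamble[rg] >= u0$u_gamble[rg]))
  # ambiguous-loss weights never increase the ambiguous-loss utility
  u3 <- subjective_utilities(sched, bump(base, "alpha_RL", 0.5), dc_high)
  expect_true(all(u3$u_gamble[sched$condition == 2] <= u0$u_gamble[sched$condition == 2]))
  u4 <- subjective_utilities(sched, bump(base, "alpha_SL", 0.5), dc_high)
  expect_true(all(u4$u_gamble[sched$condition == 8] <= u0$u_gamble[sched$condition == 8]))
})

test_that("softmax choice rule: closed form, symmetry, saturation", {
  expect_equal(p_gamble(list(u_gamble = 1, u_sure = 0), mu = 1),
               0.731059, tolerance = 1e-6)
  expect_equal(p_gamble(list(u_gamble = 3, u_sure = 3), mu = 2), 0.5)
  expect_equal(p_gamble(list(u_gamble = 5, u_sure = -1), mu = 0), 0.5)
  # complement identity
  u <- list(u_gamble = c(-2, 0.3, 4), u_sure = c(1, -0.5, 4))
  rev_u <- list(u_gamble = u$u_sure, u_sure = u$u_gamble)
  expect_equal(p_gamble(u, 1.3) + p_gamble(rev_u, 1.3), rep(1, 3))
  # numerically stable at extreme arguments
  expect_equal(p_gamble(list(u_gamble = 1e6, u_sure = 0), 10), 1)
  expect_equal(p_gamble(list(u_gamble = -1e6, u_sure = 0), 10), 0)
  expect_error(p_gamble(list(u_gamble = 1, u_sure = 0), -1))
})

test_that("log-likelihood: null closed forms and brute-force equivalence", {
  ch <- fixture_subject$choices
  n <- sum(!is.na(ch$chose_gamble))
  expect_equal(log_likelihood(ch, variant = "null1"), n * log(0.5))
  # null2 with all-gamble choices saturates at the clipping bound
  allg <- ch
  allg$chose_gamble <- 1L
  expect_equal(log_likelihood(allg, variant = "null2"),
               n * log(1 - 1e-9))
  # M5 likelihood equals the scalar product oracle
  ll <- log_likelihood(ch, fixture_subject$params, "M5",
                       fixture_subject$constants)
  ll_oracle <- oracle_loglik(ch, fixture_subject$params,
                             fixture_subject$constants$ambiguous_mean)
  expect_equal(ll, ll_oracle, tolerance = 1e-10)
  # missing trials are dropped; all-missing errors
  chm <- ch
  chm$chose_gamble[1:5] <- NA
  expect_equal(log_likelihood(chm, fixture_subject$params, "M5",
                              fixture_subject$constants),
               oracle_loglik(chm, fixture_subject$params,
                             fixture_subject$constants$ambiguous_mean),
               tolerance = 1e-10)
  chm$chose_gamble <- NA_integer_
  expect_error(log_likelihood(chm, variant = "null1"), "missing")
})

test_that("variant free-parameter counts and nesting structure", {
  ks <- vapply(c("null1", "null2", "M1", "M2", "M3", "M4", "M5"),
               function(v) model_variant(v)$k, numeric(1))
  expect_equal(unname(ks), c(0, 0, 3, 4, 5, 5, 7))
  # any M1 likelihood value is attainable by M5 with alphas at 1
  ch <- fixture_subject$choices
  par1 <- parameter_set(mu = 0.7, rho = 1.3, lambda = 1.8)
  expect_equal(
    log_likelihood(ch, par1, "M1", fixture_subject$constants),
    log_likelihood(ch, par1, "M5", fixture_subject$constants)
  )
})

test_that("invalid trials are rejected", {
  expect_error(subjective_utilities(trial_row(9, gamble_high = 1),
                                    parameter_set(), dc_high), "condition")
  expect_error(subjective_utilities(
    trial_row(1, gamble_high = 5, gamble_low = 3, sure_value = 0),
    parameter_set(), dc_high), "magnitude")
})
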