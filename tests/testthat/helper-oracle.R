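# Independent brute-force oracle for the choice model: per-trial utilities
# written out condition by condition from the utility table, probabilities
# through the logistic by hand, likelihood as an explicit product over
# trials. Deliberately scalar and unvectorised - it shares no code with the
# package's likelihood path.

oracle_utilities <- function(row, par, am) {
  rho <- par[["rho"]]; lam <- par[["lambda"]]
  aRG <- par[["alpha_RG"]]; aSG <- par[["alpha_SG"]]
  aRL <- par[["alpha_RL"]]; aSL <- par[["alpha_SL"]]
  cond <- row$condition
  if (cond == 1) {
    ug <- 0.5 * row$gamble_high^rho - 0.5 * lam * (-row$gamble_low)^rho
    us <- 0
  } else if (cond == 2) {
    ug <- 0.5 * row$gamble_high^rho - 0.5 * lam * aRL * am[["c2"]]^rho
    us <- 0
  } else if (cond == 3) {
    ug <- 0.5 * aRG * am[["c3"]]^rho - 0.5 * lam * (-row$gamble_low)^rho
    us <- 0
  } else if (cond == 4) {
    ug <- 0.5 * row$gamble_high^rho
    us <- row$sure_value^rho
  } else if (cond == 5) {
    ug <- 0.5 * aRG * am[["c5"]]^rho
    us <- row$sure_value^rho
  } else if (cond == 6) {
    ug <- 0.5 * row$gamble_high^rho
    us <- aSG * am[["c6"]]^rho
  } else if (cond == 7) {
    ug <- aSG * am[["c7"]]^rho
    us <- row$sure_value^rho
  } else {
    ug <- -lam * aSL * am[["c8"]]^rho
    us <- -lam * (-row$sure_value)^rho
  }
  c(u_gamble = ug, u_sure = us)
}

oracle_loglik <- function(choices, par, am, eps = 1e-9) {
  ll <- 0
  for (i in seq_len(nrow(choices))) {
    row <- choices[i, ]
    if (is.na(row$chose_gamble)) next
    u <- oracle_utilities(row, par, am)
    p <- 1 / (1 + exp(-par[["mu"]] * (u[["u_gamble"]] - u[["u_sure"]])))
    p <- min(max(p, eps), 1 - eps)
    ll <- ll + log(if (row$chose_gamble == 1) p else 1 - p)
  }
  ll
}
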