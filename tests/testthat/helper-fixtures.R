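# Shared small fixtures, built once per test run.

quick_opts <- fit_options(n_starts = 2, maxit = 200)

# 6-agent high-stakes cohort, shortened trial count, for structural tests
tiny_cohort <- simulate_cohort(6, "high", n_trials = 96, seed = 42)

# one 20-trial subject with known parameters, used by the likelihood oracle
fixture_subject <- local({
  dc <- design_constants("high")
  sched <- generate_schedule("high", 20, seed = 7)
  par <- parameter_set(mu = 0.4, rho = 1.1, lambda = 2.2,
                       alpha_RG = 0.7, alpha_SG = 1.3,
                       alpha_RL = 0.9, alpha_SL = 1.1)
  list(constants = dc, choices = simulate_choices(par, sched, dc, seed = 8),
       params = par)
})
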