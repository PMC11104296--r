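---
title: "Modelling choices under ambiguous outcome magnitudes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling choices under ambiguous outcome magnitudes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the model

`ambiprospect` analyses a two-option monetary gambling task with eight
trial types crossing three constructs: risk (a 50/50 gamble vs a certain
option), losses, and *outcome-magnitude ambiguity* — a payoff displayed
only as "$?" or "–$?" with no stated range. Conditions 1–3 pit a mixed
gain/loss gamble against a sure $0; conditions 4–6 pit a gain/$0 gamble
against a sure gain; conditions 7–8 offer two certain options, one
ambiguous. "Gambling" means taking the risky option (1–6) or the ambiguous
option (7–8). The task exists at two stakes levels whose payoff ranges
differ by a factor of 20 (gains to $1.20 vs $24), with real payment of one
randomly drawn trial added to an endowment, so the possible final payments
are $3.60–$5.70 (low) and $6–$48 (high).

Choice is modelled by prospect-theory utilities augmented with
multiplicative ambiguity weights. For a payoff magnitude $v \ge 0$:

* gains contribute $+\,p \cdot v^{\rho}$ and losses $-\,p \cdot \lambda
  v^{\rho}$, with outcome probability $p \in \{0.5, 1\}$;
* an ambiguous payoff is replaced by its *rational mean value* $m_c$ — the
  mean of the unambiguous values shown in structurally matched conditions
  (high stakes: $8.15, $14.15, $15, $5, $7, $7 for conditions 2, 3, 5, 6,
  7, 8; low stakes: 41¢, 71¢, 75¢, 28¢, 35¢, 35¢) — multiplied by an
  ambiguity weight $\alpha$;
* in condition 8 both options are losses, so $\lambda$ multiplies both
  sides.

The probability of gambling is a softmax of the utility difference,
$P(\text{gamble}) = 1/(1 + e^{-\mu(u_{\text{gamble}} - u_{\text{sure}})})$,
with inverse temperature $\mu \ge 0$. A value of 1 for $\rho$, $\lambda$
or any $\alpha$ is the rational no-preference baseline.

Seven variants are compared: two parameter-free nulls (a 50% rate; the
subject's own rate), the traditional three-parameter model M1
($\mu, \rho, \lambda$), and four nested ambiguity models — one shared
weight (M2, k=4), gain/loss weights (M3, k=5), loss-context/no-loss-context
weights (M4, k=5; note this tying cuts *across* the four display slots,
which is why the package's internal parameterisation is one weight per
ambiguous condition), and the full model M5 with separate weights for
ambiguous risky gains, sure gains, risky losses and sure losses (k=7).

## Estimation

Each subject is fit independently by maximum likelihood: the trial-wise
Bernoulli log-likelihood (probabilities clipped at $10^{-9}$) is maximised
by `L-BFGS-B` on log-transformed parameters under box bounds
($\mu \in [0.001, 30]$, $\rho \in [0.05, 3]$, $\lambda \in [0.05, 10]$,
$\alpha \in [0.05, 5]$ — wide enough to cover all reported estimates with
margin; no bounds are published, so these are declared, not inferred).
Besides `n_starts = 10` log-uniform random initialisations, one
deterministic start at the rational point (all parameters 1) is always
included; this makes the nested-model baseline reachable and, empirically,
makes the likelihood-nesting inequality
$\ell_{M5} \ge \ell_{M3} \ge \ell_{M2} \ge \ell_{M1}$ hold to $10^{-4}$.
The gradient is analytic (validated against central differences to
$10^{-8}$), which is what keeps whole-cohort fitting minutes-scale.

Model comparison uses per-subject pseudo-$R^2$
($1 - \ell_{\text{model}}/\ell_{\text{null1}}$, so the coin-flip null is
exactly 0) and AIC ($2k - 2\ell$), averaged over subjects, plus two
out-of-sample accuracies: within-subject (6-fold condition-stratified CV;
trials that cannot be stratified overflow to random folds, since ~42
trials per condition is not divisible by 6) and between-subject (subjects
split into 9 groups; the mean of the training subjects' parameters
predicts the held-out group). Accuracy scores 1 for a directionally
correct prediction, 0 for incorrect, 0.5 at $P = 0.5$ exactly — the tie
convention that pins the coin-flip null at exactly 50.0%. For large
designs `between_subject_cv` reuses the full-data per-subject fits when
averaging training parameters rather than refitting every repeat; the
literal refit-per-repeat path runs when no fits are supplied.

## The synthetic world

The generator emulates the task's stated statistical structure; it is the
world every stochastic check runs in.

* **Schedule**: 333 trials, near-equally allocated (333 = 42 × 5 + 41 × 3,
  remainder to the lowest-numbered conditions), pseudo-random order.
  Unambiguous payoffs are drawn uniformly from 5¢-spaced (low) or
  $1-spaced (high) grids over the stated ranges; the true design's value
  matrices are supplementary material and not reproduced, so the grids
  preserve the printed envelope without inventing the exact matrix.
* **Agents**: independent log-normal parameters whose *means* equal the
  reported cohort means per stakes level (e.g. high stakes $\rho = 1.050$,
  $\lambda = 2.258$, gain weights 0.803, loss weights 0.903). Spreads
  (sdlog 0.25 for $\rho$, 0.5 for $\lambda$, 0.45 for the $\alpha$'s, 0.6
  for $\mu$) are fixed, once, as realistic individual-difference spreads
  for this literature. $\mu$ has no published value; its default mean
  (0.6 high, 8 low — the ~20× utility-scale difference demands different
  consistency scales) was calibrated once so that the cohort's
  true-parameter pseudo-$R^2$ reproduces the printed model-fit scale
  (~.55 high, ~.47 low), before any downstream check was run.
* **Traits**: anxiety and depression composites on [0, 1], moment-matched
  Beta marginals at the printed means/SDs (.165/.149 and .282/.163)
  coupled by a Gaussian copula at r = .78, the correlation implied by the
  printed variance inflation factor (~2.5). Optional linkage coefficients
  can shift parameter log-means with traits (default 0, the reported null)
  so the regression stage can be exercised under power as well.

What a green stochastic test establishes is therefore that *the pipeline
recovers the structure this world has*; it does not certify the original
data. Features of real data the generator deliberately lacks: within-person
parameter stability across stakes (low- and high-stakes agents are drawn
independently and paired by index), response times, position/counterbalance
effects, practice effects, and any trait–parameter association.

## Validation machinery

Parameter recovery refits each subject on data re-simulated from its own
estimates and correlates estimate with recovery per parameter across the
cohort. Gambling-rate recovery correlates observed per-condition gamble
percentages with the model's *expected* rate (mean of per-trial
probabilities) at the fitted parameters. The expected-rate reading is the
package default: with only ~42 trials per condition, a single-draw
simulated rate carries so much binomial noise that the near-perfect
printed correlations — condition 4's r = .880 in particular — are
unreachable under it (we measure .27–.74 for condition 4 across seeds,
versus .66–.87 with expected rates). A `method = "stochastic"` flag
provides the single-draw reading.

In this world, condition 4 is always the weakest rate-recovery condition —
it is the only condition whose choice depends on $\rho$ and $\mu$ alone,
so between-subject rate variance is small and attenuation bites hardest;
the same pattern appears in the original report. Mean parameter recovery
runs ~0.86–0.93 here, short of the reported .973: the weak link is $\mu$,
which saturates for highly consistent high-stakes agents (the data only
bound it from below), and Pearson recovery grows with between-subject
spread, which is wider in real cohorts than under our moderate sdlogs. We
verified the shortfall is informational, not numerical: across a full
cohort, zero refits fall below the likelihood of their generating
parameters.

## Inference layer

Group-level tests are two-tailed t-tests against the no-preference
baselines (1 for parameters, 50% for gamble rates), paired t-tests for
low-vs-high-stakes contrasts with difference-score Cohen's d, and a
hand-rolled step-down Holm–Bonferroni procedure (the analysis reports the
cutoff ladder $\alpha/(m - i + 1)$ itself, which `p.adjust` does not
expose; a test cross-checks decisions against `p.adjust(, "holm")`).
Trait associations are per-parameter OLS regressions of subject-level
estimates on one trait at a time — the only structure the source analysis
spells out — with the two-predictor VIF $1/(1 - r^2)$ reported for the
multicollinearity check. Zero-variance inputs are flagged, never silently
tested.

## Numerical choices and limitations

* Likelihood clipping $\varepsilon = 10^{-9}$; losses are stored as
  positive magnitudes so $v^{\rho}$ is real for non-integer $\rho$.
* All randomness flows through integer seeds with derived per-stream
  child seeds; schedules, cohorts, fits and CV assignments are
  bit-for-bit reproducible, and functions restore the caller's RNG state.
* Cohort-level analyses in `analysis/` use 60 agents per stakes level
  (scaled down from N = 367/210) and reduced CV repeat counts; exact
  metrics (AIC, pseudo-$R^2$) are unaffected, CV estimates are noisier.
* The identity of the condition-4 sure value and the exact per-condition
  value matrices are supplementary to the source task and approximated by
  uniform grids; absolute gambling rates in conditions 4–6 therefore
  depend on our grid choice, while the model-comparison and recovery
  conclusions do not.
* Null model 2's rate is computed in-sample from the same subject's data,
  matching its in-sample accuracy bookkeeping.
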