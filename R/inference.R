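#' One-sample t-tests against a no-preference baseline
#'
#' Two-tailed t-tests of per-subject values (parameter estimates, or
#' per-condition gamble percentages) against a null value - 1 for model
#' parameters, 50 for gambling rates. Cohen's d is `(mean - null) / SD`.
#'
#' @param values Numeric vector (one value per subject) or a named list of
#'   such vectors (one test each).
#' @param null_value Baseline (scalar).
#' @param labels Test labels (defaults to list names).
#' @return Tibble of `test_result` rows: `label`, `t`, `df`, `p`, `d`,
#'   `ci_low`, `ci_high`, `degenerate` (zero-variance flag; statistics NA).
#' @export
one_sample_tests <- function(values, null_value = 1, labels = NULL) {
  if (!is.list(values)) values <- list(values)
  if (is.null(labels)) {
    labels <- if (!is.null(names(values))) names(values) else
      paste0("test", seq_along(values))
  }
  rows <- lapply(seq_along(values), function(i) {
    x <- values[[i]]
    if (length(x) < 2) stop("need n >= 2 per test")
    if (stats::sd(x) == 0) {
      return(tibble::tibble(label = labels[i], t = NA_real_,
                            df = length(x) - 1, p = NA_real_, d = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            degenerate = TRUE))
    }
    tt <- stats::t.test(x, mu = null_value)
    tibble::tibble(
      label = labels[i], t = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value,
      d = (mean(x) - null_value) / stats::sd(x),
      ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
      degenerate = FALSE
    )
  })
  dplyr::bind_rows(rows)
}

#' Paired low-vs-high-stakes t-tests
#'
#' Within-subject contrasts on matched values; tests are on the difference
#' `high - low`, with Cohen's d = mean(diff) / SD(diff).
#'
#' @param low,high Named lists of per-subject vectors (matched order), or
#'   single vectors.
#' @param labels Test labels.
#' @return Tibble of test rows as in [one_sample_tests()].
#' @export
paired_stakes_tests <- function(low, high, labels = NULL) {
  if (!is.list(low)) low <- list(low)
  if (!is.list(high)) high <- list(high)
  stopifnot(length(low) == length(high))
  diffs <- lapply(seq_along(low), function(i) {
    if (length(low[[i]]) != length(high[[i]])) {
      stop("unmatched subject sets in test ", i)
    }
    high[[i]] - low[[i]]
  })
  names(diffs) <- if (is.null(labels)) names(low) else labels
  one_sample_tests(diffs, null_value = 0, labels = labels)
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the p-values ascending; the i-th smallest is compared to
#' `alpha / (m - i + 1)` and rejections stop at the first failure.
#' Cutoffs and decisions are reported in the original order.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @param alpha Family-wise level (default 0.05).
#' @return Tibble: `p`, `rank`, `cutoff`, `reject` (original order).
#' @examples
#' holm_bonferroni(c(.01, .03, .04))  # cutoffs .0167, .025, .05
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  if (m == 0) stop("empty p-value list")
  stopifnot(all(p_values >= 0 & p_values <= 1), alpha > 0, alpha < 1)
  ord <- order(p_values)
  rank <- match(seq_len(m), ord)
  rank <- order(ord)  # rank of each original p among sorted
  cutoff <- alpha / (m - rank + 1)
  # step-down: reject while p_(i) <= alpha/(m - i + 1), stop at first failure
  sorted_ok <- p_values[ord] <= alpha / (m - seq_len(m) + 1)
  n_reject <- if (all(sorted_ok)) m else which(!sorted_ok)[1] - 1
  reject <- rank <= n_reject
  tibble::tibble(p = p_values, rank = rank, cutoff = cutoff, reject = reject)
}

#' Trait-association regressions with a VIF multicollinearity check
#'
#' Regresses each model parameter on one trait at a time
#' (`parameter ~ trait`, ordinary least squares on subject-level
#' estimates), reporting slope and p-value, plus the variance inflation
#' factor between the two traits (`1 / (1 - r^2)` for two predictors).
#'
#' @param fits Subject-level parameter estimates: tibble with `agent_id`
#'   and the parameter columns (a [fit_cohort()] table for one variant, or
#'   the ground-truth `agents` table).
#' @param agents Tibble with `agent_id`, `trait_anxiety`,
#'   `trait_depression`.
#' @param parameters Parameter columns to test (default the seven model
#'   parameters).
#' @return List with `associations` (tibble: `parameter`, `trait`,
#'   `slope`, `p`) and `vif` (scalar).
#' @export
trait_regressions <- function(fits, agents,
                              parameters = .param_names) {
  fit_cols <- intersect(c("agent_id", parameters), names(fits))
  if (!all(parameters %in% fit_cols)) {
    stop("`fits` is missing parameter columns: ",
         paste(setdiff(parameters, fit_cols), collapse = ", "))
  }
  d <- merge(fits[, fit_cols],
             agents[, c("agent_id", "trait_anxiety", "trait_depression")],
             by = "agent_id")
  if (nrow(d) < 10) stop("need n >= 10 subjects")
  for (tr in c("trait_anxiety", "trait_depression")) {
    if (stats::sd(d[[tr]]) == 0) stop("constant trait vector: ", tr)
  }
  rows <- list()
  for (pm in parameters) {
    for (tr in c("trait_anxiety", "trait_depression")) {
      fit <- stats::lm(d[[pm]] ~ d[[tr]])
      sm <- summary(fit)$coefficients
      rows[[length(rows) + 1L]] <- tibble::tibble(
        parameter = pm, trait = sub("trait_", "", tr),
        slope = sm[2, 1], p = sm[2, 4]
      )
    }
  }
  r <- stats::cor(d$trait_anxiety, d$trait_depression)
  list(associations = dplyr::bind_rows(rows), vif = 1 / (1 - r^2))
}
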