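#' Pseudo-R-squared against the coin-flip null
#'
#' `1 - loglik_model / loglik_null1`, where the baseline is the 50%
#' gambling-rate null model; the null model itself scores exactly 0.
#'
#' @param loglik_model Model log-likelihood.
#' @param loglik_null1 Null-model-1 log-likelihood (`N * log(0.5)`), `< 0`.
#' @return Unitless value in `(-Inf, 1]`.
#' @export
pseudo_r2 <- function(loglik_model, loglik_null1) {
  if (any(loglik_null1 >= 0)) stop("null log-likelihood must be negative")
  1 - loglik_model / loglik_null1
}

#' Akaike information criterion
#'
#' @param k Number of free parameters.
#' @param loglik Maximised log-likelihood.
#' @return `2k - 2 * loglik` (lower is better).
#' @export
aic <- function(k, loglik) {
  if (any(k < 0)) stop("k must be >= 0")
  2 * k - 2 * loglik
}

#' Percent choice accuracy of predicted probabilities
#'
#' A trial scores 1 when the modal prediction (`P > 0.5` vs `P < 0.5`)
#' matches the observed choice, 0 when it mismatches, and 0.5 when
#' `P = 0.5` exactly - the tie convention that makes the coin-flip null
#' score exactly 50% on any data.
#'
#' @param probabilities Per-trial P(gamble).
#' @param choices Observed choices (1/0, `NA` dropped with their
#'   probabilities).
#' @return Accuracy in percent.
#' @export
accuracy <- function(probabilities, choices) {
  keep <- !is.na(choices)
  p <- probabilities[keep]
  y <- choices[keep]
  if (length(y) == 0) stop("no non-missing trials to score")
  score <- ifelse(p == 0.5, 0.5, as.numeric((p > 0.5) == (y == 1)))
  mean(score) * 100
}

# predicted P(gamble) for a block of trials given a stored fit row
p_from_fit <- function(trials, fit_row, variant, constants) {
  variant <- as_variant(variant)
  if (variant$name == "null1") return(rep(0.5, nrow(trials)))
  if (variant$name == "null2") {
    stop("null2 has no out-of-sample prediction rule")
  }
  free <- fit_free_params(fit_row, variant)
  p_from_terms(trial_terms(trials, constants), variant$expand(free))
}

# condition-stratified assignment of trials into n_folds; remainders that
# cannot be stratified overflow to random folds
stratified_folds <- function(condition, n_folds) {
  n <- length(condition)
  fold <- integer(n)
  leftover <- integer(0)
  for (cc in unique(condition)) {
    i <- sample(which(condition == cc))
    k <- length(i) %/% n_folds
    if (k > 0) {
      fold[i[seq_len(k * n_folds)]] <- rep(seq_len(n_folds), each = k)
    }
    leftover <- c(leftover, i[seq_len(length(i)) > k * n_folds])
  }
  if (length(leftover) > 0) {
    fold[leftover] <- sample(seq_len(n_folds), length(leftover), replace = TRUE)
  }
  fold
}

#' Within-subject out-of-sample accuracy (6-fold, condition-stratified)
#'
#' Trials are partitioned into `n_folds` groups with near-equal condition
#' composition; the model is fit on the other folds and scored on the
#' held-out fold, cycling through all folds, and the whole procedure is
#' repeated `n_repeats` times with fresh fold assignments.
#'
#' @param choices One subject's rows.
#' @param variant Model variant (name or object).
#' @param constants [design_constants()].
#' @param options [fit_options()].
#' @param n_folds Number of trial folds (default 6, i.e. fit on ~5/6).
#' @param n_repeats Fold-assignment repeats (default 100; scale down for
#'   quick checks).
#' @param seed Integer seed.
#' @return Mean accuracy (percent) over folds x repeats.
#' @export
within_subject_cv <- function(choices, variant = "M5", constants,
                              options = fit_options(), n_folds = 6,
                              n_repeats = 100, seed = 1L) {
  variant <- as_variant(variant)
  keep <- !is.na(choices$chose_gamble)
  sub <- choices[keep, , drop = FALSE]
  if (nrow(sub) < 2 * n_folds) stop("too few trials to stratify folds")
  accs <- numeric(0)
  for (r in seq_len(n_repeats)) {
    rng <- local_rng(derive_seed(seed, r))
    fold <- stratified_folds(sub$condition, n_folds)
    restore_rng(rng)
    for (f in seq_len(n_folds)) {
      train <- sub[fold != f, , drop = FALSE]
      test <- sub[fold == f, , drop = FALSE]
      if (nrow(test) == 0) next
      if (variant$name == "null1") {
        p <- rep(0.5, nrow(test))
      } else if (variant$name == "null2") {
        p <- rep(mean(train$chose_gamble), nrow(test))
      } else {
        fit <- fit_subject(train, variant, constants, options,
                           seed = derive_seed(seed, 1000 + r * n_folds + f))
        p <- p_from_fit(test, fit, variant, constants)
      }
      accs <- c(accs, accuracy(p, test$chose_gamble))
    }
  }
  mean(accs)
}

#' Between-subject out-of-sample accuracy
#'
#' Subjects are split into `n_groups`; all training subjects are fit
#' individually, the free parameters are averaged, and that mean parameter
#' set predicts the held-out group's choices. Repeated `n_repeats` times
#' with fresh group assignments.
#'
#' @param dataset A `cohort_dataset` (or list with `choices`, `constants`).
#' @param variant Model variant.
#' @param options [fit_options()].
#' @param n_groups Number of subject groups (default 9).
#' @param n_repeats Repeats (default 100).
#' @param seed Integer seed.
#' @param fits Optional precomputed full-data fits (tibble from
#'   [fit_cohort()] for this variant). When supplied, training-set
#'   parameter means reuse them instead of refitting per repeat - the
#'   practical choice for large designs; refitting per training set is the
#'   literal procedure and is used when `fits` is `NULL`.
#' @return Mean accuracy (percent) over groups x repeats.
#' @export
between_subject_cv <- function(dataset, variant = "M5",
                               options = fit_options(), n_groups = 9,
                               n_repeats = 100, seed = 1L, fits = NULL) {
  variant <- as_variant(variant)
  choices <- dataset$choices
  constants <- dataset$constants
  ids <- unique(choices$agent_id)
  if (length(ids) < n_groups) stop("fewer subjects than groups")
  if (variant$name %in% c("null1", "null2")) {
    stop("between-subject prediction is defined for the utility models")
  }
  if (is.null(fits)) {
    fits <- fit_cohort(list(choices = choices, constants = constants),
                       variant, options, seed = derive_seed(seed, 999))
  } else {
    fits <- fits[fits$variant == variant$name, , drop = FALSE]
  }
  par_mat <- t(vapply(seq_len(nrow(fits)), function(i)
    fit_free_params(fits[i, ], variant),
    numeric(length(variant$par_names))))
  rownames(par_mat) <- fits$agent_id

  accs <- numeric(0)
  for (r in seq_len(n_repeats)) {
    rng <- local_rng(derive_seed(seed, r))
    grp <- sample(rep_len(seq_len(n_groups), length(ids)))
    restore_rng(rng)
    for (g in seq_len(n_groups)) {
      test_ids <- ids[grp == g]
      train_ids <- ids[grp != g]
      mean_free <- colMeans(par_mat[train_ids, , drop = FALSE])
      names(mean_free) <- variant$par_names
      theta <- variant$expand(mean_free)
      block <- choices[choices$agent_id %in% test_ids, , drop = FALSE]
      block <- block[!is.na(block$chose_gamble), , drop = FALSE]
      if (nrow(block) == 0) next
      p <- p_from_terms(trial_terms(block, constants), theta)
      accs <- c(accs, accuracy(p, block$chose_gamble))
    }
  }
  mean(accs)
}

#' Model comparison table
#'
#' Per-variant cohort metrics mirroring the task's model-selection report:
#' free-parameter count, mean per-subject pseudo-R-squared (baseline: the
#' 50% null), mean per-subject AIC, and (optionally) within- and
#' between-subject out-of-sample accuracy. The minimum-AIC variant is
#' flagged as the winner. Null-model accuracies are in-sample by
#' construction.
#'
#' @param dataset A `cohort_dataset`.
#' @param variants Variant names (default all seven).
#' @param options [fit_options()].
#' @param seed Integer seed.
#' @param cv Which cross-validated accuracies to compute: subset of
#'   `c("within", "between")`; default none (AIC/R2 only).
#' @param cv_repeats Repeats for the CV accuracies (default 10; the full
#'   procedure uses 100).
#' @param fits Optional precomputed [fit_cohort()] table covering
#'   `variants`.
#' @return Tibble with one row per variant: `variant`, `k`, `pseudo_r2`,
#'   `aic`, `acc_within`, `acc_between`, `n_subjects`, `winner`.
#' @export
comparison_table <- function(dataset,
                             variants = c("null1", "null2", "M1", "M2",
                                          "M3", "M4", "M5"),
                             options = fit_options(), seed = 1L,
                             cv = character(0), cv_repeats = 10,
                             fits = NULL) {
  choices <- dataset$choices
  constants <- dataset$constants
  ids <- unique(choices$agent_id)
  if (is.null(fits)) {
    fits <- fit_cohort(dataset, variants, options, seed = derive_seed(seed, 1))
  }
  null1_ll <- vapply(ids, function(id) {
    log_likelihood(choices[choices$agent_id == id, ], variant = "null1")
  }, numeric(1))
  names(null1_ll) <- ids

  rows <- lapply(variants, function(vn) {
    v <- as_variant(vn)
    fv <- fits[fits$variant == v$name, , drop = FALSE]
    fv <- fv[match(ids, fv$agent_id), , drop = FALSE]
    r2 <- mean(pseudo_r2(fv$loglik, null1_ll[ids]))
    maic <- mean(aic(v$k, fv$loglik))
    acc_w <- NA_real_
    acc_b <- NA_real_
    if (v$name %in% c("null1", "null2")) {
      # in-sample accuracy (the null models have nothing to fit)
      acc_w <- mean(vapply(ids, function(id) {
        sub <- choices[choices$agent_id == id, ]
        y <- sub$chose_gamble[!is.na(sub$chose_gamble)]
        p <- if (v$name == "null1") rep(0.5, length(y)) else rep(mean(y), length(y))
        accuracy(p, y)
      }, numeric(1)))
    } else {
      if ("within" %in% cv) {
        acc_w <- mean(vapply(seq_along(ids), function(i) {
          within_subject_cv(choices[choices$agent_id == ids[i], ], v,
                            constants, options, n_repeats = cv_repeats,
                            seed = derive_seed(seed, 10000 + i))
        }, numeric(1)))
      }
      if ("between" %in% cv) {
        acc_b <- between_subject_cv(dataset, v, options,
                                    n_groups = min(9, length(ids)),
                                    n_repeats = cv_repeats,
                                    seed = derive_seed(seed, 20000),
                                    fits = fv)
      }
    }
    tibble::tibble(variant = v$name, k = v$k, pseudo_r2 = r2, aic = maic,
                   acc_within = acc_w, acc_between = acc_b,
                   n_subjects = length(ids))
  })
  out <- dplyr::bind_rows(rows)
  out$winner <- out$aic == min(out$aic)
  out
}
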