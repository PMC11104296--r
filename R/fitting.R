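#' Fitting options
#'
#' Box bounds, start counts and optimizer tolerances for per-subject
#' maximum-likelihood estimation. Optimisation runs on log-transformed
#' parameters (all parameters are positive) under `L-BFGS-B`; besides
#' `n_starts` log-uniform random initialisations, one deterministic start
#' at the rational point (all parameters 1) is always included, which also
#' guarantees the nested-model baseline is reachable.
#'
#' @param n_starts Random multi-starts (default 10).
#' @param bounds Named list of `c(lower, upper)` per parameter. Defaults:
#'   mu `[0.001, 30]`, rho `[0.05, 3]`, lambda `[0.05, 10]`, every
#'   ambiguity weight `[0.05, 5]`. Setting `lower == upper` pins a
#'   parameter.
#' @param maxit Maximum optimizer iterations per start.
#' @param factr `L-BFGS-B` convergence factor (1e7 ~ 1e-9 relative).
#' @param eps Likelihood clipping bound.
#' @return List of options for [fit_subject()].
#' @export
fit_options <- function(n_starts = 10, bounds = NULL, maxit = 300,
                        factr = 1e7, eps = 1e-9) {
  default_bounds <- list(
    mu = c(0.001, 30), rho = c(0.05, 3), lambda = c(0.05, 10),
    alpha = c(0.05, 5), alpha_G = c(0.05, 5), alpha_L = c(0.05, 5),
    alpha_loss_ctx = c(0.05, 5), alpha_noloss_ctx = c(0.05, 5),
    alpha_RG = c(0.05, 5), alpha_SG = c(0.05, 5),
    alpha_RL = c(0.05, 5), alpha_SL = c(0.05, 5)
  )
  if (!is.null(bounds)) default_bounds[names(bounds)] <- bounds
  list(n_starts = n_starts, bounds = default_bounds, maxit = maxit,
       factr = factr, eps = eps)
}

# Negative log-likelihood and its analytic gradient on the log-parameter
# scale, as closures over precomputed trial terms. The gradient uses the
# logistic identity d ll / d q = sum (y - p) * d(mu * du)/d q; each trial
# has at most one ambiguity-weighted term, which makes the alpha gradients
# a masked sum. Chain rule for z = log(param) multiplies by the parameter.
make_objective <- function(terms, y, variant, eps) {
  par_names <- variant$par_names
  expand <- variant$expand
  t <- terms
  # log magnitudes (0 where the term is absent; those terms contribute 0)
  lg <- function(m) ifelse(m > 0, log(m), 0)
  lgg <- lg(t$g_gain_m); lgl <- lg(t$g_loss_m)
  lsg <- lg(t$s_gain_m); lsl <- lg(t$s_loss_m)
  # the single ambiguity-weighted slot of each trial (index 1 = none)
  amb_idx <- t$g_gain_a + t$g_loss_a + t$s_gain_a + t$s_loss_a - 3L
  amb_gain <- t$g_gain_a > 1L | t$s_gain_a > 1L
  amb_side <- ifelse(t$g_gain_a > 1L | t$g_loss_a > 1L, 1, -1)
  amb_c <- ifelse(t$g_gain_a > 1L, t$g_gain_c,
           ifelse(t$g_loss_a > 1L, t$g_loss_c,
           ifelse(t$s_gain_a > 1L, t$s_gain_c, t$s_loss_c)))
  amb_m <- ifelse(t$g_gain_a > 1L, t$g_gain_m,
           ifelse(t$g_loss_a > 1L, t$g_loss_m,
           ifelse(t$s_gain_a > 1L, t$s_gain_m, t$s_loss_m)))
  # which free parameter owns each condition weight (positions 2..7)
  owner_pos <- match(variant$alpha_owner, par_names)

  eval_parts <- function(free) {
    theta <- expand(free)
    a <- c(1, theta$acond)
    rho <- theta$rho; lam <- theta$lambda
    Pgg <- t$g_gain_c * a[t$g_gain_a] * t$g_gain_m^rho
    Pgl <- t$g_loss_c * a[t$g_loss_a] * t$g_loss_m^rho
    Psg <- t$s_gain_c * a[t$s_gain_a] * t$s_gain_m^rho
    Psl <- t$s_loss_c * a[t$s_loss_a] * t$s_loss_m^rho
    G <- Pgg - Psg
    L <- Pgl - Psl
    du <- G - lam * L
    p <- stats::plogis(theta$mu * du)
    list(theta = theta, Pgg = Pgg, Pgl = Pgl, Psg = Psg, Psl = Psl,
         G = G, L = L, du = du, p = p)
  }

  fn <- function(z) {
    free <- exp(z)
    names(free) <- par_names
    e <- eval_parts(free)
    nll <- -ll_bernoulli(e$p, y, eps)
    if (!is.finite(nll)) nll <- .Machine$double.xmax / 2
    nll
  }

  gr <- function(z) {
    free <- exp(z)
    names(free) <- par_names
    e <- eval_parts(free)
    mu <- e$theta$mu; rho <- e$theta$rho; lam <- e$theta$lambda
    r <- y - e$p
    g <- numeric(length(par_names))
    names(g) <- par_names
    g[["mu"]] <- sum(r * e$du)
    dG <- e$Pgg * lgg - e$Psg * lsg
    dL <- e$Pgl * lgl - e$Psl * lsl
    g[["rho"]] <- mu * sum(r * (dG - lam * dL))
    g[["lambda"]] <- -mu * sum(r * e$L)
    if (any(!is.na(owner_pos))) {
      base_term <- amb_c * amb_m^rho
      ddu <- amb_side * ifelse(amb_gain, base_term, -lam * base_term)
      contrib <- mu * r * ddu
      for (k in unique(owner_pos[!is.na(owner_pos)])) {
        conds <- which(owner_pos == k) + 1L   # positions in the alpha index
        g[k] <- sum(contrib[amb_idx %in% conds])
      }
    }
    out <- -g * free   # chain rule for log parameters; negative ll
    if (any(!is.finite(out))) out[!is.finite(out)] <- 0
    out
  }

  list(fn = fn, gr = gr)
}

#' Fit one subject by maximum likelihood
#'
#' Maximises the trial-wise log-likelihood of a model variant over its free
#' parameters with multi-start `L-BFGS-B` on log-scale parameters under box
#' bounds. Deterministic given `seed`. Null variants have no free
#' parameters and return their closed-form log-likelihood.
#'
#' @param choices One subject's rows (schedule columns + `chose_gamble`).
#' @param variant A [model_variant()] or name.
#' @param constants A [design_constants()].
#' @param options From [fit_options()].
#' @param seed Integer seed for the random starts.
#' @return A one-row tibble (`fit_result`): `variant`, `k`, the seven
#'   canonical parameter columns (NA where a variant does not define a
#'   slot weight - M4's context weights are reported in `alpha_loss_ctx` /
#'   `alpha_noloss_ctx`), `loglik`, `n_trials`, `n_starts`, `converged`,
#'   `best_start`.
#' @export
fit_subject <- function(choices, variant = "M5", constants,
                        options = fit_options(), seed = 1L) {
  variant <- as_variant(variant)
  y <- choices$chose_gamble
  keep <- !is.na(y)
  if (!any(keep)) stop("no non-missing trials for this subject")
  y <- y[keep]
  n <- length(y)

  vname <- variant$name
  vk <- variant$k
  out <- tibble::tibble(
    variant = vname, k = vk,
    mu = NA_real_, rho = NA_real_, lambda = NA_real_,
    alpha_RG = NA_real_, alpha_SG = NA_real_,
    alpha_RL = NA_real_, alpha_SL = NA_real_,
    alpha_loss_ctx = NA_real_, alpha_noloss_ctx = NA_real_,
    loglik = NA_real_, n_trials = n, n_starts = 0L,
    converged = TRUE, best_start = NA_integer_
  )

  if (variant$name %in% c("null1", "null2")) {
    out$loglik <- log_likelihood(choices, variant = variant,
                                 eps = options$eps)
    return(out)
  }

  terms <- trial_terms(choices[keep, , drop = FALSE], constants)
  obj <- make_objective(terms, y, variant, options$eps)
  pn <- variant$par_names
  lb <- log(vapply(options$bounds[pn], `[`, numeric(1), 1))
  ub <- log(vapply(options$bounds[pn], `[`, numeric(1), 2))

  # deterministic rational start (clamped into bounds) + random starts
  rng <- local_rng(seed)
  # byrow so that a larger n_starts extends (not reshuffles) the start list
  starts <- matrix(stats::runif(options$n_starts * length(pn)),
                   nrow = options$n_starts, byrow = TRUE)
  restore_rng(rng)
  starts <- sweep(sweep(starts, 2, ub - lb, `*`), 2, lb, `+`)
  starts <- rbind(pmin(pmax(0, lb), ub), starts)

  best <- NULL
  best_val <- Inf
  best_i <- NA_integer_
  any_ok <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], obj$fn, obj$gr, method = "L-BFGS-B",
                   lower = lb, upper = ub,
                   control = list(maxit = options$maxit,
                                  factr = options$factr)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    any_ok <- any_ok || fit$convergence == 0
    if (fit$value < best_val) {
      best_val <- fit$value
      best <- fit
      best_i <- i
    }
  }
  if (is.null(best)) {
    warning("optimizer failed on all starts for variant ", variant$name)
    out$converged <- FALSE
    return(out)
  }

  free <- exp(best$par)
  names(free) <- pn
  theta <- variant$expand(free)
  out$mu <- theta$mu; out$rho <- theta$rho; out$lambda <- theta$lambda
  if (variant$name == "M4") {
    out$alpha_loss_ctx <- free[["alpha_loss_ctx"]]
    out$alpha_noloss_ctx <- free[["alpha_noloss_ctx"]]
  } else if (variant$k > 3) {
    out$alpha_RG <- theta$acond[["c3"]]
    out$alpha_SG <- theta$acond[["c6"]]
    out$alpha_RL <- theta$acond[["c2"]]
    out$alpha_SL <- theta$acond[["c8"]]
  } else if (variant$name == "M1") {
    out$alpha_RG <- out$alpha_SG <- out$alpha_RL <- out$alpha_SL <- 1
  }
  out$loglik <- -best_val
  out$n_starts <- nrow(starts)
  out$converged <- any_ok
  out$best_start <- best_i
  out
}

# free-parameter vector of a stored fit row, in the variant's order
fit_free_params <- function(fit_row, variant) {
  variant <- as_variant(variant)
  v <- switch(variant$name,
    M1 = c(mu = fit_row$mu, rho = fit_row$rho, lambda = fit_row$lambda),
    M2 = c(mu = fit_row$mu, rho = fit_row$rho, lambda = fit_row$lambda,
           alpha = fit_row$alpha_RG),
    M3 = c(mu = fit_row$mu, rho = fit_row$rho, lambda = fit_row$lambda,
           alpha_G = fit_row$alpha_RG, alpha_L = fit_row$alpha_RL),
    M4 = c(mu = fit_row$mu, rho = fit_row$rho, lambda = fit_row$lambda,
           alpha_loss_ctx = fit_row$alpha_loss_ctx,
           alpha_noloss_ctx = fit_row$alpha_noloss_ctx),
    M5 = c(mu = fit_row$mu, rho = fit_row$rho, lambda = fit_row$lambda,
           alpha_RG = fit_row$alpha_RG, alpha_SG = fit_row$alpha_SG,
           alpha_RL = fit_row$alpha_RL, alpha_SL = fit_row$alpha_SL),
    stop("null variants have no free parameters")
  )
  v
}

#' Fit every subject under one or more model variants
#'
#' @param dataset A `cohort_dataset` from [simulate_cohort()], or a list
#'   with `choices` (including `agent_id`) and `constants`.
#' @param variants Character vector of variant names (or list of
#'   [model_variant()] objects).
#' @param options From [fit_options()].
#' @param seed Integer seed; each subject x variant gets a derived seed,
#'   so results are order-independent.
#' @param progress Print one line per subject (default `FALSE`).
#' @return Tibble of fit results, one row per subject x variant, with a
#'   leading `agent_id` column.
#' @export
fit_cohort <- function(dataset, variants = "M5", options = fit_options(),
                       seed = 1L, progress = FALSE) {
  choices <- dataset$choices
  constants <- dataset$constants
  if (inherits(variants, "model_variant")) variants <- list(variants)
  ids <- unique(choices$agent_id)
  if (length(ids) == 0) {
    return(tibble::tibble(agent_id = character(0)))
  }
  rows <- list()
  for (i in seq_along(ids)) {
    sub <- choices[choices$agent_id == ids[i], , drop = FALSE]
    for (j in seq_along(variants)) {
      v <- as_variant(variants[[j]])
      fit <- tryCatch(
        fit_subject(sub, v, constants, options,
                    seed = derive_seed(seed, i * 131 + j)),
        error = function(e) {
          warning("fit failed for ", ids[i], " / ", v$name, ": ",
                  conditionMessage(e))
          NULL
        }
      )
      if (!is.null(fit)) {
        rows[[length(rows) + 1L]] <-
          tibble::add_column(fit, agent_id = ids[i], .before = 1)
      }
    }
    if (progress) message("fitted subject ", i, "/", length(ids))
  }
  dplyr::bind_rows(rows)
}
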