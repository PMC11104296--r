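#' Construct a full parameter set for the ambiguity-augmented model
#'
#' The fullest model has seven parameters: inverse temperature `mu` (choice
#' consistency), utility curvature `rho` (risk preference; > 1 risk seeking
#' over gains), loss aversion `lambda` (> 1 means losses loom larger), and
#' four multiplicative ambiguity weights applied to the rational mean value
#' of the hidden payoff: `alpha_RG` (ambiguous risky gains, conditions 3 and
#' 5), `alpha_SG` (ambiguous sure gains, conditions 6-7), `alpha_RL`
#' (ambiguous risky loss, condition 2), `alpha_SL` (ambiguous sure loss,
#' condition 8). A value of 1 for any of `rho`, `lambda`, `alpha_*` is the
#' rational no-preference/no-aversion baseline.
#'
#' @param mu Inverse temperature, `>= 0`.
#' @param rho Utility curvature, `> 0`.
#' @param lambda Loss aversion, `> 0`.
#' @param alpha_RG,alpha_SG,alpha_RL,alpha_SL Ambiguity weights, `> 0`.
#' @return A named numeric vector of class `parameter_set`.
#' @examples
#' parameter_set(mu = 1)  # rational agent apart from noise
#' @export
parameter_set <- function(mu = 1, rho = 1, lambda = 1,
                          alpha_RG = 1, alpha_SG = 1,
                          alpha_RL = 1, alpha_SL = 1) {
  p <- c(mu = mu, rho = rho, lambda = lambda,
         alpha_RG = alpha_RG, alpha_SG = alpha_SG,
         alpha_RL = alpha_RL, alpha_SL = alpha_SL)
  if (any(!is.finite(p))) stop("parameters must be finite")
  if (p[["mu"]] < 0) stop("mu must be >= 0")
  if (any(p[-1] <= 0)) stop("rho, lambda and the alpha weights must be > 0")
  structure(p, class = "parameter_set")
}

.param_names <- c("mu", "rho", "lambda",
                  "alpha_RG", "alpha_SG", "alpha_RL", "alpha_SL")

# conditions carrying an ambiguity weight, in internal order
.acond_names <- c("c2", "c3", "c5", "c6", "c7", "c8")

# map the four slot weights onto the six ambiguous conditions
.slot_to_cond <- function(p) {
  c(c2 = p[["alpha_RL"]], c3 = p[["alpha_RG"]], c5 = p[["alpha_RG"]],
    c6 = p[["alpha_SG"]], c7 = p[["alpha_SG"]], c8 = p[["alpha_SL"]])
}

# internal canonical parameterisation: mu, rho, lambda + one ambiguity
# weight per ambiguous condition (this also represents the loss-context /
# no-loss-context tying of M4, which cuts across slots)
as_theta <- function(params) {
  if (inherits(params, "parameter_set")) {
    list(mu = params[["mu"]], rho = params[["rho"]], lambda = params[["lambda"]],
         acond = .slot_to_cond(params))
  } else if (is.list(params) && all(c("mu", "rho", "lambda", "acond") %in% names(params))) {
    stopifnot(all(.acond_names %in% names(params$acond)))
    params
  } else {
    stop("`params` must be a parameter_set or a list(mu, rho, lambda, acond)")
  }
}

#' Model variants: two null models and five nested utility models
#'
#' * `null1`: P(gamble) = 0.5 on every trial (k = 0).
#' * `null2`: P(gamble) = the subject's own overall gambling rate (k = 0).
#' * `M1`: traditional prospect theory; all ambiguity weights fixed at 1
#'   (free: mu, rho, lambda; k = 3).
#' * `M2`: one shared ambiguity weight for all six ambiguous conditions (k = 4).
#' * `M3`: separate ambiguous-gain (conditions 3, 5-7) and ambiguous-loss
#'   (conditions 2, 8) weights (k = 5).
#' * `M4`: separate weights for loss-context (conditions 2, 3, 8) and
#'   no-loss-context (conditions 5-7) trials (k = 5).
#' * `M5`: four free slot weights alpha_RG, alpha_SG, alpha_RL, alpha_SL
#'   (k = 7), the winning model.
#'
#' @param name One of `"null1"`, `"null2"`, `"M1"`...`"M5"`.
#' @return A `model_variant` object: list with `name`, `k`, `par_names`
#'   (free parameters in fitting order) and `expand()` mapping a named free
#'   vector to the internal full parameterisation.
#' @examples
#' model_variant("M5")$k  # 7
#' @export
model_variant <- function(name = c("M5", "M1", "M2", "M3", "M4", "null1", "null2")) {
  name <- match.arg(name)
  base <- c("mu", "rho", "lambda")
  # owner: which free parameter supplies each condition's ambiguity weight
  # (conditions in .acond_names order: c2, c3, c5, c6, c7, c8)
  spec <- switch(name,
    null1 = list(par = character(0), owner = NULL),
    null2 = list(par = character(0), owner = NULL),
    M1 = list(par = base, owner = rep(NA_character_, 6)),
    M2 = list(par = c(base, "alpha"), owner = rep("alpha", 6)),
    M3 = list(par = c(base, "alpha_G", "alpha_L"),
              owner = c("alpha_L", "alpha_G", "alpha_G",
                        "alpha_G", "alpha_G", "alpha_L")),
    M4 = list(par = c(base, "alpha_loss_ctx", "alpha_noloss_ctx"),
              owner = c("alpha_loss_ctx", "alpha_loss_ctx", "alpha_noloss_ctx",
                        "alpha_noloss_ctx", "alpha_noloss_ctx", "alpha_loss_ctx")),
    M5 = list(par = c(base, "alpha_RG", "alpha_SG", "alpha_RL", "alpha_SL"),
              owner = c("alpha_RL", "alpha_RG", "alpha_RG",
                        "alpha_SG", "alpha_SG", "alpha_SL"))
  )
  expand <- if (is.null(spec$owner)) NULL else {
    local({
      owner <- spec$owner
      function(free) {
        acond <- ifelse(is.na(owner), 1, free[owner])
        names(acond) <- .acond_names
        list(mu = free[["mu"]], rho = free[["rho"]], lambda = free[["lambda"]],
             acond = acond)
      }
    })
  }
  structure(list(name = name, k = length(spec$par),
                 par_names = spec$par, alpha_owner = spec$owner,
                 expand = expand),
            class = "model_variant")
}

as_variant <- function(variant) {
  if (inherits(variant, "model_variant")) variant else model_variant(variant)
}

# Precompute the per-trial utility decomposition so likelihood evaluations
# inside the optimiser are a handful of vectorised operations:
#   u = cg * a[ia_g] * mg^rho  -  lambda * cl * a[ia_l] * ml^rho
# with `a = c(1, acond)` and indices picking the condition's ambiguity
# weight only for the slot displayed as "$?". Loss magnitudes are stored
# positive so mg^rho is real for non-integer rho.
trial_terms <- function(trials, constants) {
  cond <- as.integer(trials$condition)
  if (any(cond < 1 | cond > 8)) stop("condition outside 1..8")
  n <- length(cond)
  am <- constants$ambiguous_mean
  z <- numeric(n); one <- rep(1L, n)
  t <- list(
    g_gain_m = z, g_gain_c = z, g_gain_a = one,
    g_loss_m = z, g_loss_c = z, g_loss_a = one,
    s_gain_m = z, s_gain_c = z, s_gain_a = one,
    s_loss_m = z, s_loss_c = z, s_loss_a = one
  )
  # alpha index: 1 = unweighted, 2..7 = conditions c2,c3,c5,c6,c7,c8
  ai <- c(c2 = 2L, c3 = 3L, c5 = 4L, c6 = 5L, c7 = 6L, c8 = 7L)
  gh <- trials$gamble_high; gl <- trials$gamble_low; sv <- trials$sure_value
  for (cc in unique(cond)) {
    i <- which(cond == cc)
    if (cc == 1) {
      t$g_gain_m[i] <- gh[i]; t$g_gain_c[i] <- 0.5
      t$g_loss_m[i] <- -gl[i]; t$g_loss_c[i] <- 0.5
    } else if (cc == 2) {
      t$g_gain_m[i] <- gh[i]; t$g_gain_c[i] <- 0.5
      t$g_loss_m[i] <- am[["c2"]]; t$g_loss_c[i] <- 0.5; t$g_loss_a[i] <- ai[["c2"]]
    } else if (cc == 3) {
      t$g_gain_m[i] <- am[["c3"]]; t$g_gain_c[i] <- 0.5; t$g_gain_a[i] <- ai[["c3"]]
      t$g_loss_m[i] <- -gl[i]; t$g_loss_c[i] <- 0.5
    } else if (cc == 4) {
      t$g_gain_m[i] <- gh[i]; t$g_gain_c[i] <- 0.5
      t$s_gain_m[i] <- sv[i]; t$s_gain_c[i] <- 1
    } else if (cc == 5) {
      t$g_gain_m[i] <- am[["c5"]]; t$g_gain_c[i] <- 0.5; t$g_gain_a[i] <- ai[["c5"]]
      t$s_gain_m[i] <- sv[i]; t$s_gain_c[i] <- 1
    } else if (cc == 6) {
      t$g_gain_m[i] <- gh[i]; t$g_gain_c[i] <- 0.5
      t$s_gain_m[i] <- am[["c6"]]; t$s_gain_c[i] <- 1; t$s_gain_a[i] <- ai[["c6"]]
    } else if (cc == 7) {
      t$g_gain_m[i] <- am[["c7"]]; t$g_gain_c[i] <- 1; t$g_gain_a[i] <- ai[["c7"]]
      t$s_gain_m[i] <- sv[i]; t$s_gain_c[i] <- 1
    } else { # 8
      t$g_loss_m[i] <- am[["c8"]]; t$g_loss_c[i] <- 1; t$g_loss_a[i] <- ai[["c8"]]
      t$s_loss_m[i] <- -sv[i]; t$s_loss_c[i] <- 1
    }
  }
  bad <- c(t$g_gain_m, t$g_loss_m, t$s_gain_m, t$s_loss_m)
  if (any(bad < 0, na.rm = TRUE)) {
    stop("negative magnitude where a positive magnitude is expected ",
         "(losses must be coded as negative dollars in the schedule)")
  }
  t$condition <- cond
  t
}

utilities_from_terms <- function(t, theta) {
  a <- unname(c(1, theta$acond))
  rho <- theta$rho; lam <- theta$lambda
  u_gamble <- t$g_gain_c * a[t$g_gain_a] * t$g_gain_m^rho -
    lam * t$g_loss_c * a[t$g_loss_a] * t$g_loss_m^rho
  u_sure <- t$s_gain_c * a[t$s_gain_a] * t$s_gain_m^rho -
    lam * t$s_loss_c * a[t$s_loss_a] * t$s_loss_m^rho
  list(u_gamble = u_gamble, u_sure = u_sure)
}

#' Subjective utilities of the gamble and sure option
#'
#' Evaluates the condition-specific utility equations. Gains enter as
#' `0.5 * gain^rho` (weight 1 for a certain payoff), losses as
#' `-lambda * magnitude^rho`, and any ambiguous payoff is replaced by its
#' rational mean value from the design constants, multiplied by the
#' condition's ambiguity weight. In condition 8 both options are losses and
#' `lambda` multiplies both sides.
#'
#' @param trials One or more schedule rows (tibble with `condition`,
#'   `gamble_high`, `gamble_low`, `sure_value`).
#' @param params A [parameter_set()].
#' @param constants A [design_constants()] matching the schedule's stakes.
#' @return A tibble with columns `u_gamble`, `u_sure`.
#' @examples
#' dc <- design_constants("high")
#' tr <- tibble::tibble(condition = 2, gamble_high = 10,
#'                      gamble_low = NA, sure_value = 0)
#' subjective_utilities(tr, parameter_set(), dc)  # u_gamble = 0.925
#' @export
subjective_utilities <- function(trials, params, constants) {
  u <- utilities_from_terms(trial_terms(trials, constants), as_theta(params))
  tibble::as_tibble(u)
}

#' Softmax probability of choosing the gamble
#'
#' Logistic choice rule `P(gamble) = 1 / (1 + exp(-mu * (u_gamble - u_sure)))`,
#' numerically stable at extreme arguments.
#'
#' @param u A list/tibble with elements `u_gamble` and `u_sure` (vectors).
#' @param mu Inverse temperature, `>= 0`.
#' @return Probability vector.
#' @examples
#' p_gamble(list(u_gamble = 1, u_sure = 0), mu = 1)  # 0.7310586
#' @export
p_gamble <- function(u, mu) {
  if (mu < 0) stop("mu must be >= 0")
  stats::plogis(mu * (u$u_gamble - u$u_sure))
}

# per-trial P(gamble) for a full schedule at an internal theta
p_from_terms <- function(t, theta) {
  u <- utilities_from_terms(t, theta)
  stats::plogis(theta$mu * (u$u_gamble - u$u_sure))
}

#' Predicted choice probabilities for a set of trials
#'
#' @inheritParams subjective_utilities
#' @return Vector of P(gamble), one per trial.
#' @export
predict_p_gamble <- function(trials, params, constants) {
  p_from_terms(trial_terms(trials, constants), as_theta(params))
}

# core Bernoulli log likelihood with probability clipping
ll_bernoulli <- function(p, y, eps) {
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(ifelse(y == 1, log(p), log1p(-p)))
}

#' Trial-wise choice log-likelihood for one subject
#'
#' Sums `log P(observed choice)` over non-missing trials. `null1` uses
#' P = 0.5 throughout; `null2` uses the subject's own in-sample gambling
#' rate on every trial. Probabilities are clipped to `[eps, 1 - eps]`
#' before logging.
#'
#' @param choices One subject's rows: schedule columns plus `chose_gamble`
#'   coded 1 (gamble/ambiguous option), 0 (sure/unambiguous option), or
#'   `NA` (missing response).
#' @param params A [parameter_set()] (ignored by the null variants).
#' @param variant A [model_variant()] or its name (default `"M5"`).
#' @param constants A [design_constants()].
#' @param eps Clipping bound for probabilities (default `1e-9`).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(choices, params = NULL, variant = "M5",
                           constants = NULL, eps = 1e-9) {
  variant <- as_variant(variant)
  y <- choices$chose_gamble
  keep <- !is.na(y)
  if (!any(keep)) stop("all trials missing; likelihood undefined")
  y <- y[keep]
  n <- length(y)
  if (variant$name == "null1") return(n * log(0.5))
  if (variant$name == "null2") {
    rate <- mean(y)
    return(ll_bernoulli(rep(rate, n), y, eps))
  }
  if (is.null(constants)) stop("`constants` required for utility models")
  t <- trial_terms(choices[keep, , drop = FALSE], constants)
  ll_bernoulli(p_from_terms(t, as_theta(params)), y, eps)
}
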