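#' Task design constants for the eight-condition gambling task
#'
#' The task contrasts eight trial types crossing risk (50/50 gamble vs sure
#' option), losses, and outcome-magnitude ambiguity (a payoff shown only as
#' "$?" or "-$?"). Two stakes levels exist: a low-stakes version (unambiguous
#' gains $.05-$1.20, losses -$.05 to -$.90) and a high-stakes version scaled
#' up by a factor of 20 (gains $1-$24, losses -$1 to -$18). Each ambiguous
#' slot has a fixed "rational" mean dollar value - the mean of the
#' unambiguous values shown in structurally matched conditions - which is
#' what the choice model multiplies by an ambiguity weight.
#'
#' @param stakes `"low"` or `"high"`.
#' @param gain_grid,loss_grid Optional numeric vectors of candidate
#'   unambiguous gain values and loss magnitudes (positive dollars).
#'   Defaults are uniform grids over the stated stakes ranges with 5-cent
#'   (low) or $1 (high) spacing.
#' @param ambiguous_mean Optional named numeric vector giving the rational
#'   mean dollar value of the ambiguous payoff for conditions
#'   `c2, c3, c5, c6, c7, c8`.
#' @param endowment Show-up payment in dollars ($4.50 low, $24 high); the
#'   payoff of one randomly drawn trial is added to it.
#'
#' @return An object of class `design_constants`: a list with elements
#'   `stakes`, `gain_grid`, `loss_grid` (loss magnitudes, positive),
#'   `ambiguous_mean` (named, conditions 2,3,5,6,7,8), `endowment`,
#'   `stakes_factor`.
#' @examples
#' dc <- design_constants("high")
#' dc$ambiguous_mean[["c2"]]  # 8.15
#' @export
design_constants <- function(stakes = c("high", "low"),
                             gain_grid = NULL,
                             loss_grid = NULL,
                             ambiguous_mean = NULL,
                             endowment = NULL) {
  stakes <- match.arg(stakes)
  if (stakes == "high") {
    if (is.null(gain_grid)) gain_grid <- seq(1, 24, by = 1)
    if (is.null(loss_grid)) loss_grid <- seq(1, 18, by = 1)
    if (is.null(ambiguous_mean)) {
      ambiguous_mean <- c(c2 = 8.15, c3 = 14.15, c5 = 15, c6 = 5, c7 = 7, c8 = 7)
    }
    if (is.null(endowment)) endowment <- 24
  } else {
    if (is.null(gain_grid)) gain_grid <- seq(0.05, 1.20, by = 0.05)
    if (is.null(loss_grid)) loss_grid <- seq(0.05, 0.90, by = 0.05)
    if (is.null(ambiguous_mean)) {
      ambiguous_mean <- c(c2 = 0.41, c3 = 0.71, c5 = 0.75, c6 = 0.28, c7 = 0.35, c8 = 0.35)
    }
    if (is.null(endowment)) endowment <- 4.50
  }
  need <- c("c2", "c3", "c5", "c6", "c7", "c8")
  if (!all(need %in% names(ambiguous_mean))) {
    stop("`ambiguous_mean` must name conditions ", paste(need, collapse = ", "))
  }
  if (any(gain_grid < 0) || any(loss_grid < 0)) {
    stop("grids are dollar magnitudes and must be non-negative")
  }
  structure(
    list(
      stakes = stakes,
      gain_grid = gain_grid,
      loss_grid = loss_grid,
      ambiguous_mean = ambiguous_mean[need],
      endowment = endowment,
      stakes_factor = 20
    ),
    class = "design_constants"
  )
}

# which payoff slot is displayed as "$?"/"-$?" in each condition
.ambiguity_slot <- c(
  "none", "risky_loss", "risky_gain", "none",
  "risky_gain", "sure_gain", "sure_gain", "sure_loss"
)

#' Near-equal allocation of trials to the eight conditions
#'
#' `floor(n/8)` trials per condition, with the remainder given to the
#' lowest-numbered conditions (333 trials -> 42 each for conditions 1-5,
#' 41 each for 6-8).
#'
#' @param n_trials Total trial count (>= 8).
#' @return Integer vector of length 8 summing to `n_trials`.
#' @export
condition_allocation <- function(n_trials) {
  if (n_trials < 8) stop("need at least one trial per condition (n_trials >= 8)")
  base <- n_trials %/% 8L
  rem <- n_trials %% 8L
  counts <- rep(base, 8L)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  as.integer(counts)
}

#' Generate a pseudo-random trial schedule
#'
#' Builds `n_trials` trials spread near-equally over the eight conditions,
#' draws unambiguous payoffs uniformly from the stakes-appropriate value
#' grids, and shuffles trial order. Ambiguous payoffs are `NA` in the
#' schedule (the display shows no value); the modelling layer substitutes
#' the rational mean from [design_constants()].
#'
#' Columns: conditions 1-3 pit a 50/50 gain/loss gamble against a sure $0;
#' conditions 4-6 pit a 50/50 gain/$0 gamble against a sure gain; conditions
#' 7-8 are a choice between two certain options, one of them ambiguous (the
#' ambiguous option plays the "gamble" role throughout).
#'
#' @param stakes `"low"` or `"high"`.
#' @param n_trials Number of trials (default 333, the task length).
#' @param seed Integer seed; schedules are reproducible given
#'   `(stakes, n_trials, seed, config)`.
#' @param config A [design_constants()] object; defaults to the stated
#'   grids for `stakes`.
#' @return A tibble with one row per trial: `trial_index`, `condition`,
#'   `gamble_high`, `gamble_low`, `gamble_prob`, `sure_value`,
#'   `ambiguity_slot`, `stakes`. Losses are negative dollars; ambiguous
#'   payoffs are `NA`.
#' @examples
#' sched <- generate_schedule("high", 333, seed = 1)
#' table(sched$condition)
#' @export
generate_schedule <- function(stakes = c("high", "low"), n_trials = 333L,
                              seed = 1L, config = NULL) {
  stakes <- match.arg(stakes)
  if (is.null(config)) config <- design_constants(stakes)
  stopifnot(inherits(config, "design_constants"))
  if (config$stakes != stakes) stop("`config` was built for the other stakes level")
  counts <- condition_allocation(n_trials)

  rng <- local_rng(seed)
  gg <- config$gain_grid
  lg <- config$loss_grid
  draw_gain <- function(k) sample(gg, k, replace = TRUE)
  draw_loss <- function(k) -sample(lg, k, replace = TRUE)

  rows <- vector("list", 8L)
  for (cond in 1:8) {
    k <- counts[cond]
    gh <- rep(NA_real_, k); gl <- rep(NA_real_, k); sv <- rep(NA_real_, k)
    gp <- if (cond <= 6) 0.5 else 1.0
    if (cond == 1) { gh <- draw_gain(k); gl <- draw_loss(k); sv <- rep(0, k) }
    if (cond == 2) { gh <- draw_gain(k); sv <- rep(0, k) }          # loss is "-$?"
    if (cond == 3) { gl <- draw_loss(k); sv <- rep(0, k) }          # gain is "$?"
    if (cond == 4) { gh <- draw_gain(k); gl <- rep(0, k); sv <- draw_gain(k) }
    if (cond == 5) { gl <- rep(0, k); sv <- draw_gain(k) }          # risky gain "$?"
    if (cond == 6) { gh <- draw_gain(k); gl <- rep(0, k) }          # sure gain "$?"
    if (cond == 7) { sv <- draw_gain(k) }                           # ambiguous vs sure gain
    if (cond == 8) { sv <- draw_loss(k) }                           # ambiguous vs sure loss
    rows[[cond]] <- tibble::tibble(
      condition = cond, gamble_high = gh, gamble_low = gl,
      gamble_prob = gp, sure_value = sv,
      ambiguity_slot = .ambiguity_slot[cond], stakes = stakes
    )
  }
  out <- dplyr::bind_rows(rows)
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  out <- tibble::add_column(out, trial_index = seq_len(nrow(out)), .before = 1)
  restore_rng(rng)
  out
}

#' Validate a trial schedule against the design invariants
#'
#' Checks condition codes, sure-$0 structure of conditions 1-3, gamble
#' probabilities (0.5 for 1-6, degenerate 1.0 for 7-8), ambiguity-slot
#' placement, and that unambiguous payoffs lie inside the configured grids.
#'
#' @param schedule A schedule tibble from [generate_schedule()].
#' @param config Matching [design_constants()].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_schedule <- function(schedule, config) {
  stopifnot(all(schedule$condition %in% 1:8))
  c13 <- schedule$condition %in% 1:3
  stopifnot(all(schedule$sure_value[c13] == 0))
  stopifnot(all(schedule$gamble_prob[schedule$condition <= 6] == 0.5))
  stopifnot(all(schedule$gamble_prob[schedule$condition >= 7] == 1.0))
  stopifnot(identical(unname(.ambiguity_slot[schedule$condition]),
                      schedule$ambiguity_slot))
  gains <- c(schedule$gamble_high[schedule$condition %in% c(1, 2, 4, 6)],
             schedule$sure_value[schedule$condition %in% c(4, 5, 7)])
  losses <- c(schedule$gamble_low[schedule$condition %in% c(1, 3)],
              schedule$sure_value[schedule$condition == 8])
  stopifnot(all(gains %in% config$gain_grid))
  stopifnot(all(-losses %in% config$loss_grid))
  invisible(TRUE)
}

#' Payment envelope implied by a design
#'
#' One trial is drawn at the end and its outcome added to the endowment;
#' the possible final payments are endowment plus the extreme grid values.
#'
#' @param config A [design_constants()] object.
#' @return Named numeric `c(min, max)` in dollars (high stakes: 6, 48).
#' @export
payment_envelope <- function(config) {
  c(min = config$endowment - max(config$loss_grid),
    max = config$endowment + max(config$gain_grid))
}
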