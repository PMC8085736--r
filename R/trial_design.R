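#' Trial-set construction for the money-versus-shocks choice task
#'
#' Each trial pits a *helpful* option (less money for the decider, fewer
#' electric shocks for the receiver) against a *harmful* option (more money,
#' more shocks). A trial is characterised by the money difference `delta_m`
#' (GBP, on a 0.05 grid) and shock difference `delta_s` (integer) between the
#' options; its *trial kappa*, `delta_m / (delta_s + delta_m)`, indexes how
#' profitable the harmful option is per extra shock. Money is handled
#' internally in integer pence to keep the 0.05-grid exact.
#'
#' @param delta_m money difference in GBP (harmful minus helpful); positive,
#'   on the 0.05 grid within `[0.05, 19.95]`
#' @param delta_s shock difference (harmful minus helpful); positive integer
#'   in `1:19`
#' @return `trial_kappa()`: the dimensionless trial kappa in (0, 1).
#' @examples
#' trial_kappa(4, 1)    # 0.8
#' trial_kappa(0.25, 1) # 0.2
#' @export
trial_kappa <- function(delta_m, delta_s) {
  if (any(delta_m <= 0) || any(delta_s <= 0)) {
    stop("invalid trial: money and shock differences must be positive")
  }
  delta_m / (delta_s + delta_m)
}

# money grid in pence
.M_GRID_P <- seq(5L, 1995L, by = 5L)
.S_GRID <- 1:19

#' Find a (shock, money) difference pair realising a target trial kappa
#'
#' Draws `n_draws` uniform pairs of positive differences (`delta_s` from
#' `1:19`, `delta_m` from the 0.05-grid of `[0.05, 19.95]`) and returns the
#' pair whose trial kappa is closest to `target_kappa` (first-drawn wins
#' ties). Uses the session RNG, so results are reproducible under
#' [set.seed()].
#'
#' @param target_kappa target trial kappa in `[0.05, 0.95]`
#' @param n_draws number of candidate pairs drawn
#' @return list with `delta_s`, `delta_m` (GBP) and the realised
#'   `trial_kappa`
#' @export
sample_pair_for_kappa <- function(target_kappa, n_draws = 10000L) {
  stopifnot(length(target_kappa) == 1L, target_kappa >= 0.05,
            target_kappa <= 0.95)
  ds <- sample(.S_GRID, n_draws, replace = TRUE)
  dm <- sample(.M_GRID_P, n_draws, replace = TRUE) / 100
  kap <- dm / (ds + dm)
  best <- which.min(abs(kap - target_kappa))
  list(delta_s = ds[best], delta_m = dm[best], trial_kappa = kap[best])
}

#' Expand a difference pair into full option amounts
#'
#' Draws the helpful option's money uniformly from the feasible 0.05-grid
#' (constraint `0.10 <= m_help + delta_m <= 20.00`, `m_help >= 0.05`) and its
#' shocks uniformly from the feasible integers (`2 <= s_help + delta_s <= 20`,
#' `s_help >= 1`); the harmful option follows by adding the differences.
#'
#' @inheritParams trial_kappa
#' @return one-row data frame with columns `m_help`, `s_help`, `m_harm`,
#'   `s_harm`, `delta_m`, `delta_s`, `trial_kappa`
#' @export
expand_to_options <- function(delta_s, delta_m) {
  dm_p <- as.integer(round(delta_m * 100))
  if (!(dm_p %in% .M_GRID_P) || !(delta_s %in% .S_GRID)) {
    stop("invalid trial: differences outside the designed grid")
  }
  m_lo <- max(5L, 10L - dm_p)
  m_hi <- 2000L - dm_p
  s_lo <- max(1L, 2L - delta_s)
  s_hi <- 20L - delta_s
  if (m_hi < m_lo || s_hi < s_lo) stop("invalid trial: infeasible constraints")
  m_grid <- seq(m_lo, m_hi, by = 5L)
  m_help_p <- if (length(m_grid) == 1L) m_grid else sample(m_grid, 1L)
  s_help <- if (s_lo == s_hi) s_lo else sample(seq(s_lo, s_hi), 1L)
  data.frame(
    m_help = m_help_p / 100,
    s_help = s_help,
    m_harm = (m_help_p + dm_p) / 100,
    s_harm = s_help + delta_s,
    delta_m = dm_p / 100,
    delta_s = delta_s,
    trial_kappa = trial_kappa(dm_p / 100, delta_s)
  )
}

.realise_targets <- function(targets, role, peer_tag, n_draws = 10000L) {
  rows <- lapply(targets, function(k) {
    pair <- sample_pair_for_kappa(k, n_draws)
    expand_to_options(pair$delta_s, pair$delta_m)
  })
  out <- do.call(rbind, rows)
  out <- cbind(
    data.frame(trial_id = seq_along(targets), role = role,
               peer_tag = peer_tag),
    out
  )
  out$target_kappa <- targets
  out
}

#' Generate a decision-stage trial set with evenly spaced trial kappas
#'
#' Targets are spaced linearly (inclusive) over `[kappa_lo, kappa_hi]` and
#' each is realised by [sample_pair_for_kappa()] plus [expand_to_options()].
#'
#' @param n number of trials (>= 2); 20 for the short form of the task, 48
#'   for the full form
#' @param kappa_lo,kappa_hi target range (defaults 0.05 and 0.95)
#' @param n_draws candidate draws per target
#' @return data frame of trials with a `target_kappa` column
#' @export
generate_decision_trials <- function(n, kappa_lo = 0.05, kappa_hi = 0.95,
                                     n_draws = 10000L) {
  if (!is.numeric(n) || n < 2) stop("config error: need at least 2 trials")
  targets <- seq(kappa_lo, kappa_hi, length.out = n)
  .realise_targets(targets, role = "decision", peer_tag = "none", n_draws)
}

#' Generate the paired prediction-stage trial sets
#'
#' The prosocial set has 50 trials: the first fixed at target kappa 0.5, then
#' (in randomized order) 41 targets drawn uniformly on `[0.05, 0.95]` and 8
#' *diagnostic* targets drawn from Normal(0.8, 0.1) — near the prosocial
#' peer's indifference point — clipped to `[0.05, 0.95]`. The antisocial set
#' mirrors it: each target (after the first) is one minus the prosocial
#' target, placing the diagnostic mass near 0.2.
#'
#' @param n_draws candidate draws per target
#' @return list with data frames `prosocial` and `antisocial`; both carry a
#'   logical `diagnostic` column marking the normal-component trials
#' @export
generate_prediction_trials <- function(n_draws = 10000L) {
  uni <- runif(41, 0.05, 0.95)
  diag_k <- clamp(rnorm(8, mean = 0.8, sd = 0.1), 0.05, 0.95)
  ord <- sample.int(49)
  body <- c(uni, diag_k)[ord]
  is_diag <- c(rep(FALSE, 41), rep(TRUE, 8))[ord]
  pro_targets <- c(0.5, body)
  anti_targets <- c(0.5, 1 - body)
  pro <- .realise_targets(pro_targets, "prediction", "prosocial", n_draws)
  anti <- .realise_targets(anti_targets, "prediction", "antisocial", n_draws)
  pro$diagnostic <- c(FALSE, is_diag)
  anti$diagnostic <- c(FALSE, is_diag)
  list(prosocial = pro, antisocial = anti)
}

#' Validate trial invariants
#'
#' Checks the additive structure of the options, grid membership, bounds and
#' the trial-kappa identity for every row.
#'
#' @param trials a trial data frame
#' @return invisibly `TRUE`; stops with a message on the first violation
#' @export
validate_trials <- function(trials) {
  with(trials, {
    stopifnot(
      all(abs(m_harm - (m_help + delta_m)) < 1e-9),
      all(s_harm == s_help + delta_s),
      all(m_help >= 0.05), all(m_harm >= 0.10), all(m_harm <= 20),
      all(s_help >= 1), all(s_harm >= 2), all(s_harm <= 20),
      all(delta_s == round(delta_s)), all(delta_s >= 1), all(delta_s <= 19),
      all(delta_m >= 0.05), all(delta_m <= 19.95),
      all(abs(delta_m * 100 - round(delta_m * 100 / 5) * 5) < 1e-6),
      all(abs(trial_kappa - delta_m / (delta_s + delta_m)) < 1e-9)
    )
  })
  invisible(TRUE)
}
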