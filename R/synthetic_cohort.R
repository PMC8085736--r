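#' Configuration of a synthetic two-group cohort
#'
#' Describes a complete simulated experiment with known ground truth: two
#' groups of participants (assigned to observe a prosocial or antisocial
#' peer), each making `trials_per_stage` money-versus-shocks choices before
#' and after the prediction stage. Baseline preferences are drawn from a
#' truncated Beta so that everyone passes the baseline-preference exclusion
#' by construction, and each participant's baseline diffusion weights are
#' anchored to their harm aversion through the indifference identity
#' `-w_pain / w_money = kappa / (1 - kappa)` (the utility model and the
#' diffusion model then share an indifference point). Stage deltas are a
#' group-level mean effect plus a similarity-scaled component plus noise,
#' emulating the finding that peer influence on the goal-consistent
#' attribute weight and on the starting point scales with baseline
#' similarity to the peer. Perceived shift is generated asymmetrically:
#' informative about the realised pain-weight change in the prosocial group,
#' pure noise in the antisocial group.
#'
#' @param n_per_group participants per group
#' @param trials_per_stage decision trials per stage
#' @param weight_scale_mean,weight_scale_sd overall drift-weight magnitude
#'   `c` (so `w_money = c (1 - kappa)`, `w_pain = -c kappa`)
#' @param a_mean,a_sd,z_mean,z_sd,t0_mean,t0_sd baseline threshold, start
#'   point and non-decision time distributions
#' @param d_w_pain_mean_pro prosocial-group mean stage delta of the pain
#'   weight (negative = pain weighs more after observation)
#' @param d_w_money_mean_anti antisocial-group mean stage delta of the money
#'   weight
#' @param d_a_mean stage delta of the threshold (both groups; negative:
#'   faster post-stage decisions)
#' @param d_z_mean_pro,d_z_mean_anti stage deltas of the starting point
#' @param sim_slope_d_w_pain_pro,sim_slope_d_w_money_anti,sim_slope_d_z_pro,sim_slope_d_z_anti
#'   similarity slopes of the deltas (applied to similarity centred at 0.7)
#' @param delta_w_sd,delta_z_sd,delta_a_sd participant-level noise sds of
#'   the deltas
#' @param accuracy_mean mean terminal prediction accuracy
#' @param dt Euler step used when simulating choices and RTs
#' @return list of class `cohort_config`
#' @export
cohort_config <- function(n_per_group = 34, trials_per_stage = 48,
                          weight_scale_mean = 1.5, weight_scale_sd = 0.2,
                          a_mean = 1.6, a_sd = 0.15,
                          z_mean = 0.5, z_sd = 0.04,
                          t0_mean = 0.35, t0_sd = 0.05,
                          d_w_pain_mean_pro = -0.2,
                          d_w_money_mean_anti = 0.2,
                          d_a_mean = -0.15,
                          d_z_mean_pro = -0.03, d_z_mean_anti = 0.05,
                          sim_slope_d_w_pain_pro = -0.06,
                          sim_slope_d_w_money_anti = 0.06,
                          sim_slope_d_z_pro = -0.15,
                          sim_slope_d_z_anti = 0.15,
                          delta_w_sd = 0.012, delta_z_sd = 0.02,
                          delta_a_sd = 0.05,
                          accuracy_mean = 0.87, dt = 1e-3) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_per_group >= 1, cfg$trials_per_stage >= 2,
            cfg$accuracy_mean > 0, cfg$accuracy_mean <= 1,
            cfg$a_mean > 0, cfg$z_mean > 0, cfg$z_mean < 1,
            cfg$t0_mean > 0, cfg$dt > 0)
  class(cfg) <- "cohort_config"
  cfg
}

# baseline harm aversion: Beta(4, 4) truncated to [0.2, 0.8]
.draw_baseline_kappa <- function(n) {
  out <- numeric(0)
  while (length(out) < n) {
    k <- rbeta(2 * n, 4, 4)
    out <- c(out, k[k >= 0.2 & k <= 0.8])
  }
  out[seq_len(n)]
}

.rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mean, sd)
    out <- c(out, x[x > lo & x < hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic two-group cohort with known ground truth
#'
#' Draws per-participant true parameters per the configuration, simulates
#' both decision stages through the diffusion process, and returns
#' everything the downstream pipeline needs. Fully reproducible under
#' [set.seed()].
#'
#' @param config a [cohort_config()]
#' @return list with `trials` (the decision trial set, shared by all
#'   participants and stages), `choices` (long format: `participant`,
#'   `group`, `stage`, `trial_id`, `delta_m`, `delta_s`, `choice`, `rt`,
#'   `censored`), and `participants` (true parameters, similarity, terminal
#'   prediction accuracy, perceived shift)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  trials <- generate_decision_trials(config$trials_per_stage)
  n <- 2 * config$n_per_group
  group <- rep(c("prosocial", "antisocial"), each = config$n_per_group)
  kappa <- .draw_baseline_kappa(n)
  sim <- objective_similarity(kappa, group)
  cs <- sim - 0.7  # centred similarity entering the delta structure

  wsc <- .rtrunc_norm(n, config$weight_scale_mean, config$weight_scale_sd,
                      lo = 0.3)
  pro <- group == "prosocial"
  d_w_pain <- ifelse(pro,
                     config$d_w_pain_mean_pro +
                       config$sim_slope_d_w_pain_pro * cs, 0) +
    rnorm(n, 0, config$delta_w_sd)
  d_w_money <- ifelse(pro, 0,
                      config$d_w_money_mean_anti +
                        config$sim_slope_d_w_money_anti * cs) +
    rnorm(n, 0, config$delta_w_sd)
  d_z <- ifelse(pro,
                config$d_z_mean_pro + config$sim_slope_d_z_pro * cs,
                config$d_z_mean_anti + config$sim_slope_d_z_anti * cs) +
    rnorm(n, 0, config$delta_z_sd)
  d_a <- rnorm(n, config$d_a_mean, config$delta_a_sd)

  participants <- data.frame(
    participant = sprintf("p%02d", seq_len(n)),
    group = group,
    kappa_baseline = kappa,
    similarity = sim,
    v0 = 0,
    w_money = wsc * (1 - kappa),
    w_pain = -wsc * kappa,
    d_w_money = d_w_money,
    d_w_pain = d_w_pain,
    a = .rtrunc_norm(n, config$a_mean, config$a_sd, lo = 0.6),
    d_a = d_a,
    z = .rtrunc_norm(n, config$z_mean, config$z_sd, lo = 0.2, hi = 0.8),
    d_z = d_z,
    t0 = .rtrunc_norm(n, config$t0_mean, config$t0_sd, lo = 0.15)
  )
  # clamp delta ranges so validity constraints hold with margin
  participants$d_a <- pmax(participants$d_a, 0.3 - participants$a)
  participants$d_z <- clamp(participants$d_z,
                            0.05 - participants$z,
                            0.95 - participants$z)

  chunks <- vector("list", 2 * n)
  for (i in seq_len(n)) {
    p <- participants[i, ]
    par <- ddm_params(v0 = p$v0, w_money = p$w_money, w_pain = p$w_pain,
                      d_w_money = p$d_w_money, d_w_pain = p$d_w_pain,
                      a = p$a, d_a = p$d_a, z = p$z, d_z = p$d_z,
                      t0 = p$t0)
    for (stg in 0:1) {
      sim_d <- simulate_ddm_trials(par, trials, stage = stg,
                                   dt = config$dt)
      chunks[[2 * (i - 1) + stg + 1]] <- data.frame(
        participant = p$participant, group = p$group, stage = stg,
        trial_id = sim_d$trial_id, delta_m = trials$delta_m,
        delta_s = trials$delta_s, choice = sim_d$choice, rt = sim_d$rt,
        censored = sim_d$censored)
    }
  }
  choices <- do.call(rbind, chunks)
  rownames(choices) <- NULL

  # terminal prediction accuracy over the final 10 prediction trials
  participants$accuracy <- rbinom(n, 10, config$accuracy_mean) / 10

  # perceived shift: tracks the realised pain-weight change for the
  # prosocial group only; uninformative noise for the antisocial group
  ps <- ifelse(pro, 1.5 * abs(participants$d_w_pain) + rnorm(n, 0, 0.05),
               rnorm(n, 0.3, 0.1))
  participants$perceived_shift <- clamp(ps, 0, 1)

  list(trials = trials, choices = choices, participants = participants)
}

#' Generate the prediction stage: peer choices and terminal accuracies
#'
#' Builds the mirrored prediction trial sets, simulates each peer's choices
#' through the softmax rule, and attaches each participant's terminal
#' prediction accuracy (the covariate used downstream; the learning
#' trajectory itself is not modelled).
#'
#' @param config a [cohort_config()]
#' @param participants optional participants table from [generate_cohort()];
#'   when supplied, accuracies are taken from it instead of redrawn
#' @return list with `trials` (list of the two 50-trial sets),
#'   `peer_choices` (per peer), and `accuracy` (per participant)
#' @export
generate_prediction_stage <- function(config = cohort_config(),
                                      participants = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  sets <- generate_prediction_trials()
  peer_choices <- list(
    prosocial = simulate_peer(sets$prosocial, peer_profile("prosocial")),
    antisocial = simulate_peer(sets$antisocial, peer_profile("antisocial"))
  )
  accuracy <- if (!is.null(participants)) {
    participants[, c("participant", "group", "accuracy")]
  } else {
    n <- 2 * config$n_per_group
    data.frame(
      participant = sprintf("p%02d", seq_len(n)),
      group = rep(c("prosocial", "antisocial"), each = config$n_per_group),
      accuracy = rbinom(n, 10, config$accuracy_mean) / 10)
  }
  list(trials = sets, peer_choices = peer_choices, accuracy = accuracy)
}
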