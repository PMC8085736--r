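#' The harm-aversion utility model and softmax choice rule
#'
#' The subjective value difference of choosing the harmful over the helpful
#' option is `dV = (1 - kappa) * delta_m - kappa * delta_s`, with money in
#' GBP. The harm-aversion parameter `kappa` is the decider's indifference
#' point in trial-kappa space: `dV > 0` exactly when the trial kappa exceeds
#' the decider's kappa.
#'
#' @param delta_m money difference in GBP (vectorised)
#' @param delta_s shock difference (vectorised)
#' @param kappa harm aversion in `[0, 1]`
#' @return `value_difference()`: dV in mixed GBP/shock utility units.
#' @examples
#' value_difference(4, 1, kappa = 0.8)  # 0: indifference at 4 GBP per shock
#' @export
value_difference <- function(delta_m, delta_s, kappa) {
  stopifnot(all(kappa >= 0), all(kappa <= 1))
  (1 - kappa) * delta_m - kappa * delta_s
}

#' Probability of the harmful choice under softmax with lapse
#'
#' `P(harm) = logistic(beta * dV) * (1 - 2 * epsilon) + epsilon`, which is
#' algebraically the lapse mixture `(1 - eps) * P_true + eps * (1 - P_true)`.
#' At `epsilon = 0.5` the rule is a pure coin flip for any `dV`.
#'
#' @param dv value difference (vectorised)
#' @param beta inverse temperature, >= 0
#' @param epsilon lapse rate in `[0, 0.5]`
#' @return probability of choosing the harmful option, in
#'   `[epsilon, 1 - epsilon]`
#' @export
choice_probability <- function(dv, beta, epsilon = 0) {
  stopifnot(beta >= 0, is.finite(beta), epsilon >= 0, epsilon <= 0.5)
  p_true <- 1 / (1 + exp(-beta * dv))
  p_true * (1 - 2 * epsilon) + epsilon
}

#' Draw binary choices from harmful-choice probabilities
#'
#' Harmful is coded 1, helpful 0.
#'
#' @param p_harm probability (vectorised) of the harmful choice
#' @return integer vector of 0/1 choices
#' @export
simulate_choice <- function(p_harm) {
  stopifnot(all(p_harm >= 0), all(p_harm <= 1))
  as.integer(runif(length(p_harm)) < p_harm)
}

#' Peer profiles for the prediction stage
#'
#' The simulated prosocial peer has harm aversion 0.8, the antisocial peer
#' 0.2; both choose by a near-deterministic softmax with inverse temperature
#' 100 and no lapse, so that observers can learn their preference quickly.
#'
#' @param type `"prosocial"` or `"antisocial"`
#' @return list with `kappa`, `beta`, `epsilon`
#' @export
peer_profile <- function(type = c("prosocial", "antisocial")) {
  type <- match.arg(type)
  list(kappa = if (type == "prosocial") 0.8 else 0.2, beta = 100,
       epsilon = 0)
}

#' Simulate a peer's choices over a trial set
#'
#' @param trials trial data frame (needs `delta_m`, `delta_s`)
#' @param peer a [peer_profile()] (or any list with `kappa`, `beta`,
#'   `epsilon`)
#' @return data frame with `trial_id`, `choice` (1 = harmful)
#' @export
simulate_peer <- function(trials, peer) {
  dv <- value_difference(trials$delta_m, trials$delta_s, peer$kappa)
  p <- choice_probability(dv, peer$beta, peer$epsilon)
  data.frame(trial_id = trials$trial_id, choice = simulate_choice(p))
}
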