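# shared fixtures built in code

# a fixed 48-trial decision set reused across tests
fixture_trials <- function(seed = 101, n = 48) {
  withr::with_seed(seed, generate_decision_trials(n))
}

# simulate choices from the softmax-with-lapse rule over a trial set
simulate_utility_choices <- function(trials, kappa, beta, epsilon = 0) {
  dv <- value_difference(trials$delta_m, trials$delta_s, kappa)
  simulate_choice(choice_probability(dv, beta, epsilon))
}

# small two-stage choice table for hierarchical-fit structure tests
fixture_hddm_data <- function(seed = 202, n_subj = 5, n_trials = 20) {
  withr::with_seed(seed, {
    tr <- generate_decision_trials(n_trials)
    chunks <- lapply(seq_len(n_subj), function(i) {
      par <- ddm_params(w_money = 0.8, w_pain = -0.7, d_w_pain = -0.2,
                        a = 1.6, d_a = -0.1, z = 0.5, t0 = 0.3)
      do.call(rbind, lapply(0:1, function(stg) {
        s <- simulate_ddm_trials(par, tr, stage = stg, dt = 1e-3)
        data.frame(participant = sprintf("s%d", i), stage = stg,
                   trial_id = s$trial_id, delta_m = tr$delta_m,
                   delta_s = tr$delta_s, choice = s$choice, rt = s$rt)
      }))
    })
    filter_rts(do.call(rbind, chunks))
  })
}
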