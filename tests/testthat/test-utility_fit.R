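test_that("the MLE recovers known utility parameters", {
  trials <- rbind(fixture_trials(), fixture_trials(seed = 102))  # 96 trials
  hits <- withr::with_seed(61, vapply(1:5, function(i) {
    big <- do.call(rbind, replicate(5, trials, simplify = FALSE))  # 480
    ch <- simulate_utility_choices(big, kappa = 0.6, beta = 3,
                                   epsilon = 0.02)
    fit_utility(ch, big$delta_m, big$delta_s)$kappa
  }, numeric(1)))
  expect_true(all(hits >= 0.55 & hits <= 0.65))
})

test_that("a deterministic threshold chooser pins kappa to the gap", {
  trials <- fixture_trials()
  ch <- as.integer(trials$trial_kappa > 0.5)
  fit <- fit_utility(ch, trials$delta_m, trials$delta_s)
  below <- max(trials$trial_kappa[trials$trial_kappa <= 0.5])
  above <- min(trials$trial_kappa[trials$trial_kappa > 0.5])
  expect_gte(fit$kappa, below - 0.01)
  expect_lte(fit$kappa, above + 0.01)
  expect_gte(fit$pct_correct, 0.99)
})

test_that("refitting the fit's own argmax predictions cannot lose likelihood", {
  trials <- fixture_trials()
  set.seed(8)
  ch <- simulate_utility_choices(trials, 0.45, 2, 0.1)
  fit <- fit_utility(ch, trials$delta_m, trials$delta_s)
  pred <- as.integer(choice_probability(
    value_difference(trials$delta_m, trials$delta_s, fit$kappa),
    fit$beta, fit$epsilon) >= 0.5)
  refit <- fit_utility(pred, trials$delta_m, trials$delta_s)
  expect_gte(refit$loglik, fit$loglik - 1e-6)
})

test_that("all-identical choices yield a flagged boundary estimate", {
  trials <- fixture_trials()
  fit <- fit_utility(rep(0L, nrow(trials)), trials$delta_m, trials$delta_s)
  expect_true(fit$boundary)
  expect_true(is.finite(fit$loglik))
})

test_that("pseudo-R2 is McFadden against the chance model", {
  expect_equal(pseudo_r2(48 * log(0.5), 48), 0)
  expect_equal(pseudo_r2(-1e-9, 100), 1, tolerance = 1e-7)
  expect_error(pseudo_r2(-10, 0), "zero")
  trials <- fixture_trials()
  set.seed(12)
  ch <- simulate_utility_choices(trials, 0.5, 5, 0.02)
  fit <- fit_utility(ch, trials$delta_m, trials$delta_s)
  expect_gt(fit$pseudo_r2, 0.3)
  expect_lt(fit$pseudo_r2, 1)
})

test_that("exclusion rules drop peers-exceeded baselines per mode", {
  expect_false(apply_exclusions(0.15, "antisocial", "paper")$keep)
  expect_true(apply_exclusions(0.15, "prosocial", "paper")$keep)
  expect_false(apply_exclusions(0.85, "prosocial", "paper")$keep)
  expect_true(apply_exclusions(0.85, "antisocial", "paper")$keep)
  expect_false(apply_exclusions(0.85, "prosocial", "symmetric")$keep)
  expect_false(apply_exclusions(0.85, "antisocial", "symmetric")$keep)
  expect_error(apply_exclusions(0.5, "neutral"), "group")
  # both modes agree on the interior
  kap <- seq(0.21, 0.79, by = 0.02)
  for (g in c("prosocial", "antisocial")) {
    expect_identical(apply_exclusions(kap, g, "paper")$keep,
                     apply_exclusions(kap, g, "symmetric")$keep)
    expect_true(all(apply_exclusions(kap, g, "paper")$keep))
  }
})

test_that("objective similarity is reversed distance to the peer", {
  expect_equal(objective_similarity(0.8, "prosocial"), 1)
  expect_equal(objective_similarity(0.2, "antisocial"), 1)
  expect_equal(objective_similarity(0.5, "prosocial"), 0.7)
  expect_equal(objective_similarity(0.5, "antisocial"), 0.7)
  expect_error(objective_similarity(0.5, "x"), "group")
})

test_that("exchange rate and its percent change match the worked algebra", {
  expect_equal(exchange_rate(0.8), 4)
  expect_equal(exchange_rate(0.2), 0.25)
  expect_warning(r1 <- exchange_rate(1), "infinite")
  expect_identical(r1, Inf)
  kap <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(exchange_rate(kap)) > 0))
  expect_equal(percent_change_exchange(0.37, 0.37), 0)
})

test_that("fit_utility_all returns one tidy row per participant-stage", {
  trials <- fixture_trials()
  set.seed(77)
  tab <- do.call(rbind, lapply(c("a", "b"), function(p) {
    do.call(rbind, lapply(0:1, function(s) {
      data.frame(participant = p, stage = s,
                 delta_m = trials$delta_m, delta_s = trials$delta_s,
                 choice = simulate_utility_choices(trials, 0.5, 4, 0.02))
    }))
  }))
  fits <- fit_utility_all(tab)
  expect_equal(nrow(fits), 4)
  expect_setequal(names(fits), c("participant", "stage", "kappa", "beta",
                                 "epsilon", "loglik", "pseudo_r2",
                                 "pct_correct"))
  expect_true(all(fits$kappa >= 0 & fits$kappa <= 1))
  expect_true(all(fits$loglik <= 0))
})
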