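test_that("trial kappa follows its defining ratio and rejects bad input", {
  expect_equal(trial_kappa(4, 1), 0.8)
  expect_equal(trial_kappa(1, 1), 0.5)
  expect_equal(trial_kappa(0.25, 1), 0.2)
  expect_error(trial_kappa(0, 1), "positive")
  expect_error(trial_kappa(1, -2), "positive")
  # strictly inside (0,1) and increasing in delta_m at fixed delta_s
  k <- trial_kappa(seq(0.05, 19.95, by = 0.05), 3)
  expect_true(all(k > 0 & k < 1))
  expect_true(all(diff(k) > 0))
})

test_that("pair sampling returns the closest of its own candidate stream", {
  set.seed(7)
  pick <- sample_pair_for_kappa(0.5, n_draws = 10000)
  # brute-force re-enumeration of the identical draw stream
  set.seed(7)
  ds <- sample(1:19, 10000, replace = TRUE)
  dm <- sample(seq(5L, 1995L, by = 5L), 10000, replace = TRUE) / 100
  kap <- dm / (ds + dm)
  best <- which.min(abs(kap - 0.5))
  expect_identical(pick$delta_s, ds[best])
  expect_identical(pick$delta_m, dm[best])
  expect_lte(abs(pick$trial_kappa - 0.5), min(abs(kap - 0.5)) + 1e-12)
})

test_that("pair sampling hits extreme targets within 0.01 and is reproducible", {
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    abs(sample_pair_for_kappa(0.05)$trial_kappa - 0.05)
  }, numeric(1))
  expect_true(all(hits <= 0.01))
  set.seed(99)
  a <- sample_pair_for_kappa(0.37)
  set.seed(99)
  b <- sample_pair_for_kappa(0.37)
  expect_identical(a, b)
})

test_that("option expansion respects the constraint grid", {
  set.seed(1)
  # unique feasible assignment when differences are maximal
  tr <- expand_to_options(19, 19.95)
  expect_equal(tr$m_help, 0.05)
  expect_equal(tr$s_help, 1)
  expect_equal(tr$m_harm, 20)
  expect_equal(tr$s_harm, 20)
  # minimal differences leave the full ranges available, deltas preserved
  for (i in 1:200) {
    tr <- expand_to_options(1, 0.05)
    expect_true(tr$s_help >= 1 && tr$s_help <= 19)
    expect_true(tr$m_help >= 0.05 && tr$m_help <= 19.95)
    expect_equal(tr$trial_kappa, trial_kappa(0.05, 1))
  }
  expect_error(expand_to_options(20, 0.05), "grid")
  expect_error(expand_to_options(1, 0.07), "grid")
})

test_that("every generated trial satisfies the trial invariants", {
  set.seed(5)
  ds <- sample(1:19, 2000, replace = TRUE)
  dm <- sample(seq(5L, 1995L, by = 5L), 2000, replace = TRUE) / 100
  trials <- do.call(rbind, Map(function(s, m) expand_to_options(s, m),
                               ds, dm))
  expect_true(validate_trials(trials))
})

test_that("decision sets hit evenly spaced targets within tolerance", {
  set.seed(31)
  tr20 <- generate_decision_trials(20)
  expect_equal(diff(tr20$target_kappa),
               rep(0.9 / 19, 19), tolerance = 1e-12)
  expect_true(all(abs(tr20$trial_kappa - tr20$target_kappa) <= 0.01))
  expect_equal(order(tr20$trial_kappa), seq_len(20))
  tr48 <- generate_decision_trials(48)
  expect_equal(nrow(tr48), 48)
  expect_true(validate_trials(tr48))
  expect_true(all(abs(tr48$trial_kappa - tr48$target_kappa) <= 0.01))
  expect_error(generate_decision_trials(1), "config")
})

test_that("prediction sets are mirrored with a fixed first trial", {
  set.seed(17)
  sets <- generate_prediction_trials()
  pro <- sets$prosocial
  anti <- sets$antisocial
  expect_equal(nrow(pro), 50)
  expect_equal(nrow(anti), 50)
  expect_true(validate_trials(pro))
  expect_true(validate_trials(anti))
  expect_equal(pro$target_kappa[1], 0.5)
  expect_equal(anti$target_kappa[1], 0.5)
  expect_equal(anti$target_kappa[2:50], 1 - pro$target_kappa[2:50])
  expect_equal(sum(pro$diagnostic), 8)
  expect_identical(pro$diagnostic, anti$diagnostic)
  # diagnostic targets concentrate near the prosocial peer's preference
  expect_true(all(abs(pro$target_kappa[pro$diagnostic] - 0.8) < 0.45))
  # realized mirroring within twice the matching tolerance
  expect_true(all(abs(anti$trial_kappa[2:50] -
                        (1 - pro$trial_kappa[2:50])) <= 0.02))
})

test_that("trial generation is bit-reproducible under a fixed seed", {
  set.seed(123)
  a <- generate_decision_trials(10)
  set.seed(123)
  b <- generate_decision_trials(10)
  expect_identical(a, b)
  set.seed(123)
  p1 <- generate_prediction_trials()
  set.seed(123)
  p2 <- generate_prediction_trials()
  expect_identical(p1, p2)
})
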