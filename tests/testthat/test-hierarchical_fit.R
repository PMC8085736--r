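test_that("the model space encodes the six stage-modulation variants", {
  m1 <- ddm_model_spec("M1")
  m4 <- ddm_model_spec("M4")
  m5 <- ddm_model_spec("M5")
  m6 <- ddm_model_spec("M6")
  expect_false(m1$drift_money_stage || m1$drift_pain_stage || m1$bias_stage)
  expect_true(m4$drift_money_stage && m4$drift_pain_stage)
  expect_false(m4$bias_stage)
  expect_true(m5$drift_money_stage && m5$drift_pain_stage && m5$bias_stage)
  expect_true(m6$bias_stage)
  expect_false(m6$drift_money_stage || m6$drift_pain_stage)
  for (id in paste0("M", 1:6)) {
    expect_true(ddm_model_spec(id)$threshold_stage)
  }
})

test_that("R-hat separates mixed from disjoint chains", {
  set.seed(30)
  same <- matrix(rnorm(4000), ncol = 4)
  expect_lt(rhat(same), 1.02)
  expect_identical(rhat(cbind(1:100, 1:100)), 1)  # identical chains
  apart <- cbind(rnorm(500, 0, 0.1), rnorm(500, 10, 0.1))
  expect_gt(rhat(apart), 10)
  expect_true(is.na(rhat(rnorm(100))))  # single chain undefined
})

test_that("directional probability reads posterior mass on one side", {
  expect_equal(direction_probability(c(-3, -1, -0.2), "negative"), 1)
  expect_equal(direction_probability(c(3, 1, 0.2), "positive"), 1)
  set.seed(33)
  sym <- rnorm(1e5)
  expect_equal(direction_probability(sym, "negative"), 0.5,
               tolerance = 0.01)
})

test_that("a small hierarchical fit returns a coherent posterior object", {
  dat <- fixture_hddm_data()
  fit <- fit_hddm(dat, ddm_model_spec("M3"), chains = 2, iter = 500,
                  warmup = 250, seed = 3)
  expect_s3_class(fit, "hddm_fit")
  s <- fit$summary
  expect_true(all(s$q2.5 <= s$q50 & s$q50 <= s$q97.5))
  expect_true(all(s$rhat >= 1 | is.na(s$rhat)))
  expect_true(is.finite(fit$dic))
  expect_gt(fit$p_d, 0)
  # DIC identity: dic = d_bar + p_d and p_d = d_bar - d_hat
  expect_equal(fit$dic, 2 * fit$d_bar - fit$d_hat)
  pm <- participant_means(fit)
  expect_equal(nrow(pm), 5)
  expect_true(all(c("w_money", "w_pain", "d_w_pain", "a", "d_a", "z",
                    "t0") %in% names(pm)))
  expect_false("d_z" %in% names(pm))  # inactive under M3
  expect_error(group_draws(fit, "mu_nonexistent"), "unknown parameter")
  expect_length(group_draws(fit, "mu_w_pain"), 2 * 250)
})

test_that("deviance is exchangeable under participant relabeling", {
  dat <- fixture_hddm_data(n_subj = 4, n_trials = 12)
  ids <- sort(unique(dat$participant))
  subj <- match(dat$participant, ids) - 1L
  set.seed(40)
  theta <- cbind(rnorm(4, 0, 0.1), 0.8, -0.7, 0, -0.2,
                 1.6, -0.1, 0.5, 0, 0.25)
  dev <- peerddm:::.hddm_deviance_cpp(dat$rt, as.integer(dat$choice),
                                      dat$delta_m, dat$delta_s,
                                      as.integer(dat$stage), subj, 4L,
                                      theta)
  perm <- c(3L, 1L, 4L, 2L)
  dev_p <- peerddm:::.hddm_deviance_cpp(dat$rt, as.integer(dat$choice),
                                        dat$delta_m, dat$delta_s,
                                        as.integer(dat$stage),
                                        perm[subj + 1L] - 1L, 4L,
                                        theta[order(perm), , drop = FALSE])
  expect_equal(dev, dev_p, tolerance = 1e-10)
})

test_that("model comparison ranks by DIC and reports decisive gaps", {
  dat <- fixture_hddm_data()
  cmp <- compare_models(dat, specs = list("M1", "M3"), chains = 2,
                        iter = 500, warmup = 250, seed = 6)
  expect_setequal(cmp$table$model, c("M1", "M3"))
  expect_equal(cmp$table$delta_dic[1], 0)
  expect_true(all(diff(cmp$table$dic) >= 0))
  expect_true(is.na(cmp$preferred) || cmp$preferred %in% c("M1", "M3"))
})

test_that("posterior predictive checks cover the fitted data", {
  dat <- fixture_hddm_data()
  fit <- fit_hddm(dat, ddm_model_spec("M3"), chains = 2, iter = 500,
                  warmup = 250, seed = 3)
  set.seed(50)
  ppc <- posterior_predictive_check(fit, dat, n_sims = 20, n_bins = 3)
  expect_true(all(ppc$sim_lo <= ppc$sim_hi, na.rm = TRUE))
  props <- ppc[ppc$statistic == "p_harm" & !ppc$empty, ]
  expect_true(all(props$observed >= 0 & props$observed <= 1))
  # RT quantiles monotone within each cell
  for (cl in unique(ppc$cell)) {
    q <- ppc[ppc$cell == cl & grepl("rt_q", ppc$statistic), "observed"]
    if (all(is.finite(q))) expect_true(all(diff(q) >= 0))
  }
  # model fitted to these data should reproduce most cells
  expect_gt(mean(ppc$inside[!ppc$empty]), 0.7)
})
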