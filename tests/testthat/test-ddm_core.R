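test_that("trial-level drift combines weights, attributes and stage", {
  p <- ddm_params(v0 = 0.3, w_money = 0.5, w_pain = -0.4, d_w_money = 0.1,
                  d_w_pain = -0.2, a = 1.5, z = 0.5, t0 = 0.3)
  expect_equal(drift_for_trial(ddm_params(v0 = 1.2), 3, 7, 0), 1.2)
  expect_equal(drift_for_trial(p, 2, 3, 0), 0.3 + 0.5 * 2 - 0.4 * 3)
  expect_equal(drift_for_trial(p, 2, 3, 1),
               0.3 + 0.6 * 2 - 0.6 * 3)
  # a negative pain-weight delta lowers post-stage drift when shocks loom
  expect_lt(drift_for_trial(p, 2, 3, 1), drift_for_trial(p, 2, 3, 0))
  # drift increases in delta_m iff the effective money weight is positive
  dm <- seq(0.5, 10, by = 0.5)
  expect_true(all(diff(drift_for_trial(p, dm, 3, 0)) > 0))
  p_neg <- ddm_params(w_money = -0.2, a = 1, z = 0.5, t0 = 0.2)
  expect_true(all(diff(drift_for_trial(p_neg, dm, 3, 0)) < 0))
})

test_that("the first-passage density is symmetric and properly normalised", {
  # zero drift, central start: both boundaries equally likely at all times
  rt <- seq(0.35, 6, by = 0.05)
  expect_equal(dwiener(rt, 1, v = 0, a = 1.4, z = 0.5, t0 = 0.3),
               dwiener(rt, 0, v = 0, a = 1.4, z = 0.5, t0 = 0.3),
               tolerance = 1e-12)
  # integrates to one over both boundaries, and the upper mass matches the
  # closed-form absorption probability
  for (par in list(c(0.9, 1.5, 0.45, 0.3), c(-1.8, 1.1, 0.6, 0.2),
                   c(0, 2, 0.35, 0.4))) {
    up <- integrate(function(t) dwiener(t, 1, par[1], par[2], par[3],
                                        par[4]),
                    par[4], Inf, rel.tol = 1e-9)$value
    lo <- integrate(function(t) dwiener(t, 0, par[1], par[2], par[3],
                                        par[4]),
                    par[4], Inf, rel.tol = 1e-9)$value
    expect_equal(up + lo, 1, tolerance = 1e-4)
    expect_equal(up, wiener_p_upper(par[1], par[2], par[3]),
                 tolerance = 1e-4)
  }
  # rt at or below t0 has zero density, not an error
  expect_equal(dwiener(c(0.1, 0.3), 1, 1, 1.5, 0.5, 0.3), c(0, 0))
})

test_that("the density is continuous across the series switch", {
  # scan a fine rt grid around the expansion switch: any jump larger than
  # 1e-6 would dominate the second difference at this resolution, since the
  # smooth curvature term is of order f'' * h^2 ~ 1e-8
  rt <- seq(0.32, 5, by = 1e-5)
  for (ch in 0:1) {
    d <- dwiener(rt, ch, v = 0.8, a = 1.8, z = 0.45, t0 = 0.3)
    expect_true(all(is.finite(d)))
    expect_lt(max(abs(diff(d, differences = 2))), 1e-6)
  }
})

test_that("Euler simulation matches the analytic absorption probability", {
  set.seed(20)
  for (par in list(c(0.8, 1.5, 0.45), c(-1.2, 1.2, 0.6))) {
    s <- rwiener(2e4, par[1], par[2], par[3], t0 = 0.25, dt = 1e-3,
                 seed = 1234)
    p <- wiener_p_upper(par[1], par[2], par[3])
    se <- sqrt(p * (1 - p) / 2e4)
    # 3 MC s.e. plus a small allowance for the Euler discretisation bias
    expect_lt(abs(mean(s$choice) - p), 3 * se + 0.012)
    expect_true(all(s$rt > 0.25))
  }
})

test_that("limiting cases force the expected boundary", {
  set.seed(21)
  s <- rwiener(500, v = 1, a = 1.5, z = 0.99, t0 = 0.3, dt = 1e-4)
  expect_gt(mean(s$choice), 0.99)
  expect_lt(median(s$rt - 0.3), 0.1)  # decisions nearly instantaneous
  s2 <- rwiener(500, v = 10, a = 2, z = 0.5, t0 = 0.3, dt = 1e-4)
  expect_gt(mean(s2$choice), 0.99)
  expect_false(any(s2$censored))
})

test_that("paths exceeding the horizon are flagged censored", {
  set.seed(22)
  s <- rwiener(200, v = 0, a = 40, z = 0.5, t0 = 0.3, dt = 1e-3,
               max_t = 0.5)
  expect_true(all(s$censored))
})

test_that("the RT filter keeps the closed analysis window", {
  rec <- data.frame(rt = c(0.29, 0.3, 1, 20, 20.01), choice = 0:4 %% 2)
  out <- filter_rts(rec)
  expect_equal(out$rt, c(0.3, 1, 20))
  expect_equal(attr(out, "excluded_fraction"), 2 / 5)
  clean <- data.frame(rt = runif(100, 0.4, 3))
  expect_equal(attr(filter_rts(clean), "excluded_fraction"), 0)
})

test_that("stage deltas of zero nest the baseline-only model exactly", {
  p5 <- ddm_params(v0 = 0.1, w_money = 0.6, w_pain = -0.5, d_w_money = 0,
                   d_w_pain = 0, a = 1.5, d_a = 0, z = 0.45, d_z = 0,
                   t0 = 0.3)
  p1 <- ddm_params(v0 = 0.1, w_money = 0.6, w_pain = -0.5, a = 1.5,
                   z = 0.45, t0 = 0.3)
  dm <- c(0.5, 3, 12)
  ds <- c(2, 9, 17)
  expect_identical(drift_for_trial(p5, dm, ds, 1),
                   drift_for_trial(p1, dm, ds, 0))
})
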