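#' Stage-modulated multi-attribute drift-diffusion parameters
#'
#' The decision variable is a unit-variance diffusion between absorbing
#' boundaries 0 (helpful) and `a` (harmful), starting at relative position
#' `z`. The drift on a trial is a linear function of the money and shock
#' differences, with weights that may change between the baseline (stage 0)
#' and post-influence (stage 1) decision stages:
#' `v = v0 + (w_money + d_w_money * stage) * delta_m +
#'  (w_pain + d_w_pain * stage) * delta_s`.
#' The threshold and starting point carry their own stage deltas (`d_a`,
#' `d_z`); `d_z` acts on the raw relative scale and the effective start is
#' clamped to (0.01, 0.99). The diffusion coefficient is fixed at 1 (scaling
#' convention) and `delta_m` enters in GBP.
#'
#' @param v0 drift intercept (evidence/s)
#' @param w_money drift weight per GBP of money difference (> 0: money pushes
#'   toward harmful)
#' @param w_pain drift weight per shock of shock difference (< 0: pain pushes
#'   toward helpful)
#' @param d_w_money,d_w_pain stage deltas of the weights (post minus
#'   baseline)
#' @param a threshold separation (> 0)
#' @param d_a stage delta of the threshold (`a + d_a` must stay positive)
#' @param z relative starting point in (0, 1)
#' @param d_z stage delta of the starting point
#' @param t0 non-decision time in seconds (>= 0)
#' @return list of class `ddm_params`
#' @export
ddm_params <- function(v0 = 0, w_money = 0, w_pain = 0, d_w_money = 0,
                       d_w_pain = 0, a = 1.5, d_a = 0, z = 0.5, d_z = 0,
                       t0 = 0.3) {
  p <- list(v0 = v0, w_money = w_money, w_pain = w_pain,
            d_w_money = d_w_money, d_w_pain = d_w_pain, a = a, d_a = d_a,
            z = z, d_z = d_z, t0 = t0)
  stopifnot(a > 0, a + d_a > 0, z > 0, z < 1, z + d_z > 0, z + d_z < 1,
            t0 >= 0)
  class(p) <- "ddm_params"
  p
}

#' Trial-level drift rate
#'
#' @param params a [ddm_params()]
#' @param delta_m,delta_s trial differences (vectorised)
#' @param stage 0 (baseline) or 1 (post-influence)
#' @return drift rate(s) in evidence units per second
#' @export
drift_for_trial <- function(params, delta_m, delta_s, stage = 0) {
  stopifnot(all(stage %in% 0:1))
  params$v0 +
    (params$w_money + params$d_w_money * stage) * delta_m +
    (params$w_pain + params$d_w_pain * stage) * delta_s
}

.stage_a <- function(params, stage) params$a + params$d_a * stage
.stage_z <- function(params, stage) {
  clamp(params$z + params$d_z * stage, 0.01, 0.99)
}

#' Wiener first-passage-time density
#'
#' Density of observing response time `rt` at the given boundary (`choice`
#' 1 = upper/harmful, 0 = lower/helpful) for a unit-variance diffusion with
#' drift `v`, threshold separation `a`, relative start `z` and non-decision
#' time `t0`. Computed by the small-time/large-time series with an
#' accuracy-based switch (truncation error 1e-10). Returns 0 (not an error)
#' for `rt <= t0`.
#'
#' @param rt response time(s) in seconds
#' @param choice 0/1 boundary indicator, recycled to `length(rt)`
#' @param v,a,z,t0 diffusion parameters
#' @param log return the log density
#' @export
dwiener <- function(rt, choice, v, a, z, t0, log = FALSE) {
  stopifnot(a > 0, z > 0, z < 1, t0 >= 0)
  choice <- as.integer(rep_len(choice, length(rt)))
  .dwiener_cpp(as.numeric(rt), choice, v, a, z, t0, log)
}

#' Closed-form probability of absorbing at the harmful boundary
#'
#' `(1 - exp(-2 v a z)) / (1 - exp(-2 v a))` for nonzero drift; `z` at
#' `v = 0`.
#'
#' @inheritParams dwiener
#' @export
wiener_p_upper <- function(v, a, z) {
  stopifnot(a > 0, z > 0, z < 1)
  .wiener_p_upper_cpp(v, a, z)
}

#' Simulate diffusion trials by the Euler-Maruyama scheme
#'
#' Paths are stepped at resolution `dt` until absorption, with a
#' Brownian-bridge correction for intra-step boundary crossings (plain Euler
#' stepping under-detects absorptions by order `sqrt(dt)`); the response
#' time is the hit time plus `t0`. Paths not absorbed within `max_t` seconds of
#' simulated accumulation are flagged `censored` (choice set by the nearer
#' boundary). The simulator uses its own counter-seeded stream; `seed` is
#' drawn from the session RNG when not supplied, so [set.seed()] governs
#' reproducibility.
#'
#' @param n number of trials
#' @param v,a,z,t0 diffusion parameters
#' @param dt Euler step in seconds
#' @param max_t censoring horizon in seconds
#' @param seed optional explicit integer seed for the path stream
#' @return data frame with `choice` (1 = harmful), `rt`, `censored`
#' @export
rwiener <- function(n, v, a, z, t0, dt = 1e-4, max_t = 60, seed = NULL) {
  stopifnot(a > 0, z > 0, z < 1, t0 >= 0, dt > 0)
  if (is.null(seed)) seed <- runif(1, 0, 2^31)
  out <- .rwiener_cpp(as.integer(n), v, a, z, t0, dt, max_t, seed)
  data.frame(choice = out$choice, rt = out$rt, censored = out$censored)
}

#' Simulate one participant-stage's choices and response times
#'
#' @param params a [ddm_params()]
#' @param trials trial data frame (`delta_m`, `delta_s`)
#' @param stage 0 or 1
#' @inheritParams rwiener
#' @return data frame with `trial_id`, `choice`, `rt`, `censored`
#' @export
simulate_ddm_trials <- function(params, trials, stage = 0, dt = 1e-4,
                                max_t = 60, seed = NULL) {
  stopifnot(length(stage) == 1, stage %in% 0:1)
  if (is.null(seed)) seed <- runif(1, 0, 2^31)
  v <- drift_for_trial(params, trials$delta_m, trials$delta_s, stage)
  a <- .stage_a(params, stage)
  z <- .stage_z(params, stage)
  rows <- lapply(seq_along(v), function(i) {
    .rwiener_cpp(1L, v[i], a, z, params$t0, dt, max_t, seed + i)
  })
  data.frame(
    trial_id = if (!is.null(trials$trial_id)) trials$trial_id
               else seq_along(v),
    choice = vapply(rows, function(r) r$choice[1], integer(1)),
    rt = vapply(rows, function(r) r$rt[1], numeric(1)),
    censored = vapply(rows, function(r) r$censored[1], logical(1))
  )
}

#' Filter response times to the analysis window
#'
#' Keeps trials with `0.3 <= rt <= 20` seconds (endpoints inclusive) and
#' reports the excluded fraction as an attribute.
#'
#' @param records data frame with an `rt` column
#' @return the filtered data frame, with attribute `excluded_fraction`
#' @export
filter_rts <- function(records) {
  keep <- records$rt >= 0.3 & records$rt <= 20
  out <- records[keep, , drop = FALSE]
  attr(out, "excluded_fraction") <- 1 - mean(keep)
  out
}
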