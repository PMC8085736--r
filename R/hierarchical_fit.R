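.DDM_PAR_NAMES <- c("v0", "w_money", "w_pain", "d_w_money", "d_w_pain",
                    "a", "d_a", "z", "d_z", "t0")

#' Candidate model space for the stage-modulated diffusion model
#'
#' Six nested variants differing in which parameters carry a stage delta.
#' All six let the threshold vary by stage and weight the drift by the money
#' and shock differences; they differ in whether the stage modulates the
#' money weight, the pain weight, both, and/or the starting point:
#' \describe{
#'   \item{M1}{no drift or bias stage terms}
#'   \item{M2}{stage term on the money weight}
#'   \item{M3}{stage term on the pain weight}
#'   \item{M4}{stage terms on both drift weights}
#'   \item{M5}{both drift terms plus a stage term on the starting point}
#'   \item{M6}{stage term on the starting point only}
#' }
#'
#' @param id one of `"M1"`..`"M6"`
#' @return list of class `ddm_model_spec` with logical fields
#'   `drift_money_stage`, `drift_pain_stage`, `bias_stage`,
#'   `threshold_stage` (always `TRUE`)
#' @export
ddm_model_spec <- function(id = c("M5", "M1", "M2", "M3", "M4", "M6")) {
  id <- match.arg(id)
  flags <- switch(id,
    M1 = c(FALSE, FALSE, FALSE),
    M2 = c(TRUE, FALSE, FALSE),
    M3 = c(FALSE, TRUE, FALSE),
    M4 = c(TRUE, TRUE, FALSE),
    M5 = c(TRUE, TRUE, TRUE),
    M6 = c(FALSE, FALSE, TRUE))
  structure(list(id = id, drift_money_stage = flags[1],
                 drift_pain_stage = flags[2], bias_stage = flags[3],
                 threshold_stage = TRUE),
            class = "ddm_model_spec")
}

.spec_active <- function(spec) {
  c(TRUE, TRUE, TRUE,                 # v0, w_money, w_pain
    spec$drift_money_stage, spec$drift_pain_stage,
    TRUE, TRUE,                       # a, d_a
    TRUE, spec$bias_stage,            # z, d_z
    TRUE)                             # t0
}

#' Weakly informative priors for the hierarchical diffusion model
#'
#' Group-level means: Normal(0, 5) for the drift intercept, weights and
#' their deltas; Half-Normal(2.5) for the threshold; Normal(0.5, 0.25)
#' truncated to (0.01, 0.99) for the starting point and Normal(0, 0.5) for
#' its delta; Uniform(0.05, 1) for the non-decision time. Group standard
#' deviations: Half-Normal(`sigma_sd`).
#'
#' @param sigma_sd scale of the half-normal prior on group sds
#' @return list with `mean`, `sd`, `lower`, `upper` (length-10, canonical
#'   parameter order) and `sigma_sd`
#' @export
hddm_prior <- function(sigma_sd = 1) {
  list(
    mean = c(0, 0, 0, 0, 0, 0, 0, 0.5, 0, 0.5),
    sd = c(5, 5, 5, 5, 5, 2.5, 5, 0.25, 0.5, 1e3),
    lower = c(-Inf, -Inf, -Inf, -Inf, -Inf, 0, -Inf, 0.01, -0.98, 0.05),
    upper = c(Inf, Inf, Inf, Inf, Inf, Inf, Inf, 0.99, 0.98, 1),
    sigma_sd = sigma_sd
  )
}

.check_hddm_data <- function(data) {
  need <- c("participant", "stage", "delta_m", "delta_s", "choice", "rt")
  stopifnot(all(need %in% names(data)), all(data$choice %in% 0:1),
            all(data$stage %in% 0:1), all(data$rt > 0))
  if (length(unique(data$participant)) < 2) {
    stop("hierarchical fit requires at least 2 participants")
  }
  invisible(data)
}

#' Fit the hierarchical diffusion model by MCMC
#'
#' Participant-level parameters are modelled as draws from group-level
#' normal distributions (truncated where constrained) and sampled by
#' Metropolis-within-Gibbs: adaptive componentwise random-walk updates on
#' participant parameters against the Wiener likelihood, conjugate updates
#' of group means, log-scale random-walk updates of group sds. Baseline and
#' post-influence trials enter jointly; groups (prosocial/antisocial) are
#' fitted separately.
#'
#' @param data RT-filtered long-format data frame with columns
#'   `participant`, `stage` (0/1), `delta_m`, `delta_s`, `choice` (0/1),
#'   `rt` (s)
#' @param spec a [ddm_model_spec()]
#' @param chains number of chains
#' @param iter total iterations per chain (including warmup)
#' @param warmup adaptation iterations discarded per chain
#' @param seed integer seed; chain `c` uses `seed + c`
#' @param prior a [hddm_prior()]
#' @return object of class `hddm_fit`: pooled and per-chain group-level
#'   draws, participant-level draws, deviance trace, posterior summaries
#'   with R-hat, DIC, and a `converged` flag (all R-hat < 1.1). A
#'   non-converged fit is returned (flagged), not an error.
#' @export
fit_hddm <- function(data, spec = ddm_model_spec("M5"), chains = 4,
                     iter = 1500, warmup = 500, seed = 1,
                     prior = hddm_prior()) {
  .check_hddm_data(data)
  stopifnot(iter > warmup, chains >= 1)
  ids <- sort(unique(data$participant))
  subj <- match(data$participant, ids) - 1L
  active <- .spec_active(spec)
  act_idx <- which(active)
  n_act <- length(act_idx)
  n_subj <- length(ids)
  n_save <- iter - warmup

  runs <- lapply(seq_len(chains), function(ch) {
    .hddm_chain_cpp(as.numeric(data$rt), as.integer(data$choice),
                    as.numeric(data$delta_m), as.numeric(data$delta_s),
                    as.integer(data$stage), subj, n_subj, active,
                    as.integer(iter), as.integer(warmup),
                    as.numeric(seed) + ch,
                    prior$mean, prior$sd, prior$lower, prior$upper,
                    prior$sigma_sd)
  })

  gnames <- c(paste0("mu_", .DDM_PAR_NAMES[act_idx]),
              paste0("sigma_", .DDM_PAR_NAMES[act_idx]))
  group <- array(NA_real_, dim = c(n_save, chains, length(gnames)),
                 dimnames = list(NULL, NULL, gnames))
  subj_draws <- array(NA_real_, dim = c(n_save, chains, n_act, n_subj),
                      dimnames = list(NULL, NULL, .DDM_PAR_NAMES[act_idx],
                                      ids))
  deviance <- matrix(NA_real_, n_save, chains)
  for (ch in seq_len(chains)) {
    group[, ch, ] <- runs[[ch]]$group
    deviance[, ch] <- runs[[ch]]$deviance
    sd_mat <- runs[[ch]]$subj
    for (k in seq_len(n_act)) {
      subj_draws[, ch, k, ] <-
        sd_mat[, ((k - 1) * n_subj + 1):(k * n_subj), drop = FALSE]
    }
  }

  rh <- vapply(seq_along(gnames), function(j) rhat(group[, , j]), numeric(1))
  summ <- data.frame(
    parameter = gnames,
    mean = apply(group, 3, mean),
    sd = apply(group, 3, sd),
    q2.5 = apply(group, 3, quantile, 0.025),
    q50 = apply(group, 3, quantile, 0.5),
    q97.5 = apply(group, 3, quantile, 0.975),
    rhat = rh,
    row.names = NULL
  )

  # DIC: Dbar + pD, pD = Dbar - D(theta_bar), theta_bar = posterior mean of
  # the participant-level parameters (classic Spiegelhalter form)
  theta_bar <- matrix(0, n_subj, 10)
  for (k in seq_len(n_act)) {
    theta_bar[, act_idx[k]] <- apply(subj_draws[, , k, , drop = FALSE],
                                     4, mean)
  }
  d_bar <- mean(deviance)
  d_hat <- .hddm_deviance_cpp(as.numeric(data$rt), as.integer(data$choice),
                              as.numeric(data$delta_m),
                              as.numeric(data$delta_s),
                              as.integer(data$stage), subj, n_subj,
                              theta_bar)
  p_d <- d_bar - d_hat

  structure(list(
    spec = spec, participants = ids, group_draws = group,
    subj_draws = subj_draws, deviance = deviance, summary = summ,
    dic = d_bar + p_d, d_bar = d_bar, d_hat = d_hat, p_d = p_d,
    p_v = var(as.numeric(deviance)) / 2,
    converged = all(is.finite(rh)) && all(rh < 1.1),
    n_trials = nrow(data), chains = chains, iter = iter, warmup = warmup
  ), class = "hddm_fit")
}

#' @export
print.hddm_fit <- function(x, ...) {
  cat(sprintf(
    "hierarchical DDM fit (%s): %d participants, %d trials, %d chains x %d draws\n",
    x$spec$id, length(x$participants), x$n_trials, x$chains,
    x$iter - x$warmup))
  cat(sprintf("DIC = %.1f (pD = %.1f); %s\n", x$dic, x$p_d,
              if (x$converged) "converged (all R-hat < 1.1)"
              else "NOT converged (some R-hat >= 1.1)"))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance ratio; values below 1.1 are taken
#' as converged. The raw estimator can dip a hair below 1 when the
#' between-chain variance is negligible; it is floored at 1 so perfectly
#' mixed chains report exactly 1.
#'
#' @param draws iterations x chains matrix (a vector is treated as a single
#'   chain and returns `NA`: R-hat needs at least 2 chains)
#' @export
rhat <- function(draws) {
  draws <- as.matrix(draws)
  m <- ncol(draws)
  if (m < 2) return(NA_real_)
  n <- nrow(draws)
  means <- colMeans(draws)
  w <- mean(apply(draws, 2, var))
  b <- n * var(means)
  if (w < .Machine$double.eps) {
    return(if (b < .Machine$double.eps) 1 else Inf)
  }
  max(1, sqrt(((n - 1) / n * w + b / n) / w))
}

#' Pooled posterior draws of a group-level parameter
#'
#' @param fit an `hddm_fit`
#' @param parameter group-level parameter name, e.g. `"mu_d_w_pain"`
#' @export
group_draws <- function(fit, parameter) {
  stopifnot(inherits(fit, "hddm_fit"))
  dn <- dimnames(fit$group_draws)[[3]]
  if (!parameter %in% dn) {
    stop("unknown parameter: ", parameter, " (have: ",
         paste(dn, collapse = ", "), ")")
  }
  as.numeric(fit$group_draws[, , parameter])
}

#' Posterior mass on one side of zero
#'
#' @param draws posterior draws of a contrast
#' @param side `"negative"` or `"positive"`
#' @return fraction of draws strictly on the stated side of 0
#' @export
direction_probability <- function(draws, side = c("negative", "positive")) {
  side <- match.arg(side)
  if (side == "negative") mean(draws < 0) else mean(draws > 0)
}

#' Per-participant posterior means of the fitted parameters
#'
#' The two-step route to individual-difference analysis: each participant's
#' posterior mean for every sampled parameter.
#'
#' @param fit an `hddm_fit`
#' @return data frame, one row per participant
#' @export
participant_means <- function(fit) {
  stopifnot(inherits(fit, "hddm_fit"))
  pars <- dimnames(fit$subj_draws)[[3]]
  out <- data.frame(participant = fit$participants)
  for (k in pars) {
    out[[k]] <- apply(fit$subj_draws[, , k, , drop = FALSE], 4, mean)
  }
  out
}

#' DIC model comparison over a set of candidate specifications
#'
#' Fits each specification to the same data and ranks by DIC (lower is
#' better); pairs differing by more than `rule_delta` are flagged decisive.
#'
#' @param data as in [fit_hddm()]
#' @param specs list of [ddm_model_spec()] objects (or model id strings)
#' @param rule_delta DIC difference treated as decisive (default 10)
#' @param ... passed to [fit_hddm()]
#' @return list with `table` (model, dic, delta_dic, converged, ordered by
#'   DIC), `preferred` (model id, `NA` when the top models tie within
#'   `rule_delta`), and `fits`
#' @export
compare_models <- function(data, specs = list("M1", "M2", "M3", "M4", "M5",
                                              "M6"),
                           rule_delta = 10, ...) {
  specs <- lapply(specs, function(s) {
    if (inherits(s, "ddm_model_spec")) s else ddm_model_spec(s)
  })
  fits <- lapply(specs, function(s) fit_hddm(data, spec = s, ...))
  ids <- vapply(specs, `[[`, character(1), "id")
  names(fits) <- ids
  dics <- vapply(fits, `[[`, numeric(1), "dic")
  tab <- data.frame(model = ids, dic = dics,
                    delta_dic = dics - min(dics),
                    converged = vapply(fits, `[[`, logical(1), "converged"),
                    row.names = NULL)
  tab <- tab[order(tab$dic), ]
  preferred <- if (nrow(tab) > 1 && tab$delta_dic[2] <= rule_delta) {
    NA_character_
  } else {
    tab$model[1]
  }
  list(table = tab, preferred = preferred, fits = fits)
}

#' Posterior predictive check on choice proportions and RT quantiles
#'
#' Simulates full data sets from randomly drawn joint posterior samples of
#' the participant-level parameters and compares, per stage and trial-kappa
#' bin, the observed harmful-choice proportion and RT mean/quantiles
#' (10/30/50/70/90%) with the 95% interval across simulations.
#'
#' @param fit an `hddm_fit`
#' @param data the data the model was fitted to
#' @param n_sims number of posterior draws simulated
#' @param n_bins number of trial-kappa bins
#' @param dt Euler step for the simulations
#' @return data frame with one row per stage x bin x statistic: `observed`,
#'   `sim_lo`, `sim_hi`, `inside`, and `empty` for undefined bins
#' @export
posterior_predictive_check <- function(fit, data, n_sims = 50, n_bins = 4,
                                       dt = 1e-3) {
  stopifnot(inherits(fit, "hddm_fit"))
  .check_hddm_data(data)
  kap <- data$delta_m / (data$delta_s + data$delta_m)
  brk <- unique(quantile(kap, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(kap, brk, include.lowest = TRUE)
  cell <- interaction(data$stage, bin, drop = FALSE)

  stat_names <- c("p_harm", "rt_mean", paste0("rt_q", c(10, 30, 50, 70, 90)))
  cell_stats <- function(choice, rt) {
    if (length(rt) == 0) return(rep(NA_real_, length(stat_names)))
    c(mean(choice), mean(rt), quantile(rt, c(.1, .3, .5, .7, .9)))
  }
  obs <- sapply(levels(cell), function(lv) {
    i <- cell == lv
    cell_stats(data$choice[i], data$rt[i])
  })

  n_save <- dim(fit$subj_draws)[1]
  chains <- dim(fit$subj_draws)[2]
  pars <- dimnames(fit$subj_draws)[[3]]
  subj_of <- match(data$participant, fit$participants)
  sims <- array(NA_real_, c(length(stat_names), length(levels(cell)),
                            n_sims))
  for (s in seq_len(n_sims)) {
    it <- sample.int(n_save, 1)
    ch <- sample.int(chains, 1)
    theta <- matrix(0, length(fit$participants), 10,
                    dimnames = list(NULL, .DDM_PAR_NAMES))
    theta[, pars] <- t(fit$subj_draws[it, ch, , ])
    v <- theta[subj_of, "v0"] +
      (theta[subj_of, "w_money"] + theta[subj_of, "d_w_money"] *
         data$stage) * data$delta_m +
      (theta[subj_of, "w_pain"] + theta[subj_of, "d_w_pain"] *
         data$stage) * data$delta_s
    a <- theta[subj_of, "a"] + theta[subj_of, "d_a"] * data$stage
    z <- clamp(theta[subj_of, "z"] + theta[subj_of, "d_z"] * data$stage,
               0.01, 0.99)
    t0 <- theta[subj_of, "t0"]
    sim_ch <- integer(nrow(data))
    sim_rt <- numeric(nrow(data))
    base_seed <- runif(1, 0, 2^30)
    for (i in seq_len(nrow(data))) {
      r <- .rwiener_cpp(1L, v[i], a[i], z[i], t0[i], dt, 60, base_seed + i)
      sim_ch[i] <- r$choice[1]
      sim_rt[i] <- r$rt[1]
    }
    sims[, , s] <- sapply(levels(cell), function(lv) {
      i <- cell == lv
      cell_stats(sim_ch[i], sim_rt[i])
    })
  }

  rows <- expand.grid(statistic = stat_names, cell = levels(cell),
                      stringsAsFactors = FALSE)
  rows$observed <- as.numeric(obs)
  rows$sim_lo <- as.numeric(apply(sims, c(1, 2), quantile, 0.025,
                                  na.rm = TRUE))
  rows$sim_hi <- as.numeric(apply(sims, c(1, 2), quantile, 0.975,
                                  na.rm = TRUE))
  rows$empty <- !is.finite(rows$observed)
  rows$inside <- !rows$empty & rows$observed >= rows$sim_lo &
    rows$observed <= rows$sim_hi
  rows
}
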