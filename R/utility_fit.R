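#' Maximum-likelihood fit of the harm-aversion choice model
#'
#' Fits `(kappa, beta, epsilon)` of the softmax-with-lapse rule to one
#' participant-stage's binary choices by maximising the Bernoulli
#' log-likelihood. The likelihood is multimodal in `beta` for
#' near-deterministic data, so the optimiser is a multi-start bounded
#' quasi-Newton (`L-BFGS-B`): the negative log-likelihood is evaluated on a
#' `kappa x beta x epsilon` grid and the best grid points seed the local
#' searches.
#'
#' @param choices 0/1 vector, harmful coded 1
#' @param delta_m,delta_s trial differences aligned with `choices`
#' @param n_starts number of grid points carried into local optimisation
#' @return list of class `utility_fit`: `kappa`, `beta`, `epsilon`, `loglik`,
#'   `pseudo_r2` (McFadden vs. chance), `pct_correct`, `n_trials`,
#'   `boundary` (TRUE when all choices are identical, leaving `kappa` only
#'   boundary-identified)
#' @export
fit_utility <- function(choices, delta_m, delta_s, n_starts = 6L) {
  stopifnot(length(choices) >= 10, all(choices %in% 0:1),
            length(delta_m) == length(choices),
            length(delta_s) == length(choices))
  choices <- as.integer(choices)

  nll <- function(par) {
    p <- choice_probability(value_difference(delta_m, delta_s, par[1]),
                            par[2], par[3])
    p <- clamp(p, 1e-12, 1 - 1e-12)
    -sum(ifelse(choices == 1, log(p), log(1 - p)))
  }

  grid <- expand.grid(kappa = seq(0.1, 0.9, length.out = 5),
                      beta = c(0.5, 2, 8, 32, 128),
                      epsilon = c(0.01, 0.1, 0.25))
  gvals <- apply(grid, 1, nll)
  starts <- grid[order(gvals)[seq_len(n_starts)], , drop = FALSE]

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(as.numeric(starts[i, ]), nll, method = "L-BFGS-B",
            lower = c(0, 0, 0), upper = c(1, 200, 0.5)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("utility fit failed from every start")

  ll <- -best$value
  p_hat <- choice_probability(
    value_difference(delta_m, delta_s, best$par[1]), best$par[2],
    best$par[3])
  structure(list(
    kappa = best$par[1], beta = best$par[2], epsilon = best$par[3],
    loglik = ll,
    pseudo_r2 = pseudo_r2(ll, length(choices)),
    pct_correct = mean((p_hat >= 0.5) == (choices == 1)),
    n_trials = length(choices),
    boundary = length(unique(choices)) == 1L
  ), class = "utility_fit")
}

#' @export
print.utility_fit <- function(x, ...) {
  cat(sprintf(
    "harm-aversion fit: kappa = %.3f, beta = %.2f, epsilon = %.3f\n",
    x$kappa, x$beta, x$epsilon))
  cat(sprintf("  loglik = %.2f (n = %d), pseudo-R2 = %.3f, %.0f%% correct%s\n",
              x$loglik, x$n_trials, x$pseudo_r2, 100 * x$pct_correct,
              if (x$boundary) " [boundary: all choices identical]" else ""))
  invisible(x)
}

#' McFadden pseudo-R-squared against the chance model
#'
#' `1 - loglik / (n * log(0.5))`: 0 for a chance-level model, approaching 1
#' as the likelihood approaches a perfect fit.
#'
#' @param loglik maximised Bernoulli log-likelihood (<= 0)
#' @param n_trials number of binary choices
#' @export
pseudo_r2 <- function(loglik, n_trials) {
  if (n_trials == 0) stop("pseudo_r2 undefined for zero trials")
  stopifnot(loglik <= 1e-9)
  1 - loglik / (n_trials * log(0.5))
}

#' Baseline-preference exclusion rules
#'
#' Participants whose baseline harm aversion is more extreme than their
#' assigned peer's cannot move toward the peer, so they are excluded. In
#' `"paper"` mode the rule is one-sided per group: drop antisocial-group
#' participants with baseline kappa below 0.2 and prosocial-group
#' participants above 0.8. In `"symmetric"` mode (the robustness variant)
#' both cut-offs apply to both groups.
#'
#' @param kappa_baseline baseline harm aversion (vectorised)
#' @param group `"prosocial"` or `"antisocial"` (vectorised)
#' @param mode `"paper"` or `"symmetric"`
#' @return data frame with logical `keep` and a `reason` string for drops
#' @export
apply_exclusions <- function(kappa_baseline, group,
                             mode = c("paper", "symmetric")) {
  mode <- match.arg(mode)
  stopifnot(all(kappa_baseline >= 0), all(kappa_baseline <= 1))
  if (!all(group %in% c("prosocial", "antisocial"))) {
    stop("unknown group label")
  }
  n <- length(kappa_baseline)
  group <- rep_len(group, n)
  low <- kappa_baseline < 0.2
  high <- kappa_baseline > 0.8
  drop <- if (mode == "paper") {
    (group == "antisocial" & low) | (group == "prosocial" & high)
  } else {
    low | high
  }
  reason <- rep("", n)
  reason[drop & low] <- "baseline kappa below antisocial peer (0.2)"
  reason[drop & high] <- "baseline kappa above prosocial peer (0.8)"
  data.frame(keep = !drop, reason = reason)
}

#' Objective similarity with the observed peer
#'
#' One minus the distance between the peer's harm aversion and the
#' participant's baseline harm aversion: `1 - (0.8 - kappa1)` for the
#' prosocial group, `1 - (kappa1 - 0.2)` for the antisocial group. Equals 1
#' exactly when the baseline preference matches the peer's.
#'
#' @inheritParams apply_exclusions
#' @export
objective_similarity <- function(kappa_baseline, group) {
  if (!all(group %in% c("prosocial", "antisocial"))) {
    stop("unknown group label")
  }
  ifelse(group == "prosocial", 1 - (0.8 - kappa_baseline),
         1 - (kappa_baseline - 0.2))
}

#' Money-per-shock exchange rate implied by a harm aversion
#'
#' The indifference condition `(1 - kappa) * dm = kappa * ds` gives the rate
#' `kappa / (1 - kappa)` in currency per shock: a decider with kappa 0.8
#' gives up to 4 per shock avoided, one with kappa 0.2 at most 0.25.
#'
#' @param kappa harm aversion in `[0, 1)`; `kappa = 1` yields `Inf` with a
#'   warning (shock reduction at any price)
#' @export
exchange_rate <- function(kappa) {
  stopifnot(all(kappa >= 0), all(kappa <= 1))
  if (any(kappa == 1)) warning("kappa = 1 implies an infinite exchange rate")
  kappa / (1 - kappa)
}

#' Percent change in the exchange rate between two harm aversions
#'
#' `100 * (rate(kappa2) / rate(kappa1) - 1)`, rounded to the nearest whole
#' percent, half away from zero — the scale on which stage shifts in group
#' mean harm aversion are reported.
#'
#' @param kappa1,kappa2 harm aversion before and after
#' @export
percent_change_exchange <- function(kappa1, kappa2) {
  round_half_away(100 * (exchange_rate(kappa2) / exchange_rate(kappa1) - 1))
}

#' Fit the utility model for every participant-stage in a choice table
#'
#' @param choices long-format data frame with columns `participant`, `stage`,
#'   `delta_m`, `delta_s`, `choice`
#' @return data frame, one row per participant-stage, with the fitted
#'   parameters and diagnostics
#' @export
fit_utility_all <- function(choices) {
  parts <- split(choices, list(choices$participant, choices$stage),
                 drop = TRUE)
  rows <- lapply(parts, function(d) {
    f <- fit_utility(d$choice, d$delta_m, d$delta_s)
    data.frame(participant = d$participant[1], stage = d$stage[1],
               kappa = f$kappa, beta = f$beta, epsilon = f$epsilon,
               loglik = f$loglik, pseudo_r2 = f$pseudo_r2,
               pct_correct = f$pct_correct)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant, out$stage), ]
}
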