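#' Bayesian regression of diffusion-parameter changes on similarity
#'
#' Links per-participant stage changes in the diffusion parameters (e.g.
#' the change in the pain weight) to a predictor in `[0, 1]` — objective or
#' subjective similarity with the peer, or self-reported perceived shift —
#' with a group term, their interaction, and prediction accuracy as a
#' covariate:
#' `outcome ~ predictor + group + predictor:group + accuracy`.
#'
#' The model is a conjugate Gaussian linear model sampled by Gibbs:
#' coefficients carry Normal(0, 2.5) priors on the standardized scale
#' (predictors and outcome are standardized internally; draws are mapped
#' back to the raw scale), and the residual variance a weak inverse-gamma
#' prior. "Significant" means the central 95% credible interval excludes 0.
#' Per-group simple slopes of the predictor are derived from the coefficient
#' draws (group is dummy-coded antisocial = 0, prosocial = 1).
#'
#' @param outcome numeric vector, one value per retained participant
#' @param predictor numeric vector rescaled to `[0, 1]`
#' @param group `"prosocial"`/`"antisocial"` per participant
#' @param accuracy prediction-accuracy covariate, or `NULL` to omit
#' @param n_draws posterior draws
#' @param prior_sd prior sd of standardized coefficients
#' @return object of class `bayes_lm`: `coefficients` data frame (posterior
#'   mean, sd, 95% CI, `significant`), `simple_slopes` for the predictor per
#'   group, and the coefficient draws
#' @export
regress_delta <- function(outcome, predictor, group, accuracy = NULL,
                          n_draws = 4000, prior_sd = 2.5) {
  n <- length(outcome)
  stopifnot(length(predictor) == n, length(group) == n,
            all(group %in% c("prosocial", "antisocial")))
  g <- as.numeric(group == "prosocial")
  X <- cbind(`(Intercept)` = 1, predictor = predictor, group_prosocial = g,
             `predictor:group` = predictor * g)
  if (!is.null(accuracy)) {
    stopifnot(length(accuracy) == n)
    X <- cbind(X, accuracy = accuracy)
  }
  sds <- apply(X[, -1, drop = FALSE], 2, sd)
  if (any(sds < 1e-12)) {
    stop("rank deficiency: constant predictor column(s): ",
         paste(colnames(X)[-1][sds < 1e-12], collapse = ", "))
  }

  draws <- .gibbs_lm(X, outcome, n_draws = n_draws, prior_sd = prior_sd)
  coefs <- .summarize_draws(draws$beta)
  sl_anti <- draws$beta[, "predictor"]
  sl_pro <- draws$beta[, "predictor"] + draws$beta[, "predictor:group"]
  slopes <- .summarize_draws(cbind(antisocial = sl_anti, prosocial = sl_pro))
  structure(list(coefficients = coefs, simple_slopes = slopes,
                 beta_draws = draws$beta, sigma_draws = draws$sigma,
                 n = n),
            class = "bayes_lm")
}

#' @export
print.bayes_lm <- function(x, ...) {
  cat(sprintf("Bayesian linear model (n = %d)\n", x$n))
  print(x$coefficients, digits = 3)
  cat("simple slopes of the predictor:\n")
  print(x$simple_slopes, digits = 3)
  invisible(x)
}

# Gibbs sampler for y = X b + e with N(0, prior_sd^2) priors on
# standardized coefficients and IG(0.001, 0.001) on the residual variance.
# X and y are standardized internally; returned draws are on the raw scale.
.gibbs_lm <- function(X, y, n_draws = 4000, warmup = 500, prior_sd = 2.5) {
  keep <- colnames(X) != "(Intercept)"
  x_mean <- colMeans(X[, keep, drop = FALSE])
  x_sd <- apply(X[, keep, drop = FALSE], 2, sd)
  y_mean <- mean(y)
  y_sd <- sd(y)
  if (y_sd < 1e-12) y_sd <- 1
  Xs <- X
  Xs[, keep] <- sweep(sweep(X[, keep, drop = FALSE], 2, x_mean), 2, x_sd,
                      "/")
  ys <- (y - y_mean) / y_sd

  p <- ncol(Xs)
  n <- nrow(Xs)
  XtX <- crossprod(Xs)
  Xty <- crossprod(Xs, ys)
  prior_prec <- diag(1 / prior_sd^2, p)
  prior_prec[1, 1] <- 1e-6  # effectively flat intercept

  beta <- rep(0, p)
  sig2 <- 1
  out_b <- matrix(NA_real_, n_draws, p, dimnames = list(NULL, colnames(X)))
  out_s <- numeric(n_draws)
  total <- n_draws + warmup
  for (it in seq_len(total)) {
    prec <- XtX / sig2 + prior_prec
    ch <- chol(prec)
    m <- backsolve(ch, forwardsolve(t(ch), Xty / sig2))
    beta <- m + backsolve(ch, rnorm(p))
    resid <- ys - Xs %*% beta
    sig2 <- 1 / rgamma(1, 0.001 + n / 2,
                       0.001 + sum(resid^2) / 2)
    if (it > warmup) {
      out_b[it - warmup, ] <- beta
      out_s[it - warmup] <- sqrt(sig2)
    }
  }
  # back-transform to the raw scale
  raw <- out_b
  raw[, keep] <- sweep(out_b[, keep, drop = FALSE], 2, x_sd, "/") * y_sd
  raw[, 1] <- y_mean + out_b[, 1] * y_sd -
    raw[, keep, drop = FALSE] %*% x_mean
  list(beta = raw, sigma = out_s * y_sd)
}

.summarize_draws <- function(draws) {
  out <- data.frame(
    term = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, sd),
    ci_lo = apply(draws, 2, quantile, 0.025),
    ci_hi = apply(draws, 2, quantile, 0.975),
    row.names = NULL
  )
  out$significant <- out$ci_lo > 0 | out$ci_hi < 0
  out
}

#' Awareness-of-influence analysis
#'
#' Same contract as [regress_delta()] with the predictor being the
#' participant's self-reported perceived shift in behaviour (rescaled to
#' `[0, 1]`).
#'
#' @inheritParams regress_delta
#' @param perceived_shift perceived-shift ratings in `[0, 1]`
#' @export
perceived_shift_analysis <- function(outcome, perceived_shift, group,
                                     accuracy = NULL, n_draws = 4000,
                                     prior_sd = 2.5) {
  regress_delta(outcome, perceived_shift, group, accuracy,
                n_draws = n_draws, prior_sd = prior_sd)
}
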