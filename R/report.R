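#' Effect size r from a standardized rank-test statistic
#'
#' `r = |z| / sqrt(n)`, the conventional conversion for Wilcoxon and
#' Mann-Whitney statistics; displayed to 2 decimals, half away from zero.
#'
#' @param z standardized test statistic
#' @param n sample count entering the test
#' @export
effect_size_r <- function(z, n) {
  if (any(n < 1)) stop("effect_size_r needs n >= 1")
  round_half_away(abs(z) / sqrt(n), 2)
}

#' Continuity-corrected chi-square test of a proportion against one half
#'
#' Yates-corrected goodness-of-fit statistic for `k` successes out of `n`
#' against the null proportion 0.5:
#' `sum over the 2 cells of (max(0, |O - E| - 0.5))^2 / E` with `E = n / 2`.
#' Displayed to 2 decimals, half away from zero.
#'
#' @param k successes
#' @param n total
#' @export
proportion_chisq_cc <- function(k, n) {
  if (any(n < 1) || any(k < 0) || any(k > n)) {
    stop("need 0 <= k <= n and n >= 1")
  }
  e <- n / 2
  dev <- pmax(0, abs(c(k, n - k) - e) - 0.5)
  round_half_away(sum(dev^2 / e), 2)
}

#' Group-by-stage summary of fitted harm aversion
#'
#' Collapses a per-participant utility-fit table into the headline influence
#' result: group mean (and sd) harm aversion per stage and the percent
#' change in the implied money-per-shock exchange rate from baseline to
#' post-influence, computed from the group-mean parameters.
#'
#' @param fits data frame from [fit_utility_all()] with added `group`
#'   column (`stage` coded 0 = baseline, 1 = post)
#' @return data frame with one row per group: mean/sd kappa per stage and
#'   `pct_change_exchange`
#' @export
influence_report <- function(fits) {
  stopifnot(all(c("participant", "stage", "kappa", "group") %in%
                  names(fits)))
  rows <- lapply(split(fits, fits$group), function(d) {
    k1 <- d$kappa[d$stage == 0]
    k2 <- d$kappa[d$stage == 1]
    data.frame(group = d$group[1],
               n = length(k1),
               kappa_baseline_mean = mean(k1),
               kappa_baseline_sd = sd(k1),
               kappa_post_mean = mean(k2),
               kappa_post_sd = sd(k2),
               pct_change_exchange =
                 percent_change_exchange(mean(k1), mean(k2)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
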