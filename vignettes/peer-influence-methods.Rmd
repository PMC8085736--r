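---
title: "Modeling peer influence on moral decision-making"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling peer influence on moral decision-making}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peerddm)
```

## The paradigm

`peerddm` implements a complete analysis pipeline for a moral
decision-making paradigm in which a decider repeatedly chooses between a
*helpful* option (less money for themselves, fewer electric shocks for an
anonymous receiver) and a *harmful* option (more money, more shocks).
Between two decision stages, the decider observes and predicts the choices
of a simulated peer who is either strongly harm-averse ("prosocial", harm
aversion 0.8) or weakly harm-averse ("antisocial", harm aversion 0.2). The
scientific questions are whether observing the peer shifts the decider's
own valuation of money versus others' pain, which computational components
carry that shift, and whether the shift scales with baseline similarity to
the peer and with self-reported awareness.

Every quantity in the pipeline is organised around *trial kappa*,
$\kappa_{trial} = \Delta m / (\Delta s + \Delta m)$, the profitability of
the harmful option per extra shock ($\Delta m$ in GBP on a 0.05 grid,
$\Delta s$ an integer shock count). A decider's *harm aversion* $\kappa$
is their indifference point in this space.

## Trial construction

Decision sets place trial-kappa targets evenly (inclusive linear spacing)
over $[0.05, 0.95]$ — 48 trials per stage in the full design. Each target
is realised by drawing 10,000 uniform candidate pairs
$(\Delta s \in \{1..19\}, \Delta m \in \{0.05..19.95\})$ and keeping the
pair whose trial kappa is closest; option amounts are then drawn uniformly
from the feasible grid under $0.10 \le m_{help} + \Delta m \le 20.00$ and
$2 \le s_{help} + \Delta s \le 20$. Money is carried internally in integer
pence so the 0.05 grid never drifts in floating point. The realised trial
kappa sits within 0.01 of its target essentially always at 10,000 draws;
the tolerance is configurable in the tests.

Prediction sets have 50 trials: the first target fixed at 0.5, then 41
uniform targets and 8 "diagnostic" targets drawn from Normal(0.8, 0.1) —
near the prosocial peer's indifference point, where choices are most
informative about the peer's preference. Diagnostic draws are clipped to
$[0.05, 0.95]$ (out-of-range draws are otherwise undefined in this
design). The antisocial set mirrors the prosocial targets ($1 - \kappa$)
trial by trial, placing its diagnostic mass near 0.2. Because the order of
the 49 post-first trials is not structurally constrained, the uniform and
diagnostic trials are shuffled together after trial 1.

## The harm-aversion choice model

The subjective value difference of harming is
$\Delta V = (1-\kappa)\Delta m - \kappa \Delta s$, with money in GBP —
the unit in which a harm aversion of 0.8 corresponds to giving up at most
4 currency units per shock avoided ($\kappa/(1-\kappa)$). Choices follow a
softmax with lapse,
$P(harm) = \frac{1}{1+e^{-\beta \Delta V}}(1-2\varepsilon) + \varepsilon$,
algebraically the mixture $(1-\varepsilon)P_{true} +
\varepsilon(1-P_{true})$. Simulated peers use $\beta = 100$ and
$\varepsilon = 0$, so they choose by the trial-kappa threshold except
within a whisker of indifference.

Per participant and stage, `fit_utility()` maximises the Bernoulli
likelihood over $\kappa \in [0,1]$, $\beta \in [0,200]$,
$\varepsilon \in [0, 0.5]$. The likelihood is multimodal in $\beta$ when
choices are near-deterministic, so the optimiser is multi-start: a
$5 \times 5 \times 3$ grid is scored and the best points seed bounded
L-BFGS-B searches. The reported pseudo-$R^2$ is McFadden's measure against
the chance model, $1 - \ell/(n \ln 0.5)$; the formula is a package choice,
made because the comparison to coin-flipping is the natural baseline for
binary moral choices.

Participants whose baseline harm aversion is more extreme than their
peer's cannot move toward the peer; `apply_exclusions()` implements both
the one-sided per-group rule (`"paper"`) and the symmetric robustness rule
(`"symmetric"`). Objective similarity with the peer is the reversed
distance between baseline harm aversion and the peer's: $1-(0.8-\kappa_1)$
(prosocial) or $1-(\kappa_1-0.2)$ (antisocial).

## The stage-modulated drift-diffusion model

Choices and response times are modelled jointly as a unit-variance
diffusion between absorbing boundaries 0 (helpful) and $a$ (harmful),
starting at relative position $z$, with non-decision time $t_0$ and a
trial-level drift

$$v = v_0 + (w_{money} + \Delta w_{money}\,stage)\,\Delta m +
      (w_{pain} + \Delta w_{pain}\,stage)\,\Delta s,$$

where $stage$ is 0 at baseline and 1 post-influence, so the deltas read
directly as post-minus-baseline changes. Money drives the accumulator
toward harming ($w_{money} > 0$) and pain toward helping
($w_{pain} < 0$). The threshold and starting point carry their own stage
deltas; the six-model candidate space (`ddm_model_spec()`) toggles the
stage terms on the two drift weights and the starting point, with the
threshold stage term always present (response times drop in the post
stage). The diffusion coefficient is fixed at 1 and $\Delta m$ enters in
GBP without standardisation, keeping weights interpretable per pound and
per shock. The starting-point delta acts on the raw relative scale with
the effective start clamped to $(0.01, 0.99)$; a link function would be an
alternative, but the raw scale keeps the delta in the same units as the
baseline bias.

The first-passage density is computed by the standard small-time /
large-time series expansions with an accuracy-based switch at truncation
error $10^{-10}$; response times at or below $t_0$ get zero density rather
than an error. Simulation uses Euler–Maruyama steps (default
$dt = 10^{-4}$ s) with a Brownian-bridge correction for intra-step
boundary crossings; without the correction the scheme misses crossings at
rate $O(\sqrt{dt})$, which visibly biases fast-decision distributions at
small thresholds. Analysis keeps response times in the closed window
$[0.3, 20]$ s — the window bounds are kept inclusive since only times
strictly longer or shorter are considered artefactual.

## Hierarchical estimation

Participant-level parameters are modelled as draws from group-level normal
distributions (truncated where the parameter is constrained), and the two
experimental groups are fitted separately, with both stages entering
jointly. Priors are weakly informative and configurable
(`hddm_prior()`): Normal(0, 5) group means for the drift intercept and
weights, Half-Normal(2.5) for the threshold, truncated Normal(0.5, 0.25)
for the starting point and Normal(0, 0.5) for its delta, Uniform(0.05, 1)
for the non-decision time, Half-Normal(1) for the group sds.

Sampling is Metropolis-within-Gibbs: adaptive componentwise random-walk
updates of participant parameters against the Wiener likelihood, conjugate
(truncated) normal updates of group means, and log-scale random-walk
updates of group sds. Two joint moves are essential for mixing in this
random-effects geometry: a *translation* move shifting a group mean and
all participant values together (the group-normal terms cancel, leaving a
likelihood-plus-prior ratio), and a *scale* move expanding the participant
residuals together with the group sd (which walks the narrow neck of the
funnel when the group sd is small). Without them the stage-delta means and
sds mix an order of magnitude more slowly.

Convergence is monitored with the classic Gelman–Rubin statistic,
converged below 1.1; the raw estimator is floored at 1. Model comparison
uses DIC, $\bar D + p_D$ with $p_D = \bar D - D(\bar\theta)$ evaluated at
the posterior mean of the participant-level parameters (the classic form;
the half-variance-of-deviance estimate is also reported as `p_v`).
Differences above 10 are treated as decisive. Posterior predictive checks
simulate full data sets from joint posterior draws and compare observed
harmful-choice proportions and RT means/quantiles (10/30/50/70/90%) per
stage and trial-kappa bin against 95% simulation intervals.

Two MCMC presets are sensible defaults rather than claims about any
particular historical setting: quick exploratory runs (4 chains, 1500
iterations, 500 warmup) and the longer setting used in the package's own
recovery studies (4 chains, 3000 iterations, 1200 warmup).

## Individual differences

Stage changes in the diffusion parameters are linked to similarity and
awareness by a Bayesian linear model, `outcome ~ predictor + group +
predictor:group + accuracy`, sampled by conjugate Gibbs with Normal(0,
2.5) priors on standardized coefficients and a weak inverse-gamma prior on
the residual variance. Per-group simple slopes are derived from the
coefficient draws, and "significant" means the central 95% credible
interval excludes zero. The outcome values default to per-participant
posterior means extracted from the hierarchical fit (the two-step
approach); the full draw matrix is available from the fit object when
propagating posterior uncertainty is preferred. Frequentist tests are
avoided here because the outcomes are themselves MCMC estimates.

## The synthetic cohort generator

`generate_cohort()` builds a two-group experiment with known ground truth
so every stage of the pipeline can be validated by parameter recovery. The
defaults emulate the full study design: 34 participants per group, 48
trials per stage, terminal prediction accuracy centred on 0.87. Baseline
harm aversion is drawn from Beta(4, 4) truncated to $[0.2, 0.8]$, so every
participant passes the exclusion rule by construction. Baseline drift
weights are anchored to harm aversion through the indifference identity
$-w_{pain}/w_{money} = \kappa/(1-\kappa)$ with an overall weight magnitude
near 1.5 per unit; with a threshold near 1.6 this puts the implied softmax
sensitivity and baseline fit quality in a realistic regime for this task
(pseudo-$R^2$ around 0.6–0.7).

Stage deltas are group mean plus a similarity-scaled component plus noise:
the prosocial group's pain weight strengthens (mean $-0.2$, similarity
slope $-0.06$), the antisocial group's money weight strengthens (mean
$+0.2$, slope $+0.06$), the threshold drops in both groups, and the
starting point shifts toward the peer's preferred option with
similarity slopes of opposite sign ($\mp 0.15$). Participant-level noise
on the weight deltas is small (sd 0.012) relative to the planted slopes so
that the regression recovery is a signal-detection problem, not a coin
flip, at $n = 34$ per group. Perceived shift is generated asymmetrically —
informative about the realised pain-weight change in the prosocial group,
pure noise in the antisocial group — mirroring the asymmetric-awareness
phenomenon the regression module is meant to detect.

What the generator deliberately does *not* emulate: learning dynamics
during the prediction stage (only terminal accuracy matters downstream),
questionnaires, impression trajectories, demographic structure, and any
across-trial variability in diffusion parameters. Passing recovery tests
therefore demonstrates the estimators work when the model family is true;
they say nothing about misspecification on real data beyond what the
posterior predictive checks can reveal.

## Problem sizes and numerical choices

The package's recovery studies use deliberately scaled problem sizes: the
hierarchical recovery runs on 10 participants per group with 60 trials per
stage, which is ample to separate the generating model from the
no-stage-modulation baseline by DIC (gaps in the hundreds) while keeping a
full two-group, two-model comparison inside a few minutes. Cohort
simulation uses $dt = 10^{-3}$ s (the bridge correction keeps the
discretisation honest); density-versus-simulation validation uses
$dt = 10^{-4}$ with $10^5$ paths. Ties in trial-kappa matching resolve to
the first-drawn candidate; degenerate inputs (all-identical choices,
constant predictors, empty posterior-predictive bins) are flagged rather
than raised as errors wherever a flagged result is still interpretable.

## A worked example

```{r, eval = FALSE}
set.seed(1)
coh <- generate_cohort(cohort_config(n_per_group = 10,
                                     trials_per_stage = 60))

# stage shift in fitted harm aversion
fits <- fit_utility_all(coh$choices)
fits$group <- coh$participants$group[match(fits$participant,
                                           coh$participants$participant)]
influence_report(fits)

# hierarchical fit of the full stage-modulated model, prosocial group
pro <- filter_rts(coh$choices[coh$choices$group == "prosocial", ])
fit <- fit_hddm(pro, ddm_model_spec("M5"), chains = 4, iter = 3000,
                warmup = 1200, seed = 1)
direction_probability(group_draws(fit, "mu_d_w_pain"), "negative")

# similarity scaling of the planted pain-weight change
p <- coh$participants
regress_delta(p$d_w_pain, p$similarity, p$group, p$accuracy)
```

## Known limitations

The sampler is a random-walk scheme, not gradient-based: for much larger
cohorts a Hamiltonian sampler would scale better. DIC is reported because
it is the conventional criterion for this model family; it shares the
known optimism of plug-in deviance measures. Group-level distributions
for the threshold and starting point are truncated normals on the natural
scale rather than transformed scales; this choice is documented rather
than asserted as unique, and the clamping of the effective starting point
makes extreme delta draws behave conservatively. The non-decision time is
constant within participant; paradigms with strong stage effects on motor
preparation would need a stage delta there too.
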