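Package: peerddm
Title: Peer Influence on Moral Decision-Making via Drift-Diffusion Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying how observing a peer's moral choices reshapes
    value-based decision-making. Implements the money-versus-shocks moral
    choice paradigm: construction of decision and prediction trial sets on a
    trial-kappa grid, simulated prosocial and antisocial peers driven by a
    harm-aversion utility model, per-participant maximum-likelihood fits of
    the softmax-with-lapse choice rule, a stage-modulated multi-attribute
    hierarchical drift-diffusion model estimated by MCMC with DIC model
    comparison and posterior predictive checks, Bayesian regressions linking
    stage changes in diffusion parameters to peer similarity and awareness,
    and a synthetic two-group cohort generator with known ground truth for
    end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
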