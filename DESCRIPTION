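Package: cjsfidelity
Title: Emigration-Adjusted Survival from Bayesian Cormack-Jolly-Seber Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Age-, sex-, and time-specific apparent survival estimation from
    annual mark-recapture data using a state-space Cormack-Jolly-Seber (CJS)
    model with the latent alive states marginalized out, together with a
    Poisson immigration submodel whose fitted per-capita immigration rates are
    used to derive site-fidelity rates and emigration-adjusted survival.
    Includes nine candidate detection-probability structures (site, trap
    response, fixed and random time effects, linear trend, and individual
    heterogeneity), WAIC model selection with credible intervals on WAIC
    differences and model support weights, posterior-predictive
    goodness-of-fit via a chi-squared discrepancy on individual capture
    totals, an adaptive Metropolis-within-Gibbs sampler with convergence
    diagnostics and two diffuse prior sets for sensitivity analysis, and an
    open-population simulator with known survival, emigration, immigration,
    and detection truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Rcpp, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
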