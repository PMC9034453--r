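# cjsfidelity

Age-, sex-, and time-specific survival for marked animal populations, with
the emigration bias taken out.

Cormack–Jolly–Seber (CJS) models estimate *apparent* survival — the
probability of surviving **and** staying in the study area — because a
permanent emigrant and a dead animal leave identical capture records.
`cjsfidelity` implements a Bayesian workflow for annual mark–recapture data
that pairs a state–space CJS model (age/sex/time survival, nine candidate
detection structures) with a Poisson regression of unmarked-capture counts
that estimates per-capita immigration rates; under an even-flow movement
assumption those rates equal emigration, site fidelity is their complement,
and true survival is recovered draw-by-draw as

    logit φ[a,s,t] = β_age[a] + β_sex[a]·Sex + ε[a,s,t],   ε ~ N(0, σ²)
    y[i,t] | z[i,t] ~ Bernoulli(z[i,t] · p[i,t])
    Imm[a,s,t] ~ Poisson(C[a,s,t] · I[a,s,t]),  log I = β'_age[a] + β'_sex·Sex + α_t
    r[a,s,t] = 1 − I[a,s,t+1],   φ_adjusted = φ / r,   Δ = φ_adjusted − φ

The package is aimed at population ecologists who have annual capture
histories (and counts of unmarked captures) for an age- and sex-structured
population and want survival estimates that are not confounded by
emigration, together with the supporting machinery: WAIC selection across
detection structures (site, trap response, fixed/random time effects,
trend, individual heterogeneity), credible intervals on WAIC differences,
posterior-predictive goodness of fit, convergence diagnostics, two diffuse
prior sets for sensitivity analysis, and an open-population simulator with
known truth that validates every stage.

The likelihood marginalizes the latent alive states in closed form (the
backward "chi" recursion), and sampling is by an adaptive
Metropolis-within-Gibbs written in C++ with extra moves for the
hierarchical-funnel and intercept/random-effect ridge directions, so fits
at realistic sizes (hundreds of individuals, nine occasions) take seconds.

## Worked example

Simulate a population whose true survival is 0.75 but whose members
permanently emigrate with probability 0.2 per year (so apparent survival is
0.75 × 0.8 = 0.6), fit the CJS and immigration submodels jointly, and
adjust:

```r
library(cjsfidelity)

cfg <- simulationConfig(
  nSites = 9, nOccasions = 9, nAgeClasses = 2,
  phi = 0.75, emigration = 0.2, immigrationMean = 4,
  detection = list(structure = "Null", intercept = 0.5),
  initialCohort = 10, immigrationMode = "matched")
sim <- simulatePopulation(cfg, seed = 1)
ds  <- filterForSurvival(sim$dataset)
#> retained 375 of 385 individuals captured before the final occasion

fit <- fitModel(ds, sim$counts, structure = "Null",
                chains = 3, iter = 2000, burn = 800, seed = 1)
fit
#> PosteriorResult: detection structure 'Null', 3 chains x 2000 iterations (burn-in 800, prior prior1)
#>   114 parameters; max monitored R-hat 1.016 (gate < 1.03: pass)

adj <- adjustedSurvival(fit)
tab <- adjustmentTable(adj)
round(colMeans(tab[, c("phi_mean", "I_mean", "r_mean", "phiAdj_mean", "delta_mean")]), 3)
#>    phi_mean      I_mean      r_mean phiAdj_mean  delta_mean
#>       0.571       0.197       0.803       0.722       0.151
```

Apparent survival is estimated near its confounded value (~0.6); the
fitted immigration rate recovers the emigration probability (~0.2); and
the adjusted estimate moves back toward the true survival of 0.75, with
`delta_mean` the size of the emigration bias that an unadjusted analysis
would have absorbed.  Each row of `tab` is one age × sex × interval cell
with posterior means and 95% credible intervals for all five quantities
plus clamping flags.

Detection-structure selection and goodness of fit:

```r
cmp <- selectDetectionModel(ds, chains = 2, iter = 1200, burn = 600, seed = 2)
comparisonTable(cmp)[1:3, c("model", "deltaWaic", "lower", "upper", "weight")]
ppc <- bayesP(fit, ds, nRep = 300)
bayesianP(ppc)   # ~0.5 indicates the observation model reproduces the data
```

A thin command-line wrapper with `simulate`, `validate`, `select`, `fit`,
and `report` subcommands ships in `inst/exec/cjsfidelity-cli`.

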