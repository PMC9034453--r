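#' @import methods
#' @importFrom stats quantile rnorm runif rbinom rpois dpois var sd setNames median
#' @importFrom utils read.csv write.csv
#' @useDynLib cjsfidelity, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DETECTION_STRUCTURES <- c("Null", "s", "b", "t", "T", "tRE", "mH", "b+tRE", "b+mH")

#' Capture-history dataset
#'
#' Annual binary detection histories for marked individuals, together with the
#' site, sex, and age class at first capture of each individual.  Histories are
#' conditioned on first capture: `y[i, f[i]] == 1` and all earlier entries are
#' zero.  An effort mask records which sites were trapped in which years;
#' detections are impossible (and the observation model contributes no terms)
#' at site-years without effort.
#'
#' @slot y integer matrix, individuals x occasions, 0/1 detections.
#' @slot f integer vector of first-capture occasions.
#' @slot individualId character vector of individual labels.
#' @slot site integer site index (1..S) of each individual.
#' @slot siteLevels character vector of site names.
#' @slot sex integer vector, 0 = male, 1 = female.
#' @slot ageAtFirst integer age class (1..A) at first capture.
#' @slot nAgeClasses integer, number of age classes A (3 for a flying-squirrel
#'   style configuration, 2 for a chipmunk style one).
#' @slot occasionLabels character labels (calendar years) for the occasions.
#' @slot effort integer matrix, sites x occasions, 1 where trapping occurred.
#' @export
setClass("CaptureDataset", representation(
  y = "matrix", f = "integer", individualId = "character",
  site = "integer", siteLevels = "character", sex = "integer",
  ageAtFirst = "integer", nAgeClasses = "integer",
  occasionLabels = "character", effort = "matrix"))

setValidity("CaptureDataset", function(object) {
  y <- object@y; n <- nrow(y); T <- ncol(y)
  msg <- character(0)
  if (!all(y %in% c(0L, 1L))) msg <- c(msg, "detections must be 0/1")
  if (length(object@f) != n) msg <- c(msg, "f length != individuals")
  if (length(object@site) != n || length(object@sex) != n ||
      length(object@ageAtFirst) != n || length(object@individualId) != n)
    msg <- c(msg, "metadata length != individuals")
  if (length(object@occasionLabels) != T)
    msg <- c(msg, "occasionLabels length != occasions")
  if (!all(dim(object@effort) == c(length(object@siteLevels), T)))
    msg <- c(msg, "effort must be sites x occasions")
  if (n > 0) {
    if (any(object@f < 1L | object@f > T))
      msg <- c(msg, "first-capture occasion out of range")
    else {
      if (any(y[cbind(seq_len(n), object@f)] != 1L))
        msg <- c(msg, "y[i, f_i] must be 1 (condition on first capture)")
      before <- col(y) < object@f[row(y)]
      if (any(y[before] != 0L))
        msg <- c(msg, "detection before declared first occasion")
    }
    if (!all(object@sex %in% c(0L, 1L))) msg <- c(msg, "sex must be 0/1")
    if (any(object@ageAtFirst < 1L | object@ageAtFirst > object@nAgeClasses))
      msg <- c(msg, "age at first capture outside 1..A")
    if (any(object@site < 1L | object@site > length(object@siteLevels)))
      msg <- c(msg, "site index out of range")
    off <- object@effort[cbind(object@site[as.vector(row(y))],
                               as.vector(col(y)))] == 0L & as.vector(y) == 1L
    if (any(off)) msg <- c(msg, "detection recorded at a site-year without effort")
  }
  if (length(msg)) msg else TRUE
})

#' Per-class capture and unmarked-capture counts
#'
#' Age x sex x occasion arrays of the number of distinct captured individuals
#' (`C`, the offset of the Poisson immigration regression) and of captured
#' unmarked individuals (`Imm`, its response, defined for occasions 2..T).
#'
#' @slot C integer array [A x 2 x T].
#' @slot Imm integer array [A x 2 x (T-1)], occasions 2..T.
#' @slot occasionLabels character labels for the T occasions.
#' @export
setClass("ClassCounts", representation(
  C = "array", Imm = "array", occasionLabels = "character"),
  prototype(C = array(0L, c(1, 2, 2)), Imm = array(0L, c(1, 2, 1)),
            occasionLabels = c("1", "2")))

setValidity("ClassCounts", function(object) {
  msg <- character(0)
  dC <- dim(object@C); dI <- dim(object@Imm)
  if (length(dC) != 3 || dC[2] != 2) msg <- c(msg, "C must be [A x 2 x T]")
  if (length(dI) != 3 || dI[2] != 2 || dI[1] != dC[1] || dI[3] != dC[3] - 1)
    msg <- c(msg, "Imm must be [A x 2 x (T-1)]")
  if (any(object@C < 0) || any(object@Imm < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg) == 0 && any(object@Imm > object@C[, , -1, drop = FALSE]))
    msg <- c(msg, "Imm[a,s,t] exceeds C[a,s,t]")
  if (length(dC) == 3 && length(object@occasionLabels) != dC[3])
    msg <- c(msg, "occasionLabels length != occasions")
  if (length(msg)) msg else TRUE
})

#' Survival submodel parameters
#'
#' Logit-linear apparent-survival predictor: an age-specific intercept, an
#' age-specific (or shared) female effect, and zero-centered age-, sex-, and
#' time-specific random effects with common standard deviation `sigma`.
#'
#' @slot betaAge numeric(A), logit-scale intercept per age class.
#' @slot betaSex numeric(A) (or numeric(1) when shared), female effect.
#' @slot eps numeric array [A x 2 x (T-1)] of random effects.
#' @slot sigma numeric(1), their standard deviation.
#' @export
setClass("SurvivalModel", representation(
  betaAge = "numeric", betaSex = "numeric", eps = "array", sigma = "numeric"))

setValidity("SurvivalModel", function(object) {
  d <- dim(object@eps); A <- length(object@betaAge)
  msg <- character(0)
  if (length(d) != 3 || d[1] != A || d[2] != 2)
    msg <- c(msg, "eps must be [A x 2 x (T-1)]")
  if (!length(object@betaSex) %in% c(1L, A))
    msg <- c(msg, "betaSex must have length 1 or A")
  if (length(object@sigma) != 1 || object@sigma <= 0)
    msg <- c(msg, "sigma must be a single positive value")
  if (length(msg)) msg else TRUE
})

#' Detection submodel parameters
#'
#' One of the nine candidate recapture-probability structures: "Null", "s"
#' (site effects, sum-to-zero), "b" (permanent behavioral effect after first
#' capture), "t" (occasion fixed effects), "T" (linear trend over occasions),
#' "tRE" (occasion random effects, sd `sigmaT`), "mH" (individual random
#' effects, sd `sigmaMH`), "b+tRE", and "b+mH".  Only the slots belonging to
#' the declared structure may be populated.
#'
#' @slot structure character, one of the nine structure names.
#' @slot intercept numeric(1), logit-scale intercept.
#' @slot siteEffects numeric(S), sum-to-zero site effects ("s").
#' @slot behavior numeric(1), effect after first capture ("b").
#' @slot occEffects numeric(T-1), fixed effects for occasions 2..T, first
#'   entry 0 as reference ("t").
#' @slot trend numeric(1), coefficient on the occasion index centered and
#'   scaled to unit range ("T").
#' @slot occRE numeric(T-1), random effects for occasions 2..T ("tRE").
#' @slot sigmaT numeric(1), sd of `occRE`.
#' @slot indEffects numeric(n), individual random effects ("mH").
#' @slot sigmaMH numeric(1), sd of `indEffects`.
#' @export
setClass("DetectionModel", representation(
  structure = "character", intercept = "numeric", siteEffects = "numeric",
  behavior = "numeric", occEffects = "numeric", trend = "numeric",
  occRE = "numeric", sigmaT = "numeric", indEffects = "numeric",
  sigmaMH = "numeric"),
  prototype(intercept = 0, siteEffects = numeric(0), behavior = numeric(0),
            occEffects = numeric(0), trend = numeric(0), occRE = numeric(0),
            sigmaT = numeric(0), indEffects = numeric(0), sigmaMH = numeric(0)))

setValidity("DetectionModel", function(object) {
  msg <- character(0)
  st <- object@structure
  if (length(st) != 1 || !st %in% DETECTION_STRUCTURES)
    return(sprintf("unknown detection structure '%s'", paste(st, collapse = ",")))
  has <- function(x) length(x) > 0
  allowed <- list(siteEffects = st == "s",
                  behavior = st %in% c("b", "b+tRE", "b+mH"),
                  occEffects = st == "t",
                  trend = st == "T",
                  occRE = st %in% c("tRE", "b+tRE"),
                  sigmaT = st %in% c("tRE", "b+tRE"),
                  indEffects = st %in% c("mH", "b+mH"),
                  sigmaMH = st %in% c("mH", "b+mH"))
  for (nmv in names(allowed))
    if (has(slot(object, nmv)) && !allowed[[nmv]])
      msg <- c(msg, sprintf("slot '%s' is not part of structure '%s'", nmv, st))
  if (has(object@siteEffects) && abs(sum(object@siteEffects)) > 1e-8)
    msg <- c(msg, "siteEffects must sum to zero")
  if (length(msg)) msg else TRUE
})

#' Immigration submodel parameters
#'
#' Log-linear per-capita immigration rate: age-class intercepts, a female
#' effect, and zero-centered occasion random effects with sd `sigmaT`.
#' Rates are defined for occasions 2..T.
#'
#' @slot betaAge numeric(A), log-scale intercept per age class.
#' @slot betaSex numeric(1), female effect (log scale).
#' @slot alpha numeric(T-1), occasion random effects for occasions 2..T.
#' @slot sigmaT numeric(1), their standard deviation.
#' @export
setClass("ImmigrationModel", representation(
  betaAge = "numeric", betaSex = "numeric", alpha = "numeric",
  sigmaT = "numeric"))

setValidity("ImmigrationModel", function(object) {
  msg <- character(0)
  if (length(object@betaSex) != 1) msg <- c(msg, "betaSex must be scalar")
  if (length(object@sigmaT) != 1 || object@sigmaT <= 0)
    msg <- c(msg, "sigmaT must be a single positive value")
  if (length(msg)) msg else TRUE
})

#' Prior specification
#'
#' Two diffuse prior sets used for sensitivity analysis: "prior1" places
#' Normal(0, sd 10) priors on all logit/log-scale coefficients and
#' Uniform(0, 10) priors on standard deviations; "prior2" places
#' Normal(0, sd 1.6) priors on coefficients and Half-Normal(scale 2) priors
#' on standard deviations.
#'
#' @slot name character, "prior1" or "prior2" (or a custom label).
#' @slot coefSd numeric(1), sd of the zero-mean normal coefficient prior.
#' @slot sdFamily character, "uniform" or "halfnormal".
#' @slot sdScale numeric(1), upper bound (uniform) or scale (half-normal).
#' @export
setClass("PriorSet", representation(
  name = "character", coefSd = "numeric", sdFamily = "character",
  sdScale = "numeric"))

setValidity("PriorSet", function(object) {
  msg <- character(0)
  if (object@coefSd <= 0 || object@sdScale <= 0)
    msg <- c(msg, "prior scales must be positive")
  if (!object@sdFamily %in% c("uniform", "halfnormal"))
    msg <- c(msg, "sdFamily must be 'uniform' or 'halfnormal'")
  if (length(msg)) msg else TRUE
})

#' Posterior sample from a joint survival + immigration fit
#'
#' @slot draws list of per-chain matrices (kept iterations x parameters);
#'   columns include raw coefficients, the derived apparent-survival cells
#'   `phi[a,s,t]`, and (when class counts were supplied) immigration
#'   parameters and derived rates `I[a,s,t]`.
#' @slot summary data.frame with posterior mean and equal-tailed 95% credible
#'   interval per parameter.
#' @slot rhat named numeric vector of potential scale reduction factors.
#' @slot pointwise numeric matrix (all kept draws x individuals) of pointwise
#'   capture-history log-likelihoods, the input to WAIC.
#' @slot settings list of sampler settings (structure, chains, iterations,
#'   burn-in, thinning, seed, prior set, sex-by-age flag).
#' @export
setClass("PosteriorResult", representation(
  draws = "list", summary = "data.frame", rhat = "numeric",
  pointwise = "matrix", settings = "list"))

#' WAIC comparison across detection structures
#'
#' @slot table data.frame with columns model, waic, lppd, pWaic, deltaWaic,
#'   lower, upper, weight (sorted by WAIC; lower/upper bound the 95% interval
#'   of the WAIC difference from the top model).
#' @slot pointwise named list of per-individual WAIC contributions per model.
#' @slot fits named list of `PosteriorResult` objects (possibly empty).
#' @export
setClass("ModelComparison", representation(
  table = "data.frame", pointwise = "list", fits = "list"))

#' Site fidelity and emigration-adjusted survival
#'
#' Draw-wise derived quantities: emigration over interval t..t+1 equals the
#' fitted immigration rate at occasion t+1, site fidelity r is its complement,
#' adjusted survival is apparent survival divided by r, and Delta is the
#' adjustment.  Cells with immigration rate >= 1 are clamped to a fidelity
#' floor and flagged; adjusted survival above 1 is retained but flagged.
#'
#' @slot table data.frame with one row per (age, sex, interval) cell and
#'   posterior mean / 95% CI columns for phi, I, r, phiAdjusted and delta,
#'   plus a flag column.
#' @slot floor numeric(1), fidelity floor used when clamping.
#' @export
setClass("AdjustedSurvival", representation(
  table = "data.frame", floor = "numeric"))

#' Posterior-predictive check result
#'
#' @slot observed numeric vector of the chi-squared discrepancy of the
#'   observed individual capture totals, one value per posterior draw used.
#' @slot replicated numeric vector of the same discrepancy computed on data
#'   replicated under each draw.
#' @slot bayesianP numeric(1), proportion of draws with replicated >
#'   observed (ties counted 0.5).
#' @export
setClass("PPCResult", representation(
  observed = "numeric", replicated = "numeric", bayesianP = "numeric"))

#' Simulation configuration
#'
#' Ground-truth parameterization of the open-population generator: per-cell
#' apparent-survival components (true survival `phi` and per-interval
#' emigration probability), expected immigrant arrivals per class-occasion,
#' a detection structure with true parameters, initial cohort sizes, and the
#' trapping-effort mask.
#'
#' @slot nSites integer.
#' @slot nOccasions integer.
#' @slot nAgeClasses integer.
#' @slot phi numeric array [A x 2 x (T-1)], true survival per interval.
#' @slot emigration numeric array [A x 2 x (T-1)], per-interval emigration
#'   probability given survival.
#' @slot immigrationMean numeric array [A x 2 x (T-1)], expected immigrant
#'   arrivals at occasions 2..T per class.
#' @slot detection list describing the true detection process: `structure`
#'   plus the structure's parameters (intercept, behavior, sigmaT, sigmaMH,
#'   siteEffects, occEffects, trend).
#' @slot initialCohort numeric matrix [A x 2] of per-site initial individuals.
#' @slot effort integer matrix [S x T].
#' @slot immigrationMode character, "tally" (unmarked-capture counts tallied
#'   from the capture records) or "matched" (counts drawn from the Poisson
#'   submodel with rate equal to emigration, so flows balance exactly).
#' @slot occasionLabels character.
#' @export
setClass("SimulationConfig", representation(
  nSites = "integer", nOccasions = "integer", nAgeClasses = "integer",
  phi = "array", emigration = "array", immigrationMean = "array",
  detection = "list", initialCohort = "matrix", effort = "matrix",
  immigrationMode = "character", occasionLabels = "character"))

setValidity("SimulationConfig", function(object) {
  A <- object@nAgeClasses; T <- object@nOccasions
  d <- c(A, 2L, T - 1L)
  msg <- character(0)
  for (nmv in c("phi", "emigration", "immigrationMean"))
    if (!all(dim(slot(object, nmv)) == d))
      msg <- c(msg, sprintf("%s must be [A x 2 x (T-1)]", nmv))
  if (any(object@phi < 0 | object@phi > 1) ||
      any(object@emigration < 0 | object@emigration > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (any(object@immigrationMean < 0))
    msg <- c(msg, "immigrationMean must be non-negative")
  if (length(object@detection$structure) != 1 ||
      !object@detection$structure %in% DETECTION_STRUCTURES)
    msg <- c(msg, "unknown detection structure")
  if (!all(dim(object@initialCohort) == c(A, 2L)))
    msg <- c(msg, "initialCohort must be [A x 2]")
  if (!all(dim(object@effort) == c(object@nSites, T)))
    msg <- c(msg, "effort must be [S x T]")
  if (!object@immigrationMode %in% c("tally", "matched"))
    msg <- c(msg, "immigrationMode must be 'tally' or 'matched'")
  if (length(msg)) msg else TRUE
})

#' Simulation ground truth
#'
#' @slot z integer matrix (all simulated individuals x occasions), 1 while
#'   alive and present; departure (death or emigration) is absorbing.
#' @slot events data.frame with one row per simulated individual: entry
#'   occasion, entry age, sex, site, fate ("alive", "died", "emigrated"),
#'   fate occasion, immigrant flag, captured flag, and the row index in the
#'   returned `CaptureDataset` (NA if never captured).
#' @slot config the `SimulationConfig` used.
#' @slot detectionTruth list of realized detection random effects.
#' @export
setClass("SimulationTruth", representation(
  z = "matrix", events = "data.frame", config = "SimulationConfig",
  detectionTruth = "list"))
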