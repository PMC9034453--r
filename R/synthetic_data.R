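#' Build a simulation configuration
#'
#' Defaults emulate the field study the package is designed around: 9 sites
#' trapped over 9 annual occasions, three age classes, moderate survival with
#' some temporal spread, low emigration, a steady trickle of immigrant
#' arrivals, and an intercept-only detection process.  Scalars are recycled
#' into the full [A x 2 x (T-1)] arrays.
#'
#' @param nSites,nOccasions,nAgeClasses study dimensions.
#' @param phi true per-interval survival (scalar or [A x 2 x (T-1)] array).
#' @param emigration per-interval emigration probability given survival
#'   (scalar or array).
#' @param immigrationMean expected immigrant arrivals per class at occasions
#'   2..T (scalar or array).
#' @param detection list with `structure` and the structure's true
#'   parameters; time-varying parameters (`occEffects`, `occRE` are drawn at
#'   simulation time when `sigmaT` is given) cover all T occasions.
#' @param initialCohort per-site initial individuals per age x sex cell
#'   (scalar or [A x 2] matrix).
#' @param effort sites x occasions 0/1 mask (default all 1).
#' @param immigrationMode "tally" or "matched" (see
#'   [SimulationConfig-class]).
#' @param occasionLabels occasion labels, default years from 2011.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(nSites = 9, nOccasions = 9, nAgeClasses = 3,
                             phi = 0.6, emigration = 0.1,
                             immigrationMean = 2,
                             detection = list(structure = "Null", intercept = 0.5),
                             initialCohort = 8, effort = NULL,
                             immigrationMode = "tally",
                             occasionLabels = NULL) {
  A <- as.integer(nAgeClasses); T <- as.integer(nOccasions)
  S <- as.integer(nSites)
  expand <- function(x) {
    if (length(x) == 1) array(x, c(A, 2, T - 1)) else x
  }
  if (length(initialCohort) == 1) initialCohort <- matrix(initialCohort, A, 2)
  if (is.null(effort)) effort <- matrix(1L, S, T)
  storage.mode(effort) <- "integer"
  if (is.null(occasionLabels)) occasionLabels <- as.character(2010 + seq_len(T))
  new("SimulationConfig", nSites = S, nOccasions = T, nAgeClasses = A,
      phi = expand(phi), emigration = expand(emigration),
      immigrationMean = expand(immigrationMean), detection = detection,
      initialCohort = initialCohort, effort = effort,
      immigrationMode = immigrationMode,
      occasionLabels = as.character(occasionLabels))
}

# Detection linear predictor used by the generator.  Time-varying terms are
# defined for every occasion (unlike the fitted model, the generator also
# detects individuals before their first capture, which is what makes f_i
# random and gives the behavioral effect something to act on).
simDetectionProb <- function(cfg, det, i, t, capturedBefore) {
  d <- cfg@detection
  lp <- d$intercept
  st <- d$structure
  if (st == "s") lp <- lp + d$siteEffects[det$site[i]]
  if (st %in% c("b", "b+tRE", "b+mH")) lp <- lp + d$behavior * capturedBefore
  if (st == "t") lp <- lp + det$occEffects[t]
  if (st == "T") lp <- lp + d$trend * (t - (cfg@nOccasions + 1) / 2) / (cfg@nOccasions - 1)
  if (st %in% c("tRE", "b+tRE")) lp <- lp + det$gamma[t]
  if (st %in% c("mH", "b+mH")) lp <- lp + det$eta[i]
  1 / (1 + exp(-lp))
}

#' Simulate an open mark-recapture population with known truth
#'
#' Individuals enter either in the initial cohorts (occasion 1) or as
#' Poisson-distributed immigrant arrivals at occasions 2..T assigned to sites
#' uniformly at random.  Each alive-and-present individual survives an
#' interval with probability `phi`, and a survivor permanently emigrates with
#' probability `emigration`; death and emigration are both absorbing and
#' indistinguishable in the capture record (the confounding under study),
#' but the truth records which occurred.  Ages advance deterministically to
#' the terminal class.  Detections are drawn from the configured structure
#' whenever the individual is present and the site was trapped; the first
#' detection defines the first-capture occasion.  Never-captured individuals
#' are dropped from the returned dataset but retained in the truth.
#'
#' @param cfg a [SimulationConfig-class].
#' @param seed integer seed; identical seeds give identical output.
#' @return list with elements `dataset` ([CaptureDataset-class]), `counts`
#'   ([ClassCounts-class]) and `truth` ([SimulationTruth-class]).
#' @export
simulatePopulation <- function(cfg, seed = 1) {
  set.seed(seed)
  A <- cfg@nAgeClasses; T <- cfg@nOccasions; S <- cfg@nSites
  entry <- integer(0); entryAge <- integer(0); sex <- integer(0); site <- integer(0)
  immig <- logical(0)
  for (s0 in 1:2) for (a in 1:A) {
    k <- cfg@initialCohort[a, s0] * S
    if (k > 0) {
      entry <- c(entry, rep(1L, k)); entryAge <- c(entryAge, rep(a, k))
      sex <- c(sex, rep(s0 - 1L, k))
      site <- c(site, rep(seq_len(S), each = cfg@initialCohort[a, s0]))
      immig <- c(immig, rep(FALSE, k))
    }
  }
  for (t in 2:T) for (s0 in 1:2) for (a in 1:A) {
    k <- rpois(1, cfg@immigrationMean[a, s0, t - 1])
    if (k > 0) {
      entry <- c(entry, rep(t, k)); entryAge <- c(entryAge, rep(a, k))
      sex <- c(sex, rep(s0 - 1L, k))
      site <- c(site, sample.int(S, k, replace = TRUE))
      immig <- c(immig, rep(TRUE, k))
    }
  }
  N <- length(entry)
  d <- cfg@detection
  det <- list(site = site)
  if (d$structure %in% c("mH", "b+mH"))
    det$eta <- rnorm(N, 0, d$sigmaMH)
  if (d$structure %in% c("tRE", "b+tRE"))
    det$gamma <- rnorm(T, 0, d$sigmaT)
  if (d$structure == "t")
    det$occEffects <- if (!is.null(d$occEffects)) d$occEffects else rep(0, T)

  z <- matrix(0L, N, T)
  y <- matrix(0L, N, T)
  fate <- rep("alive", N); fateOcc <- rep(NA_integer_, N)
  for (i in seq_len(N)) {
    z[i, entry[i]] <- 1L
    if (entry[i] < T) for (t in entry[i]:(T - 1)) {
      if (z[i, t] == 0L) break
      a <- min(entryAge[i] + t - entry[i], A)
      s1 <- sex[i] + 1L
      if (runif(1) > cfg@phi[a, s1, t]) { fate[i] <- "died"; fateOcc[i] <- t + 1L; break }
      if (runif(1) < cfg@emigration[a, s1, t]) {
        fate[i] <- "emigrated"; fateOcc[i] <- t + 1L; break
      }
      z[i, t + 1] <- 1L
    }
    capturedBefore <- 0L
    for (t in entry[i]:T) {
      if (z[i, t] == 1L && cfg@effort[site[i], t] == 1L) {
        p <- simDetectionProb(cfg, det, i, t, capturedBefore)
        if (runif(1) < p) { y[i, t] <- 1L; capturedBefore <- 1L }
      }
    }
  }

  captured <- rowSums(y) > 0
  f <- ifelse(captured, apply(y == 1L, 1, which.max), NA_integer_)
  ageAtF <- ifelse(captured, pmin(entryAge + f - entry, A), NA_integer_)
  ds <- captureDataset(y[captured, , drop = FALSE], site[captured],
                       sex[captured], ageAtF[captured], A,
                       occasionLabels = cfg@occasionLabels,
                       siteLevels = as.character(seq_len(S)),
                       effort = cfg@effort)
  counts <- computeClassCounts(ds)
  if (cfg@immigrationMode == "matched") {
    Imm <- counts@Imm
    for (t in 2:T) for (s1 in 1:2) for (a in 1:A) {
      lam <- counts@C[a, s1, t] * cfg@emigration[a, s1, t - 1]
      Imm[a, s1, t - 1] <- min(rpois(1, lam), counts@C[a, s1, t])
    }
    counts <- classCounts(counts@C, Imm, cfg@occasionLabels)
  }
  dsRow <- rep(NA_integer_, N)
  dsRow[captured] <- seq_len(sum(captured))
  events <- data.frame(id = seq_len(N), entry = entry, entryAge = entryAge,
                       sex = sex, site = site, fate = fate, fateOcc = fateOcc,
                       immigrant = immig, captured = captured,
                       datasetRow = dsRow, stringsAsFactors = FALSE)
  truth <- new("SimulationTruth", z = z, events = events, config = cfg,
               detectionTruth = det)
  list(dataset = ds, counts = counts, truth = truth)
}

#' Apparent-survival truth of a simulation
#'
#' The estimand the CJS stage targets is the probability of surviving AND
#' remaining: `phi x (1 - emigration)` per age x sex x interval cell.
#'
#' @param truth a [SimulationTruth-class].
#' @return numeric array [A x 2 x (T-1)].
#' @export
truthApparentSurvival <- function(truth) {
  truth@config@phi * (1 - truth@config@emigration)
}

#' Realized per-interval stay rates
#'
#' Empirical fraction of individuals alive and present at t that are still
#' alive and present at t+1, per age x sex x interval cell, with the at-risk
#' counts (for Monte-Carlo standard errors).
#'
#' @param truth a [SimulationTruth-class].
#' @return list with arrays `rate` and `atRisk`, each [A x 2 x (T-1)].
#' @export
realizedSurvival <- function(truth) {
  cfg <- truth@config
  A <- cfg@nAgeClasses; T <- cfg@nOccasions
  ev <- truth@events
  rate <- atRisk <- stay <- array(0, c(A, 2, T - 1))
  for (i in seq_len(nrow(truth@z))) {
    for (t in seq_len(T - 1)) {
      if (truth@z[i, t] == 1L) {
        a <- min(ev$entryAge[i] + t - ev$entry[i], A)
        s1 <- ev$sex[i] + 1L
        atRisk[a, s1, t] <- atRisk[a, s1, t] + 1
        stay[a, s1, t] <- stay[a, s1, t] + truth@z[i, t + 1]
      }
    }
  }
  rate <- ifelse(atRisk > 0, stay / atRisk, NA)
  list(rate = rate, atRisk = atRisk)
}

setMethod("show", "SimulationTruth", function(object) {
  ev <- object@events
  cat(sprintf("SimulationTruth: %d simulated individuals over %d occasions\n",
              nrow(object@z), ncol(object@z)))
  cat(sprintf("  captured %d; immigrants %d; died %d; emigrated %d\n",
              sum(ev$captured), sum(ev$immigrant), sum(ev$fate == "died"),
              sum(ev$fate == "emigrated")))
})
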