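invlogit <- function(x) 1 / (1 + exp(-x))

#' Deterministic age progression
#'
#' Age class advances by one per annual step from the class at first capture
#' and is capped at the terminal class A.  Occasions before first capture are
#' NA (the CJS likelihood conditions on first capture).
#'
#' @param ageAtFirst age class at first capture (1..A).
#' @param f first-capture occasion.
#' @param T number of occasions.
#' @param A number of age classes.
#' @return integer vector of length T of per-occasion age classes.
#' @export
ageTrajectory <- function(ageAtFirst, f, T, A) {
  if (ageAtFirst < 1 || ageAtFirst > A) stop("invalid age class at first capture")
  out <- rep(NA_integer_, T)
  out[f:T] <- pmin(ageAtFirst + (f:T) - f, A)
  out
}

#' Construct a survival submodel
#'
#' @param betaAge numeric(A), logit-scale age-class intercepts.
#' @param betaSex numeric(A) or numeric(1), female effect per age class (or a
#'   single shared effect).
#' @param eps array [A x 2 x (T-1)] of zero-centered random effects; defaults
#'   to all zero when `T` is given.
#' @param sigma their standard deviation.
#' @param T number of occasions (used only to shape a default `eps`).
#' @return a [SurvivalModel-class].
#' @export
survivalModel <- function(betaAge, betaSex, eps = NULL, sigma = 1, T = NULL) {
  A <- length(betaAge)
  if (is.null(eps)) {
    if (is.null(T)) stop("supply eps or T")
    eps <- array(0, c(A, 2, T - 1))
  }
  new("SurvivalModel", betaAge = betaAge, betaSex = betaSex, eps = eps,
      sigma = sigma)
}

#' Apparent survival probability for one cell
#'
#' Inverse-logit of the survival linear predictor
#' `beta_age[a] + beta_sex[a] * sex + eps[a, s, t]` for interval t -> t+1.
#'
#' @param age age class during the interval.
#' @param sex 0 = male, 1 = female.
#' @param t interval index (1..T-1).
#' @param m a [SurvivalModel-class].
#' @return probability in (0, 1).
#' @export
survivalProb <- function(age, sex, t, m) {
  bsex <- if (length(m@betaSex) == 1) m@betaSex else m@betaSex[age]
  invlogit(m@betaAge[age] + bsex * sex + m@eps[age, sex + 1, t])
}

#' Construct a detection submodel
#'
#' @param structure one of `"Null"`, `"s"`, `"b"`, `"t"`, `"T"`, `"tRE"`,
#'   `"mH"`, `"b+tRE"`, `"b+mH"`.
#' @param intercept logit-scale intercept.
#' @param ... the structure's parameters (`siteEffects`, `behavior`,
#'   `occEffects`, `trend`, `occRE`, `sigmaT`, `indEffects`, `sigmaMH`).
#' @return a [DetectionModel-class].
#' @export
detectionModel <- function(structure, intercept = 0, ...) {
  new("DetectionModel", structure = structure, intercept = intercept, ...)
}

#' Recapture probability for one individual-occasion
#'
#' Inverse-logit of the declared structure's linear predictor.  The
#' behavioral effect applies at occasions after the individual's first
#' capture (in a CJS likelihood conditioned on first capture this is every
#' modeled occasion); the trend covariate is the occasion index centered and
#' scaled to unit range.
#'
#' @param recaptured 0/1, whether the individual was captured before occasion
#'   `t` (the behavioral indicator).
#' @param site site index of the individual.
#' @param t occasion index (2..T).
#' @param individual individual index (for `indEffects`).
#' @param d a [DetectionModel-class].
#' @param T total number of occasions (needed for the trend covariate).
#' @return probability in (0, 1).
#' @export
detectionProb <- function(recaptured, site, t, individual, d, T) {
  lp <- d@intercept
  st <- d@structure
  if (st == "s") {
    if (length(d@siteEffects) < site) stop("siteEffects too short for site index")
    lp <- lp + d@siteEffects[site]
  }
  if (st %in% c("b", "b+tRE", "b+mH")) {
    if (length(d@behavior) != 1) stop("structure includes 'b' but behavior unset")
    lp <- lp + d@behavior * recaptured
  }
  if (st == "t") lp <- lp + d@occEffects[t - 1]
  if (st == "T") lp <- lp + d@trend * (t - (T + 1) / 2) / (T - 1)
  if (st %in% c("tRE", "b+tRE")) lp <- lp + d@occRE[t - 1]
  if (st %in% c("mH", "b+mH")) lp <- lp + d@indEffects[individual]
  invlogit(lp)
}

#' Marginal log-likelihood of one capture history
#'
#' Log-probability of a binary history conditional on release at the first
#' capture, with the latent alive states summed out by the backward chi
#' recursion: chi_T = 1, chi_t = (1 - phi_t) + phi_t (1 - p_{t+1}) chi_{t+1};
#' between detections each interval contributes phi_t p_{t+1} (detected) or
#' phi_t (1 - p_{t+1}) (alive, undetected), and the terminal chi absorbs
#' death/emigration after the last detection.
#'
#' @param y binary vector of length T with `y[f] == 1`.
#' @param f first-capture occasion.
#' @param phi per-interval survival, length T-1 (entries before f ignored).
#' @param p per-occasion detection, length T (entries at or before f ignored).
#' @return the log-probability.
#' @export
historyLoglik <- function(y, f, phi, p) {
  cpp_history_loglik(as.integer(y), as.integer(f), as.numeric(phi),
                     as.numeric(p))
}

#' Dataset log-likelihood under explicit survival and detection models
#'
#' Sums [historyLoglik()] over the individuals of a filtered dataset; the
#' pointwise per-individual vector is the unit of the WAIC computation.
#'
#' @param ds a [CaptureDataset-class] with all `f < T`.
#' @param m a [SurvivalModel-class].
#' @param d a [DetectionModel-class].
#' @return list with `total` and `pointwise` (ordered as the individuals).
#' @export
datasetLoglik <- function(ds, m, d) {
  T <- nOccasions(ds); n <- nIndividuals(ds); A <- nAgeClasses(ds)
  if (any(ds@f >= T)) stop("filter the dataset first (all f must be < T)")
  if (dim(m@eps)[3] != T - 1) stop("survival model eps does not match occasions")
  pw <- numeric(n)
  for (i in seq_len(n)) {
    ages <- ageTrajectory(ds@ageAtFirst[i], ds@f[i], T, A)
    phi <- numeric(T - 1)
    for (t in ds@f[i]:(T - 1)) phi[t] <- survivalProb(ages[t], ds@sex[i], t, m)
    p <- numeric(T)
    for (t in (ds@f[i] + 1):T) {
      p[t] <- if (ds@effort[ds@site[i], t] == 0L) 0 else
        detectionProb(1, ds@site[i], t, i, d, T)
    }
    pw[i] <- historyLoglik(ds@y[i, ], ds@f[i], phi, p)
  }
  list(total = sum(pw), pointwise = pw)
}
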