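# Shared fixtures and independent oracles, built in code.

# Exhaustive latent-path enumeration oracle for the CJS marginal likelihood:
# sums the joint probability of (z, y) over every admissible latent alive
# sequence.  Deliberately brute force and independent of the chi recursion.
enumHistoryLoglik <- function(y, f, phi, p) {
  T <- length(y)
  if (f == T) return(0)
  tail <- (f + 1):T
  tot <- 0
  for (code in 0:(2^length(tail) - 1)) {
    z <- c(rep(1L, f), as.integer(intToBits(code))[seq_along(tail)])
    pr <- 1
    ok <- TRUE
    for (t in f:(T - 1)) {
      pr <- pr * if (z[t + 1] == 1) z[t] * phi[t] else 1 - z[t] * phi[t]
      if (z[t] == 0 && z[t + 1] == 1) { ok <- FALSE; break }
    }
    if (!ok) next
    for (t in tail) pr <- pr * if (y[t] == 1) z[t] * p[t] else 1 - z[t] * p[t]
    tot <- tot + pr
  }
  log(tot)
}

# small hand-built dataset: 4 individuals, 4 occasions, 2 sites
toyDataset <- function() {
  y <- rbind(c(1, 1, 0, 1),
             c(0, 1, 1, 0),
             c(1, 0, 0, 0),
             c(0, 0, 1, 1))
  captureDataset(y, site = c(1, 1, 2, 2), sex = c(0, 1, 0, 1),
                 ageAtFirst = c(1, 2, 3, 1), nAgeClasses = 3,
                 occasionLabels = 2011:2014)
}

# survival truth drawn from the hierarchical model itself (so that Bayesian
# coverage statements are meaningful), with fixed structural coefficients
hierTruth <- function(A, T, betaAge, betaSex, sigma) {
  eps <- array(rnorm(A * 2 * (T - 1), 0, sigma), c(A, 2, T - 1))
  phi <- array(NA_real_, c(A, 2, T - 1))
  for (a in seq_len(A)) for (s in 0:1) for (t in seq_len(T - 1))
    phi[a, s + 1, t] <- stats::plogis(betaAge[a] + betaSex[a] * s + eps[a, s + 1, t])
  phi
}

# straightforward WAIC reimplementation (log-sum-exp free; used as oracle)
waicOracle <- function(pw) {
  nD <- nrow(pw)
  lppd <- pW <- numeric(ncol(pw))
  for (i in seq_len(ncol(pw))) {
    lppd[i] <- log(sum(exp(pw[, i])) / nD)
    pW[i] <- sum((pw[, i] - mean(pw[, i]))^2) / (nD - 1)
  }
  list(waic = -2 * sum(lppd - pW), lppd = sum(lppd), pWaic = sum(pW),
       pointwise = -2 * (lppd - pW))
}

quietFilter <- function(ds) suppressMessages(filterForSurvival(ds))
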