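test_that("age trajectories advance one class per year and cap at the terminal class", {
  expect_equal(ageTrajectory(1, 1, 4, 3), c(1L, 2L, 3L, 3L))
  expect_equal(ageTrajectory(3, 2, 4, 3), c(NA, 3L, 3L, 3L))
  expect_equal(ageTrajectory(1, 1, 4, 2), c(1L, 2L, 2L, 2L))
  expect_error(ageTrajectory(4, 1, 4, 3), "invalid age")
})

test_that("survival probabilities follow the logit-linear predictor", {
  m0 <- survivalModel(betaAge = c(0, 0, 0), betaSex = c(0, 0, 0), sigma = 1, T = 4)
  expect_equal(survivalProb(1, 0, 1, m0), 0.5)
  m1 <- survivalModel(betaAge = c(1, 0, 0), betaSex = c(0, 0, 0), sigma = 1, T = 4)
  expect_equal(survivalProb(1, 0, 1, m1), plogis(1), tolerance = 1e-12)
  eps <- array(0, c(3, 2, 3)); eps[2, 2, 1] <- 0.2
  m2 <- survivalModel(betaAge = c(0, 0, 0), betaSex = c(0, -0.5, 0), eps = eps,
                      sigma = 1)
  expect_equal(survivalProb(2, 1, 1, m2), plogis(-0.3), tolerance = 1e-12)
})

test_that("detection probabilities follow each structure's predictor", {
  expect_equal(detectionProb(1, 1, 2, 1, detectionModel("Null"), 4), 0.5)
  db <- detectionModel("b", intercept = 0, behavior = 1.2)
  expect_equal(detectionProb(1, 1, 3, 1, db, 4), plogis(1.2), tolerance = 1e-12)
  dm <- detectionModel("mH", intercept = 0, indEffects = c(-2, 0), sigmaMH = 1)
  expect_equal(detectionProb(1, 1, 2, 1, dm, 4), plogis(-2), tolerance = 1e-12)
  dsit <- detectionModel("s", intercept = 0.1, siteEffects = c(0.4, -0.1, -0.3))
  expect_equal(detectionProb(1, 3, 2, 1, dsit, 4), plogis(0.1 - 0.3),
               tolerance = 1e-12)
  dt <- detectionModel("t", intercept = 0, occEffects = c(0, 0.7, 0))
  expect_equal(detectionProb(1, 1, 3, 1, dt, 4), plogis(0.7), tolerance = 1e-12)
  # trend covariate is centered and scaled to unit range
  dT <- detectionModel("T", intercept = 0, trend = 2)
  expect_equal(detectionProb(1, 1, 4, 1, dT, 4), plogis(2 * 0.5),
               tolerance = 1e-12)
  # structure/parameter mismatch is rejected
  expect_error(detectionModel("Null", behavior = 1), "not part of structure")
  expect_error(detectionModel("s", siteEffects = c(1, 1)), "sum to zero")
})

test_that("history log-likelihood matches its closed forms", {
  expect_equal(historyLoglik(c(0, 1), 2, 0.5, c(0, 0)), 0)        # released at T
  expect_equal(historyLoglik(c(1, 1), 1, 0.5, c(0, 0.5)), log(0.25))
  expect_equal(historyLoglik(c(1, 0), 1, 0.5, c(0, 0.5)), log(0.75))
  expect_error(historyLoglik(c(0, 1, 0), 1, c(.5, .5), c(.5, .5, .5)),
               "y\\[f\\]")
})

test_that("history log-likelihood ignores detection before or at first capture", {
  y <- c(0, 1, 0, 1)
  a <- historyLoglik(y, 2, c(.6, .7, .8), c(.1, .2, .3, .4))
  b <- historyLoglik(y, 2, c(.9, .7, .8), c(.9, .9, .3, .4))
  expect_equal(a, b)
})

test_that("marginal likelihood equals latent-path enumeration on random fixtures", {
  set.seed(401)
  for (r in 1:25) {
    T <- sample(2:6, 1); f <- sample(1:(T - 1), 1)
    phi <- runif(T - 1); p <- runif(T)
    y <- integer(T); y[f] <- 1L
    y[(f + 1):T] <- rbinom(T - f, 1, 0.5)
    expect_equal(historyLoglik(y, f, phi, p), enumHistoryLoglik(y, f, phi, p),
                 tolerance = 1e-10)
  }
})

test_that("likelihood of the all-ones history increases with every phi", {
  T <- 5; y <- rep(1L, T)
  p <- rep(0.6, T)
  phi <- rep(0.5, T - 1)
  base <- historyLoglik(y, 1, phi, p)
  for (t in seq_len(T - 1)) {
    up <- phi; up[t] <- 0.6
    expect_gt(historyLoglik(y, 1, up, p), base)
  }
})

test_that("dataset log-likelihood is the sum of per-history terms", {
  ds <- toyDataset()
  ds <- quietFilter(ds)
  m <- survivalModel(betaAge = c(0.2, 0.4, 0.6), betaSex = c(0.1, 0, -0.1),
                     eps = array(rnorm(3 * 2 * 3, 0, 0.3), c(3, 2, 3)), sigma = 0.3)
  d <- detectionModel("Null", intercept = 0.4)
  ll <- datasetLoglik(ds, m, d)
  expect_equal(ll$total, sum(ll$pointwise))
  expect_length(ll$pointwise, nIndividuals(ds))
  # duplicating an individual doubles its contribution
  y2 <- captureHistories(ds)[c(1, 1, 2), ]
  ds2 <- captureDataset(y2, indSite(ds)[c(1, 1, 2)], indSex(ds)[c(1, 1, 2)],
                        ageAtFirst(ds)[c(1, 1, 2)], 3)
  ll2 <- datasetLoglik(ds2, m, d)
  expect_equal(ll2$pointwise[1], ll2$pointwise[2])
  expect_equal(ll2$total, 2 * ll$pointwise[1] + ll$pointwise[2])
  # and the total matches the enumeration oracle history by history
  T <- nOccasions(ds)
  for (i in seq_len(nIndividuals(ds))) {
    ages <- ageTrajectory(ageAtFirst(ds)[i], firstCapture(ds)[i], T, 3)
    phi <- rep(0, T - 1); p <- rep(plogis(0.4), T)
    for (t in firstCapture(ds)[i]:(T - 1))
      phi[t] <- survivalProb(ages[t], indSex(ds)[i], t, m)
    expect_equal(ll$pointwise[i],
                 enumHistoryLoglik(captureHistories(ds)[i, ],
                                   firstCapture(ds)[i], phi, p),
                 tolerance = 1e-10)
  }
})
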