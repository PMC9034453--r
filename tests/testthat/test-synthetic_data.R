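test_that("simulation is reproducible bit for bit under a fixed seed", {
  cfg <- simulationConfig(nSites = 3, nOccasions = 6, nAgeClasses = 2,
                          phi = 0.7, emigration = 0.1, immigrationMean = 2,
                          detection = list(structure = "mH", intercept = 0.3,
                                           sigmaMH = 1),
                          initialCohort = 8)
  a <- simulatePopulation(cfg, seed = 99)
  b <- simulatePopulation(cfg, seed = 99)
  expect_identical(captureHistories(a$dataset), captureHistories(b$dataset))
  expect_identical(a$truth@z, b$truth@z)
  expect_identical(unmarkedCaptures(a$counts), unmarkedCaptures(b$counts))
  c <- simulatePopulation(cfg, seed = 100)
  expect_false(identical(a$truth@z, c$truth@z))
})

test_that("degenerate probabilities give deterministic histories", {
  cfg <- simulationConfig(nSites = 1, nOccasions = 5, nAgeClasses = 2,
                          phi = 1, emigration = 0, immigrationMean = 0,
                          detection = list(structure = "Null", intercept = 50),
                          initialCohort = 5)
  sim <- simulatePopulation(cfg, seed = 1)
  y <- captureHistories(sim$dataset)
  expect_equal(nrow(y), 20)            # 5 per age x sex cell, 2 ages x 2 sexes, 1 site
  expect_true(all(y == 1L))
  expect_true(all(firstCapture(sim$dataset) == 1L))
  kept <- quietFilter(sim$dataset)
  expect_equal(nIndividuals(kept), nrow(y))
})

test_that("the latent state is absorbing and truth structures are consistent", {
  cfg <- simulationConfig(nSites = 4, nOccasions = 7, nAgeClasses = 3,
                          phi = 0.6, emigration = 0.15, immigrationMean = 2,
                          detection = list(structure = "Null", intercept = 0.4),
                          initialCohort = 6)
  sim <- simulatePopulation(cfg, seed = 17)
  z <- sim$truth@z
  # no resurrection: once 0 after entry, always 0
  ev <- sim$truth@events
  for (i in seq_len(nrow(z))) {
    zi <- z[i, ev$entry[i]:ncol(z)]
    expect_true(all(diff(zi) <= 0))
  }
  # generated counts satisfy the ClassCounts invariants (validity ran at
  # construction); Imm tallies first captures at occasions >= 2
  cc <- sim$counts
  expect_true(all(unmarkedCaptures(cc) <= totalCaptures(cc)[, , -1]))
  f <- firstCapture(sim$dataset)
  expect_equal(sum(unmarkedCaptures(cc)), sum(f >= 2))
  # dataset rows map back to truth rows
  expect_equal(sum(ev$captured), nIndividuals(sim$dataset))
  expect_equal(ev$datasetRow[ev$captured], seq_len(nIndividuals(sim$dataset)))
})

test_that("apparent-survival truth is the elementwise product phi * (1 - e)", {
  set.seed(18)
  phi <- array(runif(2 * 2 * 4), c(2, 2, 4))
  e <- array(runif(2 * 2 * 4, 0, 0.5), c(2, 2, 4))
  cfg <- simulationConfig(nSites = 2, nOccasions = 5, nAgeClasses = 2,
                          phi = phi, emigration = e, immigrationMean = 0,
                          detection = list(structure = "Null", intercept = 0),
                          initialCohort = 2)
  sim <- simulatePopulation(cfg, seed = 19)
  expect_equal(truthApparentSurvival(sim$truth), phi * (1 - e))
  expect_equal(truthApparentSurvival(sim$truth)[1, 1, 1],
               phi[1, 1, 1] * (1 - e[1, 1, 1]))
})

test_that("realized interval survival matches the apparent truth within Monte-Carlo error", {
  cfg <- simulationConfig(nSites = 9, nOccasions = 9, nAgeClasses = 2,
                          phi = 0.8, emigration = 0.1, immigrationMean = 2,
                          detection = list(structure = "Null", intercept = 0.4),
                          initialCohort = 16)
  sim <- simulatePopulation(cfg, seed = 20)
  rl <- realizedSurvival(sim$truth)
  atRisk <- sum(rl$atRisk)
  pHat <- weighted.mean(rl$rate, rl$atRisk, na.rm = TRUE)
  se <- sqrt(0.72 * 0.28 / atRisk)
  expect_lt(abs(pHat - 0.8 * 0.9), 3 * se)
})

test_that("matched immigration mode draws counts with rate equal to emigration", {
  cfg <- simulationConfig(nSites = 6, nOccasions = 9, nAgeClasses = 2,
                          phi = 0.75, emigration = 0.2, immigrationMean = 4,
                          detection = list(structure = "Null", intercept = 0.5),
                          initialCohort = 12, immigrationMode = "matched")
  sim <- simulatePopulation(cfg, seed = 21)
  cc <- sim$counts
  expect_true(all(unmarkedCaptures(cc) <= totalCaptures(cc)[, , -1]))
  # empirical per-capita unmarked rate close to e = 0.2
  rate <- sum(unmarkedCaptures(cc)) / sum(totalCaptures(cc)[, , -1])
  expect_lt(abs(rate - 0.2), 3 * sqrt(0.2 / sum(totalCaptures(cc)[, , -1])))
})

test_that("effort masks suppress detections at inactive site-years", {
  effort <- matrix(1L, 3, 6); effort[2, 5:6] <- 0L
  cfg <- simulationConfig(nSites = 3, nOccasions = 6, nAgeClasses = 2,
                          phi = 0.9, emigration = 0, immigrationMean = 1,
                          detection = list(structure = "Null", intercept = 2),
                          initialCohort = 10, effort = effort)
  sim <- simulatePopulation(cfg, seed = 23)
  y <- captureHistories(sim$dataset)
  onSite2 <- indSite(sim$dataset) == 2
  expect_true(all(y[onSite2, 5:6] == 0L))
  expect_gt(sum(y[!onSite2, 5:6]), 0)
})
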