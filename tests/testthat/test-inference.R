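test_that("the potential scale reduction factor behaves at its limits", {
  set.seed(21)
  x <- rnorm(1000)
  # two identical chains: zero between-chain variance
  expect_lt(rhat(cbind(x, x)), 1.001)
  # well-separated chains
  expect_gt(rhat(cbind(rnorm(1000, 0, 1), rnorm(1000, 5, 1))), 1.1)
  # iid chains from the same distribution
  expect_lt(rhat(cbind(rnorm(5000), rnorm(5000), rnorm(5000))), 1.01)
  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
  expect_error(rhat(list(rnorm(10), rnorm(9))), "equal lengths")
})

test_that("posterior summaries are mean plus equal-tailed 95% interval", {
  expect_equal(summarizePosterior(rep(3, 10)),
               c(mean = 3, lower = 3, upper = 3))
  s <- summarizePosterior(1:100)
  expect_equal(unname(s), c(50.5, 3.475, 97.525))
  set.seed(22)
  z <- rnorm(1e5)
  s <- summarizePosterior(z)
  expect_equal(unname(s["lower"]), -1.96, tolerance = 0.02)
  expect_equal(unname(s["upper"]), 1.96, tolerance = 0.02)
  expect_error(summarizePosterior(numeric(0)), "empty")
})

test_that("the two prior sets are genuinely different diffuse families", {
  p1 <- priorSet("prior1"); p2 <- priorSet("prior2")
  expect_equal(p1@coefSd, 10); expect_equal(p1@sdFamily, "uniform")
  expect_equal(p2@coefSd, 1.6); expect_equal(p2@sdFamily, "halfnormal")
})

test_that("degenerate all-recapture data pushes detection and survival to the boundary", {
  # every individual seen at every occasion after first capture
  set.seed(23)
  n <- 60; T <- 5
  f <- sample(1:(T - 1), n, replace = TRUE)
  y <- matrix(0L, n, T)
  for (i in seq_len(n)) y[i, f[i]:T] <- 1L
  ds <- captureDataset(y, rep(1, n), rep(0:1, length.out = n),
                       rep(1, n), 2)
  fit <- fitModel(ds, NULL, "Null", chains = 3, iter = 1500, burn = 800,
                  seed = 5)
  s <- posteriorSummary(fit)
  expect_gt(s$mean[s$parameter == "p_intercept"], 1.5)
  expect_gt(mean(s$mean[grepl("^phi\\[", s$parameter)]), 0.8)
  expect_lt(max(monitoredRhat(fit)), 1.03)
})

test_that("fits are reproducible and validate their inputs", {
  sim <- simulatePopulation(simulationConfig(
    nSites = 2, nOccasions = 5, nAgeClasses = 2, phi = 0.7, emigration = 0,
    immigrationMean = 1, detection = list(structure = "Null", intercept = 0.5),
    initialCohort = 10), seed = 3)
  ds <- quietFilter(sim$dataset)
  f1 <- fitModel(ds, sim$counts, "Null", chains = 2, iter = 400, burn = 200, seed = 7)
  f2 <- fitModel(ds, sim$counts, "Null", chains = 2, iter = 400, burn = 200, seed = 7)
  expect_identical(posteriorSummary(f1), posteriorSummary(f2))
  f3 <- fitModel(ds, NULL, "Null", chains = 2, iter = 400, burn = 200, seed = 8)
  expect_false(identical(posteriorSummary(f1)$mean[1], posteriorSummary(f3)$mean[1]))
  expect_error(fitModel(ds, NULL, "Null", chains = 1), "2 chains")
  expect_error(fitModel(ds, NULL, "bogus"), "unknown detection")
  # unfiltered dataset (individual first caught at T) is rejected
  y <- rbind(c(1, 1, 0), c(0, 0, 1))
  dsu <- captureDataset(y, c(1, 1), c(0, 1), c(1, 1), 2)
  expect_error(fitModel(dsu, NULL, "Null"), "filter")
})

test_that("posterior means agree across the two prior sets on simulated data", {
  sim <- simulatePopulation(simulationConfig(
    nSites = 6, nOccasions = 7, nAgeClasses = 2, phi = 0.65, emigration = 0.05,
    immigrationMean = 3, detection = list(structure = "Null", intercept = 0.6),
    initialCohort = 12), seed = 41)
  ds <- quietFilter(sim$dataset)
  fitA <- fitModel(ds, NULL, "Null", priorSet("prior1"), chains = 2,
                   iter = 1500, burn = 700, seed = 42)
  fitB <- fitModel(ds, NULL, "Null", priorSet("prior2"), chains = 2,
                   iter = 1500, burn = 700, seed = 43)
  phiA <- posteriorSummary(fitA); phiB <- posteriorSummary(fitB)
  ia <- grepl("^phi\\[", phiA$parameter)
  expect_true(all(abs(phiA$mean[ia] - phiB$mean[ia]) < 0.05))
})

test_that("a zero sex effect is detected as such (CI covers 0)", {
  # truth has no sex effect; over a handful of replicates the 95% CI of the
  # sex coefficients should cover 0 nearly always
  covered <- 0; total <- 0
  for (r in 1:5) {
    set.seed(600 + r)
    phi <- hierTruth(2, 7, betaAge = c(0.2, 0.6), betaSex = c(0, 0), sigma = 0.4)
    sim <- simulatePopulation(simulationConfig(
      nSites = 6, nOccasions = 7, nAgeClasses = 2, phi = phi, emigration = 0,
      immigrationMean = 3, detection = list(structure = "Null", intercept = 0.6),
      initialCohort = 12), seed = 700 + r)
    ds <- quietFilter(sim$dataset)
    fit <- fitModel(ds, NULL, "Null", chains = 2, iter = 1200, burn = 600,
                    seed = 800 + r)
    s <- posteriorSummary(fit)
    ib <- grepl("^beta_sex", s$parameter)
    covered <- covered + sum(s$lower[ib] <= 0 & s$upper[ib] >= 0)
    total <- total + sum(ib)
  }
  expect_gte(covered / total, 0.8)
})
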