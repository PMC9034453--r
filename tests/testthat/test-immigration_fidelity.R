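test_that("immigration rates are the exponentiated linear predictor", {
  m <- immigrationModel(betaAge = c(0, 0), betaSex = 0, alpha = rep(0, 3))
  expect_equal(immigrationRate(1, 0, 2, m), 1)
  m2 <- immigrationModel(betaAge = c(0, 0), betaSex = -0.33, alpha = rep(0, 3))
  expect_equal(immigrationRate(1, 1, 2, m2), exp(-0.33), tolerance = 1e-12)
  m3 <- immigrationModel(betaAge = c(-0.13, 0), betaSex = 0,
                         alpha = c(0.5, 0, 0))
  expect_equal(immigrationRate(1, 0, 2, m3), exp(0.37), tolerance = 1e-12)
  expect_error(immigrationRate(1, 0, 1, m), "occasion")
})

test_that("immigration log-likelihood matches Poisson closed forms", {
  # one active cell: C = 10, Imm = 2, I = 0.2 -> mean 2
  C <- array(0L, c(1, 2, 2)); Imm <- array(0L, c(1, 2, 1))
  C[1, 1, 2] <- 10L; Imm[1, 1, 1] <- 2L
  cc <- classCounts(C, Imm)
  m <- immigrationModel(betaAge = log(0.2), betaSex = 0, alpha = 0)
  expect_equal(immigrationLoglik(cc, m), dpois(2, 2, log = TRUE))
  expect_equal(immigrationLoglik(cc, m), log(2 * exp(-2)), tolerance = 1e-12)
  # Imm = 0 contributes -C * I
  Imm0 <- Imm; Imm0[1, 1, 1] <- 0L
  cc0 <- classCounts(C, Imm0)
  expect_equal(immigrationLoglik(cc0, m), -10 * 0.2, tolerance = 1e-12)
  # C = 0 with Imm > 0 is impossible under the model; such an object cannot
  # even be constructed, and the likelihood also guards against corruption
  Cbad <- C; Cbad[1, 1, 2] <- 0L
  expect_error(classCounts(Cbad, Imm), "exceeds")
  ccBad <- cc; ccBad@C[1, 1, 2] <- 0L
  expect_error(immigrationLoglik(ccBad, m), "C = 0")
})

test_that("immigration log-likelihood equals term-by-term summation on a random table", {
  set.seed(55)
  A <- 2; T <- 4
  C <- array(rpois(A * 2 * T, 20), c(A, 2, T))
  m <- immigrationModel(betaAge = c(-1.2, -1.8), betaSex = -0.3,
                        alpha = rnorm(T - 1, 0, 0.4))
  Imm <- array(0L, c(A, 2, T - 1))
  for (t in 2:T) for (s in 0:1) for (a in 1:A)
    Imm[a, s + 1, t - 1] <- min(rpois(1, C[a, s + 1, t] *
                                         immigrationRate(a, s, t, m)),
                                C[a, s + 1, t])
  cc <- classCounts(C, Imm)
  ref <- 0
  for (t in 2:T) for (s in 0:1) for (a in 1:A)
    ref <- ref + dpois(Imm[a, s + 1, t - 1],
                       C[a, s + 1, t] * immigrationRate(a, s, t, m), log = TRUE)
  expect_equal(immigrationLoglik(cc, m), ref, tolerance = 1e-12)
})

test_that("fidelity is the complement of immigration with clamping for rates >= 1", {
  fid <- deriveFidelity(c(0, 0.22, 1.3))
  expect_equal(fid$r, c(1, 0.78, 0.05))
  expect_equal(fid$emigration, c(0, 0.22, 1.3))
  expect_equal(fid$flagged, c(FALSE, FALSE, TRUE))
})

test_that("adjusted survival divides by fidelity and flags values above 1", {
  adj <- adjustSurvival(0.4, 0.8)
  expect_equal(adj$phiAdjusted, 0.5)
  expect_equal(adj$delta, 0.1)
  expect_false(adj$flagged)
  adj1 <- adjustSurvival(0.37, 1)
  expect_equal(adj1$phiAdjusted, 0.37)
  expect_equal(adj1$delta, 0)
  adjHi <- adjustSurvival(0.9, 0.85)
  expect_equal(adjHi$phiAdjusted, 0.9 / 0.85, tolerance = 1e-12)
  expect_true(adjHi$flagged)
  expect_error(adjustSurvival(0.5, -0.1), "non-positive fidelity")
  # flagged (clamped) cells pass through without error
  expect_silent(adjustSurvival(0.5, 0.05, flagged = TRUE))
})

test_that("the adjustment is monotone in the immigration rate and non-negative", {
  Igrid <- seq(0, 0.9, by = 0.1)
  fid <- deriveFidelity(Igrid)
  adj <- adjustSurvival(rep(0.5, length(Igrid)), fid$r, fid$flagged)
  expect_true(all(adj$delta >= 0))
  expect_true(all(diff(adj$delta) > 0))
})

test_that("draw-wise adjustment propagates immigration uncertainty into the CI", {
  set.seed(9)
  nd <- 4000
  phi <- array(plogis(rnorm(nd, 0, 0.3)), c(nd, 1, 2, 1))
  I <- array(exp(rnorm(nd, log(0.25), 0.3)), c(nd, 1, 2, 1))
  fid <- deriveFidelity(I)
  adj <- adjustSurvival(phi, fid$r, fid$flagged)
  ciW <- function(x) diff(quantile(x, c(.025, .975)))
  expect_gte(ciW(adj$phiAdjusted[, 1, 1, 1]), ciW(phi[, 1, 1, 1]))
  # and Delta >= 0 draw-wise wherever fidelity is a true complement
  expect_true(all(adj$delta[!fid$flagged] >= 0))
})
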