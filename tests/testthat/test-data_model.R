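test_that("wide capture tables parse, derive first captures, and round-trip", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("id,site,sex,age,2011,2012,2013,2014",
               "A01,site1,0,1,0,1,1,0",
               "A02,site1,1,2,1,0,0,1",
               "A03,site2,0,3,0,0,1,1"), tmp)
  ds <- readCaptureTable(tmp, nAgeClasses = 3)
  expect_s4_class(ds, "CaptureDataset")
  expect_equal(firstCapture(ds), c(2L, 1L, 3L))
  expect_equal(captureHistories(ds)[1, ], c(0L, 1L, 1L, 0L))
  expect_equal(ageAtFirst(ds), c(1L, 2L, 3L))
  expect_equal(occasionLabels(ds), c("2011", "2012", "2013", "2014"))

  out <- tempfile(fileext = ".csv")
  writeCaptureTable(ds, out)
  ds2 <- readCaptureTable(out, nAgeClasses = 3)
  expect_identical(captureHistories(ds2), captureHistories(ds))
  expect_identical(firstCapture(ds2), firstCapture(ds))
  expect_identical(indSex(ds2), indSex(ds))
  expect_identical(ageAtFirst(ds2), ageAtFirst(ds))
  expect_identical(occasionLabels(ds2), occasionLabels(ds))
})

test_that("long capture tables parse and agree with the wide dialect", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("id,site,sex,age,occasion",
               "A,site1,0,1,2011", "A,site1,0,2,2013",
               "B,site2,1,1,2012", "B,site2,1,2,2013"), tmp)
  ds <- readCaptureTable(tmp, nAgeClasses = 2,
                         occasionLabels = c("2011", "2012", "2013"))
  expect_equal(nIndividuals(ds), 2)
  expect_equal(captureHistories(ds), rbind(c(1L, 0L, 1L), c(0L, 1L, 1L)),
               ignore_attr = TRUE)
  expect_equal(ageAtFirst(ds), c(1L, 1L))
})

test_that("malformed capture tables fail with informative errors", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("id,site,sex,age,2011,2012",
               "A,site1,0,1,0,0"), tmp)
  expect_error(readCaptureTable(tmp, 2), "never captured")

  writeLines(c("id,site,sex,age,2011,2012",
               "A,site1,2,1,1,0"), tmp)
  expect_error(readCaptureTable(tmp, 2), "sex")

  writeLines(c("id,site,sex,age,2011,2012",
               "A,site1,0,4,1,0"), tmp)
  expect_error(readCaptureTable(tmp, 2), "age class")

  writeLines(c("id,site,sex,age,occasion",
               "A,site1,0,2,2012", "A,site1,0,1,2013"), tmp)
  expect_error(readCaptureTable(tmp, 2, occasionLabels = c("2012", "2013")),
               "decreases")

  expect_error(readCaptureTable(tempfile(), 2), "does not exist")
})

test_that("age classifications may only increase", {
  expect_silent(validateAgeMonotonicity(c(1, 2, 3)))
  expect_silent(validateAgeMonotonicity(c(2, 2)))
  expect_error(validateAgeMonotonicity(c(3, 2), individual = "X"),
               "X.*decreases")
})

test_that("capture dataset validity enforces first-capture conditioning", {
  y <- rbind(c(0, 1, 1), c(1, 0, 1))
  expect_s4_class(captureDataset(y, c(1, 1), c(0, 1), c(1, 1), 2), "CaptureDataset")
  # detection before declared first occasion is impossible by construction of
  # f, but a corrupted object must fail validity
  ds <- captureDataset(y, c(1, 1), c(0, 1), c(1, 1), 2)
  dsBad <- ds; dsBad@f <- c(3L, 1L)
  expect_error(validObject(dsBad), "f_i|first")
  dsBad2 <- ds; dsBad2@sex <- c(0L, 2L)
  expect_error(validObject(dsBad2), "sex")
})

test_that("filterForSurvival keeps exactly the pre-final first captures and is idempotent", {
  y <- rbind(c(1, 0, 1, 0), c(0, 1, 1, 0), c(0, 0, 0, 1), c(0, 0, 0, 1),
             c(0, 1, 0, 1))
  ds <- captureDataset(y, rep(1, 5), c(0, 1, 0, 1, 0), rep(1, 5), 2)
  expect_message(kept <- filterForSurvival(ds), "retained 3 of 5")
  expect_equal(nIndividuals(kept), 3)
  expect_true(all(firstCapture(kept) < nOccasions(kept)))
  again <- suppressMessages(filterForSurvival(kept))
  expect_identical(captureHistories(again), captureHistories(kept))

  dsAllLast <- captureDataset(rbind(c(0, 0, 1)), 1, 0, 1, 2)
  expect_warning(suppressMessages(filterForSurvival(dsAllLast)),
                 "no individuals")
})

test_that("class counts match a brute-force tally and the marked/unmarked rule", {
  # 2 juveniles (1 M, 1 F) first caught at t = 2, nothing else at t = 2
  y <- rbind(c(0, 1, 1), c(0, 1, 0), c(1, 0, 1))
  ds <- captureDataset(y, c(1, 1, 1), c(0, 1, 0), c(1, 1, 2), 3,
                       occasionLabels = c("2011", "2012", "2013"))
  cc <- computeClassCounts(ds)
  expect_equal(unmarkedCaptures(cc)[1, 1, 1], 1L)  # juv male at occ 2
  expect_equal(unmarkedCaptures(cc)[1, 2, 1], 1L)  # juv female at occ 2
  # the individual first caught at t = 1 contributes to no Imm cell
  expect_equal(sum(unmarkedCaptures(cc)), 2L)
  expect_equal(totalCaptures(cc)[2, 1, 1], 1L)     # subadult male at occ 1

  # randomized 10-individual set vs an independent per-record enumeration
  set.seed(71)
  T <- 5; n <- 10
  f <- sample(1:T, n, replace = TRUE)
  y <- matrix(0L, n, T)
  for (i in seq_len(n)) {
    y[i, f[i]] <- 1L
    if (f[i] < T) y[i, (f[i] + 1):T] <- rbinom(T - f[i], 1, 0.5)
  }
  sex <- sample(0:1, n, TRUE); age1 <- sample(1:2, n, TRUE)
  ds <- captureDataset(y, rep(1, n), sex, age1, 2)
  cc <- computeClassCounts(ds)
  Cref <- array(0L, c(2, 2, T)); Iref <- array(0L, c(2, 2, T - 1))
  for (i in seq_len(n)) for (t in seq_len(T)) if (y[i, t] == 1L) {
    a <- min(age1[i] + t - f[i], 2)
    Cref[a, sex[i] + 1, t] <- Cref[a, sex[i] + 1, t] + 1L
    if (t == f[i] && t > 1) Iref[a, sex[i] + 1, t - 1] <- Iref[a, sex[i] + 1, t - 1] + 1L
  }
  expect_identical(totalCaptures(cc), Cref)
  expect_identical(unmarkedCaptures(cc), Iref)
  # column sums of C equal distinct individuals captured per occasion
  expect_equal(apply(totalCaptures(cc), 3, sum), colSums(y))
})

test_that("class-count tables round-trip through CSV and enforce Imm <= C", {
  ds <- toyDataset()
  cc <- computeClassCounts(ds)
  tmp <- tempfile(fileext = ".csv")
  writeClassCounts(cc, tmp)
  cc2 <- readClassCounts(tmp)
  expect_identical(totalCaptures(cc2), totalCaptures(cc))
  expect_identical(unmarkedCaptures(cc2), unmarkedCaptures(cc))

  C <- array(1L, c(2, 2, 3)); Imm <- array(2L, c(2, 2, 2))
  expect_error(classCounts(C, Imm), "exceeds")
  expect_error(classCounts(array(-1L, c(2, 2, 3)), array(0L, c(2, 2, 2))),
               "non-negative")
})

test_that("run configuration files parse effort masks", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("n_age_classes: 3",
               "occasion_labels: [2011, 2012, 2013]",
               "effort:",
               "  - [1, 1, 1]",
               "  - [1, 1, 0]"), tmp)
  cfg <- readRunConfig(tmp)
  expect_equal(cfg$n_age_classes, 3)
  expect_equal(dim(cfg$effort), c(2L, 3L))
  expect_equal(cfg$effort[2, 3], 0L)
  expect_error(readRunConfig(tempfile()), "does not exist")
})
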