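test_that("decay correction scales by the elapsed half-lives and round-trips", {
  s <- buildSchedule(c(100, 100))
  tac <- timeActivityCurve(s, c(1, 1), decayCorrected = FALSE)

  ## one half-life elapsed at the first mid-time (50 s)
  out <- decayCorrect(tac, halfLifeS = 50, toTimeS = 0)
  expect_equal(activity(out)[1L], 2)
  expect_true(isDecayCorrected(out))

  ## correcting to a frame's own mid-time leaves that frame unchanged
  one <- timeActivityCurve(buildSchedule(60), 3, decayCorrected = FALSE)
  expect_equal(activity(decayCorrect(one, 1000, toTimeS = 30)), 3)

  rt <- decayUncorrect(decayCorrect(tac, 70), 70)
  expect_equal(activity(rt), activity(tac), tolerance = 1e-12)
  expect_error(decayCorrect(out, 50), "already decay-corrected")
  expect_error(decayUncorrect(tac), "not decay-corrected")
})

test_that("cumulative integral is the zero-anchored trapezoid on mid-times", {
  s <- buildSchedule(c(20, 20, 20))  # mids 10, 30, 50
  const <- timeActivityCurve(s, rep(1, 3))
  expect_equal(cumulativeIntegral(const), midTimes(s) - midTimes(s)[1L] / 2)

  expect_equal(cumulativeIntegral(timeActivityCurve(s, rep(0, 3))), rep(0, 3))

  ## linear activity a*t integrates to a*t^2/2 within 2% on 5-s frames
  a <- 0.01
  fine <- buildSchedule(rep(5, 120))
  lin <- timeActivityCurve(fine, a * midTimes(fine))
  expect_equal(cumulativeIntegral(lin), a * midTimes(fine)^2 / 2,
               tolerance = 0.02)
})

test_that("cumulative integral is monotone for non-negative TACs and additive", {
  s <- simpleSchedule(8)
  t1 <- randomPositiveTAC(s, 11)
  t2 <- randomPositiveTAC(s, 12)
  expect_true(all(diff(cumulativeIntegral(t1)) >= 0))
  both <- timeActivityCurve(s, activity(t1) + activity(t2))
  expect_equal(cumulativeIntegral(both),
               cumulativeIntegral(t1) + cumulativeIntegral(t2))
})

test_that("SUV follows dose-per-weight normalization and its invariances", {
  s <- buildSchedule(c(60, 60))
  m <- subjectMeta("r1", "WT", 5, weightKg = 0.37, injectedDoseMBq = 18.5)
  tac <- timeActivityCurve(s, c(5, 0))
  expect_equal(suv(computeSUV(tac, m)), c(0.1, 0))

  ## simultaneous rescaling of activity and dose cancels
  m2 <- subjectMeta("r1", "WT", 5, weightKg = 0.37, injectedDoseMBq = 3 * 18.5)
  tac3 <- timeActivityCurve(s, 3 * activity(tac))
  expect_equal(suv(computeSUV(tac3, m2)), suv(computeSUV(tac, m)))

  ## negative (noise) activities propagate unclipped
  neg <- timeActivityCurve(s, c(-1, 2))
  expect_equal(suv(computeSUV(neg, m))[1L], -1 / 50)

  expect_error(subjectMeta("x", "WT", 5, 0, 18.5), "weightKg")
  expect_error(subjectMeta("x", "WT", 5, 0.37, -2), "injectedDoseMBq")
  expect_error(subjectMeta("x", "G51D", 5, 0.37, 18.5), "genotype")
})

test_that("SUVr is the elementwise ratio, with dose and weight cancelling", {
  s <- simpleSchedule(4)
  m <- subjectMeta("r1", "WT", 5, 0.37, 18.5)
  str <- randomPositiveTAC(s, 21)
  cer <- randomPositiveTAC(s, 22)
  r <- suvRatio(computeSUV(str, m), computeSUV(cer, m))
  expect_equal(r, activity(str) / activity(cer))
  expect_equal(suvRatio(computeSUV(str, m), computeSUV(str, m)), rep(1, 4))
  two <- computeSUV(timeActivityCurve(s, 2 * activity(cer)), m)
  expect_equal(suvRatio(two, computeSUV(cer, m)), rep(2, 4))

  ## zero reference frames are flagged, not divided
  z <- computeSUV(timeActivityCurve(s, c(0, 1, 1, 1)), m)
  expect_warning(rz <- suvRatio(computeSUV(str, m), z), "not positive")
  expect_true(is.na(rz[1L]) && !any(is.na(rz[-1L])))
})

test_that("pseudo-equilibrium detection finds the flat segment of an SUVr curve", {
  s <- buildSchedule(rep(300, 24))
  expect_equal(unname(findPseudoEquilibrium(rep(2, 24), s)), c(0, 7200))
  ramp <- 0.01 * midTimes(s) / 60  # 0.6/min in SUVr units, far above tolerance
  expect_null(findPseudoEquilibrium(ramp, s, slopeTol = 0.005))

  ## ramp up to 3000 s then flat: the detected window spans the plateau
  suvr <- pmin(midTimes(s), 3000) / 1000
  win <- findPseudoEquilibrium(suvr, s, slopeTol = 0.005)
  expect_equal(unname(win[2L]), 7200)
  expect_gte(win[1L], 2700)  # first fully-flat frame starts at 3000 s
  expect_lte(win[1L], 3300)
})

test_that("TAC CSV export and import round-trip all regions", {
  s <- studyFrameSchedule()
  tacs <- list(left_striatum = randomPositiveTAC(s, 31),
               cerebellum = randomPositiveTAC(s, 32))
  tacs <- lapply(names(tacs), function(nm)
    timeActivityCurve(s, activity(tacs[[nm]]), regionLabel = nm))
  f <- tempfile(fileext = ".csv")
  writeTACs(tacs, "r1", f)
  back <- readTACs(f)
  expect_named(back, c("left_striatum", "cerebellum"))
  expect_equal(activity(back$cerebellum), activity(tacs[[2L]]),
               tolerance = 1e-9)
  expect_equal(frameStarts(schedule(back$left_striatum)), frameStarts(s))
})
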