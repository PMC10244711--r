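test_that("Patlak transform is exact for a linearly accumulating target", {
  s <- buildSchedule(rep(300, 24))
  ref <- timeActivityCurve(s, rep(1, 24), regionLabel = "cerebellum")
  a <- 2e-4; b <- 0.5
  tgt <- timeActivityCurve(s, a * midTimes(s) + b)
  res <- patlakReference(tgt, ref, 600, 3600)
  expect_equal(Ki(res), 60 * a, tolerance = 1e-12)
  expect_equal(graphicalFit(res)@rSquared, 1, tolerance = 1e-12)

  ## proportional curves carry no net trapping: slope 0, intercept = ratio
  prop <- timeActivityCurve(s, 3 * activity(ref))
  res0 <- patlakReference(prop, ref)
  expect_equal(Ki(res0), 0, tolerance = 1e-12)
  expect_equal(graphicalFit(res0)@intercept, 3, tolerance = 1e-12)
})

test_that("Logan transform is exact for proportional curves and self-reference", {
  s <- buildSchedule(rep(300, 24))
  r <- randomPositiveTAC(s, 41)
  for (c0 in c(0.5, 1, 2.5)) {
    tgt <- timeActivityCurve(s, c0 * activity(r))
    res <- loganReference(tgt, r, 1800, 7200)
    expect_equal(DVR(res), c0, tolerance = 1e-10)
    expect_equal(graphicalFit(res)@intercept, 0, tolerance = 1e-8)
    expect_equal(graphicalFit(res)@rSquared, 1, tolerance = 1e-10)
  }
  expect_equal(DVR(loganReference(r, r)), 1, tolerance = 1e-12)
})

test_that("EDVR reduces to Logan on the reference-subtracted curve", {
  s <- buildSchedule(rep(300, 24))
  cer <- randomPositiveTAC(s, 42)
  two <- timeActivityCurve(s, 2 * activity(cer))
  res <- edvr(two, cer)
  expect_equal(EDVR(res), 1, tolerance = 1e-10)
  expect_equal(effectiveTurnover(res), 1, tolerance = 1e-10)
  expect_error(edvr(cer, cer), "no specific binding")
})

test_that("graphical endpoints are invariant under common rescaling of both TACs", {
  sim <- defaultSim()
  for (f in c(0.2, 5)) {
    str2 <- timeActivityCurve(schedule(sim$striatum), f * activity(sim$striatum))
    cer2 <- timeActivityCurve(schedule(sim$cerebellum), f * activity(sim$cerebellum))
    expect_equal(Ki(patlakReference(str2, cer2)),
                 Ki(patlakReference(sim$striatum, sim$cerebellum)),
                 tolerance = 1e-10)
    expect_equal(DVR(loganReference(str2, cer2)),
                 DVR(loganReference(sim$striatum, sim$cerebellum)),
                 tolerance = 1e-10)
    expect_equal(EDVR(edvr(str2, cer2)),
                 EDVR(edvr(sim$striatum, sim$cerebellum)),
                 tolerance = 1e-10)
  }
})

test_that("identity and proportionality hold on random positive curves", {
  s <- buildSchedule(rep(300, 24))
  for (seed in 101:110) {
    r <- randomPositiveTAC(s, seed)
    expect_equal(DVR(loganReference(r, r)), 1, tolerance = 1e-10)
    prop <- timeActivityCurve(s, 1.7 * activity(r))
    expect_equal(Ki(patlakReference(prop, r)), 0, tolerance = 1e-10)
  }
})

test_that("the reference-efflux correction term vanishes for large k2prime", {
  sim <- defaultSim()
  base <- loganReference(sim$striatum, sim$cerebellum)
  huge <- loganReference(sim$striatum, sim$cerebellum, k2PrimePerMin = 1e9)
  expect_equal(DVR(huge), DVR(base), tolerance = 1e-6)
  ## a finite k2prime changes the abscissa and therefore the slope
  finite <- loganReference(sim$striatum, sim$cerebellum, k2PrimePerMin = 0.3)
  expect_false(isTRUE(all.equal(DVR(finite), DVR(base), tolerance = 1e-4)))
  expect_error(loganReference(sim$striatum, sim$cerebellum, k2PrimePerMin = -1),
               "k2PrimePerMin")
})

test_that("fit preconditions are enforced with informative errors", {
  s <- buildSchedule(rep(300, 24))
  r <- randomPositiveTAC(s, 51)
  tgt <- randomPositiveTAC(s, 52)
  ## too narrow a window
  expect_error(patlakReference(tgt, r, 700, 760), "at least 2 frames")
  ## non-positive reference inside the window is named
  bad <- activity(r); bad[10L] <- 0
  badRef <- timeActivityCurve(s, bad)
  expect_error(patlakReference(tgt, badRef, 600, 3600), "frame\\(s\\): 10")
  ## non-positive target inside the Logan window is named
  badT <- activity(tgt); badT[20L] <- -1
  expect_error(loganReference(timeActivityCurve(s, badT), r, 1800, 7200),
               "frame\\(s\\): 20")
  ## schedule mismatch
  other <- randomPositiveTAC(buildSchedule(rep(200, 24)), 53)
  expect_error(patlakReference(tgt, other), "share a frame schedule")
})

test_that("result rows flatten each model with its endpoint", {
  sim <- defaultSim()
  row <- resultRow(edvr(sim$striatum, sim$cerebellum), "r1", "whole_striatum")
  expect_equal(row$model, "edvr")
  expect_equal(row$EDVR, 1 / row$effective_turnover, tolerance = 1e-12)
  expect_true(is.na(row$Ki_per_min))
})
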