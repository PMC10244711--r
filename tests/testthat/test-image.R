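phantomPair <- function(noiseSeed = NULL) {
  s <- buildSchedule(rep(300, 6))
  left <- timeActivityCurve(s, c(1, 3, 5, 6, 6.5, 6.7), "left_striatum")
  right <- timeActivityCurve(s, c(1, 2.5, 4, 5, 5.5, 5.7), "right_striatum")
  cer <- timeActivityCurve(s, c(2, 3, 2.5, 2, 1.8, 1.6), "cerebellum")
  makePhantom(list(left_striatum = left, right_striatum = right,
                   cerebellum = cer),
              centersMm = rbind(c(3, 3, 3), c(9, 3, 3), c(6, 9, 3)),
              radiiMm = c(1.5, 1.5, 2),
              dim = c(30L, 30L, 15L), voxelSizeMm = c(0.4, 0.4, 0.4))
}

test_that("phantom painting and TAC extraction are an exact round trip", {
  ph <- phantomPair()
  truth <- list(left_striatum = c(1, 3, 5, 6, 6.5, 6.7),
                right_striatum = c(1, 2.5, 4, 5, 5.5, 5.7),
                cerebellum = c(2, 3, 2.5, 2, 1.8, 1.6))
  for (lab in names(ph$masks)) {
    got <- extractTAC(ph$image, ph$masks[[lab]])
    expect_equal(activity(got), truth[[lab]], tolerance = 1e-10)
    expect_equal(regionLabel(got), lab)
  }
})

test_that("TAC extraction is the masked per-frame mean", {
  s <- buildSchedule(rep(60, 3))
  vox <- array(7, c(4, 4, 2, 3))
  img <- dynamicImage(vox, c(1, 1, 1), s)
  mask <- regionMask(array(TRUE, c(4, 4, 2)), "all")
  expect_equal(activity(extractTAC(img, mask)), rep(7, 3))

  ## one-voxel mask returns that voxel's time course
  vox[2, 3, 1, ] <- c(1, 2, 3)
  img <- dynamicImage(vox, c(1, 1, 1), s)
  onevox <- array(FALSE, c(4, 4, 2)); onevox[2, 3, 1] <- TRUE
  expect_equal(activity(extractTAC(img, regionMask(onevox, "v"))), c(1, 2, 3))

  ## linearity in the image
  img2 <- dynamicImage(2 * vox + 1, c(1, 1, 1), s)
  expect_equal(activity(extractTAC(img2, mask)),
               2 * activity(extractTAC(img, mask)) + 1)

  expect_error(extractTAC(img, regionMask(array(TRUE, c(3, 3, 2)), "bad")),
               "grids differ")
  expect_error(regionMask(array(FALSE, c(4, 4, 2)), "empty"), "at least one")
})

test_that("frame averaging is duration-weighted over the window", {
  s <- buildSchedule(c(60, 60, 120))
  vox <- array(0, c(2, 2, 1, 3))
  vox[, , , 1] <- 1; vox[, , , 2] <- 3; vox[, , , 3] <- 6
  img <- dynamicImage(vox, c(1, 1, 1), s)
  expect_equal(meanFrameImage(img, 0, 60), array(1, c(2, 2, 1)))
  expect_equal(meanFrameImage(img, 0, 120), array(2, c(2, 2, 1)))
  expect_equal(meanFrameImage(img, 0, 240),
               array((1 * 60 + 3 * 60 + 6 * 120) / 240, c(2, 2, 1)))
  expect_error(meanFrameImage(img, 300, 400), "no frame mid-times")
})

test_that("Gaussian smoothing conserves intensity and reproduces the kernel", {
  vol <- array(0, c(17, 17, 17))
  vol[9, 9, 9] <- 10
  sm <- gaussianSmooth(vol, fwhmMm = 1, voxelSizeMm = c(0.4, 0.4, 0.4))
  expect_equal(sum(sm), 10, tolerance = 1e-6)
  expect_identical(gaussianSmooth(vol, 0, c(0.4, 0.4, 0.4)), vol)

  ## delta response follows the continuous Gaussian with the prescribed sigma:
  ## peak amplitude and per-axis second moment (truncation costs well under 1%)
  sigmaVox <- (1 / (2 * sqrt(2 * log(2)))) / 0.4
  expect_equal(sm[9, 9, 9], 10 * (2 * pi * sigmaVox^2)^(-3 / 2),
               tolerance = 2e-3)
  prof <- apply(sm, 1, sum)
  expect_equal(sum(prof * (seq_len(17) - 9)^2) / sum(prof), sigmaVox^2,
               tolerance = 0.02)

  ## sigma interpretation bypasses the FWHM conversion
  sm2 <- gaussianSmooth(vol, 0.4 * sigmaVox, c(0.4, 0.4, 0.4), kind = "sigma")
  expect_equal(sm2, sm, tolerance = 1e-10)
})

test_that("SUV images normalize the window average by dose per weight", {
  s <- buildSchedule(rep(60, 2))
  img <- dynamicImage(array(5, c(3, 3, 2, 2)), c(0.4, 0.4, 0.4), s)
  m <- subjectMeta("r1", "WT", 5, 0.37, 18.5)
  expect_equal(suvImage(img, m, 0, 120), array(0.1, c(3, 3, 2)))
  m2 <- subjectMeta("r1", "WT", 5, 0.37, 37)
  expect_equal(suvImage(img, m2, 0, 120), array(0.05, c(3, 3, 2)))

  ## pathway consistency: voxel SUV equals TAC-then-SUV within a region
  ph <- phantomPair()
  simg <- suvImage(ph$image, m, 0, 1800)
  tac <- extractTAC(ph$image, ph$masks$cerebellum)
  wts <- frameDurations(schedule(tac))
  suvTac <- sum(suv(computeSUV(tac, m)) * wts) / sum(wts)
  expect_equal(mean(simg[ph$masks$cerebellum@voxels]), suvTac,
               tolerance = 1e-10)
})

test_that("phantom construction rejects overlap and an asymmetric phantom keeps its sign", {
  s <- buildSchedule(rep(300, 6))
  a <- timeActivityCurve(s, rep(1, 6))
  expect_error(makePhantom(list(a = a, b = a),
                           centersMm = rbind(c(3, 3, 3), c(3.5, 3, 3)),
                           radiiMm = c(1, 1), dim = c(20L, 20L, 10L)),
               "overlap")

  ## full pipeline sign check: simulate an asymmetric pair of striatal foci
  sim <- defaultSim(schedule = buildSchedule(rep(300, 24)))
  lkin <- tissueKinetics(0.1, 0.3, 0.03, 0.014)  # faster loss on the left
  left <- simulateRegion(lkin, sim$input, schedule(sim$striatum), "left_striatum")
  right <- sim$striatum
  ph <- makePhantom(list(left_striatum = left, right_striatum = right,
                         cerebellum = sim$cerebellum),
                    centersMm = rbind(c(3, 3, 3), c(9, 3, 3), c(6, 9, 3)),
                    radiiMm = c(1.5, 1.5, 2), dim = c(30L, 30L, 15L))
  eL <- EDVR(edvr(extractTAC(ph$image, ph$masks$left_striatum),
                  extractTAC(ph$image, ph$masks$cerebellum)))
  eR <- EDVR(edvr(extractTAC(ph$image, ph$masks$right_striatum),
                  extractTAC(ph$image, ph$masks$cerebellum)))
  expect_gt(asymmetryIndex(eR, eL), 0)  # left loses tracer faster
})

test_that("dynamic images and masks survive the NIfTI round trip", {
  ph <- phantomPair()
  f <- tempfile(fileext = ".nii.gz")
  writeDynamicImage(ph$image, f)
  back <- readDynamicImage(f)
  expect_equal(back@voxels, ph$image@voxels, tolerance = 1e-6)
  expect_equal(back@voxelSizeMm, ph$image@voxelSizeMm, tolerance = 1e-6)
  expect_equal(frameStarts(schedule(back)), frameStarts(schedule(ph$image)))

  fm <- tempfile(fileext = ".nii.gz")
  writeRegionMask(ph$masks$cerebellum, fm)
  mback <- readRegionMask(fm, "cerebellum")
  expect_identical(mback@voxels, ph$masks$cerebellum@voxels)
})
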