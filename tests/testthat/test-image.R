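test_that("pulsatility segmentation recovers the true lumen and rejects noise", {
  # ROI pulsing at 1.15 Hz, stationary (noiseless) elsewhere
  fs <- makeSineFlow(period = 1 / 1.15, duration = 45, amplitude = 100)
  img <- defaultRenderConfig(backgroundOffset = 0, noiseSd = 0)
  vs <- renderVelocitySeries(fs, img)
  mask <- segmentCsfRoi(vs, c(12, 12))
  expect_identical(maskMatrix(mask), img@roi)
  expect_equal(segmentArea(mask), sum(img@roi) * 4)

  # all-zero series: no pulsatile region anywhere
  vz <- velocityMapSeries(array(0, dim = c(8, 8, 100)), 2, 0.096, 5)
  expect_error(segmentCsfRoi(vz, c(4, 4)), "no pulsatile region")

  # seed on noise-only stationary tissue: error, never a spurious mask
  set.seed(11)
  vn <- velocityMapSeries(array(rnorm(8 * 8 * 400, sd = 0.1),
                                dim = c(8, 8, 400)), 2, 0.096, 5)
  expect_error(segmentCsfRoi(vn, c(4, 4)), "no pulsatile region")

  # mask invariant to a constant velocity offset (mean-removed spectra)
  vsOff <- velocityMapSeries(velocityFrames(vs) + 0.7, 2,
                             frameInterval(vs), venc(vs))
  expect_identical(maskMatrix(segmentCsfRoi(vsOff, c(12, 12))),
                   maskMatrix(mask))
})

test_that("stationary ring recovers the background offset", {
  fs <- makeSineFlow(period = 0.9, duration = 45, amplitude = 100)
  img <- defaultRenderConfig(backgroundOffset = 0.3, noiseSd = 0)
  vs <- renderVelocitySeries(fs, img)
  mask <- new("SegmentationMask", mask = img@roi, pixelSpacing = 2)
  st <- selectStationaryRegion(vs, mask)
  expect_equal(st@referenceVelocity, 0.3, tolerance = 1e-6)
  expect_false(any(st@region & img@roi))     # disjoint from the lumen

  img0 <- defaultRenderConfig(backgroundOffset = 0, noiseSd = 0)
  vs0 <- renderVelocitySeries(fs, img0)
  expect_equal(selectStationaryRegion(vs0, mask)@referenceVelocity, 0,
               tolerance = 1e-9)
  expect_error(selectStationaryRegion(vs, mask, ringWidth = 0), "ring")
})

test_that("background correction removes a constant offset exactly", {
  fs <- makeSineFlow(period = 0.9, duration = 20, amplitude = 100)
  mkImg <- function(off) imageRenderConfig(c(12, 12), 2,
    discMask(c(12, 12), c(6, 6), 1.2), venc = 10, backgroundOffset = off)
  vs0 <- renderVelocitySeries(fs, mkImg(0))
  vsC <- renderVelocitySeries(fs, mkImg(0.3))
  mask <- new("SegmentationMask", mask = discMask(c(12, 12), c(6, 6), 1.2),
              pixelSpacing = 2)
  st <- selectStationaryRegion(vsC, mask)
  corr <- correctBackground(vsC, st)
  expect_equal(velocityFrames(corr), velocityFrames(vs0), tolerance = 1e-9)

  # the spurious flow removed for a 2-pixel 8 mm^2 lumen at 0.3 cm/s
  # is 0.3 * 10 * 8 * 60 / 1000 = 1.44 ml/min
  qBefore <- flowRate(extractFlow(vsC, mask))
  qAfter <- flowRate(extractFlow(corr, mask))
  areaMm2 <- segmentArea(mask)
  expect_equal(mean(qBefore - qAfter), 0.3 * 10 * areaMm2 * 60 / 1000,
               tolerance = 1e-9)
  # idempotent: correcting again changes (almost) nothing
  st2 <- selectStationaryRegion(corr, mask)
  expect_lt(abs(st2@referenceVelocity), 1e-9)
})

test_that("temporal de-aliasing unwraps single wraps and flags ambiguity", {
  # identity when nothing exceeds the VENC
  fr <- array(sin(seq(0, 20, length.out = 50)), dim = c(1, 1, 50))
  vs <- velocityMapSeries(fr, 2, 0.1, 5)
  expect_equal(velocityFrames(dealias(vs)), fr, tolerance = 1e-12)

  # a course crossing +1.2 venc stored as -0.8 venc is restored
  venc <- 5
  true <- 6 * sin(2 * pi * seq(0, 2, by = 0.02))     # peaks at 1.2 venc
  wrapped <- ((true + venc) %% (2 * venc)) - venc
  va <- velocityMapSeries(array(wrapped, dim = c(1, 1, length(true))),
                          2, 0.02, venc)
  expect_equal(as.numeric(velocityFrames(dealias(va))), true,
               tolerance = 1e-9)

  # generator round trip: dealias(aliased render) == alias-free render
  rec <- generateFlowRecord(simulationConfig(waveform = "sinusoid"))
  roi <- discMask(c(16, 16), c(8, 8), 3.4)
  mk <- function(al) imageRenderConfig(c(16, 16), 2, roi, venc = 1.6,
                                       alias = al)
  vsA <- renderVelocitySeries(rec$flow, mk(TRUE))
  vsN <- renderVelocitySeries(rec$flow, mk(FALSE))
  expect_gt(sum(abs(velocityFrames(vsN)) > 1.6), 0)  # aliasing did occur
  expect_equal(velocityFrames(dealias(vsA)), velocityFrames(vsN),
               tolerance = 1e-9)

  # a course whose unwrapped excursion leaves the single-wrap range
  # (here a drift spanning 8 VENC) is flagged, not silently corrected
  drift <- seq(0, 8, by = 0.4)
  stored <- ((drift + 1) %% 2) - 1
  vj <- velocityMapSeries(array(stored, dim = c(1, 1, length(stored))),
                          2, 0.1, 1)
  expect_warning(out <- dealias(vj), "unresolvable")
  expect_equal(nrow(attr(out, "flaggedPixels")), 1L)
  expect_equal(as.numeric(velocityFrames(out)), stored)  # left untouched
})

test_that("flow extraction is the documented unit conversion and is linear", {
  fr <- array(1, dim = c(1, 2, 40))
  vs <- velocityMapSeries(fr, 2, 0.1, 5)
  mask <- new("SegmentationMask", mask = matrix(TRUE, 1, 2), pixelSpacing = 2)
  q <- extractFlow(vs, mask)
  expect_equal(flowRate(q), rep(4.8, 40))         # 2 px * 4 mm^2 * 1 cm/s
  expect_equal(sampleTimes(q), (0:39) * 0.1)

  vz <- velocityMapSeries(array(0, dim = c(1, 2, 40)), 2, 0.1, 5)
  expect_equal(flowRate(extractFlow(vz, mask)), rep(0, 40))

  # linearity in pixel velocities
  vs3 <- velocityMapSeries(3 * fr, 2, 0.1, 5)
  expect_equal(flowRate(extractFlow(vs3, mask)), 3 * flowRate(q))
})

test_that("full image chain recovers the generated flow within 2% RMS", {
  rec <- generateFlowRecord(simulationConfig())
  img <- defaultRenderConfig()                    # offset 0.3, noise 0.1 cm/s
  vs <- renderVelocitySeries(rec$flow, img, seed = 2L)
  mask <- segmentCsfRoi(vs, c(12, 12))
  st <- selectStationaryRegion(vs, mask)
  fl <- extractFlow(dealias(correctBackground(vs, st)), mask)
  err <- flowRate(fl) - flowRate(rec$flow)
  relRms <- sqrt(mean(err^2)) / sqrt(mean(flowRate(rec$flow)^2))
  expect_lt(relRms, 0.02)
})
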