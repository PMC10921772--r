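test_that("cycle minima are found at the sinusoid troughs", {
  fs <- makeSineFlow(period = 0.9, duration = 45)
  mins <- detectCycleMinima(fs)
  expect_true(length(mins) %in% 49:50)
  # trough spacing equals the period within a frame interval
  expect_true(all(abs(diff(mins) - 0.9) < 0.096))
  # troughs of sin are at 3/4 period + k*period
  phase <- ((mins - 0.675) / 0.9) %% 1
  expect_true(all(pmin(phase, 1 - phase) < 0.05))

  expect_error(detectCycleMinima(flowSeries(seq(0, 10, 0.1), rep(5, 101))),
               "no cardiac structure")
  expect_error(detectCycleMinima(makeSineFlow(period = 0.9, duration = 3)),
               "no cardiac structure")
})

test_that("detected per-cycle periods track the injected sinus arrhythmia", {
  cfg <- simulationConfig(depths = c(Tc = 6), lags = c(Tc = -64))
  rec <- generateFlowRecord(cfg)
  cyc <- splitCycles(rec$flow, detectCycleMinima(rec$flow))
  tru <- rec$truth@cycles
  j <- vapply(cyc@midpoint, function(m) which.min(abs(tru$midpoint - m)), 1L)
  expect_true(all(abs(cyc@duration - tru$duration[j]) < 0.096))
  # much tighter on average
  expect_lt(mean(abs(cyc@duration - tru$duration[j])), 0.02)
})

test_that("cycle splitting keeps fencepost counts and gates gaps", {
  fs <- makeSineFlow(period = 0.9, duration = 45)
  mins <- (0:9) * 0.9 + 0.675
  cyc <- splitCycles(fs, mins)
  expect_equal(nCycles(cyc), 9L)

  # a missed minimum creates a double-length segment, discarded by the gate
  expect_message(cycGap <- splitCycles(fs, mins[-5]), "discarded")
  expect_equal(nCycles(cycGap), 7L)
  expect_equal(cycGap@nDiscarded, 1L)
  expect_false(any(abs(cycGap@duration - 1.8) < 1e-9))

  expect_error(splitCycles(fs, numeric(0)), "minima")
  expect_error(splitCycles(fs, 1.0), "minima")
})

test_that("cycle resampling is knot-exact, accurate and bounded above", {
  # cycle already sampled at 32 equispaced phases reproduces itself
  v32 <- -cos(2 * pi * (0:34) / 32)
  fs32 <- flowSeries((0:34) / 32, v32)
  expect_equal(resampleCycle(fs32, 0, 1), v32[1:32], tolerance = 1e-12)

  # 10-point sinusoid cycle interpolates to 32 points within 1% of the
  # amplitude (peak-to-peak)
  t10 <- seq(-0.5, 1.5, by = 0.1)
  fs10 <- flowSeries(t10, -cos(2 * pi * t10))
  out <- resampleCycle(fs10, 0, 1)
  expect_lt(max(abs(out - (-cos(2 * pi * (0:31) / 32)))), 0.01 * 2)

  # monotone data: no output above the sample maximum, and dips below the
  # sample minimum only by the (clamped) boundary-trough allowance
  tm <- seq(-0.2, 1.3, by = 0.1)
  ym <- tm^2 + 2 * tm
  fsm <- flowSeries(tm, ym)
  om <- resampleCycle(fsm, 0, 1)
  sel <- ym[tm >= 0 & tm < 1]
  expect_lte(max(om), max(sel) + 1e-12)
  expect_gte(min(om), min(sel) - max(abs(diff(ym))))
})

test_that("cycle averaging is the pointwise mean with mean duration", {
  fs <- makeSineFlow(period = 0.9, duration = 45)
  cyc <- splitCycles(fs, detectCycleMinima(fs))
  one <- averageCycles(cyc, 1L)
  expect_equal(qtValues(one), cyc@qt32[1, ])
  expect_equal(one@tc, cyc@duration[1])
  two <- averageCycles(cyc, 1:2)
  expect_equal(qtValues(two), (cyc@qt32[1, ] + cyc@qt32[2, ]) / 2)
  expect_equal(two@tc, mean(cyc@duration[1:2]))
  expect_equal(nCycles(two), 2L)

  # identical cycles average to any one of them
  ident <- new("CardiacCycleSet", start = c(0, 1, 2), end = c(1, 2, 3),
               midpoint = c(0.5, 1.5, 2.5), duration = rep(1, 3),
               qt32 = matrix(rep(sin(1:32), each = 3), 3, 32),
               nDiscarded = 0L)
  expect_equal(qtValues(averageCycles(ident)), ident@qt32[2, ])
  expect_error(averageCycles(ident, integer(0)), "at least 1")
})

test_that("reconstructed Qt matches the generator template (zero modulation)", {
  cfg <- simulationConfig(waveform = "sinusoid")
  rec <- generateFlowRecord(cfg)
  cyc <- splitCycles(rec$flow, detectCycleMinima(rec$flow))
  qt <- averageCycles(cyc)
  tru <- rec$truth@cycles
  j <- vapply(cyc@start, function(s) which.min(abs(tru$start - s)), 1L)
  off <- mean(cyc@start - tru$start[j]) / cfg@cardiacPeriod
  template <- cfg@netFlow +
    cfg@amplitude * (-cos(2 * pi * (((0:31) / 32 + off) %% 1)) / 2)
  expect_lt(max(abs(qtValues(qt) - template)), 0.01 * cfg@amplitude)
  expect_equal(qt@tc, cfg@cardiacPeriod, tolerance = 0.01)
})

test_that("cycle parameters follow their closed forms and symmetries", {
  # pure sinusoid: Qnet 0, Amplitude 2A, SV = A Tc 1000 / (60 pi)
  A <- 160; Tc <- 0.87
  qt <- makeQt(A * sin(2 * pi * (0:31) / 32), Tc)
  p <- parameterValues(computeParameters(qt, area = 148))
  expect_equal(p[["Qnet"]], 0, tolerance = 1e-9)
  expect_equal(p[["Amplitude"]], 2 * A * sin(2 * pi * 8 / 32), tolerance = 1e-9)
  expect_equal(p[["SV"]], A * Tc * 1000 / (60 * pi), tolerance = 0.005 * 739)
  expect_equal(p[["SVpos"]], p[["SVneg"]])

  # constant positive flow: all volume is caudocranial
  qc <- makeQt(rep(12, 32), 0.8)
  pc <- parameterValues(computeParameters(qc))
  expect_equal(pc[["SVpos"]], 12 * 0.8 * 1000 / 60)
  expect_equal(pc[["SVneg"]], 0)
  expect_equal(pc[["SV"]], pc[["SVpos"]] / 2)
  expect_equal(pc[["Amplitude"]], 0)

  # velocity conversion: 10 ml/min over 3 mm^2 -> 5.56 cm/s
  qv <- makeQt(10 * sin(2 * pi * (0:31) / 32), 0.87)
  pv <- parameterValues(computeParameters(qv, area = 3))
  expect_equal(pv[["Vmax"]], max(qtValues(qv)) * (1000 / 60) / 30,
               tolerance = 1e-9)
  expect_error(computeParameters(qv, area = -1), "area")

  # flipping the flow sign swaps the directional quantities
  pFlip <- parameterValues(computeParameters(
    makeQt(-qtValues(qt), Tc), area = 148))
  expect_equal(pFlip[["SVpos"]], p[["SVneg"]])
  expect_equal(pFlip[["SVneg"]], p[["SVpos"]])
  expect_equal(pFlip[["Vmax"]], p[["Vmin"]])
  expect_equal(pFlip[["SV"]], p[["SV"]])
  expect_equal(pFlip[["Amplitude"]], p[["Amplitude"]])

  # adding a constant shifts Qnet by exactly that constant
  pShift <- parameterValues(computeParameters(
    makeQt(qtValues(qt) + 7, Tc)))
  expect_equal(pShift[["Qnet"]], p[["Qnet"]] + 7)
  expect_equal(pShift[["Amplitude"]], p[["Amplitude"]])
})
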