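test_that("belt delineation finds complete cycles and labels phases", {
  t <- seq(0, 45, by = 0.096)
  belt <- breathingSignal(t, 0.5 * (1 - cos(2 * pi * t / 3.4)))
  ph <- delineatePhases(belt)
  expect_equal(ph@nCycles, 12L)                   # 45 / 3.4 complete cycles
  expect_equal(ph@meanPeriod, 3.4, tolerance = 0.01)
  iv <- ph@intervals
  expect_true(all(iv$phase[c(TRUE, FALSE)] == "IN"))
  expect_true(all(iv$phase[c(FALSE, TRUE)] == "EX"))
  # inspiration and expiration each last half the cycle
  expect_equal(mean((iv$end - iv$start)[iv$phase == "IN"]), 1.7,
               tolerance = 0.02)
  expect_equal(mean((iv$end - iv$start)[iv$phase == "EX"]), 1.7,
               tolerance = 0.02)

  # monotone ramp: no complete cycle
  expect_error(delineatePhases(breathingSignal(t, t)), "breathing")

  # inverting the belt swaps the labels exactly
  phInv <- delineatePhases(breathingSignal(t, -0.5 * (1 - cos(2 * pi * t / 3.4))))
  ivI <- phInv@intervals
  midIn <- (iv$start + iv$end)[iv$phase == "IN"] / 2
  labAt <- function(p, x) p@intervals$phase[findInterval(x, p@intervals$start)]
  inner <- midIn[midIn > ivI$start[1] & midIn < ivI$end[nrow(ivI)]]
  expect_true(all(labAt(phInv, inner) == "EX"))

  # irregular breathing is rejected
  tIr <- seq(0, 40, by = 0.05)
  irr <- sin(2 * pi * tIr / ifelse(tIr < 20, 2, 6))
  expect_error(delineatePhases(breathingSignal(tIr, irr)), "irregular")
})

test_that("cycle assignment follows the half-open shifted-window rule", {
  t <- seq(0, 45, by = 0.096)
  belt <- breathingSignal(t, 0.5 * (1 - cos(2 * pi * t / 3.4)))
  ph <- delineatePhases(belt)
  # synthetic cycle set with controlled midpoints
  mkCycles <- function(mid) new("CardiacCycleSet",
    start = mid - 0.4, end = mid + 0.4, midpoint = mid,
    duration = rep(0.8, length(mid)),
    qt32 = matrix(0, length(mid), 32), nDiscarded = 0L)
  b2 <- ph@intervals$start[2]                     # an interior boundary
  a <- assignCycles(mkCycles(b2), ph, 0)
  # a midpoint exactly on a boundary joins the interval starting there
  expect_equal(ph@intervals$phase[2],
               if (length(a$insp)) "IN" else "EX")

  # a full-period shift reproduces the zero-shift assignment (interior)
  mids <- seq(7, 38, by = 0.83)
  a0 <- assignCycles(mkCycles(mids), ph, 0)
  aT <- assignCycles(mkCycles(mids), ph, ph@meanPeriod)
  inner <- mids > ph@boundaries[1] + 3.4 &
    mids < ph@boundaries[length(ph@boundaries)] - 3.4
  expect_equal(intersect(a0$insp, which(inner)),
               intersect(aT$insp, which(inner)))

  # on a generated record the zero-shift assignment matches the truth
  rec <- generateFlowRecord(simulationConfig(depths = c(Amplitude = 6.8)))
  cyc <- splitCycles(rec$flow, detectCycleMinima(rec$flow))
  phG <- delineatePhases(rec$belt)
  aG <- assignCycles(cyc, phG, 0)
  tru <- rec$truth@cycles
  j <- vapply(cyc@midpoint, function(m) which.min(abs(tru$midpoint - m)), 1L)
  lab <- rep(NA_character_, nCycles(cyc))
  lab[aG$insp] <- "IN"; lab[aG$exp] <- "EX"
  ok <- !is.na(lab)
  agree <- mean(lab[ok] == tru$phase[j[ok]])
  expect_gt(agree, 0.9)   # boundary-adjacent beats may differ by one label
})

test_that("delta computation is inspiration minus expiration", {
  qa <- makeQt(100 * sin(2 * pi * (0:31) / 32), 0.85)
  expect_equal(unname(computeDelta(qa, qa)), rep(0, 4))
  qIn <- makeQt(1.05 * qtValues(qa), 0.85)
  qEx <- makeQt(0.95 * qtValues(qa), 0.85)
  d <- computeDelta(qIn, qEx)
  expect_equal(d[["Amplitude"]], 0.10 * (max(qtValues(qa)) - min(qtValues(qa))),
               tolerance = 1e-9)
  expect_error(reconstructPhaseQt(
    new("CardiacCycleSet", start = 1, end = 2, midpoint = 1.5, duration = 1,
        qt32 = matrix(0, 1, 32), nDiscarded = 0L),
    list(insp = 1L, exp = integer(0))), "at least one")
})

test_that("delta-curve summary reproduces the worked SV example", {
  g <- seq(-3, 3, by = 0.1)
  # curve with extremes +144 at -0.3 s and -137 at +1.4 s of a 3.4 s cycle
  curve <- 3.5 + 140.5 * cos(2 * pi * (g + 0.3) / 3.4)
  s <- deltaCurveSummary(g, curve, 3.4)
  expect_equal(s$delta, (144 - (-137)) / 2)        # 140.5, the mean peak
  expect_equal(s$phiS, -0.3)                       # |-9%| < |41%|
  expect_equal(s$phiDeg, 3.6 * s$phiPercent)
  expect_false(s$flat)

  # with Tb chosen so that -0.3 s is exactly -9%, the degrees conversion
  # gives -32.4
  curve2 <- 140.5 * cos(2 * pi * (g + 0.3) / (10 / 3))
  s2 <- deltaCurveSummary(g, curve2, 10 / 3)
  expect_equal(s2$phiPercent, -9)
  expect_equal(s2$phiDeg, -32.4)

  # flat curve: zero intensity, flagged
  sf <- deltaCurveSummary(g, rep(2, length(g)), 3.4)
  expect_true(sf$flat)
  expect_equal(sf$delta, 0)
  expect_equal(sf$phiS, 0)
})

test_that("phase sweep is null on unmodulated records and scales correctly", {
  cfg <- simulationConfig(waveform = "sinusoid")
  out <- runFlowPipeline(cfg)
  expect_true(all(abs(sweepSummary(out$sweep)$deltaPercent) < 0.5))

  # doubling the flow doubles the raw deltas, leaves percentages unchanged
  cfgA <- simulationConfig(depths = c(Amplitude = 6.8), lags = c(Amplitude = -11))
  rec <- generateFlowRecord(cfgA)
  cyc1 <- splitCycles(rec$flow, detectCycleMinima(rec$flow))
  fl2 <- flowSeries(sampleTimes(rec$flow), 2 * flowRate(rec$flow))
  cyc2 <- splitCycles(fl2, detectCycleMinima(fl2))
  ph <- delineatePhases(rec$belt)
  s1 <- sweepSummary(sweepPhase(cyc1, ph, 148))
  s2 <- sweepSummary(sweepPhase(cyc2, ph, 148))
  expect_equal(s2["Amplitude", "delta"], 2 * s1["Amplitude", "delta"],
               tolerance = 1e-6)
  expect_equal(s2["Qnet", "delta"], 2 * s1["Qnet", "delta"], tolerance = 1e-6)
  expect_equal(s2["Amplitude", "deltaPercent"], s1["Amplitude", "deltaPercent"],
               tolerance = 1e-6)
  expect_equal(s2["Qnet", "deltaPercent"], s1["Qnet", "deltaPercent"],
               tolerance = 1e-6)
})

test_that("noiseless amplitude modulation is recovered with phase", {
  cfg <- simulationConfig(depths = c(Amplitude = 6.8), lags = c(Amplitude = -11))
  out <- runFlowPipeline(cfg)
  s <- sweepSummary(out$sweep)
  expect_equal(s["Amplitude", "deltaPercent"], 6.8, tolerance = 0.1 * 6.8)
  expect_lt(abs(s["Amplitude", "phiDeg"] - (-11)), 15)

  # the delta curve is breathing-periodic
  cv <- deltaCurves(out$sweep)[, "Amplitude"]
  g <- out$sweep@phiGrid
  Tb <- out$sweep@meanPeriod
  shiftIdx <- round(Tb / 0.1)
  both <- seq_len(length(g) - shiftIdx)
  # a 45 s record holds ~13 breathing cycles, and shifting by a full period
  # exchanges the edge beats of every set, so the curve repeats only up to
  # finite-record composition changes of the averaged sets
  intensity <- abs(s["Amplitude", "delta"])
  expect_lt(max(abs(cv[both + shiftIdx] - cv[both])), 0.15 * intensity)
  expect_lt(stats::median(abs(cv[both + shiftIdx] - cv[both])), 0.1 * intensity)
})

test_that("shifting the belt shifts the recovered phase oppositely", {
  cfg <- simulationConfig(depths = c(Amplitude = 6.8), lags = c(Amplitude = 0))
  rec <- generateFlowRecord(cfg)
  cyc <- splitCycles(rec$flow, detectCycleMinima(rec$flow))
  ph0 <- delineatePhases(rec$belt)
  delta <- 0.4
  tB <- sampleTimes(rec$belt)
  beltShift <- breathingSignal(tB, 0.5 * (1 - cos(2 * pi * (tB - delta) / 3.4)))
  phS <- delineatePhases(beltShift)
  s0 <- sweepSummary(sweepPhase(cyc, ph0, 148))["Amplitude", "phiS"]
  sS <- sweepSummary(sweepPhase(cyc, phS, 148))["Amplitude", "phiS"]
  dphi <- (sS - s0 + 3.4 / 2) %% 3.4 - 3.4 / 2
  expect_equal(dphi, -delta, tolerance = 0.15)
})
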