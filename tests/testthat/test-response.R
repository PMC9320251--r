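test_that("phase segmentation respects counts and the boundary tie rule", {
  rr <- makeWalkRecord(seed = 5)
  s <- segmentPhases(rr)
  labels <- phaseLabels(rr)
  counts <- table(labels[!is.na(labels)])
  expect_equal(length(s$baseline), unname(counts[["baseline"]]))
  expect_equal(length(s$walking), unname(counts[["walking"]]))
  expect_equal(length(s$recovery), unname(counts[["recovery"]]))
  # boundary exactly at a beat time goes to the later phase
  rrB <- RRSeries(rep(1000, 900))   # beats at 1, 2, ..., 900 s
  seg <- PhaseSegmentation(tWalkStart = 300, tWalkEnd = 500,
                           tRecoveryEnd = 900)
  sB <- segmentPhases(rrB, seg)
  expect_false(300 %in% beatTimes(sB$baseline))
  expect_true(300 %in% beatTimes(sB$walking))
  expect_false(500 %in% beatTimes(sB$walking))
  expect_true(500 %in% beatTimes(sB$recovery))
  # segmentation outside the record errors
  segBad <- suppressWarnings(PhaseSegmentation(
    tWalkStart = 300, tWalkEnd = 500, tRecoveryEnd = 2000))
  expect_error(segmentPhases(rrB, segBad), "outside")
})

test_that("instantaneous HR is exact for constants and identity at window 0", {
  rr <- plainRR(rep(800, 100))
  hc <- instantaneousHr(rr, 10)
  expect_true(all(abs(hc$hr - 75) < 1e-9))
  rr2 <- makeRestSegment(seed = 3, durationS = 60)
  raw <- instantaneousHr(rr2, 0)
  expect_equal(raw$hr, 60000 / rrIntervals(rr2))
})

test_that("smoothing suppresses a single spurious HR spike", {
  v <- rep(800, 100)
  v[50] <- 400                       # 150 bpm artifact-like dip
  hc <- instantaneousHr(plainRR(v), 10)
  expect_lt(max(hc$hr), 100)
})

test_that("delta-t matches the closed-form peak of a drifting rise", {
  # hr(t) = 70 + 20(1 - e^(-t/10)) - 0.1 t peaks at t* = 10 ln(20/(10*0.1))
  walk <- walkProfileConfig(hrBaseline = 70, hrMax = 90, riseTau = 10,
                            paceDrift = 0.1, walkDurationS = 180)
  rr <- generateWalkTestRR(walk, ipfmConfig(ampLF = 0, ampHF = 0,
                                            noiseSd = 0, seed = 1))
  resp <- computeResponseIndices(rr)
  tStar <- 10 * log(20 / (10 * 0.1))
  expect_lt(abs(resp$delta_t - tStar), 2)
})

test_that("monotone and flat walking profiles pin delta-t at the extremes", {
  modz <- ipfmConfig(ampLF = 0, ampHF = 0, noiseSd = 0, seed = 1)
  # monotone rise: maximum at walk end
  walkUp <- walkProfileConfig(hrBaseline = 70, hrMax = 110, riseTau = 120,
                              walkDurationS = 180)
  respUp <- computeResponseIndices(generateWalkTestRR(walkUp, modz))
  expect_gt(respUp$delta_t, 180 - 12)
  expect_lte(respUp$delta_t, 180 + 1)
  # flat profile: maximum attained at onset
  walkFlat <- walkProfileConfig(hrBaseline = 80, hrMax = 80, riseTau = 10,
                                walkDurationS = 180)
  respFlat <- computeResponseIndices(generateWalkTestRR(walkFlat, modz))
  expect_lt(respFlat$delta_t, 12)
})

test_that("vresp is the stated ratio with its degenerate flag", {
  expect_equal(computeVresp(60, 120)$vResp, 2)
  z <- computeVresp(0, 120)
  expect_true(is.na(z$vResp))
  expect_true(z$instantaneous)
  expect_error(computeVresp(-1, 120), ">= 0")
  # identity vresp * delta_t = hr_max whenever both defined
  for (s in 1:5) {
    rr <- makeWalkRecord(seed = s)
    resp <- computeResponseIndices(rr)
    if (!is.na(resp$v_resp))
      expect_equal(resp$v_resp * resp$delta_t, resp$hr_max,
                   tolerance = 1e-9 * resp$hr_max)
  }
})

test_that("a slow-rise profile yields lower vresp at equal HR max", {
  modz <- ipfmConfig(ampLF = 0, ampHF = 0, noiseSd = 0, seed = 1)
  young <- computeResponseIndices(generateWalkTestRR(
    walkProfileConfig(hrBaseline = 75, hrMax = 105, riseTau = 10,
                      paceDrift = 0.05, walkDurationS = 180), modz))
  frail <- computeResponseIndices(generateWalkTestRR(
    walkProfileConfig(hrBaseline = 75, hrMax = 105, riseTau = 60,
                      paceDrift = 0.02, walkDurationS = 180), modz))
  expect_lt(frail$v_resp, young$v_resp)
  expect_gt(frail$delta_t, young$delta_t)
})

test_that("percentage HR change follows its defining arithmetic", {
  expect_equal(computeDeltaHr(120, 100), 20)
  expect_equal(computeDeltaHr(88, 88), 0)
  expect_error(computeDeltaHr(100, 0), "positive")
})

test_that("identical phase means give zero percentage changes", {
  rrB <- RRSeries(rep(800, 1200))   # constant HR throughout
  seg <- PhaseSegmentation(tWalkStart = 300, tWalkEnd = 480,
                           tRecoveryEnd = 780)
  rrB@segmentation <- seg
  resp <- computeResponseIndices(rrB)
  expect_equal(resp$dhr_wb, 0, tolerance = 1e-9)
  expect_equal(resp$dhr_rw, 0, tolerance = 1e-9)
})

test_that("delta-t is invariant to uniform time translation", {
  rr <- makeWalkRecord(seed = 9)
  seg <- segmentation(rr)
  shift <- 500
  seg2 <- PhaseSegmentation(tBaselineStart = seg@tBaselineStart + shift,
                            tWalkStart = seg@tWalkStart + shift,
                            tWalkEnd = seg@tWalkEnd + shift,
                            tRecoveryEnd = seg@tRecoveryEnd + shift)
  rr2 <- RRSeries(intervals = rrIntervals(rr),
                  beatTimes = beatTimes(rr) + shift,
                  segmentation = seg2)
  expect_equal(computeResponseIndices(rr2)$delta_t,
               computeResponseIndices(rr)$delta_t, tolerance = 1e-9)
})

test_that("zero and positive recovery offsets steer the recovery contrast", {
  modz <- ipfmConfig(ampLF = 0, ampHF = 0, noiseSd = 0, seed = 2)
  zero <- computeResponseIndices(generateWalkTestRR(
    walkProfileConfig(hrBaseline = 75, hrMax = 95, riseTau = 12,
                      recoveryTau = 8, recoveryOffset = 0), modz))
  expect_lt(abs(zero$dhr_rb), 1)
  offset <- computeResponseIndices(generateWalkTestRR(
    walkProfileConfig(hrBaseline = 75, hrMax = 95, riseTau = 12,
                      recoveryTau = 8, recoveryOffset = 5), modz))
  expect_gt(offset$dhr_rb, 0)
})
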