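test_that("flat noiseless synthesis gives a constant trace", {
  tr <- synthDoppler(gasSchedule(), 100, c(1, 1, 1), 350, rippleAmp = 0)
  expect_equal(length(bpuValues(tr)), 30 * 60 * 10)
  expect_lt(max(bpuValues(tr)) - min(bpuValues(tr)), 1e-12)
  pm <- phaseMeanBPU(tr, gasSchedule())
  expect_equal(pm$meanBpu, rep(100, 3))
  expect_equal(percentChangeBPU(pm)$percent, c(0, 0))
  expect_error(
    synthDoppler(gasSchedule(), 100, c(1, 1, 1), 350,
                 corruptWindows = list(c(1750, 1900))), "outside")
})

test_that("phase means and percent changes track generator plateaus", {
  # +50% step in hypercapnia, fast kinetics, noiseless, no ripple
  tr <- synthDoppler(gasSchedule(), 80, c(1, 1.5, 1.5), 350,
                     rippleAmp = 0, tauMin = 0.25)
  pm <- phaseMeanBPU(tr, gasSchedule())
  pc <- percentChangeBPU(pm)
  expect_equal(pc$percent[1], 50, tolerance = 1e-6)
  expect_equal(pc$percent[2], 0, tolerance = 1e-6)
  # invariance to the arbitrary BPU gain
  tr2 <- dopplerTrace(traceTimes(tr), 9.1 * bpuValues(tr))
  pc2 <- percentChangeBPU(phaseMeanBPU(tr2, gasSchedule()))
  expect_equal(pc2$percent, pc$percent, tolerance = 1e-9)
})

test_that("corruption flagging recovers injected windows exactly", {
  clean <- synthDoppler(gasSchedule(), 100, c(1, 1.2, 1), 350,
                        noiseSigma = 0.02, seed = 5L)
  cleanF <- flagCorruption(clean)
  expect_true(all(qualityFlags(cleanF)$ok))

  win <- list(c(600, 650), c(1500, 1520))
  bad <- synthDoppler(gasSchedule(), 100, c(1, 1.2, 1), 350,
                      noiseSigma = 0.02, corruptWindows = win, seed = 5L)
  badF <- flagCorruption(bad)
  q <- qualityFlags(badF)
  flagged <- q[!q$ok, ]
  inWin <- function(s) any(vapply(win, function(w)
    s >= w[1] & s < w[2], logical(1)))
  # flagged windows are exactly the injected ones (10-s aligned)
  expect_true(all(vapply(flagged$startS, inWin, logical(1))))
  expect_equal(sum(!q$ok), sum(vapply(win, function(w) w[2] - w[1],
                                      numeric(1))) / 10)
})

test_that("a phase with a fully corrupted end window is 'not measured'", {
  totS <- 30 * 60
  tr <- synthDoppler(gasSchedule(), 100, c(1, 1.33, 1), 350,
                     corruptWindows = list(c(totS - 120, totS)), seed = 2L)
  pm <- phaseMeanBPU(tr, gasSchedule())
  expect_false(pm$measured[3])
  expect_true(is.na(pm$meanBpu[3]))
  pc <- percentChangeBPU(pm)
  expect_false(pc$measured[pc$phase == 3])
  expect_true(is.na(pc$percent[pc$phase == 3]))
  # the measured hypercapnia row is untouched
  expect_equal(pc$percent[pc$phase == 2], 33, tolerance = 0.05)
})

test_that("spectral heart-rate extraction unfolds the aliased rat rate", {
  # pure 350 bpm ripple: 5.83 Hz is above the 5 Hz Nyquist of 10 Hz
  # sampling, so the raw peak is aliased; the estimator reports 350
  tr <- synthDoppler(gasSchedule(), 100, c(1, 1, 1), 350, rippleAmp = 0.05)
  hr <- heartRate(tr, gasSchedule())
  expect_true(all(abs(hr$windows$bpm - 350) < 0.05))
  expect_equal(hr$percentChanges$percent, c(0, 0), tolerance = 0.02)

  # stepped rate: +11% in hypercapnia, +1% more on return
  tr2 <- synthDoppler(gasSchedule(), 100, c(1, 1, 1), 350,
                      hrPhaseFactors = c(1, 1.11, 1.11 * 1.01),
                      tauMin = 1)
  hr2 <- heartRate(tr2, gasSchedule())
  expect_equal(hr2$phaseBpm, c(350, 350 * 1.11, 350 * 1.11 * 1.01),
               tolerance = 1e-3)
  expect_equal(hr2$percentChanges$percent, c(11, 1), tolerance = 0.02)

  # ramping ground truth: final-window estimate matches the generator's
  # instantaneous rate in that window
  tr3 <- synthDoppler(gasSchedule(), 100, c(1, 1, 1), 360,
                      hrPhaseFactors = c(1, 1.2, 1.2), tauMin = 4)
  hr3 <- heartRate(tr3, gasSchedule())
  truthHr <- tr3@groundTruth$trueHrBpm
  sel <- traceTimes(tr3) >= 1140 & traceTimes(tr3) < 1200
  expect_equal(hr3$phaseBpm[2], mean(truthHr[sel]), tolerance = 0.01)

  # no pulsatile component -> flagged windows, not a bogus rate
  flat <- synthDoppler(gasSchedule(), 100, c(1, 1, 1), 350, rippleAmp = 0,
                       noiseSigma = 0.02, seed = 9L)
  hrFlat <- heartRate(flat, gasSchedule())
  expect_true(all(is.na(hrFlat$windows$bpm)))
})

test_that("preset traces reproduce their encoded responses", {
  # noiseless: recovered percent change equals generator truth
  trM <- dopplerPreset("male")
  pcM <- percentChangeBPU(phaseMeanBPU(trM, gasSchedule()))
  expect_equal(pcM$percent, c(-12, -24), tolerance = 0.01)
  hrM <- heartRate(trM, gasSchedule())
  expect_equal(hrM$percentChanges$percent[1], 11, tolerance = 0.02)

  trF <- dopplerPreset("female")
  pcF <- percentChangeBPU(phaseMeanBPU(trF, gasSchedule()))
  expect_equal(pcF$percent[1], 33, tolerance = 0.01)
  expect_true(is.na(pcF$percent[2]))

  # with measurement noise the recovery stays within 2 percentage points
  trMn <- dopplerPreset("male", noiseSigma = 0.05, seed = 31L)
  pcMn <- percentChangeBPU(phaseMeanBPU(trMn, gasSchedule()))
  expect_lt(max(abs(pcMn$percent - c(-12, -24))), 2)
})

test_that("doppler CSV round trip preserves the samples", {
  tr <- synthDoppler(gasSchedule(), 100, c(1, 1.2, 1), 350,
                     noiseSigma = 0.01, seed = 3L)
  p <- withr::local_tempfile(fileext = ".csv")
  writeDopplerCSV(tr, p)
  back <- readDopplerCSV(p)
  expect_equal(bpuValues(back), bpuValues(tr), tolerance = 1e-9)
  expect_equal(traceTimes(back), traceTimes(tr), tolerance = 1e-9)
})
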