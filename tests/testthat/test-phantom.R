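test_that("blood-volume kinetics follow the per-phase exponential model", {
  sched <- gasSchedule()
  kin <- vasoKinetics(3)
  flat <- tissueSpec("m", 1100, 800, 0.10, phaseFactors = c(1, 1, 1))
  expect_equal(vOfT(flat, kin, sched, c(0, 7, 13, 22, 30)), rep(0.10, 5))

  ts <- tissueSpec("m", 1100, 800, 0.10, phaseFactors = c(1, 1.30, 1))
  # closed form at 10 min into the hypercapnia phase (phase starts at 10)
  expect_equal(vOfT(ts, kin, sched, 20),
               0.10 + 0.03 * (1 - exp(-10 / 3)), tolerance = 1e-12)
  # against independent forward-Euler integration
  expect_equal(vOfT(ts, kin, sched, 20),
               eulerV(0.10, c(1, 1.30, 1), 3, sched, 20),
               tolerance = 1e-4)
  expect_equal(vOfT(ts, kin, sched, 27),
               eulerV(0.10, c(1, 1.30, 1), 3, sched, 27),
               tolerance = 1e-4)
  # continuity across the phase boundary
  eps <- 1e-8
  expect_equal(vOfT(ts, kin, sched, 10 + eps), vOfT(ts, kin, sched, 10),
               tolerance = 1e-6)
  expect_equal(vOfT(ts, kin, sched, 20 + eps), vOfT(ts, kin, sched, 20),
               tolerance = 1e-6)
  expect_error(vOfT(ts, kin, sched, 31), "regime")
  expect_error(vOfT(ts, kin, sched, -1), "regime")
})

test_that("plasma concentration decays mono-exponentially", {
  cm <- contrastModel(cPlasma0MM = 0.5, eliminationHalflifeMin = 300)
  expect_equal(cOfT(cm, 0), 0.5)
  expect_equal(cOfT(cm, 30), 0.5 * 2^(-0.1), tolerance = 1e-12)
  expect_true(all(diff(cOfT(cm, 0:30)) < 0))
  stable <- contrastModel(eliminationHalflifeMin = 1e9)
  expect_equal(cOfT(stable, c(0, 30)), rep(0.5, 2), tolerance = 1e-7)
  expect_error(cOfT(cm, -1), "tMin")
  # default half-life keeps enhancement within 5% over the 30-min regime
  cmDef <- contrastModel()
  expect_gt(cOfT(cmDef, 30) / cOfT(cmDef, 0), 0.95)
})

test_that("fast-exchange relaxation model behaves and inverts", {
  expect_equal(tissueR1(1195, 19, 0, 0.5), 1195)
  expect_equal(tissueR1(1195, 19, 0.1, 0), 1195)
  # linearity: doubling v*C doubles the contrast-induced delta-R1
  dR1 <- function(v) 1000 / tissueR1(1195, 19, v, 0.5) - 1000 / 1195
  expect_equal(dR1(0.2), 2 * dR1(0.1), tolerance = 1e-12)
  # monotone: dilation strictly lowers T1 at fixed C > 0
  v <- seq(0, 0.5, by = 0.05)
  expect_true(all(diff(tissueR1(1195, 19, v, 0.5)) < 0))
  # numeric-inversion oracle: find v*C giving tissue T1 = 452 ms from a
  # 1195 ms pre-contrast myocardium, then round-trip through the model
  f <- function(vc) tissueR1(1195, 19, vc, 1) - 452
  vcStar <- uniroot(f, c(1e-6, 10), tol = 1e-12)$root
  expect_equal(vcStar, (1000 / 452 - 1000 / 1195) / 19, tolerance = 1e-9)
  expect_equal(tissueR1(1195, 19, vcStar, 1), 452, tolerance = 1e-9)
})

test_that("ground truth encodes preset trajectories and model invariants", {
  spec <- smallPreset("female")
  tt <- truthTable(groundTruth(spec))
  sep <- tt[tt$tissue == "septum", ]
  expect_equal(sep$t1Ms,
               c(452, 452, 452, 452 * 0.88, 452 * 0.80,
                 452 * 0.80 * 1.18, 452 * 0.80 * 1.23),
               tolerance = 1e-12)
  expect_true(all(sep$v >= 0 & sep$v <= 1))
  # monotone coupling: larger v*C always means lower T1 (ties allowed only
  # where v*C is numerically tied)
  vc <- sep$v * sep$cMM
  o <- order(vc)
  tied <- abs(diff(vc[o])) < 1e-12 * max(vc)
  expect_true(all(diff(sep$t1Ms[o]) < 0 | tied))

  # conservation: no modulation + effectively infinite half-life
  # => constant true T1 across the regime
  spec2 <- phantomSpec(
    vfa = vfaParams(matrixSize = 32L, nSlices = 2L),
    cine = cineParams(matrixSize = 32L, nSlices = 2L),
    tissues = defaultTissues(myoPhaseFactors = c(1, 1, 1)),
    contrast = contrastModel(eliminationHalflifeMin = 1e12))
  tt2 <- truthTable(groundTruth(spec2))
  for (lab in unique(tt2$tissue)) {
    t1s <- tt2$t1Ms[tt2$tissue == lab]
    expect_lt(max(t1s) - min(t1s), 1e-6)
  }

  # a target trajectory implying v > 1 is rejected
  bad <- phantomSpec(
    vfa = vfaParams(matrixSize = 32L, nSlices = 2L),
    cine = cineParams(matrixSize = 32L, nSlices = 2L),
    tissues = list(tissueSpec("septum", 1195, 800, 0.1, c(1, 1, 1),
                              t1TargetsMs = rep(50, 7))))
  expect_error(groundTruth(bad), "outside")
})

test_that("rendered series are deterministic and geometrically sound", {
  spec <- smallMechanisticSpec(noiseSigma = 0.02, seed = 42L)
  s1 <- renderSeries(spec)
  s2 <- renderSeries(spec)
  expect_identical(s1$vfa, s2$vfa)
  expect_identical(s1$cine, s2$cine)
  expect_identical(truthTable(s1$truth), truthTable(s2$truth))
  s3 <- renderSeries(smallMechanisticSpec(noiseSigma = 0.02, seed = 43L))
  expect_false(identical(s1$cine, s3$cine))

  # noiseless: every voxel of a tissue carries the same intensity
  sn <- renderSeries(smallMechanisticSpec())
  lab <- sn$rois@labelVolume
  for (k in 1:4) {
    vox <- sn$cine[, , , 1][lab == k]
    expect_lt(max(vox) - min(vox), 1e-12)
  }
  # ROIs disjoint and all labels present
  expect_setequal(unique(as.vector(lab)), 0:4)
  expect_equal(sort(unname(sn$rois@roiNames)),
               sort(c("septum", "anterior_wall", "posterior_wall",
                      "lv_blood")))
})

test_that("NIfTI and JSON round trips preserve the series", {
  spec <- smallPreset("male")
  d <- withr::local_tempdir()
  ser <- renderSeries(spec, outDir = d)
  expect_true(all(file.exists(file.path(
    d, c("vfa.nii.gz", "cine.nii.gz", "rois.nii.gz",
         "ground_truth.json", "schedule.json")))))
  back <- readVolume(file.path(d, "cine.nii.gz"))
  expect_equal(back, ser$cine, tolerance = 1e-6, ignore_attr = TRUE)
  spec2 <- specFromList(specToList(spec))
  expect_equal(truthTable(groundTruth(spec2)), truthTable(groundTruth(spec)))
})
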