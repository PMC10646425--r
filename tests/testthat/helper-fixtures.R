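# small-grid phantom specs used across tests (reduced geometry keeps the
# suite fast; the physics is size-invariant)

smallPreset <- function(sex = "female", noiseSigma = 0, seed = 1L)
  phantomPreset(sex, matrixSize = 32L, nSlices = 2L,
                noiseSigma = noiseSigma, seed = seed)

smallMechanisticSpec <- function(noiseSigma = 0, seed = 1L,
                                 myoPhaseFactors = c(1, 1.25, 1))
  phantomSpec(
    vfa = vfaParams(matrixSize = 32L, nSlices = 2L),
    cine = cineParams(matrixSize = 32L, nSlices = 2L),
    tissues = defaultTissues(myoPhaseFactors = myoPhaseFactors),
    noiseSigma = noiseSigma, seed = seed)

# pooled myocardial mean of a T1Map given an ROISet
pooledMyoMean <- function(map, rois) {
  rm <- roiMeanT1(map, myocardialROIs(rois))
  mean(rm$means)
}

# independent forward-Euler integration of the per-phase exponential
# blood-volume kinetics: dv/dt = (target(t) - v) / tau
eulerV <- function(vBase, factors, tauMin, schedule, tEndMin, dt = 0.001) {
  ends <- phaseEndsMin(schedule)
  v <- vBase
  t <- 0
  while (t < tEndMin - dt / 2) {
    ph <- which(t < ends)[1]
    target <- vBase * factors[ph]
    v <- v + dt * (target - v) / tauMin
    t <- t + dt
  }
  v
}

# brute-force VFA least-squares oracle: grid over T1, closed-form M0 per
# candidate (signal is linear in M0)
gridVFAOracle <- function(signals, alphasDeg, trMs,
                          t1Grid = seq(1, 5000, by = 0.1)) {
  best <- c(t1 = NA_real_, m0 = NA_real_, rss = Inf)
  for (t1 in t1Grid) {
    f <- spgrSignal(1, t1, alphasDeg, trMs)
    m0 <- sum(signals * f) / sum(f^2)
    rss <- sum((signals - m0 * f)^2)
    if (rss < best["rss"]) best <- c(t1 = t1, m0 = m0, rss = rss)
  }
  best
}
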