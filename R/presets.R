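#' Sex-specific phantom presets
#'
#' Ready-made phantom specifications whose myocardial ground-truth T1
#' trajectory encodes the measured group-mean values for healthy adult
#' female and male rats: pre-contrast myocardial T1 of 1195 ms (female) /
#' 963 ms (male); post-contrast baseline T1 of 452 / 312 ms held through
#' the first normoxia block; hypercapnic percent steps of -12%, -20%
#' (female) and -1%, +5% (male) at 5 and 10 min relative to baseline; and
#' normoxia-return steps of +18%, +23% (female) and +16%, +19% (male)
#' relative to the end-of-hypercapnia value. The generator inverts the
#' relaxation model to find the blood-volume fraction producing each
#' target, so the trajectory is bona fide model ground truth, not painted
#' pixels.
#'
#' @param sex "female" or "male".
#' @param matrixSize,nSlices phantom grid (defaults: the full 128 x 128,
#'   16-slice acquisition matrix).
#' @param noiseSigma Rician noise scale relative to blood M0 (default 0).
#' @param seed random seed.
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- phantomPreset("female", matrixSize = 32, nSlices = 2)
#' groundTruth(spec)@table[1:7, ]
#' @export
phantomPreset <- function(sex = c("female", "male"), matrixSize = 128L,
                          nSlices = 16L, noiseSigma = 0, seed = 1L) {
  sex <- match.arg(sex)
  p <- .presetTable[[sex]]
  targets <- .presetT1Trajectory(sex)
  tissues <- c(
    lapply(c("septum", "anterior_wall", "posterior_wall"), function(lab)
      tissueSpec(lab, t1PreMs = p$t1PreMs, m0 = 800, vBase = 0.10,
                 phaseFactors = c(1, 1, 1), t1TargetsMs = targets)),
    list(tissueSpec("lv_blood", t1PreMs = 1650, m0 = 1000, vBase = 1,
                    phaseFactors = c(1, 1, 1))))
  phantomSpec(
    vfa = vfaParams(matrixSize = matrixSize, nSlices = nSlices),
    cine = cineParams(matrixSize = matrixSize, nSlices = nSlices),
    tissues = tissues, noiseSigma = noiseSigma, seed = seed)
}

# group-mean trajectory parameters (T1 in ms, steps in percent)
.presetTable <- list(
  female = list(t1PreMs = 1195, t1BaselineMs = 452,
                co2StepsPct = c(-12, -20), returnStepsPct = c(18, 23),
                bpuCO2Pct = 33, bpuReturnPct = NA_real_,
                hrCO2Pct = 4, hrReturnPct = 5),
  male = list(t1PreMs = 963, t1BaselineMs = 312,
              co2StepsPct = c(-1, 5), returnStepsPct = c(16, 19),
              bpuCO2Pct = -12, bpuReturnPct = -24,
              hrCO2Pct = 11, hrReturnPct = 1)
)

# target myocardial T1 at the 7 default imaging timepoints
.presetT1Trajectory <- function(sex) {
  p <- .presetTable[[sex]]
  b <- p$t1BaselineMs
  co2 <- b * (1 + p$co2StepsPct / 100)
  ret <- co2[2] * (1 + p$returnStepsPct / 100)
  c(b, b, b, co2, ret)
}

#' Sex-specific laser Doppler presets
#'
#' Synthetic perfusion traces over the default gas regime whose plateau
#' factors encode the measured perfusion and heart-rate responses: female —
#' +33% perfusion under hypercapnia with the normoxia-return phase
#' corrupted by probe motion (reported "not measured"); male — -12%
#' perfusion under hypercapnia and a further -24% on return, with an +11%
#' hypercapnic heart-rate rise. Baseline heart rate is 350 bpm; transitions
#' use a 1-min time constant so the end-of-phase analysis window sits on
#' the plateau.
#'
#' @param sex "female" or "male".
#' @param baselineBpu baseline perfusion level.
#' @param noiseSigma Gaussian noise as a fraction of baseline (default 0).
#' @param seed random seed.
#' @return A [DopplerTrace-class].
#' @export
dopplerPreset <- function(sex = c("female", "male"), baselineBpu = 100,
                          noiseSigma = 0, seed = 1L) {
  sex <- match.arg(sex)
  p <- .presetTable[[sex]]
  sched <- gasSchedule()
  perf <- c(1, 1 + p$bpuCO2Pct / 100,
            if (is.na(p$bpuReturnPct)) 1
            else (1 + p$bpuCO2Pct / 100) * (1 + p$bpuReturnPct / 100))
  hrf <- c(1, 1 + p$hrCO2Pct / 100,
           (1 + p$hrCO2Pct / 100) * (1 + p$hrReturnPct / 100))
  corrupt <- if (sex == "female") {
    totS <- totalDurationMin(sched) * 60
    list(c(totS - 120, totS))   # probe motion ruins the final end-window
  } else NULL
  synthDoppler(sched, baselineBpu = baselineBpu,
               phasePerfusionFactors = perf, heartRateBpm = 350,
               hrPhaseFactors = hrf, tauMin = 1,
               noiseSigma = noiseSigma, corruptWindows = corrupt,
               seed = seed)
}
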