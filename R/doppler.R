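#' Construct a laser Doppler trace
#'
#' @param timeS sample times in seconds (uniform 10 Hz grid starting at 0).
#' @param bpu perfusion samples in relative blood perfusion units.
#' @param groundTruth optional list of generator truth (synthetic traces).
#' @return A [DopplerTrace-class].
#' @export
dopplerTrace <- function(timeS, bpu, groundTruth = list()) {
  new("DopplerTrace", timeS = as.numeric(timeS), bpu = as.numeric(bpu),
      sampleRateHz = 10, quality = data.frame(), groundTruth = groundTruth)
}

#' Synthesize a laser Doppler perfusion trace over a gas regime
#'
#' BPU(t) = baseline * g(t) * (1 + ripple) + Gaussian noise, where g(t)
#' follows the per-phase perfusion factors with the same exponential
#' phase-approach kinetics as the phantom's blood-volume fraction, and the
#' ripple is a sinusoid at the (possibly phase-modulated) heart rate. The
#' ripple phase is integrated from the instantaneous rate so heart-rate
#' transitions are continuous. Corruption windows replace samples with
#' high-variance noise around the local level, emulating motion of the
#' heart against the optical probe; negative samples are clipped at 0
#' (perfusion units are magnitudes).
#'
#' @param schedule a [GasSchedule-class]; the trace spans it at 10 Hz.
#' @param baselineBpu baseline perfusion (> 0).
#' @param phasePerfusionFactors per-phase multiplicative perfusion targets.
#' @param heartRateBpm baseline heart rate in beats per minute.
#' @param hrPhaseFactors per-phase multiplicative heart-rate targets
#'   (default: no change).
#' @param rippleAmp relative amplitude of the cardiac ripple (0 disables).
#' @param tauMin exponential approach time constant in minutes for both
#'   perfusion and heart-rate transitions.
#' @param noiseSigma Gaussian noise SD as a fraction of \code{baselineBpu}.
#' @param corruptWindows list of \code{c(startS, endS)} windows to corrupt;
#'   must lie inside the trace.
#' @param seed integer random seed.
#' @return A [DopplerTrace-class] with generator truth in
#'   \code{groundTruth}: per-phase plateau factors, heart-rate targets, the
#'   instantaneous true rate, and the corrupt windows.
#' @examples
#' tr <- synthDoppler(gasSchedule(), 100, c(1, 1.33, 1), 350)
#' length(tr@bpu)
#' @export
synthDoppler <- function(schedule, baselineBpu, phasePerfusionFactors,
                         heartRateBpm, hrPhaseFactors = NULL,
                         rippleAmp = 0.05, tauMin = 1, noiseSigma = 0,
                         corruptWindows = NULL, seed = 1L) {
  stopifnot(baselineBpu > 0)
  fs <- 10
  totS <- totalDurationMin(schedule) * 60
  n <- as.integer(totS * fs)
  tS <- (seq_len(n) - 1) / fs
  tMin <- tS / 60
  if (is.null(hrPhaseFactors))
    hrPhaseFactors <- rep(1, nrow(schedule@phases))
  g <- .phaseResponse(tMin, schedule, phasePerfusionFactors, tauMin)
  hr <- heartRateBpm * .phaseResponse(tMin, schedule, hrPhaseFactors, tauMin)
  phase <- 2 * pi * cumsum(hr / 60) / fs
  set.seed(as.integer(seed))
  bpu <- baselineBpu * g * (1 + rippleAmp * sin(phase)) +
    stats::rnorm(n, sd = noiseSigma * baselineBpu)
  if (!is.null(corruptWindows)) {
    for (w in corruptWindows) {
      if (w[1] < 0 || w[2] > totS || w[2] <= w[1])
        stop("corrupt window [", w[1], ", ", w[2], "] s outside the trace")
      sel <- tS >= w[1] & tS < w[2]
      bpu[sel] <- stats::rnorm(sum(sel), mean = baselineBpu * g[sel],
                               sd = baselineBpu)
    }
  }
  dopplerTrace(tS, pmax(bpu, 0), groundTruth = list(
    baselineBpu = baselineBpu,
    phasePerfusionFactors = phasePerfusionFactors,
    heartRateBpm = heartRateBpm, hrPhaseFactors = hrPhaseFactors,
    trueHrBpm = hr, trueG = g,
    corruptWindows = if (is.null(corruptWindows)) list() else corruptWindows,
    schedule = schedule))
}

#' Flag motion-corrupted windows of a Doppler trace
#'
#' Splits the trace into consecutive windows and computes a normalized
#' variance metric per window, var(x) / mean(x)^2 (a squared coefficient of
#' variation, so the flagging is invariant to the arbitrary BPU gain). A
#' window is flagged bad when its metric exceeds \code{varThreshold} times
#' the median window metric — the robust stand-in for the clean-trace
#' variance, matching the failure mode where probe motion degrades the
#' signal to noise.
#'
#' @param trace a [DopplerTrace-class].
#' @param windowS window length in seconds (default 10).
#' @param varThreshold multiple of the clean (median) metric above which a
#'   window is flagged (default 5).
#' @return the trace with its \code{quality} slot filled (columns
#'   \code{startS}, \code{endS}, \code{ok}, \code{metric}).
#' @export
flagCorruption <- function(trace, windowS = 10, varThreshold = 5) {
  fs <- trace@sampleRateHz
  wlen <- as.integer(windowS * fs)
  nwin <- floor(length(trace@bpu) / wlen)
  starts <- (seq_len(nwin) - 1) * wlen + 1
  metric <- vapply(starts, function(s) {
    x <- trace@bpu[s:(s + wlen - 1)]
    m <- mean(x)
    if (m <= 0) return(Inf)
    stats::var(x) / m^2
  }, numeric(1))
  ref <- stats::median(metric)
  ok <- if (ref == 0) metric == 0 else metric <= varThreshold * ref
  trace@quality <- data.frame(
    startS = (starts - 1) / fs, endS = (starts - 1 + wlen) / fs,
    ok = ok, metric = metric)
  trace
}

# logical mask of samples lying in windows flagged bad (all-good if quality
# has not been computed)
.badSampleMask <- function(trace) {
  bad <- rep(FALSE, length(trace@timeS))
  q <- trace@quality
  if (nrow(q)) for (i in which(!q$ok))
    bad[trace@timeS >= q$startS[i] & trace@timeS < q$endS[i]] <- TRUE
  bad
}

#' Per-phase end-window perfusion means
#'
#' Mean BPU over the final \code{windowS} seconds of each gas phase,
#' excluding samples in windows flagged as corrupted. A phase whose entire
#' end window is corrupted is reported as "not measured" (NA mean) rather
#' than an error.
#'
#' @param trace a [DopplerTrace-class]; if its quality flags have not been
#'   computed, [flagCorruption()] is applied with defaults first.
#' @param schedule the [GasSchedule-class] the trace spans.
#' @param windowS averaging window in seconds (default 60).
#' @return data.frame with one row per phase: \code{phase}, \code{label},
#'   \code{gas}, \code{meanBpu} (NA when not measured), \code{nSamples},
#'   \code{measured}.
#' @export
phaseMeanBPU <- function(trace, schedule, windowS = 60) {
  totS <- totalDurationMin(schedule) * 60
  if (max(trace@timeS) < totS - 1 / trace@sampleRateHz - 1e-9)
    stop("trace does not span the schedule")
  if (!nrow(trace@quality)) trace <- flagCorruption(trace)
  bad <- .badSampleMask(trace)
  ends <- phaseEndsMin(schedule) * 60
  out <- lapply(seq_along(ends), function(p) {
    sel <- trace@timeS >= ends[p] - windowS & trace@timeS < ends[p] & !bad
    data.frame(phase = p, label = schedule@phases$label[p],
               gas = schedule@phases$gas[p],
               meanBpu = if (any(sel)) mean(trace@bpu[sel]) else NA_real_,
               nSamples = sum(sel), measured = any(sel),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-phase perfusion percent changes
#'
#' Expresses each phase's end-window mean BPU as a percent change relative
#' to the previous phase's end-window mean — the same reference convention
#' as the MRI percent-change table. A "not measured" phase (or reference)
#' propagates as a "not measured" row.
#'
#' @param phaseMeans data.frame from [phaseMeanBPU()].
#' @return data.frame with one row per transition: \code{interval},
#'   \code{phase}, \code{percent} (NA when not measured), \code{measured}.
#' @export
percentChangeBPU <- function(phaseMeans) {
  pm <- phaseMeans
  rows <- lapply(seq_len(nrow(pm))[-1], function(p) {
    ok <- pm$measured[p] && pm$measured[p - 1]
    nm <- if (p > 2 && pm$label[p] == "normoxia") "normoxia_return"
          else pm$label[p]
    data.frame(
      interval = nm, phase = p,
      percent = if (ok)
        100 * (pm$meanBpu[p] - pm$meanBpu[p - 1]) / pm$meanBpu[p - 1]
      else NA_real_,
      measured = ok, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# periodogram magnitude of x (sampled at fs) at frequencies fHz; for real
# signals power at f equals power at fs - f, so evaluating at a
# beyond-Nyquist candidate directly probes its aliased component
.tonePower <- function(x, fs, fHz) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  vapply(fHz, function(f) Mod(sum(x * exp(-2i * pi * f * t))) / n, numeric(1))
}

#' Windowed spectral heart-rate extraction
#'
#' Estimates the heart rate in consecutive windows from the dominant
#' spectral peak of the mean-removed trace, then refines the peak on a fine
#' frequency grid. Rat heart rates (> 300 bpm, i.e. > 5 Hz) exceed the
#' Nyquist frequency of the fixed 10 Hz sampling and appear aliased; the
#' estimator therefore searches candidate rates inside a physiological band
#' and scores each candidate by its (alias-equivalent) spectral power, so
#' the reported rate is the true one. Windows whose peak does not rise
#' above the noise floor, or that are flagged as corrupted, yield NA.
#'
#' Per-phase percent changes use each phase's final window relative to the
#' previous phase's final window, as in the perfusion table.
#'
#' @param trace a [DopplerTrace-class].
#' @param schedule optional [GasSchedule-class]; when supplied, per-phase
#'   heart rates and percent changes are included.
#' @param windowS analysis window in seconds (default 60; at 10 Hz this
#'   gives 1-bpm native spectral resolution before refinement).
#' @param bpmRange physiological search band in bpm (default c(300, 550)).
#' @param peakSNR minimum ratio of peak power to median spectral power for
#'   a window to count as having a pulsatile peak (default 5).
#' @return list with \code{windows} (data.frame: \code{startS},
#'   \code{endS}, \code{bpm}, \code{ok}) and, with a schedule,
#'   \code{phaseBpm} (final-window bpm per phase) and
#'   \code{percentChanges} (data.frame like [percentChangeBPU()]'s).
#' @export
heartRate <- function(trace, schedule = NULL, windowS = 60,
                      bpmRange = c(300, 550), peakSNR = 5) {
  fs <- trace@sampleRateHz
  wlen <- as.integer(windowS * fs)
  nwin <- floor(length(trace@bpu) / wlen)
  if (!nrow(trace@quality)) trace <- flagCorruption(trace)
  bad <- .badSampleMask(trace)
  coarse <- seq(bpmRange[1], bpmRange[2], by = 1)
  est <- vapply(seq_len(nwin), function(w) {
    s <- (w - 1) * wlen + 1
    idx <- s:(s + wlen - 1)
    if (mean(bad[idx]) > 0.5) return(NA_real_)
    x <- trace@bpu[idx]
    x <- x - mean(x)
    pw <- .tonePower(x, fs, coarse / 60)
    pk <- which.max(pw)
    if (pw[pk] < peakSNR * stats::median(pw)) return(NA_real_)
    fine <- seq(coarse[pk] - 1, coarse[pk] + 1, by = 0.01)
    fine[which.max(.tonePower(x, fs, fine / 60))]
  }, numeric(1))
  windows <- data.frame(
    startS = (seq_len(nwin) - 1) * windowS,
    endS = seq_len(nwin) * windowS,
    bpm = est, ok = !is.na(est))
  out <- list(windows = windows)
  if (!is.null(schedule)) {
    ends <- phaseEndsMin(schedule) * 60
    phaseBpm <- vapply(ends, function(e) {
      w <- which(windows$endS <= e + 1e-9)
      w <- w[windows$endS[w] > e - windowS - 1e-9]
      if (length(w)) windows$bpm[max(w)] else NA_real_
    }, numeric(1))
    pm <- data.frame(phase = seq_along(ends),
                     label = schedule@phases$label,
                     gas = schedule@phases$gas,
                     meanBpu = phaseBpm, nSamples = wlen,
                     measured = !is.na(phaseBpm))
    pc <- percentChangeBPU(pm)
    out$phaseBpm <- phaseBpm
    out$percentChanges <- pc
  }
  out
}
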