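#' Construct SPGR acquisition parameters
#'
#' @param flipAnglesDeg numeric vector of flip angles in degrees.
#' @param trMs repetition time in ms.
#' @param teMs echo time in ms (metadata only).
#' @param matrixSize in-plane matrix size.
#' @param fovMm in-plane field of view in mm.
#' @param nSlices number of slices.
#' @param sliceThicknessMm slice thickness in mm.
#' @return An [AcquisitionParams-class] object.
#' @examples
#' vfaParams()
#' cineParams(matrixSize = 64)
#' @export
acquisitionParams <- function(flipAnglesDeg, trMs, teMs = NA_real_,
                              matrixSize = 128L, fovMm = 70,
                              nSlices = 16L, sliceThicknessMm = 1) {
  new("AcquisitionParams",
      flipAnglesDeg = as.numeric(flipAnglesDeg), trMs = as.numeric(trMs),
      teMs = as.numeric(teMs), matrixSize = as.integer(matrixSize),
      fovMm = as.numeric(fovMm), nSlices = as.integer(nSlices),
      sliceThicknessMm = as.numeric(sliceThicknessMm))
}

#' @describeIn acquisitionParams CINE protocol defaults: FA 15 deg, TR 6 ms,
#'   TE 2.79 ms, 70 mm FOV, 128 x 128, 16 slices of 1 mm.
#' @param ... overrides passed to [acquisitionParams()].
#' @export
cineParams <- function(...) {
  args <- utils::modifyList(
    list(flipAnglesDeg = 15, trMs = 6, teMs = 2.79), list(...))
  do.call(acquisitionParams, args)
}

#' @describeIn acquisitionParams VFA T1-mapping protocol defaults:
#'   FA {2, 5, 10, 15, 20} deg, TR 7 ms, TE 3.36 ms, same geometry.
#' @export
vfaParams <- function(...) {
  args <- utils::modifyList(
    list(flipAnglesDeg = c(2, 5, 10, 15, 20), trMs = 7, teMs = 3.36),
    list(...))
  do.call(acquisitionParams, args)
}

#' Construct a gas challenge schedule
#'
#' The default mirrors the standard regime: 10 min normoxia (21% O2), 10 min
#' hypercapnia (10% CO2), 10 min normoxia, imaged every 5 min, so imaging
#' timepoints fall at 0, 5, 10, 15, 20, 25, 30 min with t = 0 the
#' post-contrast baseline.
#'
#' @param labels character vector of phase labels
#'   ("normoxia"/"hypercapnia").
#' @param gas character vector of gas mixture descriptions.
#' @param durationMin numeric vector of phase durations in minutes.
#' @param imagingIntervalMin minutes between CINE acquisitions.
#' @return A [GasSchedule-class] object.
#' @examples
#' sched <- gasSchedule()
#' imagingTimes(sched)
#' @export
gasSchedule <- function(labels = c("normoxia", "hypercapnia", "normoxia"),
                        gas = c("21% O2", "10% CO2", "21% O2"),
                        durationMin = c(10, 10, 10),
                        imagingIntervalMin = 5) {
  new("GasSchedule",
      phases = data.frame(label = labels, gas = gas,
                          durationMin = as.numeric(durationMin),
                          stringsAsFactors = FALSE),
      imagingIntervalMin = as.numeric(imagingIntervalMin))
}

#' @rdname gasSchedule
#' @param schedule a [GasSchedule-class].
#' @return \code{totalDurationMin}: total regime length in minutes.
#' @export
totalDurationMin <- function(schedule) sum(schedule@phases$durationMin)

#' @rdname gasSchedule
#' @return \code{phaseStartsMin}: start time (min) of each phase.
#' @export
phaseStartsMin <- function(schedule)
  c(0, cumsum(schedule@phases$durationMin))[seq_len(nrow(schedule@phases))]

#' @rdname gasSchedule
#' @return \code{phaseEndsMin}: end time (min) of each phase.
#' @export
phaseEndsMin <- function(schedule) cumsum(schedule@phases$durationMin)

#' @rdname gasSchedule
#' @return \code{imagingTimes}: the CINE imaging timepoints in minutes,
#'   from 0 to the end of the regime at \code{imagingIntervalMin} steps.
#' @export
imagingTimes <- function(schedule)
  seq(0, totalDurationMin(schedule), by = schedule@imagingIntervalMin)

# phase index containing each time t (boundaries belong to the earlier
# phase, except t = 0 which belongs to phase 1)
.phaseIndexAt <- function(schedule, tMin) {
  ends <- phaseEndsMin(schedule)
  idx <- findInterval(tMin, c(0, ends), left.open = TRUE, all.inside = FALSE)
  idx[tMin == 0] <- 1L
  if (any(idx < 1L | idx > length(ends)))
    stop("time outside the gas regime [0, ", totalDurationMin(schedule),
         "] min")
  idx
}
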