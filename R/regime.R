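#' Construct an ROI set
#'
#' @param labelVolume 3D integer array (0 = background).
#' @param roiNames named character vector mapping label values (names, as
#'   characters) to region names.
#' @return An [ROISet-class].
#' @export
roiSet <- function(labelVolume, roiNames) {
  storage.mode(labelVolume) <- "integer"
  new("ROISet", labelVolume = labelVolume, roiNames = roiNames)
}

#' Subset an ROI set to the myocardial wall regions
#'
#' @param rois an [ROISet-class].
#' @param regions region names to keep (default: the three wall sectors).
#' @return An [ROISet-class] restricted to \code{regions}.
#' @export
myocardialROIs <- function(rois, regions = c("septum", "anterior_wall",
                                             "posterior_wall")) {
  keep <- rois@roiNames %in% regions
  if (!any(keep)) stop("none of the requested regions are present")
  new("ROISet", labelVolume = rois@labelVolume,
      roiNames = rois@roiNames[keep])
}

#' Per-ROI mean T1
#'
#' Arithmetic mean of T1 over the valid voxels of each ROI. An ROI with no
#' valid voxels is an error naming the region: a silent NA would poison the
#' percent-change table downstream.
#'
#' @param map a [T1Map-class].
#' @param rois an [ROISet-class].
#' @return list with \code{means} (named numeric, ms) and \code{nVoxels}
#'   (named integer counts of valid voxels).
#' @export
roiMeanT1 <- function(map, rois) {
  if (!identical(dim(map@t1Ms), dim(rois@labelVolume)))
    stop("map and ROI volumes must be congruent")
  labs <- as.integer(names(rois@roiNames))
  means <- numeric(length(labs))
  nv <- integer(length(labs))
  for (i in seq_along(labs)) {
    sel <- rois@labelVolume == labs[i] & map@validMask
    nv[i] <- sum(sel)
    if (nv[i] == 0L)
      stop("ROI '", rois@roiNames[i], "' has no valid voxels")
    means[i] <- mean(map@t1Ms[sel])
  }
  list(means = stats::setNames(means, unname(rois@roiNames)),
       nVoxels = stats::setNames(nv, unname(rois@roiNames)))
}

#' Assemble a per-ROI T1 time course
#'
#' Computes post-contrast T1 maps for every CINE timepoint (via
#' [mapPostT1()]), the per-ROI mean T1 at each timepoint, and the pooled
#' myocardial mean — the average of the per-ROI means across the septum,
#' anterior and posterior wall, which is how the myocardium is summarised
#' for reporting.
#'
#' @param cineSeries 4D numeric array (x, y, z, timepoint).
#' @param pre a pre-contrast [T1Map-class].
#' @param acq the CINE [AcquisitionParams-class].
#' @param rois an [ROISet-class]; only myocardial wall regions enter the
#'   pooled mean.
#' @param schedule a [GasSchedule-class] supplying imaging times.
#' @return A [T1TimeCourse-class].
#' @export
t1TimeCourse <- function(cineSeries, pre, acq, rois, schedule) {
  tp <- imagingTimes(schedule)
  if (dim(cineSeries)[4] != length(tp))
    stop("CINE series has ", dim(cineSeries)[4], " timepoints but the ",
         "schedule implies ", length(tp))
  myo <- myocardialROIs(rois)
  nms <- unname(myo@roiNames)
  roiM <- matrix(NA_real_, length(tp), length(nms),
                 dimnames = list(NULL, nms))
  nVox <- matrix(NA_integer_, length(tp), length(nms),
                 dimnames = list(NULL, nms))
  for (i in seq_along(tp)) {
    m <- mapPostT1(cineSeries[, , , i, drop = FALSE][, , , 1], pre, acq)
    rm <- roiMeanT1(m, myo)
    roiM[i, names(rm$means)] <- rm$means
    nVox[i, names(rm$nVoxels)] <- rm$nVoxels
  }
  new("T1TimeCourse", timepointsMin = tp, roiMeans = roiM, nVoxels = nVox,
      pooled = rowMeans(roiM),
      percentChanges = data.frame())
}

#' Gas-interval percent changes of the pooled myocardial T1
#'
#' Reproduces the regime bookkeeping of the standard results table: within
#' each post-baseline gas phase, the T1 at each imaging timepoint is
#' expressed as a percent change relative to the T1 at the end of the
#' previous phase. For the default regime this means the two hypercapnia
#' timepoints are referenced to the post-contrast baseline (end of the
#' first normoxia block) and the two normoxia-return timepoints to the end
#' of hypercapnia. Percent change is 100 * (T1_t - T1_ref) / T1_ref.
#'
#' @param course a [T1TimeCourse-class].
#' @param schedule the [GasSchedule-class] the course was imaged under.
#' @return The course with its \code{percentChanges} slot filled: a
#'   data.frame with columns \code{interval} (e.g. "hypercapnia_10min"),
#'   \code{phase}, \code{minutesIntoPhase}, \code{timeMin},
#'   \code{referenceMin}, \code{percent}.
#' @export
percentChanges <- function(course, schedule) {
  tp <- course@timepointsMin
  if (!isTRUE(all.equal(tp, imagingTimes(schedule))))
    stop("course timepoints do not align with the schedule")
  t1 <- course@pooled
  starts <- phaseStartsMin(schedule)
  ends <- phaseEndsMin(schedule)
  labs <- schedule@phases$label
  rows <- list()
  for (p in seq_along(labs)[-1]) {
    refT <- starts[p]          # end of previous phase
    refIdx <- which(tp == refT)
    if (!length(refIdx))
      stop("missing reference timepoint at ", refT, " min")
    inPhase <- which(tp > starts[p] & tp <= ends[p])
    for (i in inPhase) {
      dmin <- tp[i] - starts[p]
      nm <- if (p > 2 && labs[p] == "normoxia") "normoxia_return" else labs[p]
      rows[[length(rows) + 1L]] <- data.frame(
        interval = sprintf("%s_%gmin", nm, dmin),
        phase = labs[p], minutesIntoPhase = dmin,
        timeMin = tp[i], referenceMin = refT,
        percent = 100 * (t1[i] - t1[refIdx]) / t1[refIdx],
        stringsAsFactors = FALSE)
    }
  }
  course@percentChanges <- do.call(rbind, rows)
  course
}
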