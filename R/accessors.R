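#' Accessors for vasoreact objects
#'
#' Slot access for the core classes, so user code never reaches into
#' \code{@} slots directly.
#'
#' @param object a vasoreact S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @return \code{t1Values}: the T1 array (ms) of a [T1Map-class].
#' @export
setGeneric("t1Values", function(object) standardGeneric("t1Values"))

#' @rdname accessors
#' @export
setMethod("t1Values", "T1Map", function(object) object@t1Ms)

#' @rdname accessors
#' @return \code{m0Values}: the M0 array of a [T1Map-class].
#' @export
setGeneric("m0Values", function(object) standardGeneric("m0Values"))

#' @rdname accessors
#' @export
setMethod("m0Values", "T1Map", function(object) object@m0)

#' @rdname accessors
#' @return \code{validMask}: the logical validity array of a
#'   [T1Map-class].
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setMethod("validMask", "T1Map", function(object) object@validMask)

#' @rdname accessors
#' @return \code{pooledT1}: pooled myocardial mean T1 per timepoint of a
#'   [T1TimeCourse-class].
#' @export
setGeneric("pooledT1", function(object) standardGeneric("pooledT1"))

#' @rdname accessors
#' @export
setMethod("pooledT1", "T1TimeCourse", function(object) object@pooled)

#' @rdname accessors
#' @return \code{roiMeans}: the timepoint-by-ROI matrix of mean T1 (ms).
#' @export
setGeneric("roiMeans", function(object) standardGeneric("roiMeans"))

#' @rdname accessors
#' @export
setMethod("roiMeans", "T1TimeCourse", function(object) object@roiMeans)

#' @rdname accessors
#' @return \code{changeTable}: the percent-change data.frame of a
#'   [T1TimeCourse-class].
#' @export
setGeneric("changeTable", function(object) standardGeneric("changeTable"))

#' @rdname accessors
#' @export
setMethod("changeTable", "T1TimeCourse",
          function(object) object@percentChanges)

#' @rdname accessors
#' @return \code{bpuValues}: the BPU samples of a [DopplerTrace-class].
#' @export
setGeneric("bpuValues", function(object) standardGeneric("bpuValues"))

#' @rdname accessors
#' @export
setMethod("bpuValues", "DopplerTrace", function(object) object@bpu)

#' @rdname accessors
#' @return \code{traceTimes}: the sample times (s) of a
#'   [DopplerTrace-class].
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))

#' @rdname accessors
#' @export
setMethod("traceTimes", "DopplerTrace", function(object) object@timeS)

#' @rdname accessors
#' @return \code{qualityFlags}: the per-window quality data.frame of a
#'   [DopplerTrace-class].
#' @export
setGeneric("qualityFlags", function(object) standardGeneric("qualityFlags"))

#' @rdname accessors
#' @export
setMethod("qualityFlags", "DopplerTrace", function(object) object@quality)

#' @rdname accessors
#' @return \code{truthTable}: the trajectory data.frame of a
#'   [GroundTruth-class].
#' @export
setGeneric("truthTable", function(object) standardGeneric("truthTable"))

#' @rdname accessors
#' @export
setMethod("truthTable", "GroundTruth", function(object) object@table)
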