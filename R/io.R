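#' Write a volume or series as NIfTI
#'
#' @param arr 3D or 4D numeric array (x, y, z[, t/flip-angle]).
#' @param acq an [AcquisitionParams-class] supplying voxel geometry.
#' @param path output path (".nii.gz").
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(arr, acq, path) {
  px <- acq@fovMm / acq@matrixSize
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(px, px, acq@sliceThicknessMm,
                           rep(1, nd - 3))[seq_len(nd)]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path a NIfTI file.
#' @return numeric array.
#' @export
readVolume <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Read / write a Doppler trace as CSV
#'
#' Plain CSV with columns \code{time_s} and \code{bpu}.
#'
#' @param trace a [DopplerTrace-class].
#' @param path CSV path.
#' @return \code{writeDopplerCSV}: \code{path} invisibly;
#'   \code{readDopplerCSV}: a [DopplerTrace-class].
#' @export
writeDopplerCSV <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace@timeS, bpu = trace@bpu),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDopplerCSV
#' @export
readDopplerCSV <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "bpu") %in% names(df)))
    stop("Doppler CSV needs columns time_s, bpu")
  dopplerTrace(df$time_s, df$bpu)
}

# ---- JSON serialization of specs ----------------------------------------

.scheduleToList <- function(s)
  list(phases = s@phases, imagingIntervalMin = s@imagingIntervalMin)

.scheduleFromList <- function(l)
  gasSchedule(labels = l$phases$label, gas = l$phases$gas,
              durationMin = l$phases$durationMin,
              imagingIntervalMin = l$imagingIntervalMin)

.acqToList <- function(a)
  list(flipAnglesDeg = a@flipAnglesDeg, trMs = a@trMs, teMs = a@teMs,
       matrixSize = a@matrixSize, fovMm = a@fovMm, nSlices = a@nSlices,
       sliceThicknessMm = a@sliceThicknessMm)

.acqFromList <- function(l) do.call(acquisitionParams, l)

.tissueToList <- function(t)
  list(label = t@label, t1PreMs = t@t1PreMs, m0 = t@m0, vBase = t@vBase,
       phaseFactors = t@phaseFactors, t1TargetsMs = t@t1TargetsMs)

.tissueFromList <- function(l) {
  l$phaseFactors <- as.numeric(unlist(l$phaseFactors))
  l$t1TargetsMs <- as.numeric(unlist(l$t1TargetsMs))
  do.call(tissueSpec, l)
}

#' Serialize a phantom spec to / from a JSON-ready list
#'
#' @param spec a [PhantomSpec-class].
#' @return \code{specToList}: a plain list; \code{specFromList}: a
#'   [PhantomSpec-class].
#' @export
specToList <- function(spec) {
  list(vfa = .acqToList(spec@vfa), cine = .acqToList(spec@cine),
       schedule = .scheduleToList(spec@schedule),
       tissues = lapply(spec@tissues, .tissueToList),
       contrast = list(doseMmolPerKg = spec@contrast@doseMmolPerKg,
                       r1PerMMPerS = spec@contrast@r1PerMMPerS,
                       cPlasma0MM = spec@contrast@cPlasma0MM,
                       eliminationHalflifeMin =
                         spec@contrast@eliminationHalflifeMin),
       kinetics = list(tauResponseMin = spec@kinetics@tauResponseMin),
       noiseSigma = spec@noiseSigma, seed = spec@seed)
}

#' @rdname specToList
#' @param l a list as produced by \code{specToList} (e.g. parsed JSON).
#' @export
specFromList <- function(l) {
  phantomSpec(
    vfa = .acqFromList(l$vfa), cine = .acqFromList(l$cine),
    schedule = .scheduleFromList(l$schedule),
    tissues = lapply(l$tissues, .tissueFromList),
    contrast = do.call(contrastModel, l$contrast),
    kinetics = do.call(vasoKinetics, l$kinetics),
    noiseSigma = l$noiseSigma, seed = l$seed)
}

#' Write a rendered series to disk
#'
#' Writes the VFA stack, CINE series and ROI labels as NIfTI and the
#' ground truth (trajectory table + generating spec) and schedule as JSON.
#'
#' @param series list from [renderSeries()].
#' @param spec the generating [PhantomSpec-class].
#' @param outDir output directory (created if absent).
#' @return \code{outDir}, invisibly.
#' @export
writeSeries <- function(series, spec, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeVolume(series$vfa, spec@vfa, file.path(outDir, "vfa.nii.gz"))
  writeVolume(series$cine, spec@cine, file.path(outDir, "cine.nii.gz"))
  writeVolume(series$rois@labelVolume, spec@cine,
              file.path(outDir, "rois.nii.gz"))
  jsonlite::write_json(
    list(roiNames = as.list(series$rois@roiNames)),
    file.path(outDir, "rois.json"), auto_unbox = TRUE)
  jsonlite::write_json(
    list(trajectory = series$truth@table, spec = specToList(spec)),
    file.path(outDir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")
  jsonlite::write_json(.scheduleToList(spec@schedule),
                       file.path(outDir, "schedule.json"),
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(outDir)
}
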