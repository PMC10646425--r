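#' @import methods
NULL

#' SPGR acquisition parameters
#'
#' Describes a spoiled gradient echo (SPGR) acquisition: the flip angles
#' played out, repetition time, and the imaging geometry. The same class
#' describes both the multi-flip-angle (VFA) T1-mapping acquisition and the
#' single-flip-angle CINE acquisition; the simulator and the fitters share it
#' so that simulated signal and model inversion always agree on TR and flip
#' angle.
#'
#' @slot flipAnglesDeg numeric, flip angles in degrees, each in (0, 90].
#' @slot trMs numeric(1), repetition time in ms (> 0).
#' @slot teMs numeric(1), echo time in ms. Metadata only: the steady-state
#'   SPGR signal model used throughout ignores TE decay.
#' @slot matrixSize integer(1), in-plane matrix (>= 8), images are
#'   \code{matrixSize x matrixSize}.
#' @slot fovMm numeric(1), in-plane field of view in mm.
#' @slot nSlices integer(1), number of slices.
#' @slot sliceThicknessMm numeric(1), slice thickness in mm.
#' @seealso [cineParams()], [vfaParams()] for constructors with protocol
#'   defaults.
#' @exportClass AcquisitionParams
setClass("AcquisitionParams",
  representation(
    flipAnglesDeg = "numeric",
    trMs = "numeric",
    teMs = "numeric",
    matrixSize = "integer",
    fovMm = "numeric",
    nSlices = "integer",
    sliceThicknessMm = "numeric"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (length(object@flipAnglesDeg) < 1L ||
      any(object@flipAnglesDeg <= 0 | object@flipAnglesDeg > 90))
    msg <- c(msg, "flip angles must lie in (0, 90] degrees")
  if (length(object@trMs) != 1L || object@trMs <= 0)
    msg <- c(msg, "trMs must be a single positive number")
  if (length(object@matrixSize) != 1L || object@matrixSize < 8L)
    msg <- c(msg, "matrixSize must be >= 8")
  if (object@nSlices < 1L) msg <- c(msg, "nSlices must be >= 1")
  if (object@fovMm <= 0 || object@sliceThicknessMm <= 0)
    msg <- c(msg, "fovMm and sliceThicknessMm must be positive")
  if (length(msg)) msg else TRUE
})

#' Gas challenge schedule
#'
#' An ordered sequence of gas phases (normoxia / hypercapnia) with durations
#' in minutes, plus the interval at which CINE volumes are acquired. Time 0
#' is the post-contrast baseline: the first CINE acquired after the
#' stabilisation wait that follows contrast injection.
#'
#' @slot phases data.frame with columns \code{label} (character, one of
#'   "normoxia"/"hypercapnia"), \code{gas} (free-text gas mixture, e.g.
#'   "21% O2"), \code{durationMin} (positive minutes).
#' @slot imagingIntervalMin numeric(1), minutes between CINE acquisitions.
#' @exportClass GasSchedule
setClass("GasSchedule",
  representation(phases = "data.frame", imagingIntervalMin = "numeric")
)

setValidity("GasSchedule", function(object) {
  ph <- object@phases
  msg <- character()
  need <- c("label", "gas", "durationMin")
  if (!all(need %in% names(ph)))
    return("phases must have columns label, gas, durationMin")
  if (nrow(ph) < 1L) msg <- c(msg, "at least one phase required")
  if (any(ph$durationMin <= 0)) msg <- c(msg, "phase durations must be > 0")
  if (!all(ph$label %in% c("normoxia", "hypercapnia")))
    msg <- c(msg, "phase labels must be 'normoxia' or 'hypercapnia'")
  if (object@imagingIntervalMin <= 0)
    msg <- c(msg, "imagingIntervalMin must be > 0")
  if (length(msg)) msg else TRUE
})

#' Tissue specification for the digital phantom
#'
#' Per-tissue ground truth: pre-contrast T1, equilibrium signal scale M0,
#' baseline microvascular blood-volume fraction, and per-gas-phase
#' multiplicative targets on that fraction (a hypercapnia factor of 1.25
#' means the vasculature dilates towards 125% of its baseline volume during
#' that phase). Alternatively a tissue can carry an explicit per-timepoint
#' target T1 trajectory (\code{t1TargetsMs}); the generator then inverts the
#' relaxation model to obtain the blood-volume fraction that produces it,
#' which is how the sex-specific presets encode their measured trajectories.
#'
#' @slot label character(1) tissue name, e.g. "septum", "lv_blood".
#' @slot t1PreMs numeric(1), pre-contrast T1 in ms (> 0).
#' @slot m0 numeric(1), equilibrium signal scale (arbitrary units, >= 0).
#' @slot vBase numeric(1), baseline blood-volume fraction in [0, 1].
#' @slot phaseFactors numeric, per-phase multiplicative target on the
#'   blood-volume fraction (recycled/validated against the schedule at
#'   render time); \code{vBase * max(phaseFactors)} must stay <= 1.
#' @slot t1TargetsMs numeric, optional explicit tissue T1 (ms) at each
#'   imaging timepoint; length 0 means "use the kinetic model".
#' @exportClass TissueSpec
setClass("TissueSpec",
  representation(
    label = "character",
    t1PreMs = "numeric",
    m0 = "numeric",
    vBase = "numeric",
    phaseFactors = "numeric",
    t1TargetsMs = "numeric"
  )
)

setValidity("TissueSpec", function(object) {
  msg <- character()
  if (object@t1PreMs <= 0) msg <- c(msg, "t1PreMs must be > 0")
  if (object@m0 < 0) msg <- c(msg, "m0 must be >= 0")
  if (object@vBase < 0 || object@vBase > 1)
    msg <- c(msg, "vBase must be in [0, 1]")
  if (length(object@phaseFactors) &&
      object@vBase * max(object@phaseFactors) > 1 + 1e-12)
    msg <- c(msg, "vBase * max(phaseFactors) must be <= 1")
  if (any(object@phaseFactors < 0)) msg <- c(msg, "phaseFactors must be >= 0")
  if (any(object@t1TargetsMs <= 0)) msg <- c(msg, "t1TargetsMs must be > 0")
  if (length(msg)) msg else TRUE
})

#' Blood-pool contrast agent model
#'
#' Mono-exponential plasma kinetics of an intravascular (albumin-binding)
#' gadolinium agent after the first-pass has settled. The default half-life
#' is long relative to the 30-min regime, so enhancement decays by well under
#' 5% over the experiment — the stable-enhancement window the blood-pool
#' method relies on.
#'
#' @slot doseMmolPerKg numeric(1), injected dose (metadata).
#' @slot r1PerMMPerS numeric(1), longitudinal relaxivity in 1/mM/s.
#' @slot cPlasma0MM numeric(1), plasma concentration (mM) at the
#'   post-contrast baseline (t = 0).
#' @slot eliminationHalflifeMin numeric(1), plasma half-life in minutes.
#' @exportClass ContrastModel
setClass("ContrastModel",
  representation(
    doseMmolPerKg = "numeric",
    r1PerMMPerS = "numeric",
    cPlasma0MM = "numeric",
    eliminationHalflifeMin = "numeric"
  )
)

setValidity("ContrastModel", function(object) {
  vals <- c(object@doseMmolPerKg, object@r1PerMMPerS, object@cPlasma0MM,
            object@eliminationHalflifeMin)
  if (any(vals <= 0)) "all contrast model parameters must be positive" else TRUE
})

#' Vasomodulation kinetics
#'
#' The blood-volume fraction approaches each gas phase's target
#' exponentially; \code{tauResponseMin} is the time constant of that
#' approach. Cardiac vasomodulatory responses to hypercapnia act on the
#' scale of minutes, hence the default of 3 minutes.
#'
#' @slot tauResponseMin numeric(1), exponential time constant in minutes (> 0).
#' @exportClass VasoKinetics
setClass("VasoKinetics", representation(tauResponseMin = "numeric"))

setValidity("VasoKinetics", function(object) {
  if (length(object@tauResponseMin) != 1L || object@tauResponseMin <= 0)
    "tauResponseMin must be a single positive number" else TRUE
})

#' Full phantom specification
#'
#' Everything needed to render a synthetic gas-challenge cardiac MRI
#' experiment: the two acquisitions (VFA pre-contrast, CINE time series),
#' the gas schedule, the tissues, the contrast agent, the vasomodulation
#' kinetics, the Rician noise level and the random seed.
#'
#' @slot vfa,cine [AcquisitionParams-class] for the two acquisitions.
#' @slot schedule [GasSchedule-class].
#' @slot tissues list of [TissueSpec-class] with unique labels.
#' @slot contrast [ContrastModel-class].
#' @slot kinetics [VasoKinetics-class].
#' @slot noiseSigma numeric(1), Rician noise scale as a fraction of the
#'   blood-pool M0 (0 = noiseless).
#' @slot seed integer(1), random seed for noise generation.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    vfa = "AcquisitionParams",
    cine = "AcquisitionParams",
    schedule = "GasSchedule",
    tissues = "list",
    contrast = "ContrastModel",
    kinetics = "VasoKinetics",
    noiseSigma = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!all(vapply(object@tissues, is, logical(1), "TissueSpec")))
    msg <- c(msg, "tissues must all be TissueSpec objects")
  labs <- vapply(object@tissues, function(t) t@label, character(1))
  if (anyDuplicated(labs)) msg <- c(msg, "tissue labels must be unique")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Phantom ground truth
#'
#' The true per-tissue trajectory underlying a rendered phantom: the
#' blood-volume fraction v(t), plasma concentration C(t) and tissue T1(t) at
#' every imaging timepoint, together with the [PhantomSpec-class] that
#' produced it. Serialized as JSON alongside the images so downstream
#' estimates can be compared against truth.
#'
#' @slot table data.frame with columns \code{tissue}, \code{timeMin},
#'   \code{v}, \code{cMM}, \code{t1Ms}.
#' @slot spec the generating [PhantomSpec-class].
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(table = "data.frame", spec = "PhantomSpec")
)

setValidity("GroundTruth", function(object) {
  need <- c("tissue", "timeMin", "v", "cMM", "t1Ms")
  if (!all(need %in% names(object@table)))
    return("table must have columns tissue, timeMin, v, cMM, t1Ms")
  if (any(object@table$t1Ms <= 0)) return("true T1 must be positive")
  TRUE
})

#' Voxelwise T1 map
#'
#' The result of voxelwise T1 quantification: T1 (ms) and M0 arrays, a
#' validity mask (TRUE where the fit or inversion succeeded and produced a
#' physical value), and a goodness-of-fit array (R^2 of the linearised VFA
#' regression; NA for single-point inversions). Invalid voxels hold NA in
#' \code{t1Ms} and are excluded from ROI statistics — never imputed.
#'
#' @slot t1Ms 3D numeric array, T1 in ms (NA where invalid).
#' @slot m0 3D numeric array, equilibrium signal (arbitrary units).
#' @slot validMask 3D logical array.
#' @slot r2Fit 3D numeric array (NA where not applicable).
#' @exportClass T1Map
setClass("T1Map",
  representation(
    t1Ms = "array", m0 = "array", validMask = "array", r2Fit = "array"
  )
)

setValidity("T1Map", function(object) {
  d <- dim(object@t1Ms)
  if (!identical(d, dim(object@m0)) || !identical(d, dim(object@validMask)) ||
      !identical(d, dim(object@r2Fit)))
    return("t1Ms, m0, validMask, r2Fit must share dimensions")
  ok <- object@validMask
  if (any(ok & (is.na(object@t1Ms) | object@t1Ms <= 0)))
    return("valid voxels must have positive finite T1")
  TRUE
})

#' Region-of-interest label set
#'
#' An integer label volume (0 = background) together with a map from label
#' value to region name. Regions are disjoint by construction of the label
#' volume.
#'
#' @slot labelVolume 3D integer array.
#' @slot roiNames named character: names are label values (as character),
#'   values are region names such as "septum".
#' @exportClass ROISet
setClass("ROISet",
  representation(labelVolume = "array", roiNames = "character")
)

setValidity("ROISet", function(object) {
  labs <- as.integer(names(object@roiNames))
  if (anyNA(labs)) return("roiNames must be named by integer label values")
  present <- labs %in% unique(as.vector(object@labelVolume))
  if (!all(present))
    return(paste("labels absent from volume:",
                 paste(labs[!present], collapse = ", ")))
  TRUE
})

#' Per-ROI T1 time course
#'
#' Mean T1 per ROI at each imaging timepoint, the number of valid voxels
#' entering each mean, the pooled myocardial mean (the average of the three
#' myocardial ROI means, matching how the wall regions are pooled for
#' reporting), and — once computed — the gas-interval percent-change table.
#'
#' @slot timepointsMin numeric, imaging times in minutes.
#' @slot roiMeans matrix (timepoints x ROIs) of mean T1 in ms.
#' @slot nVoxels matrix (timepoints x ROIs) of valid-voxel counts.
#' @slot pooled numeric, pooled myocardial mean T1 per timepoint.
#' @slot percentChanges data.frame as returned by [percentChanges()]
#'   (0 rows until computed).
#' @exportClass T1TimeCourse
setClass("T1TimeCourse",
  representation(
    timepointsMin = "numeric",
    roiMeans = "matrix",
    nVoxels = "matrix",
    pooled = "numeric",
    percentChanges = "data.frame"
  )
)

setValidity("T1TimeCourse", function(object) {
  if (nrow(object@roiMeans) != length(object@timepointsMin))
    return("roiMeans rows must match timepoints")
  if (length(object@pooled) != length(object@timepointsMin))
    return("pooled must have one value per timepoint")
  TRUE
})

#' Laser Doppler flowmetry trace
#'
#' A uniformly sampled (10 Hz) blood perfusion trace in relative blood
#' perfusion units (BPU), with per-window quality flags (set by
#' [flagCorruption()]) and, for synthetic traces, the generator ground
#' truth.
#'
#' @slot timeS numeric, sample times in seconds (uniform 10 Hz grid).
#' @slot bpu numeric, perfusion in BPU (>= 0).
#' @slot sampleRateHz numeric(1), fixed at 10.
#' @slot quality data.frame with columns \code{startS}, \code{endS},
#'   \code{ok} (0 rows until [flagCorruption()] is run).
#' @slot groundTruth list, generator truth for synthetic traces (empty for
#'   measured data).
#' @exportClass DopplerTrace
setClass("DopplerTrace",
  representation(
    timeS = "numeric",
    bpu = "numeric",
    sampleRateHz = "numeric",
    quality = "data.frame",
    groundTruth = "list"
  )
)

setValidity("DopplerTrace", function(object) {
  msg <- character()
  if (length(object@timeS) != length(object@bpu))
    return("timeS and bpu must have equal length")
  if (length(object@timeS) > 1L) {
    dt <- diff(object@timeS)
    if (max(abs(dt - 1 / object@sampleRateHz)) > 1e-9)
      msg <- c(msg, "sampling must be uniform at sampleRateHz")
  }
  if (any(object@bpu < 0)) msg <- c(msg, "bpu must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ANOVA + Fisher LSD result
#'
#' One-way ANOVA decomposition together with Fisher's Least Significant
#' Difference pairwise comparisons (unadjusted t tests on the pooled
#' within-group variance). Significance is flagged at P < 0.05.
#'
#' @slot anova list with elements \code{F}, \code{dfBetween},
#'   \code{dfWithin}, \code{p}, \code{msWithin}, \code{groupMeans},
#'   \code{groupN}.
#' @slot lsd data.frame with one row per pair: \code{group1}, \code{group2},
#'   \code{meanDiff}, \code{t}, \code{p}, \code{significant}.
#' @exportClass StatsResult
setClass("StatsResult", representation(anova = "list", lsd = "data.frame"))

setValidity("StatsResult", function(object) {
  a <- object@anova
  need <- c("F", "dfBetween", "dfWithin", "p")
  if (!all(need %in% names(a))) return("anova list incomplete")
  if (a$p < 0 || a$p > 1) return("p must lie in [0, 1]")
  if (nrow(object@lsd) &&
      !identical(object@lsd$significant, object@lsd$p < 0.05))
    return("significance flag must equal p < 0.05")
  TRUE
})
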