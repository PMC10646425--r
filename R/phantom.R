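#' Construct a tissue specification
#'
#' @param label tissue name.
#' @param t1PreMs pre-contrast T1 in ms.
#' @param m0 equilibrium signal scale (arbitrary units).
#' @param vBase baseline blood-volume fraction in [0, 1].
#' @param phaseFactors per-gas-phase multiplicative target on the
#'   blood-volume fraction.
#' @param t1TargetsMs optional explicit T1 (ms) at each imaging timepoint;
#'   when supplied it overrides the kinetic model for this tissue.
#' @return A [TissueSpec-class].
#' @export
tissueSpec <- function(label, t1PreMs, m0, vBase, phaseFactors = numeric(),
                       t1TargetsMs = numeric()) {
  new("TissueSpec", label = label, t1PreMs = as.numeric(t1PreMs),
      m0 = as.numeric(m0), vBase = as.numeric(vBase),
      phaseFactors = as.numeric(phaseFactors),
      t1TargetsMs = as.numeric(t1TargetsMs))
}

#' Construct a blood-pool contrast agent model
#'
#' Defaults describe an albumin-binding gadolinium agent at 0.3 mmol/kg with
#' relaxivity 19 /mM/s (typical of the albumin-bound regime), 0.5 mM plasma
#' concentration at the post-contrast baseline and a 420-min elimination
#' half-life, under which plasma concentration decays by under 5% across a
#' 30-min regime (2^(-30/420) ~ 0.952) — the stable-enhancement window the
#' blood-pool method assumes.
#'
#' @param doseMmolPerKg injected dose in mmol/kg.
#' @param r1PerMMPerS longitudinal relaxivity in 1/mM/s.
#' @param cPlasma0MM plasma concentration (mM) at baseline.
#' @param eliminationHalflifeMin plasma half-life in minutes.
#' @return A [ContrastModel-class].
#' @export
contrastModel <- function(doseMmolPerKg = 0.3, r1PerMMPerS = 19,
                          cPlasma0MM = 0.5, eliminationHalflifeMin = 420) {
  new("ContrastModel", doseMmolPerKg = as.numeric(doseMmolPerKg),
      r1PerMMPerS = as.numeric(r1PerMMPerS),
      cPlasma0MM = as.numeric(cPlasma0MM),
      eliminationHalflifeMin = as.numeric(eliminationHalflifeMin))
}

#' Construct vasomodulation kinetics
#'
#' @param tauResponseMin exponential time constant (minutes) with which the
#'   blood-volume fraction approaches each phase's target. Default 3 min
#'   (cardiac vasomodulation acts over minutes).
#' @return A [VasoKinetics-class].
#' @export
vasoKinetics <- function(tauResponseMin = 3)
  new("VasoKinetics", tauResponseMin = as.numeric(tauResponseMin))

#' Construct a phantom specification
#'
#' @param vfa,cine [AcquisitionParams-class] objects (defaults:
#'   [vfaParams()], [cineParams()]).
#' @param schedule a [GasSchedule-class].
#' @param tissues list of [TissueSpec-class]; default is the standard
#'   short-axis annulus tissue set from [defaultTissues()].
#' @param contrast a [ContrastModel-class].
#' @param kinetics a [VasoKinetics-class].
#' @param noiseSigma Rician noise scale relative to the blood-pool M0
#'   (0 = noiseless).
#' @param seed integer random seed used when rendering noise.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(vfa = vfaParams(), cine = cineParams(),
                        schedule = gasSchedule(),
                        tissues = defaultTissues(),
                        contrast = contrastModel(),
                        kinetics = vasoKinetics(),
                        noiseSigma = 0, seed = 1L) {
  new("PhantomSpec", vfa = vfa, cine = cine, schedule = schedule,
      tissues = tissues, contrast = contrast, kinetics = kinetics,
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
}

#' Default phantom tissue set
#'
#' A short-axis rat heart reduced to four tissues: three myocardial sectors
#' (septum, anterior wall, posterior wall) sharing one T1/M0/blood-volume
#' parameterisation, and the LV blood pool (blood-volume fraction 1, so its
#' T1 tracks plasma concentration directly). Myocardial defaults: T1 1100 ms
#' at 3 T, blood-volume fraction 0.10, hypercapnic dilation target 1.25.
#'
#' @param t1MyoMs pre-contrast myocardial T1 (ms).
#' @param m0Myo,m0Blood equilibrium signal scales.
#' @param vBaseMyo baseline myocardial blood-volume fraction.
#' @param myoPhaseFactors per-phase blood-volume factors for the myocardium
#'   (default: no change in normoxia, 1.25 in hypercapnia, return to 1).
#' @param t1BloodMs pre-contrast blood T1 (ms).
#' @return list of [TissueSpec-class].
#' @export
defaultTissues <- function(t1MyoMs = 1100, m0Myo = 800, m0Blood = 1000,
                           vBaseMyo = 0.10,
                           myoPhaseFactors = c(1, 1.25, 1),
                           t1BloodMs = 1650) {
  myo <- function(lab) tissueSpec(lab, t1MyoMs, m0Myo, vBaseMyo,
                                  myoPhaseFactors)
  list(myo("septum"), myo("anterior_wall"), myo("posterior_wall"),
       tissueSpec("lv_blood", t1BloodMs, m0Blood, vBase = 1,
                  phaseFactors = rep(1, length(myoPhaseFactors))))
}

# Shared per-phase exponential approach: multiplier g(t) starting at 1,
# approaching each phase's factor with time constant tauMin, continuous
# across phase boundaries. Vectorised over tMin.
.phaseResponse <- function(tMin, schedule, factors, tauMin) {
  nph <- nrow(schedule@phases)
  if (length(factors) != nph)
    stop("need one phase factor per schedule phase (", nph, ")")
  starts <- phaseStartsMin(schedule)
  durs <- schedule@phases$durationMin
  # multiplier at the start of each phase (sequential closed form)
  g0 <- numeric(nph)
  g0[1] <- 1
  if (nph > 1) for (p in seq_len(nph - 1)) {
    g0[p + 1] <- factors[p] + (g0[p] - factors[p]) * exp(-durs[p] / tauMin)
  }
  idx <- .phaseIndexAt(schedule, tMin)
  dt <- tMin - starts[idx]
  factors[idx] + (g0[idx] - factors[idx]) * exp(-dt / tauMin)
}

#' Blood-volume fraction over the gas regime
#'
#' Within each gas phase the tissue blood-volume fraction approaches
#' \code{vBase * phaseFactor} exponentially with time constant
#' \code{tauResponseMin}, continuously across phase boundaries, starting
#' from \code{vBase} at t = 0.
#'
#' @param tissue a [TissueSpec-class] with \code{phaseFactors} set.
#' @param kinetics a [VasoKinetics-class].
#' @param schedule a [GasSchedule-class].
#' @param tMin time(s) in minutes within [0, total regime duration].
#' @return blood-volume fraction(s) at \code{tMin}.
#' @examples
#' ts <- tissueSpec("septum", 1100, 800, 0.10, phaseFactors = c(1, 1.3, 1))
#' vOfT(ts, vasoKinetics(3), gasSchedule(), c(0, 10, 20, 30))
#' @export
vOfT <- function(tissue, kinetics, schedule, tMin) {
  if (any(tMin < 0 | tMin > totalDurationMin(schedule)))
    stop("tMin outside the gas regime [0, ", totalDurationMin(schedule),
         "] min")
  tissue@vBase *
    .phaseResponse(tMin, schedule, tissue@phaseFactors,
                   kinetics@tauResponseMin)
}

#' Plasma contrast agent concentration over time
#'
#' Mono-exponential elimination from the post-contrast baseline:
#' C(t) = C0 * 2^(-t / halflife).
#'
#' @param contrast a [ContrastModel-class].
#' @param tMin time(s) in minutes since baseline (>= 0).
#' @return concentration(s) in mM.
#' @export
cOfT <- function(contrast, tMin) {
  if (any(tMin < 0)) stop("tMin must be >= 0")
  contrast@cPlasma0MM * 2^(-tMin / contrast@eliminationHalflifeMin)
}

#' Tissue T1 under the fast-exchange blood-pool relaxation model
#'
#' With a blood-pool agent confined to the blood-volume fraction v and fast
#' water exchange, tissue relaxation rate is linear in the compartmental
#' agent content: R1 = 1/T1_pre + r1 * v * C (all in 1/s, with T1_pre in
#' ms converted internally). Dilation (larger v) therefore lowers tissue T1
#' — the core premise of blood-pool vasoreactivity imaging.
#'
#' @param t1PreMs pre-contrast tissue T1 in ms.
#' @param r1PerMMPerS agent relaxivity in 1/mM/s.
#' @param v blood-volume fraction (>= 0).
#' @param cMM plasma agent concentration in mM (>= 0).
#' @return tissue T1 in ms. Vectorised over any argument.
#' @examples
#' tissueR1(1195, 19, 0.145, 0.5)  # ~ strongly shortened T1
#' tissueR1(1195, 19, 0, 0.5)      # no agent in tissue -> unchanged
#' @export
tissueR1 <- function(t1PreMs, r1PerMMPerS, v, cMM) {
  if (any(t1PreMs <= 0)) stop("t1PreMs must be > 0")
  if (any(v * cMM < 0)) stop("v * cMM must be >= 0")
  r1 <- 1000 / t1PreMs + r1PerMMPerS * v * cMM   # 1/s
  1000 / r1
}

# invert tissueR1: blood-volume fraction that yields t1Ms given C
.vFromT1 <- function(t1Ms, t1PreMs, r1PerMMPerS, cMM) {
  (1000 / t1Ms - 1000 / t1PreMs) / (r1PerMMPerS * cMM)
}

#' Ground-truth trajectories for a phantom
#'
#' Evaluates, at every imaging timepoint, each tissue's true blood-volume
#' fraction v(t), the plasma concentration C(t), and the resulting tissue
#' T1(t). Tissues with an explicit \code{t1TargetsMs} trajectory have v(t)
#' obtained by inverting the relaxation model instead.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [GroundTruth-class].
#' @export
groundTruth <- function(spec) {
  tp <- imagingTimes(spec@schedule)
  cm <- spec@contrast
  cc <- cOfT(cm, tp)
  rows <- lapply(spec@tissues, function(ts) {
    if (length(ts@t1TargetsMs)) {
      if (length(ts@t1TargetsMs) != length(tp))
        stop("tissue '", ts@label, "': t1TargetsMs must have one value per ",
             "imaging timepoint (", length(tp), ")")
      t1 <- ts@t1TargetsMs
      v <- .vFromT1(t1, ts@t1PreMs, cm@r1PerMMPerS, cc)
      if (any(v < -1e-9 | v > 1 + 1e-9))
        stop("tissue '", ts@label, "': target T1 trajectory implies a ",
             "blood-volume fraction outside [0, 1]")
      v <- pmin(pmax(v, 0), 1)
    } else {
      v <- vOfT(ts, spec@kinetics, spec@schedule, tp)
      t1 <- tissueR1(ts@t1PreMs, cm@r1PerMMPerS, v, cc)
    }
    if (any(t1 <= 0))
      stop("tissue '", ts@label, "': nonpositive tissue T1")
    data.frame(tissue = ts@label, timeMin = tp, v = v, cMM = cc, t1Ms = t1,
               stringsAsFactors = FALSE)
  })
  new("GroundTruth", table = do.call(rbind, rows), spec = spec)
}

#' Short-axis annulus label volume
#'
#' Builds the phantom geometry on the acquisition grid: a central LV
#' blood-pool disc surrounded by a myocardial annulus split into three
#' 120-degree sectors (septum, anterior wall, posterior wall). Radii are in
#' mm and converted via the in-plane pixel spacing; geometry is identical
#' across slices. Labels: 0 background, then tissues in the order of
#' \code{labels}.
#'
#' @param acq an [AcquisitionParams-class] (geometry source).
#' @param labels character vector of tissue names to place; must contain
#'   "lv_blood" and the three wall sectors.
#' @param innerRadiusMm LV blood-pool radius (mm).
#' @param outerRadiusMm outer myocardial radius (mm).
#' @return An [ROISet-class] whose label volume covers all tissues.
#' @export
phantomGeometry <- function(acq, labels = c("septum", "anterior_wall",
                                            "posterior_wall", "lv_blood"),
                            innerRadiusMm = 3.5, outerRadiusMm = 6.5) {
  n <- acq@matrixSize
  px <- acq@fovMm / n
  ctr <- (n + 1) / 2
  xy <- (seq_len(n) - ctr) * px
  xg <- matrix(xy, n, n)
  yg <- t(xg)
  r <- sqrt(xg^2 + yg^2)
  theta <- atan2(yg, xg) * 180 / pi
  sl <- matrix(0L, n, n)
  sectors <- list(
    septum = theta >= -60 & theta < 60,
    anterior_wall = theta >= 60 & theta < 180,
    posterior_wall = theta >= -180 & theta < -60
  )
  codes <- seq_along(labels)
  names(codes) <- labels
  annulus <- r > innerRadiusMm & r <= outerRadiusMm
  for (nm in names(sectors)) sl[annulus & sectors[[nm]]] <- codes[[nm]]
  sl[r <= innerRadiusMm] <- codes[["lv_blood"]]
  vol <- array(sl, dim = c(n, n, acq@nSlices))
  new("ROISet", labelVolume = vol,
      roiNames = stats::setNames(labels, as.character(codes)))
}

# Rician noise: magnitude of (S + sigma Z1) + i sigma Z2
.ricianNoise <- function(signal, sigma) {
  if (sigma == 0) return(signal)
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, sd = sigma))^2 +
       stats::rnorm(n, sd = sigma)^2)
}

#' Render a synthetic gas-challenge acquisition series
#'
#' Produces the full synthetic experiment implied by a phantom spec: the
#' pre-contrast multi-flip-angle SPGR stack, the post-contrast CINE time
#' series at every imaging timepoint, the ROI label volume, and the ground
#' truth. Every voxel's noiseless intensity is the SPGR steady-state signal
#' for its tissue's true (M0, T1) at that acquisition's TR and flip angle;
#' Rician noise is applied when \code{noiseSigma > 0}, seeded from the spec.
#'
#' @param spec a [PhantomSpec-class].
#' @param outDir optional directory; when given, writes
#'   \code{vfa.nii.gz}, \code{cine.nii.gz}, \code{rois.nii.gz},
#'   \code{ground_truth.json} and \code{schedule.json} there.
#' @return list with elements \code{vfa} (4D array, 4th axis = flip angle),
#'   \code{cine} (4D array, 4th axis = timepoint), \code{rois}
#'   ([ROISet-class]), \code{truth} ([GroundTruth-class]).
#' @examples
#' spec <- phantomSpec(vfa = vfaParams(matrixSize = 32, nSlices = 2),
#'                     cine = cineParams(matrixSize = 32, nSlices = 2))
#' ser <- renderSeries(spec)
#' dim(ser$cine)
#' @export
renderSeries <- function(spec, outDir = NULL) {
  truth <- groundTruth(spec)
  rois <- phantomGeometry(spec@cine,
                          labels = vapply(spec@tissues, function(t) t@label,
                                          character(1)))
  lab <- rois@labelVolume
  m0lab <- vapply(spec@tissues, function(t) t@m0, numeric(1))
  sigmaAbs <- spec@noiseSigma * .bloodM0(spec)
  set.seed(spec@seed)

  # voxelwise M0 by tissue code (0 outside)
  m0vol <- array(0, dim(lab))
  for (k in seq_along(spec@tissues)) m0vol[lab == k] <- m0lab[k]

  # pre-contrast VFA stack
  t1pre <- vapply(spec@tissues, function(t) t@t1PreMs, numeric(1))
  t1vol <- array(1, dim(lab))   # dummy T1 outside tissue; M0 = 0 there
  for (k in seq_along(spec@tissues)) t1vol[lab == k] <- t1pre[k]
  vfaArr <- array(0, c(dim(lab), length(spec@vfa@flipAnglesDeg)))
  for (j in seq_along(spec@vfa@flipAnglesDeg)) {
    s <- spgrSignal(m0vol, t1vol, spec@vfa@flipAnglesDeg[j], spec@vfa@trMs)
    vfaArr[, , , j] <- .ricianNoise(s, sigmaAbs)
  }

  # post-contrast CINE series
  tp <- imagingTimes(spec@schedule)
  tt <- truth@table
  cineArr <- array(0, c(dim(lab), length(tp)))
  for (i in seq_along(tp)) {
    t1i <- array(1, dim(lab))
    for (k in seq_along(spec@tissues)) {
      t1k <- tt$t1Ms[tt$tissue == spec@tissues[[k]]@label &
                     tt$timeMin == tp[i]]
      t1i[lab == k] <- t1k
    }
    s <- spgrSignal(m0vol, t1i, spec@cine@flipAnglesDeg[1], spec@cine@trMs)
    cineArr[, , , i] <- .ricianNoise(s, sigmaAbs)
  }

  out <- list(vfa = vfaArr, cine = cineArr, rois = rois, truth = truth)
  if (!is.null(outDir)) writeSeries(out, spec, outDir)
  out
}

# blood-pool M0 (noise reference); falls back to max tissue M0
.bloodM0 <- function(spec) {
  labs <- vapply(spec@tissues, function(t) t@label, character(1))
  i <- match("lv_blood", labs)
  if (is.na(i)) max(vapply(spec@tissues, function(t) t@m0, numeric(1)))
  else spec@tissues[[i]]@m0
}
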