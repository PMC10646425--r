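#' Spoiled gradient echo steady-state signal
#'
#' S = M0 sin(a) (1 - E1) / (1 - E1 cos(a)), with E1 = exp(-TR/T1). This is
#' the forward model for both the phantom renderer and the T1 inversions.
#'
#' @param m0 equilibrium signal (arbitrary units).
#' @param t1Ms longitudinal relaxation time in ms (> 0).
#' @param alphaDeg flip angle in degrees, in (0, 90].
#' @param trMs repetition time in ms (> 0).
#' @return signal in the units of \code{m0}. Vectorised over any argument.
#' @examples
#' spgrSignal(1000, 963, 15, 6)
#' @export
spgrSignal <- function(m0, t1Ms, alphaDeg, trMs) {
  stopifnot(all(t1Ms > 0), all(alphaDeg > 0 & alphaDeg <= 90), all(trMs > 0))
  a <- alphaDeg * pi / 180
  e1 <- exp(-trMs / t1Ms)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Variable flip angle (DESPOT1) T1 fit
#'
#' Linearises the SPGR signal equation: regressing y = S/sin(a) on
#' x = S/tan(a) gives slope E1 and intercept M0 (1 - E1), so
#' T1 = -TR / log(slope) and M0 = intercept / (1 - slope). The fit is
#' flagged invalid (not an error) when the slope falls outside (0, 1), the
#' intercept is non-positive, or the regressor is degenerate.
#'
#' @param signals numeric vector of SPGR signals, one per flip angle.
#' @param alphasDeg flip angles in degrees (>= 2 distinct values).
#' @param trMs repetition time in ms.
#' @return list with \code{t1Ms}, \code{m0}, \code{r2} (R^2 of the
#'   linearised regression) and \code{valid}.
#' @examples
#' s <- spgrSignal(800, 1195, c(2, 5, 10, 15, 20), 7)
#' fitVFA(s, c(2, 5, 10, 15, 20), 7)
#' @export
fitVFA <- function(signals, alphasDeg, trMs) {
  if (length(unique(alphasDeg)) < 2L)
    stop("at least two distinct flip angles are required")
  if (length(signals) != length(alphasDeg))
    stop("signals and alphasDeg must have equal length")
  if (any(signals < 0)) stop("signals must be non-negative")
  a <- alphasDeg * pi / 180
  y <- signals / sin(a)
  x <- signals / tan(a)
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  bad <- list(t1Ms = NA_real_, m0 = NA_real_, r2 = NA_real_, valid = FALSE)
  if (sxx < .Machine$double.eps * max(1, sum(x^2))) return(bad)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  syy <- sum((y - mean(y))^2)
  r2 <- if (syy > 0) 1 - sum((y - (intercept + slope * x))^2) / syy else NA_real_
  if (!is.finite(slope) || slope <= 0 || slope >= 1 || intercept <= 0) {
    bad$r2 <- r2
    return(bad)
  }
  list(t1Ms = -trMs / log(slope), m0 = intercept / (1 - slope),
       r2 = r2, valid = TRUE)
}

#' Voxelwise VFA T1 mapping
#'
#' Applies the linearised DESPOT1 regression to every voxel of a 4D VFA
#' stack (4th axis = flip angle), fully vectorised. Voxels failing the
#' validity conditions of [fitVFA()] are masked out.
#'
#' @param vfaStack 4D numeric array, dimensions (x, y, z, flip angle).
#' @param acq an [AcquisitionParams-class] whose \code{flipAnglesDeg} match
#'   the 4th axis and whose \code{trMs} is the VFA repetition time.
#' @return A [T1Map-class].
#' @export
fitVFAMap <- function(vfaStack, acq) {
  d <- dim(vfaStack)
  if (length(d) != 4L || d[4] != length(acq@flipAnglesDeg))
    stop("vfaStack must be 4D with one volume per flip angle")
  nv <- prod(d[1:3])
  sig <- matrix(vfaStack, nv, d[4])
  a <- matrix(acq@flipAnglesDeg * pi / 180, nv, d[4], byrow = TRUE)
  y <- sig / sin(a)
  x <- sig / tan(a)
  n <- d[4]
  xm <- rowMeans(x); ym <- rowMeans(y)
  sxx <- rowSums((x - xm)^2)
  sxy <- rowSums((x - xm) * (y - ym))
  syy <- rowSums((y - ym)^2)
  slope <- sxy / sxx
  intercept <- ym - slope * xm
  resid <- y - (intercept + slope * x)
  r2 <- ifelse(syy > 0, 1 - rowSums(resid^2) / syy, NA_real_)
  valid <- is.finite(slope) & slope > 0 & slope < 1 &
    is.finite(intercept) & intercept > 0 &
    sxx > .Machine$double.eps * pmax(1, rowSums(x^2))
  slope[!valid] <- NA_real_
  t1 <- -acq@trMs / log(slope)
  m0 <- ifelse(valid, intercept / (1 - slope), NA_real_)
  dim3 <- d[1:3]
  new("T1Map",
      t1Ms = array(t1, dim3), m0 = array(m0, dim3),
      validMask = array(valid, dim3), r2Fit = array(r2, dim3))
}

#' Single-point SPGR T1 inversion
#'
#' Solves the SPGR signal equation for T1 given the post-contrast signal
#' and a known M0: E1 = (M0 sin(a) - S) / (M0 sin(a) - S cos(a)),
#' T1 = -TR / log(E1). Signals at or above the physical ceiling
#' M0 sin(a) (E1 <= 0), or otherwise inconsistent (E1 >= 1), yield NA — an
#' invalid-voxel flag, not an exception. Vectorised.
#'
#' @param sPost post-contrast signal (> 0 for a valid inversion).
#' @param m0 equilibrium signal from the pre-contrast fit (> 0).
#' @param alphaDeg flip angle in degrees.
#' @param trMs repetition time in ms.
#' @return T1 in ms, NA where the inversion is invalid.
#' @examples
#' invertSPGR(spgrSignal(800, 452, 15, 6), 800, 15, 6)  # 452
#' @export
invertSPGR <- function(sPost, m0, alphaDeg, trMs) {
  a <- alphaDeg * pi / 180
  e1 <- (m0 * sin(a) - sPost) / (m0 * sin(a) - sPost * cos(a))
  ok <- is.finite(e1) & e1 > 0 & e1 < 1 & sPost > 0 & m0 > 0
  e1[!ok] <- NA_real_   # keep log() off the invalid domain
  -trMs / log(e1)
}

#' Post-contrast T1 map from a CINE volume
#'
#' Computes a voxelwise post-contrast T1 map by inverting the SPGR signal
#' equation with the M0 map from the pre-contrast VFA fit and the CINE
#' acquisition's own TR and flip angle (the CINE TR differs from the VFA
#' TR; M0 transfers unchanged, E1 uses the CINE TR). Voxels invalid in the
#' pre-contrast map stay invalid; voxels whose inversion fails are masked.
#'
#' @param cineVolume 3D numeric array, one CINE timepoint.
#' @param pre a [T1Map-class] from [fitVFAMap()].
#' @param acq the CINE [AcquisitionParams-class] (single flip angle).
#' @return A [T1Map-class] for the timepoint.
#' @export
mapPostT1 <- function(cineVolume, pre, acq) {
  if (!identical(dim(cineVolume), dim(pre@t1Ms)))
    stop("cineVolume dimensions must match the pre-contrast map")
  t1 <- invertSPGR(as.vector(cineVolume), as.vector(pre@m0),
                   acq@flipAnglesDeg[1], acq@trMs)
  valid <- as.vector(pre@validMask) & !is.na(t1)
  t1[!valid] <- NA_real_
  d <- dim(cineVolume)
  new("T1Map", t1Ms = array(t1, d), m0 = pre@m0,
      validMask = array(valid, d),
      r2Fit = array(NA_real_, d))
}
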