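# Scalar and tensor summaries of stress fields: pressure, volume-weighted
# means, principal decomposition, normal-stress-versus-angle profiles, and
# validation comparison metrics.

voigtToMatrix <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

#' Pressure of a stress tensor
#'
#' \eqn{\sigma_{Pres} = -\mathrm{tr}(\sigma)/3}; positive values indicate
#' compressive isotropic stress.
#'
#' @param sigma symmetric 3 x 3 stress tensor, Pa.
#' @param tol relative symmetry tolerance.
#' @return pressure, Pa.
#' @examples
#' stressPressure(diag(c(-600, -800, -1000)))   # 800
#' @export
stressPressure <- function(sigma, tol = 1e-8) {
  sigma <- as.matrix(sigma)
  stopifnot(all(dim(sigma) == c(3, 3)))
  if (max(abs(sigma - t(sigma))) > tol * max(1, max(abs(sigma))))
    stop("stress tensor is not symmetric")
  -sum(diag(sigma)) / 3
}

#' Volume-weighted mean Cauchy tensor of a stress field
#'
#' \eqn{\sigma^{\O} = \sum_i \sigma_i^e v_i^e / \sum_i v_i^e} over all
#' integration points, with current-configuration point volumes as weights.
#'
#' @param field a [StressField].
#' @return symmetric 3 x 3 matrix, Pa.
#' @export
volumetricMean <- function(field) {
  stopifnot(is(field, "StressField"))
  if (nrow(field@tensors) == 0) stop("empty stress field")
  vtot <- sum(field@volumes)
  if (vtot <= 0) stop("total integration-point volume must be positive")
  voigtToMatrix(colSums(field@tensors * field@volumes) / vtot)
}

#' Principal stresses and directions
#'
#' Eigen-decomposition of a symmetric stress tensor with values sorted
#' descending. Directions are columns, fixed to a deterministic sign (first
#' component of largest magnitude positive) so comparisons are stable.
#'
#' @param sigma symmetric 3 x 3 tensor, Pa.
#' @return list with `values` (descending) and `directions` (3 x 3,
#'   columns).
#' @export
principalStresses <- function(sigma) {
  sigma <- as.matrix(sigma)
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  D <- e$vectors
  for (k in 1:3) {
    lead <- which.max(abs(D[, k]))
    if (D[lead, k] < 0) D[, k] <- -D[, k]
  }
  list(values = e$values, directions = D)
}

#' Summarize a stress field
#'
#' Builds the volumetric mean tensor, its principal decomposition, the mean
#' pressure, and the current/reference volumes.
#'
#' @param field a [StressField].
#' @param referenceVolume reference-configuration volume, um^3 (NA if
#'   unknown).
#' @return a [StressSummary].
#' @export
summarizeStress <- function(field, referenceVolume = NA_real_) {
  m <- volumetricMean(field)
  p <- principalStresses(m)
  new("StressSummary", meanTensor = m, principalValues = p$values,
      principalDirections = p$directions,
      meanPressure = -sum(p$values) / 3,
      currentVolume = sum(field@volumes),
      referenceVolume = as.numeric(referenceVolume))
}

#' Normal stress as a function of in-plane direction
#'
#' Evaluates \eqn{\sigma_{nn}(\varphi) = n(\varphi)\cdot\sigma\,n(\varphi)}
#' with \eqn{n(\varphi) = (\cos\varphi, \sin\varphi, 0)} on a regular angle
#' grid in \eqn{[0, 2\pi)}.
#'
#' @param sigma symmetric 3 x 3 tensor (typically a volumetric mean), Pa.
#' @param nAngles number of angles (>= 4).
#' @return a [NormalStressProfile] with one time point.
#' @export
normalStressProfile <- function(sigma, nAngles = 180) {
  stopifnot(nAngles >= 4)
  sigma <- as.matrix(sigma)
  phi <- seq(0, 2 * pi, length.out = nAngles + 1)[seq_len(nAngles)]
  n <- cbind(cos(phi), sin(phi), 0)
  v <- rowSums((n %*% sigma) * n)
  new("NormalStressProfile", angles = phi,
      values = matrix(v, nrow = 1), amplification = 1, normalized = FALSE)
}

#' Stack single-time profiles into a series
#' @param ... [NormalStressProfile] objects on identical angle grids.
#' @return a [NormalStressProfile] with one row per time point.
#' @export
profileSeries <- function(...) {
  ps <- list(...)
  stopifnot(length(ps) >= 1)
  ang <- ps[[1]]@angles
  for (p in ps) stopifnot(isTRUE(all.equal(p@angles, ang)))
  new("NormalStressProfile", angles = ang,
      values = do.call(rbind, lapply(ps, function(p) p@values)),
      amplification = 1, normalized = FALSE)
}

#' Amplify deviations and normalize a profile series
#'
#' Per time point t, deviations from that time point's angular mean are
#' scaled: \eqn{v'(\varphi) = m_t + f\,(v(\varphi) - m_t)}, which leaves
#' every per-time-point mean unchanged. The whole series is then divided by
#' the maximum of \eqn{|v'|} over all time points and angles, so the
#' largest absolute value is exactly 1.
#'
#' @param profile a [NormalStressProfile] series.
#' @param factor amplification factor (default 5).
#' @return a normalized [NormalStressProfile].
#' @export
amplifyNormalize <- function(profile, factor = 5) {
  stopifnot(is(profile, "NormalStressProfile"))
  v <- profile@values
  m <- rowMeans(v)
  va <- m + factor * (v - m)
  mx <- max(abs(va))
  if (mx == 0) stop("all-zero profile series: normalization undefined")
  new("NormalStressProfile", angles = profile@angles, values = va / mx,
      amplification = factor, normalized = TRUE)
}

#' Angle of maximum amplitude of a profile
#'
#' The angle maximizing the absolute deviation from the per-time-point
#' mean (one angle per time point).
#'
#' @param profile a [NormalStressProfile].
#' @return numeric vector of angles, radians.
#' @export
maxAmplitudeAngle <- function(profile) {
  v <- profile@values
  m <- rowMeans(v)
  profile@angles[apply(abs(v - m), 1, which.max)]
}

# angle (deg) between a direction and the eigen-subspace of ref directions
# whose eigenvalues lie within tol of value i (handles degeneracy)
subspaceAngle <- function(d, refDirs, refVals, i, tol) {
  near <- abs(refVals - refVals[i]) <= tol
  B <- refDirs[, near, drop = FALSE]
  proj <- B %*% crossprod(B, d)
  c2 <- min(1, sqrt(sum(proj^2)) / sqrt(sum(d^2)))
  acos(c2) * 180 / pi
}

#' Compare a reconstructed stress summary to a reference
#'
#' Reports per-principal-value differences
#' \eqn{\Delta\sigma_i = \sigma_{i,rec} - \sigma_{i,ref}}, the relative
#' mean-pressure difference
#' \eqn{(\sigma_{Pres,rec} - \sigma_{Pres,ref})/\sigma_{Pres,ref}}, and the
#' angles (degrees) between matched principal directions. For nearly
#' degenerate reference eigenvalues the angle is measured against the
#' invariant subspace, which is the quantity that is actually determined.
#'
#' @param rec reconstructed [StressSummary].
#' @param ref reference [StressSummary].
#' @param degeneracyTol eigenvalue closeness (Pa) treated as degenerate;
#'   default 2% of the largest principal-stress magnitude (directions
#'   within such a pair are determined only up to rotation in their
#'   plane).
#' @return list with `principalDiffs`, `pressureDiff`, `pressureRelDiff`
#'   (NA when the reference pressure is zero) and `directionAngles` (deg).
#' @export
compareToReference <- function(rec, ref, degeneracyTol = NULL) {
  stopifnot(is(rec, "StressSummary"), is(ref, "StressSummary"))
  dv <- rec@principalValues - ref@principalValues
  dp <- rec@meanPressure - ref@meanPressure
  rel <- if (abs(ref@meanPressure) > 0) dp / ref@meanPressure else NA_real_
  if (is.null(degeneracyTol)) {
    mx <- max(abs(ref@principalValues))
    degeneracyTol <- if (mx > 0) 0.02 * mx else 1e-9
  }
  ang <- vapply(1:3, function(i)
    subspaceAngle(rec@principalDirections[, i], ref@principalDirections,
                  ref@principalValues, i, degeneracyTol), numeric(1))
  list(principalDiffs = dv, pressureDiff = dp, pressureRelDiff = rel,
       directionAngles = ang)
}
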