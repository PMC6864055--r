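# Forward virtual load scenarios on the standard validation bead, the
# forward/inverse round-trip harness, and the diameter/modulus uncertainty
# analysis.
#
# Pressure fields are follower loads (they act along the current deformed
# surface normal, with the magnitude assigned per material surface point);
# tangential shear loads are dead loads with fixed direction evaluated on
# the reference sphere.

#' Homogeneous surface pressure scenario
#' @param p pressure, Pa (default 1000, the validation value).
#' @return a [LoadScenario].
#' @export
scenarioHomogeneous <- function(p = 1000) {
  force(p)
  new("LoadScenario", name = "homogeneous",
      pressureFun = function(x, R) rep(p, nrow(x)),
      tractionFun = function(x, R) matrix(0, nrow(x), 3),
      params = list(p = p))
}

#' Sinusoidal periodic surface pressure scenario
#'
#' Pressure varying sinusoidally with the circle coordinate angle
#' \eqn{\varphi} in the x-y plane between `pMin` and `pMax` with the given
#' angular wavelength (default \eqn{\pi/4}, i.e. 8 periods around the
#' equator).
#'
#' @param pMin,pMax pressure range, Pa (defaults 600 and 1000).
#' @param wavelength angular wavelength, radians; must divide \eqn{2\pi}.
#' @return a [LoadScenario].
#' @export
scenarioPeriodic <- function(pMin = 600, pMax = 1000, wavelength = pi / 4) {
  stopifnot(pMax >= pMin)
  k <- 2 * pi / wavelength
  if (abs(k - round(k)) > 1e-9)
    stop("wavelength must divide 2*pi, otherwise the field is discontinuous")
  force(pMin); force(pMax); force(wavelength)
  new("LoadScenario", name = "periodic",
      pressureFun = function(x, R) {
        phi <- atan2(x[, 2], x[, 1])
        (pMax + pMin) / 2 + (pMax - pMin) / 2 * sin(2 * pi * phi / wavelength)
      },
      tractionFun = function(x, R) matrix(0, nrow(x), 3),
      params = list(pMin = pMin, pMax = pMax, wavelength = wavelength))
}

#' Quadratic pole-to-equator surface pressure scenario
#'
#' Pressure varying quadratically with the axial coordinate: `pEquator` at
#' the equator and `pPole` at both poles of the chosen axis.
#'
#' @param pEquator equatorial pressure, Pa (default 1000).
#' @param pPole polar pressure, Pa (default 600).
#' @param axis rotation axis (unit vector, default z).
#' @return a [LoadScenario].
#' @export
scenarioQuadratic <- function(pEquator = 1000, pPole = 600,
                              axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  force(pEquator); force(pPole)
  new("LoadScenario", name = "quadratic",
      pressureFun = function(x, R) {
        s <- pmin(1, pmax(-1, as.vector(x %*% axis) / R))
        pEquator - (pEquator - pPole) * s^2
      },
      tractionFun = function(x, R) matrix(0, nrow(x), 3),
      params = list(pEquator = pEquator, pPole = pPole))
}

# unit meridional direction pointing away from pole `axis` (towards the
# antipode); zero within `tol` of the poles where it is undefined
meridionalAway <- function(x, axis, tol = 1e-9) {
  xn <- x / sqrt(rowSums(x^2))
  ca <- as.vector(xn %*% axis)
  d <- xn * ca - matrix(axis, nrow(x), 3, byrow = TRUE)
  dn <- sqrt(rowSums(d^2))
  d[dn > tol, ] <- d[dn > tol, ] / dn[dn > tol]
  d[dn <= tol, ] <- 0
  d
}

#' Combined homogeneous pressure and hemispherical shear scenario
#'
#' Homogeneous surface pressure `p` plus two tangential shear loads of
#' magnitude `tau`: on the hemisphere with x > 0 the load is meridional
#' from the north (+z) to the south (-z) pole; on the hemisphere with
#' x < 0 it is meridional from the east (+x) to the west (-x) pole. Shear
#' tractions are tangential everywhere.
#'
#' @param p homogeneous pressure, Pa (default 800).
#' @param tau shear magnitude, Pa (default 120).
#' @return a [LoadScenario].
#' @export
scenarioPressureShear <- function(p = 800, tau = 120) {
  force(p); force(tau)
  new("LoadScenario", name = "pressure_shear",
      pressureFun = function(x, R) rep(p, nrow(x)),
      tractionFun = function(x, R) {
        east <- x[, 1] > 0
        tr <- matrix(0, nrow(x), 3)
        tr[east, ] <- tau * meridionalAway(x[east, , drop = FALSE],
                                           c(0, 0, 1))
        tr[!east, ] <- tau * meridionalAway(x[!east, , drop = FALSE],
                                            c(1, 0, 0))
        tr
      },
      params = list(p = p, tau = tau))
}

# build traction BCs for a scenario on a (spherical) reference mesh
scenarioTractions <- function(scenario, mesh, R) {
  g <- faceGeometry(mesh@nodes, mesh@boundaryFaces)
  nf <- nrow(mesh@boundaryFaces)
  pvals <- scenario@pressureFun(g$centroids, R)
  tvals <- scenario@tractionFun(g$centroids, R)
  out <- list(tractionPressure(seq_len(nf), pvals))
  if (any(tvals != 0)) out <- c(out, list(tractionVector(seq_len(nf), tvals)))
  out
}

#' Forward reference simulation of a load scenario
#'
#' Solves the scenario loads on a spherical bead mesh centred at the
#' origin and returns the reference ("virtual data") stress state.
#'
#' @param scenario a [LoadScenario].
#' @param mesh spherical reference [TetMesh] centred at the origin.
#' @param mat a [Material].
#' @param nLoadSteps,tol solver controls.
#' @return list with `field`, `summary`, `solution`, `mesh` (deformed).
#' @export
forwardScenario <- function(scenario, mesh, mat, nLoadSteps = 5,
                            tol = 1e-8) {
  R <- max(sqrt(rowSums(mesh@nodes[mesh@surfaceNodeIds, ]^2)))
  trs <- scenarioTractions(scenario, mesh, R)
  sol <- solveStatic(mesh, mat, tractions = trs,
                     nLoadSteps = nLoadSteps, tol = tol)
  field <- cauchyStress(mesh, sol, mat)
  list(field = field,
       summary = summarizeStress(field, referenceVolume = meshVolume(mesh)),
       solution = sol, mesh = deformedMesh(mesh, sol))
}

#' Surface-traction mean-stress identity
#'
#' For a body in equilibrium the volume-mean Cauchy stress equals the
#' boundary integral \eqn{(1/V)\oint t \otimes x\, dA} (symmetrized).
#' Evaluated here for the scenario loads on the undeformed reference
#' sphere; in the small-load limit the FE volumetric mean must approach
#' it. Tangential loads on a sphere satisfy \eqn{t \cdot x = 0} and hence
#' contribute nothing to the trace.
#'
#' @param scenario a [LoadScenario].
#' @param mesh reference [TetMesh] centred at the origin.
#' @return symmetric 3 x 3 matrix, Pa.
#' @export
appliedMeanStress <- function(scenario, mesh) {
  g <- faceGeometry(mesh@nodes, mesh@boundaryFaces)
  R <- max(sqrt(rowSums(mesh@nodes[mesh@surfaceNodeIds, ]^2)))
  p <- scenario@pressureFun(g$centroids, R)
  tau <- scenario@tractionFun(g$centroids, R)
  tvec <- -p * g$normals + tau
  S <- matrix(0, 3, 3)
  for (i in 1:3)
    for (j in 1:3)
      S[i, j] <- sum(tvec[, i] * g$centroids[, j] * g$areas)
  S <- (S + t(S)) / 2
  S / meshVolume(mesh)
}

#' Boundary surface of a tet mesh as a standalone triangle mesh
#' @param mesh a [TetMesh].
#' @return a [TriSurfaceMesh].
#' @export
boundarySurface <- function(mesh) {
  ids <- mesh@surfaceNodeIds
  map <- integer(nrow(mesh@nodes))
  map[ids] <- seq_along(ids)
  new("TriSurfaceMesh", vertices = mesh@nodes[ids, , drop = FALSE],
      faces = matrix(map[mesh@boundaryFaces], ncol = 3))
}

#' Forward/inverse validation round trip for one scenario
#'
#' Runs the forward reference simulation of the scenario on a spherical
#' bead (default: the validation bead, 17.0 um diameter, E = 1.8 kPa,
#' nu = 0.443), hands the resulting deformed shape to the inverse
#' reconstruction (by default on the matched mesh, isolating method error;
#' optionally through the full image rendering/segmentation round trip),
#' and compares both stress summaries.
#'
#' @param scenario a [LoadScenario].
#' @param mat a [Material]; default the validation bead material.
#' @param diameter bead diameter, um.
#' @param refinement icosphere subdivision of the bead surface.
#' @param layers radial tet layers (NULL = auto).
#' @param imaging if TRUE, pass the deformed shape through
#'   [renderBeadStack()] and [segmentBead()] before meshing.
#' @param spacingXY,spacingZ,blurSigma,noiseLevel,seed imaging parameters
#'   when `imaging = TRUE`.
#' @param nLoadSteps,tol solver controls.
#' @return a [ValidationResult]; its `comparison` list additionally holds
#'   `localPressureRMSDiff` and `localPressureMaxDiff` (Pa, element-wise
#'   local map discrepancies; matched-mesh path only).
#' @export
runValidation <- function(scenario, mat = material(1800, 0.443),
                          diameter = 17, refinement = 3, layers = NULL,
                          imaging = FALSE, spacingXY = 0.1, spacingZ = 1,
                          blurSigma = 0.2, noiseLevel = 0.05, seed = 1,
                          nLoadSteps = 5, tol = 1e-8) {
  surf <- makeSphereSurface(diameter / 2, refinement)
  mesh <- tetrahedralize(surf, layers = layers)
  fwd <- forwardScenario(scenario, mesh, mat, nLoadSteps, tol)
  defSurf <- boundarySurface(fwd$mesh)

  if (imaging) {
    stack <- renderBeadStack(defSurf, spacingXY, spacingZ, blurSigma,
                             noiseLevel, seed)
    defMesh <- buildDeformedMesh(stack, refinement = refinement,
                                 layers = layers)
  } else {
    defMesh <- fwd$mesh
  }
  rec <- reconstructFromMesh(defMesh, mat, diameter = diameter,
                             nLoadSteps = nLoadSteps, tol = tol)
  cmp <- compareToReference(rec$summary, fwd$summary)
  if (!imaging) {
    # element-wise local pressure maps are comparable: the reconstruction
    # preserves the forward mesh connectivity on the matched path
    pFwd <- -rowSums(stressTensors(fwd$field)[, 1:3]) / 3
    pRec <- -rowSums(stressTensors(rec$field)[, 1:3]) / 3
    w <- pointVolumes(fwd$field)
    cmp$localPressureRMSDiff <- sqrt(sum(w * (pRec - pFwd)^2) / sum(w))
    cmp$localPressureMaxDiff <- max(abs(pRec - pFwd))
  } else {
    cmp$localPressureRMSDiff <- NA_real_
    cmp$localPressureMaxDiff <- NA_real_
  }
  new("ValidationResult", scenario = scenario@name,
      reference = fwd$summary, recovered = rec$summary, comparison = cmp,
      deformedSurface = defSurf)
}

# truncated-normal sampler: within +/- 3 SD and strictly positive
rtruncpos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mean, sd)
      if (x > 0 && abs(x - mean) <= 3 * sd) break
    }
    out[i] <- x
  }
  out
}

#' Uncertainty of the recovered mean pressure
#'
#' Monte-Carlo propagation of the bead-to-bead spread in diameter and
#' Young's modulus through the inverse reconstruction: the observed shape
#' is fixed (forward simulation of the scenario at the nominal bead), and
#' each sample reconstructs stresses assuming a diameter and modulus drawn
#' from truncated normal distributions (+/- 3 SD, positive).
#'
#' @param scenario a [LoadScenario].
#' @param diameterMean,diameterSD reference diameter distribution, um
#'   (defaults 17.0 and 0.5, the production spread).
#' @param EMean,ESD Young's modulus distribution, Pa (defaults 1800 and
#'   700, the AFM spread).
#' @param nu Poisson ratio (fixed).
#' @param nSamples number of Monte-Carlo samples (>= 2).
#' @param seed RNG seed; identical seeds give identical summaries.
#' @param refinement,layers mesh resolution.
#' @param nLoadSteps,tol solver controls.
#' @return list with `samples` (data.frame: diameter, E, pressure),
#'   `mean`, `sd` and `relSD` of the recovered volumetric mean pressure.
#' @export
uncertaintyAnalysis <- function(scenario, diameterMean = 17,
                                diameterSD = 0.5, EMean = 1800, ESD = 700,
                                nu = 0.443, nSamples = 32, seed = 1,
                                refinement = 2, layers = NULL,
                                nLoadSteps = 5, tol = 1e-8) {
  stopifnot(nSamples >= 2, diameterSD >= 0, ESD >= 0)
  surf <- makeSphereSurface(diameterMean / 2, refinement)
  mesh <- tetrahedralize(surf, layers = layers)
  fwd <- forwardScenario(scenario, mesh, material(EMean, nu), nLoadSteps,
                         tol)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  D <- rtruncpos(nSamples, diameterMean, diameterSD)
  E <- rtruncpos(nSamples, EMean, ESD)
  p <- vapply(seq_len(nSamples), function(i) {
    rec <- reconstructFromMesh(fwd$mesh, material(E[i], nu),
                               diameter = D[i], nLoadSteps = nLoadSteps,
                               tol = tol)
    meanPressure(rec$summary)
  }, numeric(1))
  list(samples = data.frame(diameter = D, E = E, pressure = p),
       mean = mean(p), sd = sd(p), relSD = sd(p) / abs(mean(p)))
}
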