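# S4 classes for the bead-stress toolkit. Geometry is carried in physical
# micrometres; moduli and stresses in pascals.

#' Compressible Neo-Hookean material parameters
#'
#' Stores Young's modulus \eqn{E} (Pa) and Poisson ratio \eqn{\nu}; the
#' derived moduli (shear \eqn{\mu = E/(2(1+\nu))}, first Lame parameter
#' \eqn{\lambda = E\nu/((1+\nu)(1-2\nu))}, bulk \eqn{\kappa = E/(3(1-2\nu))})
#' are computed on demand so they are always consistent to machine
#' precision.
#'
#' @slot E Young's modulus in Pa.
#' @slot nu Poisson ratio, in \eqn{[0, 0.5)}.
#' @export
setClass("Material", representation(E = "numeric", nu = "numeric"))

setValidity("Material", function(object) {
  if (length(object@E) != 1 || !is.finite(object@E) || object@E <= 0)
    return("E must be a single positive finite number (Pa)")
  if (length(object@nu) != 1 || !is.finite(object@nu) ||
      object@nu < 0 || object@nu >= 0.5)
    return("nu must lie in [0, 0.5)")
  TRUE
})

#' 3D fluorescence image stack
#'
#' A voxel intensity grid with anisotropic physical spacing: square pixels
#' of `spacingXY` micrometres within each confocal section and a section
#' separation of `spacingZ` micrometres.
#'
#' @slot voxels 3D numeric array of non-negative intensities.
#' @slot spacingXY pixel size within a slice, um.
#' @slot spacingZ slice separation, um.
#' @export
setClass("ImageStack",
         representation(voxels = "array", spacingXY = "numeric",
                        spacingZ = "numeric"))

setValidity("ImageStack", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3) return("voxels must be a 3D array")
  if (d[3] < 3) return("stack must have at least 3 slices")
  if (!all(is.finite(object@voxels))) return("intensities must be finite")
  if (any(object@voxels < 0)) return("intensities must be non-negative")
  if (object@spacingXY <= 0 || object@spacingZ <= 0)
    return("spacings must be positive")
  TRUE
})

#' Binary segmentation of a bead stack
#'
#' @slot labels 3D logical array (TRUE = bead).
#' @slot spacingXY,spacingZ voxel spacing, um.
#' @export
setClass("LabelStack",
         representation(labels = "array", spacingXY = "numeric",
                        spacingZ = "numeric"))

setValidity("LabelStack", function(object) {
  d <- dim(object@labels)
  if (length(d) != 3) return("labels must be a 3D array")
  if (!is.logical(object@labels)) return("labels must be logical")
  if (object@spacingXY <= 0 || object@spacingZ <= 0)
    return("spacings must be positive")
  TRUE
})

#' Closed triangulated surface
#'
#' Vertices in physical um coordinates, faces as 1-based vertex triples with
#' consistent outward winding. Validity checks closure (every edge shared by
#' exactly two faces) and absence of degenerate faces.
#'
#' @slot vertices numeric matrix, one row per vertex (x, y, z) in um.
#' @slot faces integer matrix, one row per triangle.
#' @export
setClass("TriSurfaceMesh",
         representation(vertices = "matrix", faces = "matrix"))

setValidity("TriSurfaceMesh", function(object) {
  V <- object@vertices; F <- object@faces
  if (ncol(V) != 3) return("vertices must be N x 3")
  if (ncol(F) != 3) return("faces must be F x 3")
  if (!all(is.finite(V))) return("vertex coordinates must be finite")
  if (min(F) < 1 || max(F) > nrow(V)) return("face indices out of range")
  if (any(F[, 1] == F[, 2] | F[, 1] == F[, 3] | F[, 2] == F[, 3]))
    return("degenerate faces present")
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  if (any(tab != 2)) return("surface is not closed (edge not shared by 2 faces)")
  # consistent winding: each undirected edge appears once in each direction
  dkey <- paste(e[, 1], e[, 2])
  if (any(table(dkey) != 1)) return("inconsistent face winding")
  TRUE
})

#' Tetrahedral volume mesh
#'
#' Node coordinates in um; tets as 1-based quadruples ordered for positive
#' signed volume. The boundary triangulation (outward winding) and the ids
#' of boundary nodes are stored with the mesh because the inverse pipeline
#' addresses surface nodes repeatedly.
#'
#' @slot nodes numeric matrix N x 3, um.
#' @slot tets integer matrix M x 4.
#' @slot boundaryFaces integer matrix, outward-wound boundary triangles.
#' @slot surfaceNodeIds integer vector of boundary node ids.
#' @export
setClass("TetMesh",
         representation(nodes = "matrix", tets = "matrix",
                        boundaryFaces = "matrix", surfaceNodeIds = "integer"))

setValidity("TetMesh", function(object) {
  if (ncol(object@nodes) != 3) return("nodes must be N x 3")
  if (ncol(object@tets) != 4) return("tets must be M x 4")
  if (min(object@tets) < 1 || max(object@tets) > nrow(object@nodes))
    return("tet indices out of range")
  v <- tetVolumes(object@nodes, object@tets)
  if (any(v <= 0))
    return(sprintf("non-positive tet volume (first at element %d)",
                   which(v <= 0)[1]))
  bf <- sort(unique(as.vector(object@boundaryFaces)))
  if (!identical(as.integer(bf), sort(object@surfaceNodeIds)))
    return("surfaceNodeIds must be exactly the boundary-face nodes")
  TRUE
})

#' Prescribed-displacement boundary condition
#' @slot nodeIds integer node ids (unique).
#' @slot values numeric matrix (length(nodeIds) x 3) of displacements, um.
#' @export
setClass("DirichletBC",
         representation(nodeIds = "integer", values = "matrix"))

setValidity("DirichletBC", function(object) {
  if (anyDuplicated(object@nodeIds)) return("nodeIds must be unique")
  if (nrow(object@values) != length(object@nodeIds) ||
      ncol(object@values) != 3)
    return("values must be length(nodeIds) x 3")
  if (!all(is.finite(object@values))) return("displacements must be finite")
  TRUE
})

#' Surface traction boundary condition
#'
#' Either a follower normal pressure (Pa, positive = compressive, acting
#' along the current deformed surface normal) given per boundary face, or a
#' fixed-direction (dead) traction vector per boundary face (Pa).
#'
#' @slot faceIds integer indices into the mesh boundary-face list.
#' @slot type `"pressure"` or `"traction"`.
#' @slot pressure numeric per-face pressure (Pa), for type "pressure".
#' @slot traction numeric matrix per-face traction vectors (Pa), for type
#'   "traction".
#' @export
setClass("TractionBC",
         representation(faceIds = "integer", type = "character",
                        pressure = "numeric", traction = "matrix"))

setValidity("TractionBC", function(object) {
  if (!object@type %in% c("pressure", "traction"))
    return("type must be 'pressure' or 'traction'")
  if (object@type == "pressure" &&
      length(object@pressure) != length(object@faceIds))
    return("pressure must have one value per face")
  if (object@type == "traction" &&
      (nrow(object@traction) != length(object@faceIds) ||
       ncol(object@traction) != 3))
    return("traction must be length(faceIds) x 3")
  TRUE
})

#' Solution of a static FE solve
#' @slot displacements numeric N x 3 nodal displacements, um.
#' @slot converged logical.
#' @slot iterations integer Newton iteration count per accepted load step.
#' @export
setClass("DisplacementField",
         representation(displacements = "matrix", converged = "logical",
                        iterations = "integer"))

#' Per-integration-point Cauchy stress state
#'
#' One integration point per linear tetrahedron: symmetric Cauchy tensor
#' (Voigt order xx, yy, zz, xy, xz, yz; Pa), current-configuration point
#' volume (um^3), deformation-gradient determinant J, and the current
#' centroid position of the element (um) for local maps.
#'
#' @slot tensors numeric M x 6 matrix.
#' @slot volumes numeric current-configuration integration-point volumes.
#' @slot J numeric per-point determinant of the deformation gradient.
#' @slot centroids numeric M x 3 current element centroids.
#' @export
setClass("StressField",
         representation(tensors = "matrix", volumes = "numeric",
                        J = "numeric", centroids = "matrix"))

setValidity("StressField", function(object) {
  if (ncol(object@tensors) != 6) return("tensors must be M x 6 (Voigt)")
  if (length(object@volumes) != nrow(object@tensors))
    return("one volume per integration point required")
  if (any(object@volumes <= 0)) return("integration-point volumes must be > 0")
  if (any(object@J <= 0)) return("J must be positive")
  TRUE
})

#' Volumetric summary of a stress field
#'
#' The volume-weighted mean Cauchy tensor, its principal values (sorted
#' descending) and orthonormal principal directions, the mean pressure
#' \eqn{-tr(\sigma)/3} (positive = compression), and the current and
#' reference bead volumes.
#'
#' @slot meanTensor numeric 3 x 3 symmetric matrix, Pa.
#' @slot principalValues numeric length 3, descending, Pa.
#' @slot principalDirections numeric 3 x 3, directions in columns.
#' @slot meanPressure numeric, Pa.
#' @slot currentVolume,referenceVolume numeric, um^3 (NA when unknown).
#' @export
setClass("StressSummary",
         representation(meanTensor = "matrix", principalValues = "numeric",
                        principalDirections = "matrix",
                        meanPressure = "numeric", currentVolume = "numeric",
                        referenceVolume = "numeric"))

setValidity("StressSummary", function(object) {
  S <- object@meanTensor
  if (max(abs(S - t(S))) > 1e-6 * max(1, max(abs(S))))
    return("mean tensor must be symmetric")
  if (is.unsorted(rev(object@principalValues)))
    return("principal values must be sorted descending")
  D <- object@principalDirections
  if (max(abs(crossprod(D) - diag(3))) > 1e-6)
    return("principal directions must be orthonormal")
  if (abs(object@meanPressure + sum(object@principalValues) / 3) >
      1e-9 * max(1, max(abs(object@principalValues))))
    return("meanPressure must equal -(s1+s2+s3)/3")
  TRUE
})

#' Normal-stress-versus-angle profile series
#'
#' In-plane normal stress \eqn{\sigma_{nn}(\varphi) = n(\varphi) \cdot
#' \sigma\, n(\varphi)} with \eqn{n(\varphi) = (\cos\varphi, \sin\varphi,
#' 0)}, one row per time point. Profiles can be amplified about their
#' per-time-point mean and normalized by the maximum absolute value over
#' the whole series.
#'
#' @slot angles numeric angles in radians, in \eqn{[0, 2\pi)}.
#' @slot values numeric T x A matrix, Pa (or dimensionless if normalized).
#' @slot amplification numeric amplification factor applied (1 = none).
#' @slot normalized logical.
#' @export
setClass("NormalStressProfile",
         representation(angles = "numeric", values = "matrix",
                        amplification = "numeric", normalized = "logical"))

setValidity("NormalStressProfile", function(object) {
  if (ncol(object@values) != length(object@angles))
    return("values must have one column per angle")
  if (any(object@angles < 0 | object@angles >= 2 * pi))
    return("angles must lie in [0, 2*pi)")
  TRUE
})

#' Spherical reference configuration
#' @slot diameter reference sphere diameter, um.
#' @slot center numeric length-3 sphere centre, um.
#' @export
setClass("ReferenceSpec",
         representation(diameter = "numeric", center = "numeric"))

setValidity("ReferenceSpec", function(object) {
  if (object@diameter <= 0) return("diameter must be positive")
  if (length(object@center) != 3) return("center must be length 3")
  TRUE
})

#' Radial distance vectors from a deformed surface to the reference sphere
#'
#' One vector per boundary node, parallel to (node - centre), carrying the
#' node onto the sphere of the stored radius.
#'
#' @slot nodeIds integer boundary node ids.
#' @slot vectors numeric matrix of per-node vectors, um.
#' @slot center numeric sphere centre, um.
#' @slot radius numeric sphere radius, um.
#' @export
setClass("RadialVectors",
         representation(nodeIds = "integer", vectors = "matrix",
                        center = "numeric", radius = "numeric"))

#' Parametric surface load scenario
#'
#' Pressure and tangential traction fields over the reference sphere
#' surface, given as functions of material surface points (N x 3 matrix,
#' centred sphere) and sphere radius.
#'
#' @slot name scenario name.
#' @slot pressureFun function(points, R) -> Pa vector (follower pressure).
#' @slot tractionFun function(points, R) -> N x 3 Pa matrix (dead traction).
#' @slot params named list of scenario parameters.
#' @export
setClass("LoadScenario",
         representation(name = "character", pressureFun = "function",
                        tractionFun = "function", params = "list"))

#' Result of a forward/inverse validation round trip
#' @slot scenario scenario name.
#' @slot reference StressSummary of the forward (virtual-data) simulation.
#' @slot recovered StressSummary of the inverse reconstruction.
#' @slot comparison named list: principal-value differences, relative
#'   pressure difference, principal-direction angles (deg), local
#'   surface-pressure RMS discrepancy.
#' @slot deformedSurface TriSurfaceMesh of the forward deformed shape.
#' @export
setClass("ValidationResult",
         representation(scenario = "character", reference = "StressSummary",
                        recovered = "StressSummary", comparison = "list",
                        deformedSurface = "TriSurfaceMesh"))

#' Pipeline run configuration
#'
#' Defaults are the production/validation bead parameters: E = 1800 Pa,
#' nu = 0.443, reference diameter 17 um, 0.1 um xy pixels and 1 um
#' z-sections.
#'
#' @slot material a [Material].
#' @slot diameter reference sphere diameter, um.
#' @slot refinement icosphere subdivision level for surface extraction.
#' @slot layers radial layer count for tetrahedralization (0 = auto).
#' @slot nLoadSteps default Newton load steps.
#' @slot tol relative residual tolerance of the FE solver.
#' @slot spacingXY,spacingZ rendering/segmentation voxel spacing, um.
#' @slot blurSigma rendering blur, um.
#' @slot noiseLevel rendering additive-noise level (fraction of foreground).
#' @slot seed integer RNG seed.
#' @slot outputDir output directory for pipeline products.
#' @export
setClass("RunConfig",
         representation(material = "Material", diameter = "numeric",
                        refinement = "integer", layers = "integer",
                        nLoadSteps = "integer", tol = "numeric",
                        spacingXY = "numeric", spacingZ = "numeric",
                        blurSigma = "numeric", noiseLevel = "numeric",
                        seed = "integer", outputDir = "character"))
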