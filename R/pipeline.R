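# The three-step inverse reconstruction:
#  1. deformed tetrahedral mesh from the observed (segmented) bead shape;
#  2. spherical reference construction: radial distance vectors from the
#     deformed surface nodes to the assumed reference sphere, applied as
#     Dirichlet data in a preprocessing FE solve whose deformed output
#     becomes the assumed stress-free mesh;
#  3. main FE solve applying the inverse vectors as surface displacements
#     on the reference mesh, recovering the stress state of the deformed
#     bead.

#' Spherical reference specification
#' @param diameter reference sphere diameter, um (default: production mean
#'   17.0).
#' @param center sphere centre, um; defaults to the deformed-mesh volume
#'   centroid when used in the pipeline.
#' @return a [ReferenceSpec].
#' @export
referenceSpec <- function(diameter = 17, center = c(0, 0, 0)) {
  new("ReferenceSpec", diameter = as.numeric(diameter),
      center = as.numeric(center))
}

# volume centroid of a tet mesh
tetMeshCentroid <- function(mesh) {
  v <- tetVolumes(mesh@nodes, mesh@tets)
  cent <- (mesh@nodes[mesh@tets[, 1], ] + mesh@nodes[mesh@tets[, 2], ] +
           mesh@nodes[mesh@tets[, 3], ] + mesh@nodes[mesh@tets[, 4], ]) / 4
  colSums(cent * v) / sum(v)
}

#' Build the deformed-configuration mesh from an image stack
#'
#' Composition of [segmentBead()], [surfaceFromLabels()] and
#' [tetrahedralize()].
#'
#' @param stack an [ImageStack] with one fully imaged bead.
#' @param smoothingIterations passed to [surfaceFromLabels()].
#' @param refinement icosphere template subdivision for the surface.
#' @param layers radial layers for [tetrahedralize()] (NULL = auto).
#' @param method threshold rule for [segmentBead()].
#' @param verbose log the segmented volume and equivalent diameter.
#' @return a [TetMesh].
#' @export
buildDeformedMesh <- function(stack, smoothingIterations = 10,
                              refinement = 3, layers = NULL,
                              method = "otsu", verbose = FALSE) {
  labels <- segmentBead(stack, method = method)
  surf <- surfaceFromLabels(labels, smoothingIterations, refinement)
  mesh <- tetrahedralize(surf, layers = layers)
  if (verbose) {
    v <- meshVolume(mesh)
    message(sprintf("deformed mesh: V = %.1f um^3, d_eq = %.2f um",
                    v, equivalentDiameter(v)))
  }
  mesh
}

#' Radial distance vectors to the reference sphere
#'
#' For every boundary node \eqn{x_i} of the deformed mesh, the vector
#' \eqn{(R - |x_i - c|)\,(x_i - c)/|x_i - c|} pointing from the node
#' radially onto the sphere of radius \eqn{R} about \eqn{c}.
#'
#' @param mesh deformed [TetMesh].
#' @param ref a [ReferenceSpec]; `center = NULL` uses the mesh volume
#'   centroid.
#' @return a [RadialVectors].
#' @export
radialDistanceVectors <- function(mesh, ref = NULL) {
  stopifnot(is(mesh, "TetMesh"))
  if (is.null(ref)) ref <- referenceSpec(center = tetMeshCentroid(mesh))
  cen <- ref@center
  R <- ref@diameter / 2
  ids <- mesh@surfaceNodeIds
  x <- sweep(mesh@nodes[ids, , drop = FALSE], 2, cen)
  d <- sqrt(rowSums(x^2))
  if (any(d < 1e-9)) stop("boundary node coincides with the sphere centre")
  vec <- x * ((R - d) / d)
  new("RadialVectors", nodeIds = ids, vectors = vec, center = cen,
      radius = R)
}

#' Construct the reference mesh (step two)
#'
#' Applies the radial distance vectors as Dirichlet boundary conditions in
#' a preprocessing FE solve on the deformed mesh; the resulting deformed
#' configuration is the mesh of the assumed stress-free spherical
#' reference. Boundary nodes land on the reference sphere to solver
#' tolerance; connectivity is unchanged.
#'
#' @param deformed deformed [TetMesh].
#' @param vectors [RadialVectors] on its boundary nodes.
#' @param mat a [Material] (the same material is used for the
#'   preprocessing and the main solve).
#' @param nLoadSteps,tol solver controls, see [solveStatic()].
#' @return a [TetMesh].
#' @export
makeReferenceMesh <- function(deformed, vectors, mat, nLoadSteps = 5,
                              tol = 1e-8) {
  stopifnot(is(vectors, "RadialVectors"))
  if (!identical(sort(vectors@nodeIds), sort(deformed@surfaceNodeIds)))
    stop("vectors must be defined on all boundary nodes of the mesh")
  bc <- dirichletBC(vectors@nodeIds, vectors@vectors)
  sol <- solveStatic(deformed, mat, dirichlet = bc,
                     nLoadSteps = nLoadSteps, tol = tol)
  out <- deformedMesh(deformed, sol)
  ids <- vectors@nodeIds
  offs <- sqrt(rowSums(sweep(out@nodes[ids, , drop = FALSE], 2,
                             vectors@center)^2)) - vectors@radius
  if (max(abs(offs)) > 1e-6 * vectors@radius)
    warning("boundary nodes deviate from the reference sphere by up to ",
            signif(max(abs(offs)), 3), " um")
  out
}

#' Main stress-recovery solve (step three)
#'
#' Applies the inverse radial distance vectors as surface displacements on
#' the reference mesh, returning the bead back to the observed shape, and
#' recovers the full Cauchy stress field of the deformed state.
#'
#' @param reference [TetMesh] from [makeReferenceMesh()] built with the
#'   same `vectors`.
#' @param vectors the [RadialVectors].
#' @param mat a [Material].
#' @param nLoadSteps,tol solver controls.
#' @return list with `field` (a [StressField]), `summary` (a
#'   [StressSummary] whose reference volume is the reference-mesh volume),
#'   `solution` (the [DisplacementField]) and `mesh` (the deformed
#'   [TetMesh]).
#' @export
reconstructStress <- function(reference, vectors, mat, nLoadSteps = 5,
                              tol = 1e-8) {
  stopifnot(is(vectors, "RadialVectors"))
  bc <- dirichletBC(vectors@nodeIds, -vectors@vectors)
  sol <- solveStatic(reference, mat, dirichlet = bc,
                     nLoadSteps = nLoadSteps, tol = tol)
  field <- cauchyStress(reference, sol, mat)
  list(field = field,
       summary = summarizeStress(field, referenceVolume = meshVolume(reference)),
       solution = sol, mesh = deformedMesh(reference, sol))
}

#' Full inverse reconstruction from a deformed mesh
#'
#' Runs steps two and three of the pipeline on an already meshed deformed
#' shape.
#'
#' @param deformed deformed [TetMesh].
#' @param mat a [Material].
#' @param diameter reference sphere diameter, um.
#' @param center reference sphere centre (NULL = deformed-mesh volume
#'   centroid).
#' @param nLoadSteps,tol solver controls.
#' @return as [reconstructStress()], plus `vectors` and `reference`.
#' @export
reconstructFromMesh <- function(deformed, mat, diameter = 17,
                                center = NULL, nLoadSteps = 5, tol = 1e-8) {
  ref <- if (is.null(center)) referenceSpec(diameter, tetMeshCentroid(deformed))
         else referenceSpec(diameter, center)
  vec <- radialDistanceVectors(deformed, ref)
  refMesh <- makeReferenceMesh(deformed, vec, mat, nLoadSteps, tol)
  out <- reconstructStress(refMesh, vec, mat, nLoadSteps, tol)
  out$vectors <- vec
  out$reference <- refMesh
  out
}

#' Full inverse reconstruction from an image stack
#'
#' @param stack an [ImageStack].
#' @param mat a [Material].
#' @param diameter reference sphere diameter, um.
#' @param ... passed to [buildDeformedMesh()].
#' @return as [reconstructFromMesh()].
#' @export
reconstructFromStack <- function(stack, mat, diameter = 17, ...) {
  deformed <- buildDeformedMesh(stack, ...)
  reconstructFromMesh(deformed, mat, diameter = diameter)
}

#' Small-strain approximation of the volumetric mean pressure
#'
#' \eqn{\sigma_{Pres}^{\O} \approx -\kappa (V_c - V_r)/V_r} with bulk
#' modulus \eqn{\kappa}; positive = compression. Exact only in the
#' small-strain limit; at larger volume changes the volume average of the
#' nonlinear local pressure deviates from this whole-bead evaluation.
#'
#' @param Vc current-configuration volume, um^3.
#' @param Vr reference-configuration volume, um^3.
#' @param kappa bulk modulus, Pa.
#' @return approximate mean pressure, Pa.
#' @examples
#' approxMeanPressure(0.9, 1, 6200)   # 620
#' @export
approxMeanPressure <- function(Vc, Vr, kappa) {
  stopifnot(Vc > 0, Vr > 0)
  -kappa * (Vc - Vr) / Vr
}
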