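# Accessors and show methods.

#' @describeIn Material-class Young's modulus, Pa.
#' @param x object.
#' @export
setMethod("youngModulus", "Material", function(x) x@E)

#' @describeIn Material-class Poisson ratio.
#' @export
setMethod("poissonRatio", "Material", function(x) x@nu)

#' @describeIn Material-class shear modulus \eqn{\mu = E/(2(1+\nu))}, Pa.
#' @export
setMethod("shearModulus", "Material", function(x) x@E / (2 * (1 + x@nu)))

#' @describeIn Material-class first Lame parameter
#'   \eqn{\lambda = E\nu/((1+\nu)(1-2\nu))}, Pa.
#' @export
setMethod("lameFirst", "Material",
          function(x) x@E * x@nu / ((1 + x@nu) * (1 - 2 * x@nu)))

#' @describeIn Material-class bulk modulus \eqn{\kappa = E/(3(1-2\nu))}, Pa.
#' @export
setMethod("bulkModulus", "Material", function(x) x@E / (3 * (1 - 2 * x@nu)))

setMethod("show", "Material", function(object) {
  cat(sprintf(
    "Material: E = %.4g Pa, nu = %.4g (mu = %.4g, lambda = %.4g, kappa = %.4g Pa)\n",
    object@E, object@nu, shearModulus(object), lameFirst(object),
    bulkModulus(object)))
})

#' @describeIn ImageStack-class voxel intensity array.
#' @param x object.
#' @export
setMethod("voxelData", "ImageStack", function(x) x@voxels)

#' @describeIn ImageStack-class in-plane pixel size, um.
#' @export
setMethod("spacingXY", "ImageStack", function(x) x@spacingXY)

#' @describeIn ImageStack-class slice separation, um.
#' @export
setMethod("spacingZ", "ImageStack", function(x) x@spacingZ)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageStack: %d x %d x %d voxels, %.3g um xy / %.3g um z\n",
              d[1], d[2], d[3], object@spacingXY, object@spacingZ))
})

#' @describeIn LabelStack-class logical label array.
#' @param x object.
#' @export
setMethod("labelData", "LabelStack", function(x) x@labels)

#' @describeIn LabelStack-class in-plane pixel size, um.
#' @export
setMethod("spacingXY", "LabelStack", function(x) x@spacingXY)

#' @describeIn LabelStack-class slice separation, um.
#' @export
setMethod("spacingZ", "LabelStack", function(x) x@spacingZ)

setMethod("show", "LabelStack", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelStack: %d x %d x %d voxels, %d foreground\n",
              d[1], d[2], d[3], sum(object@labels)))
})

#' @describeIn TriSurfaceMesh-class vertex coordinate matrix, um.
#' @param x object.
#' @export
setMethod("meshVertices", "TriSurfaceMesh", function(x) x@vertices)

#' @describeIn TriSurfaceMesh-class face index matrix (1-based).
#' @export
setMethod("meshFaces", "TriSurfaceMesh", function(x) x@faces)

setMethod("show", "TriSurfaceMesh", function(object) {
  cat(sprintf("TriSurfaceMesh: %d vertices, %d faces, volume %.4g um^3\n",
              nrow(object@vertices), nrow(object@faces), meshVolume(object)))
})

#' @describeIn TetMesh-class node coordinate matrix, um.
#' @param x object.
#' @export
setMethod("meshNodes", "TetMesh", function(x) x@nodes)

#' @describeIn TetMesh-class tetrahedron index matrix (1-based).
#' @export
setMethod("meshTets", "TetMesh", function(x) x@tets)

#' @describeIn TetMesh-class outward-wound boundary triangles.
#' @export
setMethod("boundaryFaces", "TetMesh", function(x) x@boundaryFaces)

#' @describeIn TetMesh-class ids of boundary nodes.
#' @export
setMethod("surfaceNodeIds", "TetMesh", function(x) x@surfaceNodeIds)

setMethod("show", "TetMesh", function(object) {
  cat(sprintf(
    "TetMesh: %d nodes, %d tets, %d boundary nodes, volume %.4g um^3\n",
    nrow(object@nodes), nrow(object@tets), length(object@surfaceNodeIds),
    meshVolume(object)))
})

#' @describeIn DisplacementField-class nodal displacement matrix, um.
#' @param x object.
#' @export
setMethod("displacements", "DisplacementField", function(x) x@displacements)

setMethod("show", "DisplacementField", function(object) {
  cat(sprintf(
    "DisplacementField: %d nodes, max |u| = %.4g um, converged = %s (%s Newton iters)\n",
    nrow(object@displacements), sqrt(max(rowSums(object@displacements^2))),
    object@converged, paste(object@iterations, collapse = "+")))
})

#' @describeIn StressField-class M x 6 Voigt stress matrix, Pa.
#' @param x object.
#' @export
setMethod("stressTensors", "StressField", function(x) x@tensors)

#' @describeIn StressField-class current integration-point volumes, um^3.
#' @export
setMethod("pointVolumes", "StressField", function(x) x@volumes)

setMethod("show", "StressField", function(object) {
  cat(sprintf("StressField: %d integration points, V = %.4g um^3, mean pressure %.4g Pa\n",
              nrow(object@tensors), sum(object@volumes),
              stressPressure(volumetricMean(object))))
})

#' @describeIn StressSummary-class volume-weighted mean Cauchy tensor, Pa.
#' @param x object.
#' @export
setMethod("meanTensor", "StressSummary", function(x) x@meanTensor)

#' @describeIn StressSummary-class principal stresses, descending, Pa.
#' @export
setMethod("principalValues", "StressSummary", function(x) x@principalValues)

#' @describeIn StressSummary-class principal directions (columns).
#' @export
setMethod("principalDirections", "StressSummary",
          function(x) x@principalDirections)

#' @describeIn StressSummary-class volumetric mean pressure, Pa.
#' @export
setMethod("meanPressure", "StressSummary", function(x) x@meanPressure)

setMethod("show", "StressSummary", function(object) {
  cat("StressSummary\n")
  cat(sprintf("  principal stresses (Pa): %.4g  %.4g  %.4g\n",
              object@principalValues[1], object@principalValues[2],
              object@principalValues[3]))
  cat(sprintf("  mean pressure (Pa):      %.4g\n", object@meanPressure))
  cat(sprintf("  V_c / V_r (um^3):        %.4g / %.4g\n",
              object@currentVolume, object@referenceVolume))
})

setMethod("show", "LoadScenario", function(object) {
  cat(sprintf("LoadScenario '%s' (%s)\n", object@name,
              paste(names(object@params), unlist(object@params),
                    sep = " = ", collapse = ", ")))
})

setMethod("show", "ValidationResult", function(object) {
  cat(sprintf("ValidationResult '%s'\n", object@scenario))
  cat(sprintf("  reference mean pressure: %.4g Pa\n",
              meanPressure(object@reference)))
  cat(sprintf("  recovered mean pressure: %.4g Pa (rel. diff %.3g)\n",
              meanPressure(object@recovered),
              object@comparison$pressureRelDiff))
})

#' Current and reference volumes stored in a summary
#' @param x a [StressSummary].
#' @return numeric length-2 vector (current, reference), um^3.
#' @export
summaryVolumes <- function(x) {
  stopifnot(is(x, "StressSummary"))
  c(current = x@currentVolume, reference = x@referenceVolume)
}
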