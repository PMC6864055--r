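# Generics. Accessors are preferred over direct slot access throughout.

#' @export
setGeneric("meshVolume", function(x, ...) standardGeneric("meshVolume"))

#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @export
setGeneric("meshNodes", function(x) standardGeneric("meshNodes"))

#' @export
setGeneric("meshTets", function(x) standardGeneric("meshTets"))

#' @export
setGeneric("boundaryFaces", function(x) standardGeneric("boundaryFaces"))

#' @export
setGeneric("surfaceNodeIds", function(x) standardGeneric("surfaceNodeIds"))

#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))

#' @export
setGeneric("spacingXY", function(x) standardGeneric("spacingXY"))

#' @export
setGeneric("spacingZ", function(x) standardGeneric("spacingZ"))

#' @export
setGeneric("youngModulus", function(x) standardGeneric("youngModulus"))

#' @export
setGeneric("poissonRatio", function(x) standardGeneric("poissonRatio"))

#' @export
setGeneric("shearModulus", function(x) standardGeneric("shearModulus"))

#' @export
setGeneric("lameFirst", function(x) standardGeneric("lameFirst"))

#' @export
setGeneric("bulkModulus", function(x) standardGeneric("bulkModulus"))

#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))

#' @export
setGeneric("stressTensors", function(x) standardGeneric("stressTensors"))

#' @export
setGeneric("pointVolumes", function(x) standardGeneric("pointVolumes"))

#' @export
setGeneric("meanTensor", function(x) standardGeneric("meanTensor"))

#' @export
setGeneric("principalValues", function(x) standardGeneric("principalValues"))

#' @export
setGeneric("principalDirections",
           function(x) standardGeneric("principalDirections"))

#' @export
setGeneric("meanPressure", function(x) standardGeneric("meanPressure"))
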