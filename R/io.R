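# File formats: multi-page TIFF stacks (with a YAML sidecar carrying the
# voxel spacing, since TIFF z-spacing conventions vary), legacy VTK
# unstructured grids for meshes and fields, STL/PLY surfaces, JSON
# summaries and CSV profiles.

sidecarPath <- function(path) paste0(path, ".yml")

#' Write an image stack as multi-page TIFF plus spacing sidecar
#'
#' Intensities are scaled into [0, 1] for TIFF storage; the scale factor
#' and the voxel spacings (`spacing_xy_um`, `spacing_z_um`) go to a YAML
#' sidecar next to the image.
#'
#' @param stack an [ImageStack].
#' @param path output TIFF path.
#' @return the TIFF path, invisibly.
#' @export
writeImageStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  v <- stack@voxels
  mx <- max(v, 1e-12)
  pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  yaml::write_yaml(list(spacing_xy_um = stack@spacingXY,
                        spacing_z_um = stack@spacingZ,
                        intensity_scale = mx), sidecarPath(path))
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' Spacings are taken from the YAML sidecar when present, otherwise from
#' the arguments.
#'
#' @param path TIFF path.
#' @param spacingXY,spacingZ fallback spacings, um.
#' @return an [ImageStack].
#' @export
readImageStack <- function(path, spacingXY = 0.1, spacingZ = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- 1
  if (file.exists(sidecarPath(path))) {
    meta <- yaml::read_yaml(sidecarPath(path))
    spacingXY <- meta$spacing_xy_um %||% spacingXY
    spacingZ <- meta$spacing_z_um %||% spacingZ
    scale <- meta$intensity_scale %||% 1
  }
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    arr[, , k] <- p
  }
  imageStack(arr * scale, spacingXY, spacingZ)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vtkCells <- function(con) {
  paste(ncol(con), apply(con - 1L, 1, paste, collapse = " "))
}

#' Write a mesh (with optional fields) as legacy VTK
#'
#' Writes ASCII legacy VTK unstructured grids: tetrahedra for a [TetMesh],
#' triangles for a [TriSurfaceMesh]. Point and cell data may hold numeric
#' vectors (scalars), N x 3 matrices (vectors) or N x 6 Voigt matrices
#' (symmetric tensors).
#'
#' @param mesh a [TetMesh] or [TriSurfaceMesh].
#' @param path output `.vtk` path.
#' @param pointData,cellData named lists of fields.
#' @return the path, invisibly.
#' @export
writeVTK <- function(mesh, path, pointData = list(), cellData = list()) {
  if (is(mesh, "TetMesh")) {
    pts <- mesh@nodes; con <- mesh@tets; ctype <- 10L
  } else if (is(mesh, "TriSurfaceMesh")) {
    pts <- mesh@vertices; con <- mesh@faces; ctype <- 5L
  } else stop("unsupported mesh class")
  con <- matrix(as.integer(con), nrow = nrow(con))
  out <- c("# vtk DataFile Version 3.0", "beadstress mesh", "ASCII",
           "DATASET UNSTRUCTURED_GRID",
           sprintf("POINTS %d double", nrow(pts)),
           apply(pts, 1, paste, collapse = " "),
           sprintf("CELLS %d %d", nrow(con), nrow(con) * (1 + ncol(con))),
           vtkCells(con),
           sprintf("CELL_TYPES %d", nrow(con)),
           rep(as.character(ctype), nrow(con)))
  writeData <- function(fields, n) {
    lines <- character(0)
    for (nm in names(fields)) {
      f <- fields[[nm]]
      if (is.null(dim(f))) {
        lines <- c(lines, sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default", as.character(f))
      } else if (ncol(f) == 3) {
        lines <- c(lines, sprintf("VECTORS %s double", nm),
                   apply(f, 1, paste, collapse = " "))
      } else if (ncol(f) == 6) {
        full <- f[, c(1, 4, 5, 4, 2, 6, 5, 6, 3), drop = FALSE]
        lines <- c(lines, sprintf("TENSORS %s double", nm),
                   apply(full, 1, paste, collapse = " "))
      } else stop("unsupported field shape for ", nm)
    }
    lines
  }
  if (length(pointData))
    out <- c(out, sprintf("POINT_DATA %d", nrow(pts)),
             writeData(pointData, nrow(pts)))
  if (length(cellData))
    out <- c(out, sprintf("CELL_DATA %d", nrow(con)),
             writeData(cellData, nrow(con)))
  writeLines(out, path)
  invisible(path)
}

#' Write a reconstruction result as VTK
#'
#' Deformed mesh with nodal displacements and per-element stress tensor,
#' pressure and J.
#'
#' @param rec result list from [reconstructFromMesh()].
#' @param path output `.vtk` path.
#' @return the path, invisibly.
#' @export
writeStressVTK <- function(rec, path) {
  sf <- rec$field
  writeVTK(rec$mesh, path,
           pointData = list(displacement = displacements(rec$solution)),
           cellData = list(cauchy_stress = stressTensors(sf),
                           pressure = -rowSums(stressTensors(sf)[, 1:3]) / 3,
                           J = sf@J))
}

#' Write a surface as ASCII STL
#' @param surface a [TriSurfaceMesh].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSTL <- function(surface, path) {
  V <- surface@vertices; F <- surface@faces
  g <- faceGeometry(V, F)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid bead", con)
  for (f in seq_len(nrow(F))) {
    writeLines(c(sprintf("facet normal %.10g %.10g %.10g", g$normals[f, 1],
                         g$normals[f, 2], g$normals[f, 3]),
                 "  outer loop",
                 sprintf("    vertex %.10g %.10g %.10g", V[F[f, ], 1],
                         V[F[f, ], 2], V[F[f, ], 3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid bead", con)
  invisible(path)
}

#' Read an ASCII STL surface
#' @param path STL path.
#' @param tol vertex-merge tolerance, um.
#' @return a [TriSurfaceMesh].
#' @export
readSTL <- function(path, tol = 1e-9) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  if (nrow(xyz) %% 3 != 0) stop("malformed STL")
  key <- apply(round(xyz / max(tol, 1e-12)), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  ids <- match(key, key[uk])
  V <- xyz[uk, , drop = FALSE]
  F <- matrix(ids, ncol = 3, byrow = TRUE)
  triSurfaceMesh(V, F)
}

#' Write a surface as ASCII PLY
#' @param surface a [TriSurfaceMesh].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePLY <- function(surface, path) {
  V <- surface@vertices; F <- surface@faces
  out <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(V)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices", "end_header",
           apply(V, 1, paste, collapse = " "),
           paste(3, apply(F - 1L, 1, paste, collapse = " ")))
  writeLines(out, path)
  invisible(path)
}

#' Serialize a stress summary to JSON
#' @param summary a [StressSummary].
#' @param path output path (NULL = return the JSON string).
#' @return path or JSON string, invisibly.
#' @export
writeStressSummaryJSON <- function(summary, path = NULL) {
  x <- list(mean_tensor = summary@meanTensor,
            principal_values_Pa = summary@principalValues,
            principal_directions = summary@principalDirections,
            mean_pressure_Pa = summary@meanPressure,
            current_volume_um3 = summary@currentVolume,
            reference_volume_um3 = summary@referenceVolume)
  js <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE, na = "null")
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' Write a profile series as CSV
#'
#' Columns: time, phi, value_raw, value_amplified_normalized.
#'
#' @param raw un-amplified [NormalStressProfile] series.
#' @param amplified matching output of [amplifyNormalize()] (or NULL).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeProfileCSV <- function(raw, amplified = NULL, path) {
  nt <- nrow(raw@values)
  na <- length(raw@angles)
  df <- data.frame(time = rep(seq_len(nt), each = na),
                   phi = rep(raw@angles, nt),
                   value_raw = as.vector(t(raw@values)))
  df$value_amplified_normalized <- if (is.null(amplified)) NA_real_
    else as.vector(t(amplified@values))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
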