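# Surface and tetrahedral mesh construction.
#
# Volume meshes are built by radially layering a triangulated star-shaped
# surface towards its centre (concentric scaled copies of the surface,
# prisms split into tetrahedra with index-consistent diagonals, innermost
# layer coned to the centre node). This produces a boundary that matches
# the input surface vertices exactly, which the inverse pipeline relies on.

rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# signed volumes of all tets (positive for correctly oriented elements)
tetVolumes <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  d <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  rowSums(a * rowCross(b, d)) / 6
}

faceGeometry <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- rowCross(e1, e2)
  areas <- sqrt(rowSums(cr^2)) / 2
  normals <- cr / (2 * areas)
  centroids <- (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
                V[F[, 3], , drop = FALSE]) / 3
  list(areas = areas, normals = normals, centroids = centroids)
}

#' Construct a closed triangulated surface
#'
#' @param vertices numeric N x 3 matrix of coordinates, um.
#' @param faces integer F x 3 matrix of 1-based vertex triples; winding is
#'   made outward (positive enclosed volume) if it is not already.
#' @return a [TriSurfaceMesh].
#' @export
triSurfaceMesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  vol <- sum(rowSums(vertices[faces[, 1], , drop = FALSE] *
                     rowCross(vertices[faces[, 2], , drop = FALSE],
                              vertices[faces[, 3], , drop = FALSE]))) / 6
  if (vol < 0) faces <- faces[, c(1, 3, 2)]
  new("TriSurfaceMesh", vertices = vertices, faces = faces)
}

#' @describeIn triSurfaceMesh enclosed volume of a closed surface by the
#'   divergence theorem, um^3.
#' @param x a [TriSurfaceMesh].
#' @param ... unused.
#' @export
setMethod("meshVolume", "TriSurfaceMesh", function(x, ...) {
  V <- x@vertices; F <- x@faces
  sum(rowSums(V[F[, 1], , drop = FALSE] *
              rowCross(V[F[, 2], , drop = FALSE],
                       V[F[, 3], , drop = FALSE]))) / 6
})

#' @describeIn tetMesh total mesh volume as the sum of signed tetrahedron
#'   volumes, um^3. Errors (reporting the element id) if any element is
#'   inverted.
#' @param x a [TetMesh].
#' @param ... unused.
#' @export
setMethod("meshVolume", "TetMesh", function(x, ...) {
  v <- tetVolumes(x@nodes, x@tets)
  if (any(v <= 0))
    stop("inverted element at id ", which(v <= 0)[1])
  sum(v)
})

# icosahedron subdivided towards the unit sphere; returns unit vertices
# and outward-wound faces
icosphereUnit <- function(refinement) {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- 1 + rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))
  for (r in seq_len(refinement)) {
    nv <- nrow(V)
    edges <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
    ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    uk <- unique(ekey)
    mid <- match(ekey, uk) + nv
    ue <- edges[!duplicated(ekey), , drop = FALSE]
    newV <- (V[ue[, 1], , drop = FALSE] + V[ue[, 2], , drop = FALSE]) / 2
    newV <- newV / sqrt(rowSums(newV^2))
    V <- rbind(V, newV)
    nf <- nrow(F)
    mab <- mid[seq_len(nf)]
    mbc <- mid[nf + seq_len(nf)]
    mca <- mid[2 * nf + seq_len(nf)]
    F <- rbind(cbind(F[, 1], mab, mca),
               cbind(F[, 2], mbc, mab),
               cbind(F[, 3], mca, mbc),
               cbind(mab, mbc, mca))
  }
  list(V = V, F = matrix(as.integer(F), ncol = 3))
}

#' Icosphere surface of a given radius
#'
#' Subdivided icosahedron with all vertices at exactly the requested radius
#' from the origin; `20 * 4^refinement` faces.
#'
#' @param radius sphere radius, um.
#' @param refinement subdivision level (>= 0).
#' @return a [TriSurfaceMesh].
#' @examples
#' s <- makeSphereSurface(8.5, 3)
#' meshVolume(s) / (4 / 3 * pi * 8.5^3)   # -> just under 1
#' @export
makeSphereSurface <- function(radius, refinement = 3) {
  stopifnot(radius > 0, refinement >= 0)
  ico <- icosphereUnit(as.integer(refinement))
  new("TriSurfaceMesh", vertices = ico$V * radius, faces = ico$F)
}

# orient boundary faces of a tet mesh outward using the opposite node
orientBoundary <- function(nodes, faces, opposite) {
  e1 <- nodes[faces[, 2], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  e2 <- nodes[faces[, 3], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  d <- nodes[opposite, , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  inward <- rowSums(rowCross(e1, e2) * d) > 0
  faces[inward, c(2, 3)] <- faces[inward, c(3, 2)]
  faces
}

#' Construct a tetrahedral mesh from nodes and connectivity
#'
#' Extracts and orients the boundary triangulation and records the boundary
#' node ids.
#'
#' @param nodes numeric N x 3 matrix, um.
#' @param tets integer M x 4 matrix, ordered for positive signed volume.
#' @return a [TetMesh].
#' @export
tetMesh <- function(nodes, tets) {
  nodes <- as.matrix(nodes)
  tets <- matrix(as.integer(as.matrix(tets)), ncol = 4)
  fc <- rbind(cbind(tets[, 1], tets[, 2], tets[, 3], tets[, 4]),
              cbind(tets[, 1], tets[, 2], tets[, 4], tets[, 3]),
              cbind(tets[, 1], tets[, 3], tets[, 4], tets[, 2]),
              cbind(tets[, 2], tets[, 3], tets[, 4], tets[, 1]))
  key <- paste(pmin(fc[, 1], pmin(fc[, 2], fc[, 3])),
               fc[, 1] + fc[, 2] + fc[, 3],
               pmax(fc[, 1], pmax(fc[, 2], fc[, 3])))
  once <- !(key %in% key[duplicated(key)])
  bf <- fc[once, 1:3, drop = FALSE]
  opp <- fc[once, 4]
  bf <- orientBoundary(nodes, bf, opp)
  new("TetMesh", nodes = nodes, tets = tets,
      boundaryFaces = matrix(as.integer(bf), ncol = 3),
      surfaceNodeIds = sort(unique(as.integer(bf))))
}

# split the prism between two concentric surface layers into 3 tets with
# index-consistent quad diagonals (no mismatched faces between neighbours)
prismTets <- function(bot, top) {
  nf <- nrow(bot)
  out <- matrix(0L, 3 * nf, 4)
  for (f in seq_len(nf)) {
    tri <- bot[f, ]
    rot <- which.min(tri)                      # cyclic: smallest first
    ord <- ((rot - 1 + 0:2) %% 3) + 1
    A <- bot[f, ord[1]]; B <- bot[f, ord[2]]; C <- bot[f, ord[3]]
    A2 <- top[f, ord[1]]; B2 <- top[f, ord[2]]; C2 <- top[f, ord[3]]
    if (B < C) {
      t3 <- rbind(c(A, B, C, C2), c(A, B, C2, B2), c(A, B2, C2, A2))
    } else {
      t3 <- rbind(c(A, B, C, B2), c(A, C, C2, B2), c(A, B2, C2, A2))
    }
    out[3 * f - (2:0), ] <- t3
  }
  out
}

#' Tetrahedralize a closed star-shaped surface
#'
#' Fills the interior with concentric radially scaled copies of the surface
#' connected by tetrahedralized prisms; the boundary nodes of the result
#' are exactly the surface vertices. The surface must be star-shaped with
#' respect to its volume centroid (every boundary point visible from the
#' centre along its ray), which is also the geometric assumption of the
#' radial inverse reconstruction; a violation is an error.
#'
#' @param surface a closed [TriSurfaceMesh].
#' @param maxTetVolume target maximum tetrahedron volume, um^3 (sets the
#'   number of radial layers); ignored when `layers` is given.
#' @param layers explicit number of radial layers (>= 2).
#' @return a [TetMesh].
#' @examples
#' tm <- tetrahedralize(makeSphereSurface(8.5, 2), layers = 5)
#' abs(meshVolume(tm) / (4 / 3 * pi * 8.5^3) - 1) < 0.01
#' @export
tetrahedralize <- function(surface, maxTetVolume = NULL, layers = NULL) {
  stopifnot(is(surface, "TriSurfaceMesh"))
  V <- surface@vertices
  F <- surface@faces
  vol <- meshVolume(surface)
  if (vol <= 0) stop("surface must enclose positive volume")
  # volume centroid via signed cone decomposition about the origin
  w <- rowSums(V[F[, 1], , drop = FALSE] *
               rowCross(V[F[, 2], , drop = FALSE],
                        V[F[, 3], , drop = FALSE])) / 6
  cen <- colSums((V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
                  V[F[, 3], , drop = FALSE]) / 4 * w) / sum(w)
  assertStarShaped(V, F, cen)

  nv <- nrow(V); nf <- nrow(F)
  if (is.null(layers)) {
    if (is.null(maxTetVolume)) {
      layers <- max(2L, as.integer(round(sqrt(nf / 20))) + 2L)
    } else {
      ntet <- max(1, ceiling(vol / maxTetVolume))
      layers <- max(2L, as.integer(ceiling((ntet / nf - 1) / 3 + 1)))
    }
  }
  layers <- as.integer(layers)
  stopifnot(layers >= 2)

  rel <- sweep(V, 2, cen)
  nodes <- matrix(0, nv * layers + 1, 3)
  for (k in seq_len(layers))
    nodes[(k - 1) * nv + seq_len(nv), ] <-
      sweep(rel * (k / layers), 2, cen, "+")
  nodes[nv * layers + 1, ] <- cen
  centerId <- nv * layers + 1L

  tets <- vector("list", layers)
  # innermost cone to the centre
  tets[[1]] <- cbind(centerId, F[, 1], F[, 2], F[, 3])
  for (k in seq_len(layers - 1)) {
    off <- (k - 1L) * nv
    tets[[k + 1]] <- prismTets(F + off, F + off + nv)
  }
  tets <- do.call(rbind, tets)
  v <- tetVolumes(nodes, tets)
  if (any(v <= 0))
    stop("tetrahedralization produced an inverted element (id ",
         which(v <= 0)[1], "); surface may be too irregular")
  m <- tetMesh(nodes, tets)
  if (abs(meshVolume(m) - vol) > 0.01 * vol)
    stop("tetrahedralization volume deviates > 1% from the surface volume")
  m
}

assertStarShaped <- function(V, F, cen) {
  g <- faceGeometry(V, F)
  dirs <- sweep(g$centroids, 2, cen)
  dn <- sqrt(rowSums(dirs^2))
  if (any(dn < 1e-9)) stop("surface passes through its centroid")
  dirs <- dirs / dn
  cnt <- cpp_ray_mesh_crossings(V, F - 1L, as.numeric(cen), dirs)
  if (any(cnt != 1L))
    stop("surface is not star-shaped with respect to its centroid; ",
         "the radial reconstruction is undefined for this geometry")
  invisible(TRUE)
}

# uniform-weight Taubin (lambda/mu) smoothing; near volume-preserving
taubinSmooth <- function(V, F, iterations, lambda = 0.5, mu = -0.53) {
  if (iterations <= 0) return(V)
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(nrow(V), nrow(V)))
  A@x[] <- 1            # drop duplicate accumulation
  A <- A / Matrix::rowSums(A)
  for (it in seq_len(iterations)) {
    V <- V + lambda * (as.matrix(A %*% V) - V)
    V <- V + mu * (as.matrix(A %*% V) - V)
  }
  V
}

#' Extract a bead surface from a segmented label stack
#'
#' Locates the 0.5-level of the binary label field along rays cast from the
#' label centroid in the directions of an icosphere template (respecting
#' the anisotropic voxel spacing), then optionally applies
#' volume-preserving Taubin smoothing. Physical coordinates have their
#' origin at the stack corner.
#'
#' @param labels a [LabelStack] with a single foreground component fully
#'   inside the stack.
#' @param smoothingIterations Taubin smoothing passes (0 = raw isosurface).
#' @param refinement icosphere template subdivision level.
#' @return a [TriSurfaceMesh].
#' @export
surfaceFromLabels <- function(labels, smoothingIterations = 10,
                              refinement = 3) {
  stopifnot(is(labels, "LabelStack"))
  arr <- labels@labels
  d <- dim(arr)
  if (!any(arr)) stop("label stack has no foreground")
  idx <- which(arr, arr.ind = TRUE)
  if (any(idx == 1) || any(sweep(idx, 2, d) == 0))
    stop("foreground touches the stack border; bead must be fully imaged")
  if (length(unique(idx[, 3])) < 3)
    stop("foreground must span at least 3 slices")
  dx <- labels@spacingXY; dz <- labels@spacingZ
  sp <- c(dx, dx, dz)
  cen <- colMeans(sweep(idx - 0.5, 2, sp, "*"))
  ico <- icosphereUnit(as.integer(refinement))
  rmax <- sqrt(sum((d * sp)^2)) / 2 + max(sp)
  r <- cpp_ray_isosurface(as.double(arr), d[1], d[2], d[3], dx, dx, dz,
                          cen, ico$V, 0.5, min(sp) / 2, rmax)
  if (any(is.na(r)))
    stop("isosurface not found along ", sum(is.na(r)), " rays; ",
         "segmentation may be fragmented")
  V <- sweep(ico$V * r, 2, cen, "+")
  rawVol <- abs(sum(rowSums(V[ico$F[, 1], ] *
                            rowCross(V[ico$F[, 2], ], V[ico$F[, 3], ]))) / 6)
  V <- taubinSmooth(V, ico$F, smoothingIterations)
  out <- triSurfaceMesh(V, ico$F)
  if (smoothingIterations > 0) {
    # restore the enclosed volume exactly (isotropic rescale about the
    # volume centroid): smoothing must not bias the volumetry
    sc <- (rawVol / meshVolume(out))^(1 / 3)
    w <- rowSums(V[ico$F[, 1], ] * rowCross(V[ico$F[, 2], ], V[ico$F[, 3], ])) / 6
    vc <- colSums((V[ico$F[, 1], ] + V[ico$F[, 2], ] + V[ico$F[, 3], ]) / 4 * w) /
      sum(w)
    out <- triSurfaceMesh(sweep(sweep(V, 2, vc) * sc, 2, vc, "+"), ico$F)
  }
  out
}
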