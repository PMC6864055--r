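# Shared fixtures, memoised so expensive meshes/solves are built once per
# test run.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

valMaterial <- function() material(1800, 0.443)

sphereVol <- function(R) 4 / 3 * pi * R^3

# standard validation bead meshes (17 um diameter)
beadMesh1 <- function() memo("m1", tetrahedralize(makeSphereSurface(8.5, 1),
                                                  layers = 3))
beadMesh2 <- function() memo("m2", tetrahedralize(makeSphereSurface(8.5, 2),
                                                  layers = 5))

allBoundaryFaces <- function(mesh) seq_len(nrow(boundaryFaces(mesh)))

# analytic voxelized sphere label stack (centre of the grid)
sphereLabels <- function(R = 8.5, sxy = 0.1, sz = 1, pad = 2) {
  nx <- ceiling(2 * (R + pad) / sxy)
  nz <- ceiling(2 * (R + pad) / sz)
  cx <- nx * sxy / 2
  cz <- nz * sz / 2
  x <- (seq_len(nx) - 0.5) * sxy - cx
  z <- (seq_len(nz) - 0.5) * sz - cz
  r2 <- outer(outer(x^2, x^2, "+"), z^2, "+")
  labelStack(array(r2 <= R^2, dim = c(nx, nx, nz)), sxy, sz)
}

# rotation matrix about z
rotZ <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1),
                           3, 3)
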