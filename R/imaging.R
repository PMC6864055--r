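# Synthetic confocal imaging and segmentation.
#
# The renderer emulates the observation geometry of confocal stacks of
# fluorescent beads: fine square pixels within each section and a much
# coarser section separation (defaults 0.1 um xy, 1 um z), partial-volume
# foreground values at the bead boundary, Gaussian blur, and additive
# Gaussian noise proportional to the foreground intensity.

#' Construct an image stack
#' @param voxels 3D numeric array of non-negative intensities.
#' @param spacingXY pixel size, um.
#' @param spacingZ slice separation, um.
#' @return an [ImageStack].
#' @export
imageStack <- function(voxels, spacingXY, spacingZ) {
  new("ImageStack", voxels = voxels, spacingXY = as.numeric(spacingXY),
      spacingZ = as.numeric(spacingZ))
}

#' Construct a label stack
#' @param labels 3D logical array.
#' @param spacingXY pixel size, um.
#' @param spacingZ slice separation, um.
#' @return a [LabelStack].
#' @export
labelStack <- function(labels, spacingXY, spacingZ) {
  new("LabelStack", labels = labels, spacingXY = as.numeric(spacingXY),
      spacingZ = as.numeric(spacingZ))
}

#' Render a synthetic confocal stack of a bead
#'
#' Voxelizes the closed surface with sub-voxel partial-volume sampling
#' (foreground intensity 1, background 0), applies an anisotropy-aware
#' Gaussian blur of physical width `blurSigma`, and adds clamped Gaussian
#' noise with standard deviation `noiseLevel` times the foreground
#' intensity. The mesh is placed with a margin inside the stack; stack
#' coordinates have their origin at the stack corner.
#'
#' @param surface a closed [TriSurfaceMesh] (um coordinates).
#' @param spacingXY pixel size, um.
#' @param spacingZ slice separation, um.
#' @param blurSigma blur standard deviation, um (0 = none).
#' @param noiseLevel noise standard deviation as a fraction of the
#'   foreground intensity (0 = none).
#' @param seed integer seed; identical seeds give identical stacks.
#' @param nsub sub-voxel sampling density per axis for partial volume.
#' @return an [ImageStack].
#' @examples
#' st <- renderBeadStack(makeSphereSurface(8.5, 2), 0.2, 1, 0, 0, seed = 1)
#' @export
renderBeadStack <- function(surface, spacingXY = 0.1, spacingZ = 1,
                            blurSigma = 0.2, noiseLevel = 0.05, seed = 1,
                            nsub = 3) {
  stopifnot(is(surface, "TriSurfaceMesh"))
  stopifnot(spacingXY > 0, spacingZ > 0, noiseLevel >= 0, blurSigma >= 0)
  V <- surface@vertices
  F <- surface@faces
  if (meshVolume(surface) <= 0) stop("surface must enclose positive volume")
  pad <- 3 * blurSigma + 2 * max(spacingXY, spacingZ)
  lo <- apply(V, 2, min) - pad
  hi <- apply(V, 2, max) + pad
  Vs <- sweep(V, 2, lo)
  nx <- ceiling((hi[1] - lo[1]) / spacingXY)
  ny <- ceiling((hi[2] - lo[2]) / spacingXY)
  nz <- max(3, ceiling((hi[3] - lo[3]) / spacingZ))
  vox <- cpp_voxelize_mesh(Vs, F - 1L, spacingXY, spacingXY, spacingZ,
                           nx, ny, nz, as.integer(nsub))
  if (blurSigma > 0)
    vox <- cpp_gauss_blur(vox, nx, ny, nz, blurSigma / spacingXY,
                          blurSigma / spacingXY, blurSigma / spacingZ)
  if (noiseLevel > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(as.integer(seed))
    vox <- vox + rnorm(length(vox), sd = noiseLevel)
    vox[vox < 0] <- 0
  }
  imageStack(array(vox, dim = c(nx, ny, nz)), spacingXY, spacingZ)
}

#' Segment a bead from an image stack
#'
#' Thresholds the stack (Otsu's criterion on the full-stack histogram by
#' default, computed on intensities normalized to [0, 1] so segmentation is
#' invariant to uniform intensity scaling), keeps the largest 6-connected
#' foreground component, and fills enclosed holes slice by slice.
#'
#' @param stack an [ImageStack] containing one bright bead on a darker
#'   background.
#' @param method `"otsu"` or a numeric threshold on the normalized [0, 1]
#'   intensity scale.
#' @return a [LabelStack].
#' @export
segmentBead <- function(stack, method = "otsu") {
  stopifnot(is(stack, "ImageStack"))
  vox <- stack@voxels
  mx <- max(vox)
  if (mx <= 0) stop("segmentation failed: stack has no signal")
  vn <- vox / mx
  thr <- if (is.numeric(method)) {
    method
  } else if (identical(method, "otsu")) {
    EBImage::otsu(matrix(vn, nrow = dim(vn)[1]), range = c(0, 1))
  } else stop("unknown thresholding method: ", method)
  m <- vn >= thr
  if (!any(m)) stop("segmentation failed: no foreground above threshold")
  d <- dim(vox)
  m <- cpp_largest_component(as.vector(m), d[1], d[2], d[3])
  m <- cpp_fill_holes_slices(m, d[1], d[2], d[3])
  labelStack(array(m, dim = d), stack@spacingXY, stack@spacingZ)
}

#' Volume of a segmented bead
#'
#' Foreground voxel count times the voxel volume
#' `spacingXY^2 * spacingZ` (the voxel-counting volume estimate used for
#' osmotic-compression volumetry).
#'
#' @param labels a [LabelStack].
#' @return volume, um^3.
#' @export
labelVolume <- function(labels) {
  stopifnot(is(labels, "LabelStack"))
  n <- sum(labels@labels)
  if (n == 0) stop("empty label stack")
  n * labels@spacingXY^2 * labels@spacingZ
}

#' Equivalent spherical diameter of a volume
#'
#' \eqn{d = (6V/\pi)^{1/3}}.
#'
#' @param volume volume, um^3 (> 0).
#' @return diameter, um.
#' @examples
#' equivalentDiameter(pi / 6)   # 1
#' @export
equivalentDiameter <- function(volume) {
  if (any(volume <= 0)) stop("volume must be positive")
  (6 * volume / pi)^(1 / 3)
}
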