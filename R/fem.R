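# Geometrically nonlinear static finite-element solver.
#
# Total-Lagrangian formulation on 4-node tetrahedra with the compressible
# Neo-Hookean strain energy
#   W = mu/2 (I1 - 3) - mu ln J + lambda/2 (ln J)^2,
# which linearizes to (E, nu) at small strain. Pressure loads are follower
# loads (consistent nodal forces and load stiffness on the current
# surface); tangential tractions are dead loads evaluated on the reference
# surface. Newton iterations use the full consistent tangent and automatic
# load-step halving. Pure-traction problems are regularized by Lagrange
# multipliers constraining net translation and rotation.
#
# Units: coordinates um, moduli Pa; nodal forces are then Pa um^2 = pN.

#' Prescribed-displacement boundary condition
#' @param nodeIds integer node ids.
#' @param values numeric matrix (length(nodeIds) x 3) of displacements, um.
#' @return a [DirichletBC].
#' @export
dirichletBC <- function(nodeIds, values) {
  new("DirichletBC", nodeIds = as.integer(nodeIds),
      values = matrix(as.numeric(values), ncol = 3))
}

#' Follower normal-pressure traction
#' @param faceIds indices into the mesh boundary-face list.
#' @param pressure pressure per face, Pa (positive = compressive); recycled.
#' @return a [TractionBC].
#' @export
tractionPressure <- function(faceIds, pressure) {
  faceIds <- as.integer(faceIds)
  new("TractionBC", faceIds = faceIds, type = "pressure",
      pressure = rep_len(as.numeric(pressure), length(faceIds)),
      traction = matrix(numeric(0), 0, 3))
}

#' Fixed-direction (dead) surface traction
#' @param faceIds indices into the mesh boundary-face list.
#' @param traction numeric matrix (length(faceIds) x 3), Pa.
#' @return a [TractionBC].
#' @export
tractionVector <- function(faceIds, traction) {
  new("TractionBC", faceIds = as.integer(faceIds), type = "traction",
      pressure = numeric(0), traction = matrix(as.numeric(traction), ncol = 3))
}

# rigid-body constraint matrix: net translation and net rotation of all
# nodes are zero; rows scaled to O(1)
rigidConstraints <- function(X) {
  n <- nrow(X)
  dofx <- 3 * seq_len(n) - 2
  i <- c(rep(1, n), rep(2, n), rep(3, n),
         rep(4, 2 * n), rep(5, 2 * n), rep(6, 2 * n))
  j <- c(dofx, dofx + 1, dofx + 2,
         dofx + 1, dofx + 2,    # rot x: -Xz u_y + Xy u_z
         dofx, dofx + 2,        # rot y:  Xz u_x - Xx u_z
         dofx, dofx + 1)        # rot z: -Xy u_x + Xx u_y
  r0 <- mean(sqrt(rowSums(X^2))) + 1e-9
  x <- c(rep(1 / n, 3 * n),
         c(-X[, 3], X[, 2]) / (n * r0),
         c(X[, 3], -X[, 1]) / (n * r0),
         c(-X[, 2], X[, 1]) / (n * r0))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(6, 3 * n))
}

# supernodal CHOLMOD factorization with symbolic-analysis reuse (the
# sparsity pattern is constant across Newton iterations); NULL on failure
# (caller treats it as a failed Newton step)
cholFactor <- function(K, cache) {
  tryCatch({
    if (is.null(cache$ch)) cache$ch <- Matrix::Cholesky(K, super = TRUE)
    else cache$ch <- Matrix::update(cache$ch, K)
    cache$ch
  }, error = function(e) NULL, warning = function(w) NULL)
}

cholSolve <- function(K, b, cache) {
  ch <- cholFactor(K, cache)
  if (is.null(ch)) return(NULL)
  tryCatch(as.numeric(Matrix::solve(ch, b)), error = function(e) NULL)
}

# 3-2-1 support: 6 dofs whose fixation removes all rigid-body modes
# (node A fully; node B transverse to AB; node C normal to plane ABC)
pickSupportDofs <- function(X) {
  cen <- colMeans(X)
  A <- which.max(rowSums(sweep(X, 2, cen)^2))
  B <- which.max(rowSums(sweep(X, 2, X[A, ])^2))
  ab <- X[B, ] - X[A, ]
  ab <- ab / sqrt(sum(ab^2))
  bAxes <- order(abs(ab))[1:2]
  dline <- sweep(X, 2, X[A, ])
  dline <- dline - outer(as.vector(dline %*% ab), ab)
  Cn <- which.max(rowSums(dline^2))
  nrm <- c(ab[2] * dline[Cn, 3] - ab[3] * dline[Cn, 2],
           ab[3] * dline[Cn, 1] - ab[1] * dline[Cn, 3],
           ab[1] * dline[Cn, 2] - ab[2] * dline[Cn, 1])
  cAxis <- which.max(abs(nrm))
  sort(c(3 * (A - 1) + 1:3, 3 * (B - 1) + bAxes, 3 * (Cn - 1) + cAxis))
}

# exact solve of the bordered system [[K, C'], [C, 0]] [du; lam] = [r; d]
# by partitioning 6 support dofs out of K and forming the 12 x 12 Schur
# complement over (u_pinned, lam); K_QQ is factored with CHOLMOD
borderedSolve <- function(K, C, pinned, r, d, cache) {
  ndof <- nrow(K)
  Q <- setdiff(seq_len(ndof), pinned)
  KQQ <- K[Q, Q, drop = FALSE]
  ch <- cholFactor(KQQ, cache)
  if (is.null(ch)) return(NULL)
  KQP <- as.matrix(K[Q, pinned, drop = FALSE])
  CQt <- t(as.matrix(C[, Q, drop = FALSE]))
  RHS <- cbind(r[Q], KQP, CQt)
  Y <- as.matrix(Matrix::solve(ch, RHS))
  yb <- Y[, 1]
  YK <- Y[, 2:7, drop = FALSE]
  YC <- Y[, 8:13, drop = FALSE]
  KPP <- as.matrix(K[pinned, pinned, drop = FALSE])
  CP <- as.matrix(C[, pinned, drop = FALSE])          # 6 x 6
  # remaining equations in (u_P, lam)
  S <- rbind(cbind(KPP - crossprod(KQP, YK), t(CP) - crossprod(KQP, YC)),
             cbind(CP - crossprod(CQt, YK), -crossprod(CQt, YC)))
  rhs <- c(r[pinned] - crossprod(KQP, yb),
           d - as.numeric(crossprod(CQt, yb)))
  sol <- tryCatch(solve(S, rhs), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  uP <- sol[1:6]
  lamS <- sol[7:12]
  du <- numeric(ndof)
  du[pinned] <- uP
  du[Q] <- yb - YK %*% uP - YC %*% lamS
  list(du = du, lam = lamS)
}

# expand traction BCs into a full per-boundary-face pressure vector and a
# dead nodal force vector
expandTractions <- function(mesh, tractions) {
  bf <- mesh@boundaryFaces
  nfb <- nrow(bf)
  pvec <- numeric(nfb)
  fdead <- numeric(3 * nrow(mesh@nodes))
  if (is(tractions, "TractionBC")) tractions <- list(tractions)
  g <- faceGeometry(mesh@nodes, bf)
  for (tr in tractions) {
    stopifnot(is(tr, "TractionBC"))
    if (any(tr@faceIds < 1 | tr@faceIds > nfb))
      stop("traction faceIds outside the boundary-face list")
    if (tr@type == "pressure") {
      pvec[tr@faceIds] <- pvec[tr@faceIds] + tr@pressure
    } else {
      fpf <- tr@traction * g$areas[tr@faceIds] / 3
      for (a in 1:3) {
        ids <- bf[tr@faceIds, a]
        for (cc in 1:3)
          fdead[3 * (ids - 1) + cc] <- fdead[3 * (ids - 1) + cc] + fpf[, cc]
      }
    }
  }
  list(pvec = pvec, fdead = fdead)
}

#' Solve a static large-deformation problem
#'
#' Newton iteration with consistent tangent, incremental load stepping
#' (prescribed displacements, dead loads and follower pressures are all
#' scaled by the load fraction) and automatic step halving when an
#' increment fails to converge or inverts an element.
#'
#' @param mesh a [TetMesh].
#' @param mat a [Material].
#' @param dirichlet a [DirichletBC] or NULL. Without one, rigid-body modes
#'   are removed by zero-net-translation/rotation constraints (for
#'   self-equilibrated traction problems).
#' @param tractions a [TractionBC] or list of them.
#' @param nLoadSteps initial number of equal load increments.
#' @param tol relative residual tolerance.
#' @param maxIter Newton iteration cap per increment.
#' @return a [DisplacementField].
#' @export
solveStatic <- function(mesh, mat, dirichlet = NULL, tractions = list(),
                        nLoadSteps = 5, tol = 1e-8, maxIter = 25) {
  stopifnot(is(mesh, "TetMesh"), is(mat, "Material"))
  X <- mesh@nodes
  n <- nrow(X)
  ndof <- 3 * n
  tets0 <- mesh@tets - 1L
  bf0 <- mesh@boundaryFaces - 1L
  mu <- shearModulus(mat)
  lam <- lameFirst(mat)

  tr <- expandTractions(mesh, tractions)
  hasPressure <- any(tr$pvec != 0)
  hasDead <- any(tr$fdead != 0)

  if (!is.null(dirichlet)) {
    stopifnot(is(dirichlet, "DirichletBC"))
    if (any(dirichlet@nodeIds < 1 | dirichlet@nodeIds > n))
      stop("Dirichlet node ids out of range")
    fix <- as.vector(t(outer(3 * (dirichlet@nodeIds - 1), 1:3, "+")))
    uD <- as.vector(t(dirichlet@values))
    free <- setdiff(seq_len(ndof), fix)
    C <- NULL
  } else {
    fix <- integer(0); uD <- numeric(0)
    free <- seq_len(ndof)
    C <- rigidConstraints(X)
  }

  u <- numeric(ndof)
  lamC <- numeric(6)
  iters <- integer(0)
  sDone <- 0
  ds <- 1 / nLoadSteps
  dsMin <- ds / 64
  pinned <- if (is.null(C)) NULL else pickSupportDofs(X)
  cache <- new.env(parent = emptyenv())
  # absolute residual floor: machine-level forces on the scale mu * V^(2/3)
  # (so zero-load/zero-displacement problems converge immediately)
  fFloor <- 1e-10 * mu * sum(tetVolumes(X, mesh@tets))^(2 / 3)

  newtonStep <- function(u, lamC, s) {
    firstRes <- NA_real_
    for (it in seq_len(maxIter)) {
      asm <- cpp_tet4_assemble(X, tets0, u, mu, lam, TRUE)
      if (!isTRUE(asm$ok)) return(list(ok = FALSE))
      fext <- s * tr$fdead
      if (hasPressure) {
        pr <- cpp_follower_pressure(X, bf0, s * tr$pvec, u, TRUE)
        fext <- fext + pr$fext
      }
      r <- asm$fint - fext
      ru <- if (is.null(C)) r else r + as.numeric(Matrix::crossprod(C, lamC))
      rn <- sqrt(sum(ru[free]^2))
      if (is.na(firstRes)) firstRes <- rn
      scale <- max(sqrt(sum(fext^2)), firstRes, 1e-12)
      if (rn <= tol * scale || rn <= fFloor)
        return(list(ok = TRUE, u = u, lamC = lamC, iters = it - 1L))
      K <- Matrix::sparseMatrix(i = asm$Ki, j = asm$Kj, x = asm$Kx,
                                dims = c(ndof, ndof))
      if (hasPressure)
        K <- K - Matrix::sparseMatrix(i = pr$Ki, j = pr$Kj, x = pr$Kx,
                                      dims = c(ndof, ndof))
      # the elastic tangent is symmetric; the follower-pressure load
      # stiffness is symmetric up to the (small) nonuniform-pressure part,
      # so the symmetrized tangent is factored with sparse Cholesky
      K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
      if (is.null(C)) {
        du <- cholSolve(K[free, free, drop = FALSE], -r[free], cache)
        if (is.null(du)) return(list(ok = FALSE))
        u[free] <- u[free] + du
      } else {
        sol <- borderedSolve(K, C, pinned, -r, -as.numeric(C %*% u), cache)
        if (is.null(sol)) return(list(ok = FALSE))
        u <- u + sol$du
        lamC <- sol$lam
      }
    }
    list(ok = FALSE)
  }

  while (sDone < 1 - 1e-12) {
    s <- min(1, sDone + ds)
    utrial <- u
    if (length(fix)) utrial[fix] <- s * uD
    res <- newtonStep(utrial, lamC, s)
    if (res$ok) {
      u <- res$u; lamC <- res$lamC
      iters <- c(iters, res$iters)
      sDone <- s
    } else {
      ds <- ds / 2
      if (ds < dsMin)
        stop(sprintf(
          "Newton iteration diverged; last converged load fraction %.3f",
          sDone))
    }
  }
  new("DisplacementField",
      displacements = matrix(u, ncol = 3, byrow = TRUE),
      converged = TRUE, iterations = as.integer(iters))
}

#' Recover the Cauchy stress field from a converged solution
#'
#' Evaluates \eqn{\sigma = J^{-1} \partial W/\partial F\, F^T} at the
#' integration point of every element, together with the current
#' integration-point volume and J.
#'
#' @param mesh the [TetMesh] the solution was computed on.
#' @param field a [DisplacementField] from [solveStatic()].
#' @param mat the [Material] used in the solve.
#' @return a [StressField].
#' @export
cauchyStress <- function(mesh, field, mat) {
  stopifnot(is(mesh, "TetMesh"), is(field, "DisplacementField"),
            is(mat, "Material"))
  u <- as.vector(t(field@displacements))
  asm <- cpp_tet4_assemble(mesh@nodes, mesh@tets - 1L, u,
                           shearModulus(mat), lameFirst(mat), FALSE)
  if (!isTRUE(asm$ok))
    stop("deformation gradient not invertible at element ", asm$bad)
  xcur <- mesh@nodes + field@displacements
  cent <- (xcur[mesh@tets[, 1], ] + xcur[mesh@tets[, 2], ] +
           xcur[mesh@tets[, 3], ] + xcur[mesh@tets[, 4], ]) / 4
  new("StressField", tensors = asm$sigma, volumes = asm$vcur,
      J = asm$J, centroids = cent)
}

#' Deformed mesh for a converged solution
#'
#' @param mesh a [TetMesh].
#' @param field a [DisplacementField] on that mesh.
#' @return a [TetMesh] with displaced nodes (same connectivity).
#' @export
deformedMesh <- function(mesh, field) {
  new("TetMesh", nodes = mesh@nodes + field@displacements,
      tets = mesh@tets, boundaryFaces = mesh@boundaryFaces,
      surfaceNodeIds = mesh@surfaceNodeIds)
}

#' Analytic uniform-dilatation state under hydrostatic pressure
#'
#' For the Neo-Hookean energy used by the solver, a homogeneous follower
#' pressure p produces a uniform deformation \eqn{F = J^{1/3} I} whose
#' radial Cauchy stress is \eqn{\sigma(J) = (\mu(J^{2/3} - 1) + \lambda
#' \ln J)/J}. This solves \eqn{\sigma(J) + p = 0} for J (bisection via
#' [stats::uniroot()]), giving an exact oracle for the FE solver.
#'
#' @param pressure applied pressure, Pa (positive = compression).
#' @param mat a [Material].
#' @return named vector with `J` and the uniform stress `sigma` (Pa).
#' @export
uniformDilatationState <- function(pressure, mat) {
  mu <- shearModulus(mat); lam <- lameFirst(mat)
  s <- function(J) (mu * (J^(2 / 3) - 1) + lam * log(J)) / J
  f <- function(J) s(J) + pressure
  root <- uniroot(f, lower = 1e-4, upper = 1e4, tol = 1e-14)
  c(J = root$root, sigma = s(root$root))
}
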