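---
title: "Reconstructing cell-scale stresses from deformed hydrogel microbeads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing cell-scale stresses from deformed hydrogel microbeads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadstress)
```

## The measurement principle

Soft polyacrylamide (PAAm) microbeads implanted in living tissue deform
under the forces that surrounding cells exert on them. Unlike oil
microdroplets, hydrogel beads are *compressible*, so their volume change
carries information about isotropic pressure, and because their elastic
moduli are known, the full Cauchy stress tensor inside the bead can be
inferred from its deformed shape alone. The beads this package models are
produced microfluidically with a narrow size distribution (17.0 ± 0.5 µm
diameter), so the unknown stress-free configuration of any observed bead
can reasonably be *assumed* to be a sphere of the production mean
diameter. That assumption replaces the missing reference configuration
and is what makes a shape-only inverse problem solvable.

## Constitutive model

The bead is a compressible Neo-Hookean solid with strain energy

$$ W(\mathbf F) = \tfrac{\mu}{2}\left(I_1 - 3\right) - \mu \ln J
   + \tfrac{\lambda}{2} (\ln J)^2, \qquad
   I_1 = \operatorname{tr}(\mathbf F^\top \mathbf F), \quad
   J = \det \mathbf F, $$

which linearizes to isotropic elasticity with Young's modulus $E$ and
Poisson ratio $\nu$ at small strain ($\mu = E/2(1+\nu)$,
$\lambda = E\nu/((1+\nu)(1-2\nu))$). The Cauchy stress is
$\boldsymbol\sigma = J^{-1}(\mu(\mathbf B - \mathbf I) + \lambda \ln J\,
\mathbf I)$ with $\mathbf B = \mathbf F\mathbf F^\top$. Different
commercial codes use slightly different compressible Neo-Hookean splits
that agree at small strain and diverge at large strain; here the same $W$
is used for the forward virtual experiments and the inverse
reconstruction, so validation round trips are internally consistent by
construction.

Default parameters (all overridable):

| parameter | default | unit | origin |
|---|---|---|---|
| $E$ | 1800 | Pa | virtual-experiment bead; osmotic + AFM characterization supports ~2.1 kPa via $E = 3\kappa(1-2\nu)$ |
| $\nu$ | 0.443 | – | independently measured for this PAAm formulation |
| $D$ | 17.0 | µm | production mean diameter |
| $\kappa$ | derived, $E/3(1-2\nu)$ | Pa | consistency with $(E,\nu)$ to machine precision |

`fitBulkModulus()` estimates $\kappa$ from an osmotic compression series
as the least-squares slope of pressure versus volumetric strain
$-\Delta V/V$ *through the origin* (zero pressure cannot strain the
bead), restricted to strains ≤ 0.15 where the material response is close
to linear.

## The three-step inverse reconstruction

1. **Deformed mesh.** The observed bead (confocal stack) is segmented
   (Otsu threshold on the full-stack histogram, largest 6-connected
   component, per-slice hole filling), a closed surface is extracted, and
   the interior is tetrahedralized.
2. **Reference construction.** Radial distance vectors
   $\mathbf v_i = (R - |\mathbf x_i - \mathbf c|)
   \,(\mathbf x_i - \mathbf c)/|\mathbf x_i - \mathbf c|$ carry each
   boundary node onto the assumed reference sphere. Applied as Dirichlet
   data in a preprocessing finite-element solve, they deform the whole
   mesh into the assumed stress-free spherical configuration; interior
   nodes follow elastic equilibrium, which keeps element quality
   reasonable.
3. **Main solve.** The *inverse* vectors are applied as surface
   displacements on the reference mesh, returning the boundary exactly to
   the observed shape; the converged state provides the per-element Cauchy
   tensors, and the volume-weighted mean
   $\boldsymbol\sigma^{\varnothing} = \sum_i \boldsymbol\sigma_i v_i /
   \sum_i v_i$, its principal decomposition, and the mean pressure
   $-\operatorname{tr}(\boldsymbol\sigma^{\varnothing})/3$ (positive =
   compression) are reported.

Choices made where the procedure is underdetermined:

* **Sphere centre.** The volume centroid of the deformed mesh. It is the
  unique rigid-motion-equivariant choice that needs no extra input.
* **Material of the preprocessing solve.** The same material as the main
  solve. The preprocessing deformation is an auxiliary mesh-morphing
  device; any well-behaved elastic law would do, and using one material
  keeps the configuration chain consistent.
* **Star-shapedness.** The radial construction is undefined if some
  boundary point is not visible from the centre along its ray.
  `tetrahedralize()` verifies this (ray-crossing count per boundary face)
  and errors on violation rather than silently producing a wrong
  reference.

A quick small-strain estimate of the mean pressure,
$-\kappa (V_c - V_r)/V_r$, is available as `approxMeanPressure()`; at
volume changes beyond a few percent it deviates from the volume average
of the nonlinear local pressure, which is why the full solve is the
primary quantity.

## Finite-element solver

* **Elements.** 4-node tetrahedra with one integration point, in a total
  Lagrangian setting with the exact consistent material tangent. At
  $\nu = 0.443$ the volumetric-locking risk of linear elements is mild,
  and the states probed by the validation scenarios are dominated by
  smooth, nearly hydrostatic deformation: a uniform dilatation is
  representable *exactly* by linear elements, which is why the
  homogeneous-pressure round trip reproduces the applied load to
  machine precision. Because forward and inverse solves share the
  discretization, the residual element-order error largely cancels in
  round-trip comparisons; the mesh-convergence test (halving element
  size changes the recovered mean pressure by < 1 %) guards the choice.
* **Follower pressure.** Surface pressures act along the current deformed
  normal with consistent nodal forces ($-p\,(\mathbf e_1 \times \mathbf
  e_2)/6$ per triangle node) and the corresponding load stiffness.
  Tangential shear loads are dead loads evaluated on the reference
  sphere (magnitude and pole-to-pole orientation are the stated facts;
  a follower variant would differ only at higher order for the moderate
  strains involved).
* **Linear algebra.** The elastic tangent is symmetric; the
  follower-pressure stiffness is symmetric up to a small nonuniform-
  pressure part. The solver symmetrizes the tangent and factors it with
  supernodal sparse Cholesky (CHOLMOD), reusing the symbolic analysis
  across Newton iterations. Convergence is quadratic in all shipped
  scenarios.
* **Rigid-body modes.** Pure-traction problems are closed by Lagrange
  multipliers enforcing zero net translation and rotation. The bordered
  system is solved exactly via a 3-2-1 support partition (six
  well-separated support degrees of freedom) and a 12 × 12 Schur
  complement, which keeps the sparse factor positive definite.
* **Newton controls.** Relative residual tolerance $10^{-8}$ (with an
  absolute floor at machine-level forces so unloaded problems converge
  immediately), 5 equal load increments by default, automatic halving of
  an increment on divergence or element inversion, hard error after six
  halvings reporting the last converged load fraction.
* **Units.** Geometry in µm, moduli in Pa; nodal forces are then
  piconewtons. No internal rescaling is needed at these magnitudes.

## Geometry processing

Volume meshes are built by radially layering the (star-shaped) boundary
surface: concentric scaled copies of the surface connected by prisms,
each split into three tetrahedra with index-ordered diagonals so shared
quad faces always match, and the innermost shell coned to the centre.
The boundary of the volume mesh is *exactly* the input surface — the
property the inverse pipeline depends on. Tetrahedra near the centre are
radially stretched; they are also small, so their contribution to
volume-weighted summaries is negligible.

Surfaces are extracted from label stacks by sampling the 0.5-level of
the binary field along rays from the label centroid in the directions of
an icosphere template (anisotropic voxel spacing respected, trilinear
interpolation, outermost crossing taken). Compared with marching cubes
this yields a watertight, uniformly triangulated surface whose
connectivity feeds directly into the layered tetrahedralization, at the
cost of assuming star-shapedness — an assumption the reconstruction
makes anyway. Optional Taubin smoothing ($\lambda|\mu$ passes, default
10) removes voxelization ridges; after smoothing the surface is rescaled
isotropically about its volume centroid so the enclosed volume is
restored exactly — smoothing must not bias the volumetry that the
pressure estimate rests on.

## Synthetic imaging

`renderBeadStack()` emulates the confocal observation: 0.1 µm square
pixels within a section, 1 µm between sections, partial-volume
(sub-voxel area fraction) foreground values at the bead boundary,
Gaussian blur of physical width, and additive Gaussian noise with
standard deviation proportional to the foreground intensity (clamped at
zero). It does **not** model an anisotropic confocal PSF, depth-dependent
attenuation, Poisson photon statistics, bleaching, or drift between
sections. Passing round-trip tests therefore demonstrate correctness of
the geometry/segmentation/solver chain under idealized imaging, not
robustness to every real-microscope artifact; the stated production
spread (± 0.5 µm) is the fidelity yardstick used for the imaging round
trip.

## Virtual load scenarios

Four parametric scenarios on the standard bead serve as virtual
experiments: homogeneous pressure (1000 Pa), sinusoidal pressure in the
equatorial angle (600–1000 Pa, wavelength π/4, i.e. eight periods),
quadratic pole-to-equator pressure (1000 Pa equator, 600 Pa poles), and
homogeneous 800 Pa combined with two hemispherical tangential loads of
120 Pa (north→south on one half, east→west on the other). Unstated
details fixed here: the sinusoid uses $\sin$ with zero phase (only range
and wavelength are constrained); the shear hemispheres split at the
$x = 0$ plane with pole axes $+z$ and $+x$. The printed claims —
magnitudes, tangency, mean-pressure behaviour — are insensitive to these
choices.

`runValidation()` compares the forward ("virtual data") summary with the
reconstruction on the matched mesh by default, isolating method error
from imaging error; `imaging = TRUE` interposes the full render/segment
round trip. Principal-direction agreement is reported as the angle to
the reference eigenvector, or to the reference *eigenspace* when
eigenvalues are within 2 % of the largest magnitude of each other — for
nearly degenerate pairs (e.g. the in-plane pair of the eight-fold
sinusoidal scenario) the individual directions are not determined, only
their plane.

Normal-stress profiles $\sigma_{nn}(\varphi)$ are computed from the
volumetric mean tensor in the x–y plane (the equatorial-plane convention
used for time-series displays); per time point, deviations from the
angular mean may be amplified by a factor of 5 — leaving each mean
unchanged — and the series normalized by its global maximum absolute
value. The profile could alternatively be built from surface-sampled
stresses in the confocal plane; the mean-tensor variant is the default
because it is insensitive to surface discretization noise.

## Uncertainty analysis

`uncertaintyAnalysis()` propagates bead-to-bead spread through the
inverse step: the observed shape is fixed, while each Monte-Carlo sample
reconstructs with a diameter and modulus drawn from truncated normal
distributions (± 3 SD, positive; defaults 17.0 ± 0.5 µm and 1.8 ± 0.7
kPa). Because the reconstruction is displacement-driven, the recovered
stress scales *exactly* linearly in the assumed modulus at fixed shape
and diameter — the property the test suite checks. A published summary
figure of "up to 30 % standard deviation" cannot be reproduced exactly
because the underlying sampling protocol is not published; the linearity
oracle replaces it.

## Problem sizes and tolerances

The shipped acceptance computations use an icosphere of subdivision 3
with 8 radial layers (642 boundary vertices, ~28k tetrahedra), which
this package treats as its standard production resolution: the
homogeneous round trip is then exact to solver precision and the
pressure+shear mean recovers to ~0.05 %. The unit-test suite exercises
the same code paths at subdivisions 1–2 (hundreds to thousands of
elements), where every tolerance asserted is still met with an order of
magnitude to spare. Rendering tests use 0.2 µm pixels; the nominal
0.1 µm is used where the production spread (± 0.5 µm) is the criterion.

## Known limitations

* Surface shear transmitted by the tissue is not observable from shape
  alone: reconstructed local surface-pressure and shear maps deviate
  from the true fields whenever loading has a strong tangential
  component, even while the volumetric mean pressure and principal
  directions remain reliable. This is a property of the method, and the
  pressure+shear validation asserts it rather than hiding it.
* Non-star-shaped beads are rejected, not approximated.
* The material is elastic: no poroelastic fluid exchange or viscous
  relaxation, so time series are interpreted quasi-statically.
* Linear tetrahedra trade some local stress accuracy for robustness and
  speed; volumetric summaries converge quickly, local extrema more
  slowly.
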