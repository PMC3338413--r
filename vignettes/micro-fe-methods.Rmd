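---
title: "Voxel micro-FE compression analysis: models, solver and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel micro-FE compression analysis: models, solver and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microfe)
```

## The model

`microfe` estimates the apparent mechanical competence of trabecular bone from
a 3D image of bone-volume fraction (BVF). Every voxel becomes one 8-node
hexahedral element with tri-linear displacement interpolation; a voxel's
Young's modulus is `tissue_modulus * BVF` (grayscale mode, the default) or an
all-or-nothing value against a threshold (binary mode). The tissue material is
isotropic linear elastic, `sigma = C(E, nu) epsilon` in Voigt notation with
engineering shear strains. Tissue-level anisotropy is deliberately not
modelled: at the imaging resolutions this package targets, the dominant
anisotropy of the specimen comes from the trabecular architecture itself,
which the voxel mesh resolves explicitly.

Defaults are `tissue_modulus = 15000` MPa and `nu = 0.3`, the common
convention in image-based micro-FE of trabecular bone; both are plain
arguments of `material_law()` and should be set to whatever calibration the
image source provides. Voxels must be cubic — the shared element kernel is
derived for a cube, and anisotropic spacing is rejected rather than silently
approximated.

A simulated compression test (`simulate_compression()`) prescribes
displacements on the two faces normal to the load axis: the bottom face is
held at zero axial displacement and the top face moved by `-strain * L`. With
the default `axial-only` ends the transverse directions remain free
(frictionless platens); `clamped` additionally pins them. The apparent
stiffness is `total stress / strain`, where the total stress is the sum of
axial reaction forces on the displaced face divided by the full cross-section
area (apparent stress, in MPa). Dividing by the bone-only area would be an
equally defensible convention; the full-section one is used because it makes
the stiffness of a solid block equal the tissue modulus exactly and matches
how patient stiffness is usually quoted in MPa.

### Degenerate inputs

Connected components of material (vertex-sharing, i.e. 26-neighbour
connectivity — the weakest coupling that still links elements in the
stiffness graph) that touch no constrained vertex would make the system
singular; `prune_unanchored()` removes them before numbering the unknowns.
With `axial-only` ends the reduced system is still only positive
*semi*-definite: whole-body transverse translations and the rotation about
the load axis cost no energy and are unconstrained. This is harmless — the
right-hand side is orthogonal to those modes, conjugate gradients converges on
the range space, and the reported stress and stiffness are invariant to them —
but it is why oracle comparisons against a direct sparse solve in the test
suite use `clamped` ends, where the solution is unique.

## The solver

The equilibrium system `A U = B` on the free (vertex, direction) pairs is
never assembled. The element-by-element (EBE) operator stores, per element,
only the BVF-scaled modulus and the 24 global variable indices; one shared
24×24 unit-modulus kernel (computed once per Poisson ratio and edge length by
2×2×2 Gauss quadrature, which is exact for this integrand) serves all
elements. `apply` gathers, multiplies, scatter-adds — always in the same
element order, so serial results are bit-reproducible. Jacobi-preconditioned
conjugate gradients drives the solve; the preconditioner is the inverse of
the assembled diagonal, accumulated element by element.

The analytic memory model (`ebe_memory_model()`) prices this choice: 1 byte
of BVF, 16 bytes of base indices (one sixth of the 24 four-byte indices —
the rest follow by offsetting, because variables are numbered with direction
innermost and raster order over vertices), 80 bytes for five single-precision
CG vectors at the empirical four variables per element, and at most 32 bytes
of index lookup map, about 130 bytes per element in total against up to 1296
for an assembled sparse matrix — a factor of about ten, paid for by roughly
1.8× more multiplications per iteration (`multiplication_ratio()`). The R
implementation itself uses double precision throughout; the byte model
describes the single-precision production layout the accounting is meant for,
not this process's allocator.

### Partitioned execution

`partition_z()` cuts the vertex layers into K contiguous slabs with
near-equal free-variable counts (cut planes by cumulative quantiles of the
per-layer counts). `partitioned_pcg()` then executes the slab-reorganised
iteration: per-region operator application on inner vertices, per-region
partial inner products, a global reduction in ascending region order,
per-region updates, and an exchange of the search direction on the duplicated
interface layers. Reductions always sum in ascending region then variable
order, so the iterates do not depend on any execution schedule: `K = 1` is
bitwise identical to the serial solver and other K agree to summation
round-off. K is therefore a data-layout contract that a threaded runtime
could exploit; correctness never depends on it. Memory overhead grows as
`2(K-1)/N_z` (two duplicated vertex layers per internal interface).

### Stopping: the stress-based error estimate

The quantity of interest is the total stress, not the residual, so the
default stopping rule models the monitored stress series as
`S_n ~ S_inf + alpha exp(b n)`. A least-squares line through
`log |S_n - S_{n-1}|` over the 30 most recent iterations (zero differences
dropped) gives slope `b` and intercept `a`, and the modelled remaining
relative error `exp(a + b n) / (|b| |S_n|)` is compared with the tolerance
(default 0.01). The estimate is first consulted after `window + 5`
iterations and is declared unavailable when the fitted slope is nonnegative
or fewer than three usable points remain, in which case iteration simply
continues. The stress is monitored every iteration; it is evaluated from the
loaded-face element subset only, which costs a small fraction of a full
operator application. A `scaled-residual` mode (`||r||/||B||`) and a
`fixed-iterations` mode (used on coarse pre-iteration grids) are also
available.

On series that truly decay exponentially the estimator is essentially exact
(the test suite recovers the slope to machine precision and the error to
within 5%). Its practical accuracy on real solves depends on how smoothly
the stress converges, which is where the package's synthetic fixtures are
*harder* than typical imaged bone: see "What the tests do and do not show"
below.

### Pre-iteration on coarser grids

`picg_solve()` runs the compression problem on a coarse-to-fine hierarchy.
Each level is produced by `downsample_model()` — block means of `f×f×f`
voxels after zero-padding to a multiple of `f` (padding adds only empty
material and cannot change the fine system) — with the voxel size scaled by
`f`, so the physical specimen is preserved. Block averaging is the natural
BVF-preserving aggregation; it produces fractional coarse BVF, so coarse
levels always use grayscale material scaling whatever the fine mode is.
Boundary conditions are regenerated from the coarse geometry at the same
macroscopic strain rather than restricted from the fine grid, avoiding
interpolation artefacts on the loaded faces. Displacements prolong to the
next level by tri-linear interpolation at physical vertex positions (no
rescaling — displacements are physical millimetres at every level) and seed
the next solve; prescribed dofs are overwritten by their boundary values.
The default schedule is factors 4, 2, 1 with a fixed budget of 200 CG
iterations per coarse level, the configuration that needed the fewest
fine-grid iterations in our experiments — deeper hierarchies added cost
without saving fine-grid work, and starving the coarse levels (12 instead of
200 iterations) roughly doubled it. This is warm-starting only: no residual
restriction or V-cycles, which keeps every level an ordinary compression
solve.

## Synthetic structures

No bone images ship with the package; `synthgen` builds models that exercise
every code path:

* `solid_block()` and `layered_block()` have closed-form stiffness (the
  tissue modulus; the series-springs harmonic mean) and anchor the
  acceptance suite. The layered closed form is exact only for `nu = 0`:
  with `nu > 0` the layers' different lateral contractions are incompatible
  at the interface, a genuine boundary-layer effect that slightly stiffens
  the composite, so the quantitative check is run at `nu = 0`.
* `plate_rod_lattice()` is a periodic union of plates normal to the load
  axis and full-height rods — the idealised version of the interconnected
  plates and struts of trabecular bone, with an exact inclusion–exclusion
  volume fraction and guaranteed spanning connectivity.
* `random_porous()` thresholds smoothed Gaussian noise. Because trabeculae
  align with habitual loading, the field mixes an axially invariant 2D
  component (weight `axial_mix = 0.5`) into the 3D noise, which forms
  vertical load-bearing ridges; `smoothing = 3` neighbour-averaging passes
  set the feature scale. Only components spanning both loaded faces are
  kept, and the threshold is bisected (the kept volume is monotone in the
  threshold) until the achieved BVF is within ±0.01 of the target. The
  default benchmark condition is a 32³ grid at target BVF 0.12, inside the
  0.10–0.15 range typical of human trabecular sites. Output is binary
  (BVF 0 or 1), like a segmented micro-CT volume.
* `degrade()` randomly zeroes a fraction of surface voxels, a crude
  resorption surrogate for monotonicity and longitudinal-change tests.

All generators are pure functions of their arguments; seeded ones use an
isolated RNG stream and leave `.Random.seed` untouched.

What these fixtures do *not* emulate: grayscale partial-volume shells around
trabeculae (segmented-binary fields are mechanically rougher than calibrated
MR BVF maps), realistic trabecular thickness distributions or marrow, and
image noise. Passing tests demonstrate solver correctness and the documented
qualitative behaviours on these structures, not validation against measured
bone stiffness.

## What the tests do and do not show

The oracle chain is: analytic elasticity matrices and a refined-quadrature
kernel for the element; dense/sparse assembled operators for EBE
application, diagonals and right-hand sides; direct sparse solves for PCG;
bitwise serial equivalence for the partitioned iteration; and closed-form
stiffness for solid and layered blocks. All of these pass at tolerances of
1e-8 and tighter.

Two documented behaviours of the *stress-based stopping rule* do not carry
over from large imaged volumes to the desk-scale synthetic fixtures, and the
corresponding acceptance tests are intentionally left failing rather than
weakened:

* On 32³ binary porous fixtures the stress series converges as a staircase:
  one-voxel struts and fragments hinged on single vertices give the operator
  isolated small eigenvalues, CG resolves them one at a time, and during the
  plateaus the 30-iteration window fit sees a steep, clean, *local* decay.
  The estimate then undershoots the true remaining error — by roughly a
  factor of three to six in the exponential regime on these fixtures (the
  acceptance suite computes the exact factors) — and the 1% stopping rule
  fires early. Requiring the criterion to hold over several consecutive
  checks was tried and does not help: the plateaus outlast any reasonable
  streak.
* Consequently, two runs that both stop at "1% estimated error" (for
  instance with and without coarse-grid pre-iteration) can disagree on
  stiffness by a few percent, even though against a long reference solve
  the warm-started run is the more accurate one and the fine-grid iteration
  saving is real.

For small, rough, binary structures the practical advice is to stop on the
scaled residual (`stopping_policy("scaled-residual", tolerance = 1e-8)`), as
every quantitative test in this package does; the stress-based estimate is
designed for, and reported accurate within a factor of two on,
multi-million-element imaged volumes whose spectra are dense enough for the
exponential model to hold.

## Problem sizes and run times

The test and acceptance workloads are sized for a single CPU: element
oracles on 4³ structures (explicit assembly is cheap there), partition and
lattice properties at 16–24³, solver-behaviour studies at 32³ with
5000-iteration reference solves, and the analytic resource models evaluated
at 75 million elements (arithmetic only). These sizes are the package's
fixture choices; nothing in the implementation is specific to them, and the
resource model is the tool for extrapolating memory to production volumes.

## Known limitations

Linear elasticity only — no failure load, no post-yield behaviour; a single
uniaxial compression test rather than the full homogenised stiffness tensor;
isotropic voxel spacing required; Jacobi is the only preconditioner;
partitioned execution is a serial contract for a threaded runtime, not
multi-process distribution. Image calibration (intensity to BVF) is the
reader's responsibility via sidecar slope/intercept; no registration or
k-space processing is provided.
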