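# microfe

Image-based micro-finite-element (micro-FE) analysis of trabecular bone in R,
built for desk-scale use: every voxel of a bone-volume-fraction (BVF) image
becomes one hexahedral element, and the apparent stiffness of the specimen is
obtained from a simulated uniaxial compression test.

The package is aimed at researchers working with high-resolution CT/MR bone
images (or synthetic stand-ins) who want specimen-level mechanics without a
cluster or a commercial FE code.

## The method

A BVF map `b(v) ∈ [0,1]` on an isotropic voxel grid defines one 8-node brick
element per voxel with Young's modulus `E(v) = E_t · b(v)` (grayscale mode;
`E_t` is the tissue modulus, default 15 000 MPa, Poisson ratio ν = 0.3) and
tri-linear shape functions. Compression by strain ε along an axis prescribes
`u_z = 0` on the bottom face and `u_z = −εL` on the top face; equilibrium at
the `N_v` free (vertex, direction) pairs gives the linear system

    A U = B,   A ∈ R^{N_v×N_v} symmetric positive (semi-)definite.

`A` is never assembled. All elements share one 24×24 unit-modulus kernel
`K = ∫ Bᵀ C B dV` (2×2×2 Gauss quadrature, exact), so applying `A` is an
element-by-element gather–multiply–scatter over per-element indices and
moduli — about 130 bytes per element instead of up to 1296 for a sparse
matrix. The system is solved by Jacobi-preconditioned conjugate gradients,
optionally

* warm-started by **pre-iteration on coarser grids** (block-averaged models
  at downsampling factors 4, 2, then 1, 200 iterations per coarse level,
  displacements prolonged tri-linearly), and
* executed over **K load-balanced z-slabs** whose iterates are identical to
  the serial solver up to summation order (bitwise for K = 1).

Iteration stops when the modelled relative error of the total stress
`S_n ≈ S_∞ + α e^{bn}` — a line fit to `log|S_n − S_{n−1}|` over the last 30
iterations — drops below a tolerance (default 1%), or on a scaled-residual
or fixed-iteration policy. Post-processing yields the total stress (reaction
forces on the displaced face over the full cross-section), apparent
stiffness `S/ε` in MPa, and a per-voxel strain-energy map.

Analytic resource models (`ebe_memory_model()`, `full_matrix_memory_model()`,
`multiplication_ratio()`, `overhead_fraction()`) price memory and iteration
cost before committing to a large volume.

## Worked example

```r
library(microfe)

# synthetic trabecular network: 32^3 voxels, 50 um, target BVF 12%
model <- random_porous(dims = c(32, 32, 32), target_bvf = 0.12, seed = 42)
model
#> <voxel_model> 32 x 32 x 32 voxels, 0.05 mm, mean BVF 0.1183

law <- material_law(tissue_modulus = 15000, poisson_ratio = 0.3)
result <- simulate_compression(model, law, strain = 0.01,
                               schedule = c(4, 2, 1))
result
#> <mufe_result>
#>   apparent stiffness: 255.336 MPa (stress 2.55336 MPa at strain 0.01, z axis, axial-only ends)
#>   3878 elements, 28732 free variables
#>   iterations per grid level [4 2 1]: 200 200 280; converged: TRUE
#>   estimated relative error at stop: 0.00805
```

A 1% compression of this 12%-BVF network carries 2.55 MPa of apparent
stress, i.e. an apparent stiffness of 255 MPa — two orders of magnitude
below the 15 GPa tissue modulus, which is the expected knock-down for a
porous architecture at this volume fraction. The coarse grids used their
fixed 200-iteration budgets; the fine grid stopped after 280 iterations at
an estimated stress error of 0.8%.

Planning a large run instead of executing one:

```r
ebe_memory_model(90.3e6, dims = c(600, 600, 251), K = 8)
#> Expected memory usage, element-by-element method
#>   Bone-volume fraction map                 90300000 bytes
#>   Element vertex-variable indices        1444800000 bytes
#>   Five CG vectors + preconditioner       7224000000 bytes
#>   Variable index lookup map               361440000 bytes
#>   Duplication overhead (K = 8)                 5.6%
#>   Total                                  9629255378 bytes (~110 bytes/element)
```

so a 90-million-element femur model fits in ~9.6 GB when split across 8
workers.

The same pipeline is scriptable from a shell via `exec/microfe`:

```sh
microfe synth --kind porous --dims 32,32,32 --target-bvf 0.12 \
        --seed 42 --output bone.nii.gz
microfe run --input bone.nii.gz --strain 0.01 --schedule 4,2,1 \
        --report report.txt --energy-map energy.nii.gz
microfe estimate --elements 90.3e6 --dims 600,600,251 --threads 8
```

`run` accepts NIfTI (`.nii/.nii.gz`), MetaImage (`.mhd/.mha`) and raw+JSON
sidecar volumes, and writes a plain `key: value` report plus optional energy
and displacement maps.

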