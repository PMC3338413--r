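# fixtures are generated in code; seeds fixed for reproducibility

default_law <- function(...) material_law(...)

# random porous mini-block with solid top and bottom plates (always anchored
# and spanning), BVF in (0,1] on interior voxels
tiny_random_model <- function(seed, dims = c(4, 4, 4), voxel_size = 0.05,
                              p_solid = 0.7) {
  withr::with_seed(seed, {
    bvf <- array(stats::rbinom(prod(dims), 1, p_solid) *
                   stats::runif(prod(dims), 0.3, 1), dims)
    bvf[, , 1] <- 1
    bvf[, , dims[3]] <- 1
    voxel_model(bvf, voxel_size)
  })
}

# full pipeline up to the linear system
build_system <- function(model, law = default_law(), strain = 0.01,
                         axis = "z", end_condition = "axial-only") {
  bcs <- uniaxial_compression_bcs(model, law, strain, axis, end_condition)
  model <- prune_unanchored(model, law, bcs, quiet = TRUE)
  dm <- build_dof_map(model, law, bcs)
  op <- ebe_operator(model, law, dm)
  list(model = model, law = law, bcs = bcs, dm = dm, op = op,
       B = rhs_from_bcs(op))
}

tight_policy <- function(tol = 1e-9) stopping_policy("scaled-residual", tolerance = tol)

solve_stiffness <- function(model, law = default_law(), schedule = 1,
                            tol = 1e-9, ...) {
  simulate_compression(model, law, schedule = schedule,
                       policy = tight_policy(tol), ...)$stiffness
}
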