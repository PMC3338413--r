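test_that("compression boundary conditions prescribe the right displacements", {
  law <- default_law()
  m <- solid_block(c(4, 4, 10), 0.1)
  b0 <- uniaxial_compression_bcs(m, law, 0)
  expect_true(all(b0$entries$value == 0))
  b <- uniaxial_compression_bcs(m, law, 0.01, "z")
  expect_equal(min(b$entries$value), -0.01)    # 10 voxels x 0.1 mm x 1%
  # axial-only: one constrained dof per active face vertex
  expect_equal(nrow(b$entries), 2L * 5L * 5L)
  expect_true(all(b$entries$d == 3L))
  bc <- uniaxial_compression_bcs(m, law, 0.01, "z", "clamped")
  expect_equal(nrow(bc$entries), 3L * 2L * 5L * 5L)
  expect_error(uniaxial_compression_bcs(m, law, 0.2), "strain")
  # a structure that misses one loaded face cannot be tested
  gap <- array(0, c(3, 3, 3)); gap[, , 1] <- 1
  expect_error(uniaxial_compression_bcs(voxel_model(gap, 0.05), law),
               "span")
})

test_that("a solid block reproduces the tissue modulus exactly", {
  law <- default_law()
  r <- simulate_compression(solid_block(c(8, 8, 8)), law, schedule = 1,
                            policy = tight_policy(1e-10))
  expect_equal(r$stress, 150, tolerance = 1e-9)       # E * eps
  expect_equal(r$stiffness, 15000, tolerance = 1e-9)
  # linearity in the applied strain
  r2 <- simulate_compression(solid_block(c(8, 8, 8)), law, strain = 0.02,
                             schedule = 1, policy = tight_policy(1e-10))
  expect_equal(r2$stress, 2 * r$stress, tolerance = 1e-8)
})

test_that("series springs: layered composite matches the harmonic mean", {
  law0 <- material_law(15000, 0)            # nu = 0: layers decouple laterally
  lay <- layered_block(c(8, 8, 8), c(1, 0.5))
  r <- simulate_compression(lay, law0, schedule = 1,
                            policy = tight_policy(1e-10))
  expect_equal(r$stiffness, 2 * 15000 * 7500 / (15000 + 7500),
               tolerance = 1e-8)
  one <- layered_block(c(6, 6, 6), 1)
  expect_equal(one$bvf, solid_block(c(6, 6, 6))$bvf)
})

test_that("grayscale stiffness is homogeneous in BVF", {
  m <- random_porous(c(10, 10, 10), 0.3, seed = 6)
  gam <- 0.4
  scaled <- voxel_model(gam * m$bvf, m$voxel_size)
  s1 <- solve_stiffness(m, tol = 1e-10)
  s2 <- solve_stiffness(scaled, tol = 1e-10)
  expect_equal(s2, gam * s1, tolerance = 1e-8)
})

test_that("strain-energy map balances the external work", {
  law <- default_law()
  m <- random_porous(c(10, 10, 10), 0.3, seed = 8)
  bcs <- uniaxial_compression_bcs(m, law)
  sys <- build_system(m, law)
  sol <- pcg_solve(sys$op, sys$B, policy = tight_policy(1e-11))
  full <- full_displacement(sys$op, sol$u)
  emap <- strain_energy_map(sys$op, full, sys$model)
  expect_true(all(emap >= 0))
  expect_equal(dim(emap), sys$model$dims)
  expect_true(all(emap[sys$model$bvf == 0] == 0))
  # external work 0.5 sum(reaction x prescribed displacement)
  forces <- total_vertex_forces(sys$op, full)
  dm <- sys$dm
  constrained <- which(!is.na(dm$var_id) & dm$var_id == 0L)
  work <- 0.5 * sum(forces[constrained] * dm$bc_value[constrained])
  expect_equal(sum(emap), work, tolerance = 1e-6)
  expect_equal(strain_energy_map(sys$op, 0 * full, sys$model),
               array(0, sys$model$dims))
})

test_that("stiffness is invariant to 90-degree rotation about the load axis", {
  m <- random_porous(c(12, 12, 12), 0.25, seed = 12)
  rot <- voxel_model(aperm(m$bvf[, dim(m$bvf)[2]:1, ], c(2, 1, 3)),
                     m$voxel_size)
  expect_equal(solve_stiffness(rot, tol = 1e-10),
               solve_stiffness(m, tol = 1e-10), tolerance = 1e-8)
})

test_that("removing material never increases apparent stiffness", {
  m <- random_porous(c(12, 12, 12), 0.3, seed = 21)
  base <- solve_stiffness(m, tol = 1e-10)
  for (s in 1:3) {
    weaker <- withr::with_seed(s, {
      bvf <- m$bvf
      act <- which(bvf > 0)
      hit <- sample(act, length(act) %/% 5)
      bvf[hit] <- bvf[hit] * runif(length(hit))
      voxel_model(bvf, m$voxel_size)
    })
    expect_lte(solve_stiffness(weaker, tol = 1e-10), base * (1 + 1e-6))
  }
})

test_that("both stress evaluation routes agree", {
  sys <- build_system(tiny_random_model(14))
  sol <- pcg_solve(sys$op, sys$B, policy = tight_policy(1e-11))
  mon <- microfe:::make_stress_monitor(sys$op, sys$bcs, sys$model)
  s_fast <- mon(sol$u, 0)
  s_full <- total_stress(sys$op, full_displacement(sys$op, sol$u),
                         sys$bcs, sys$model)
  expect_equal(s_fast, s_full, tolerance = 1e-12)
})

test_that("apparent stiffness guards against zero strain", {
  expect_equal(apparent_stiffness(150, 0.01), 15000)
  expect_error(apparent_stiffness(150, 0), "positive")
})
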