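test_that("downsampling block-averages BVF and scales the voxel size", {
  m <- random_porous(c(8, 8, 8), 0.3, seed = 1)
  expect_identical(downsample_model(m, 1), m)
  u <- voxel_model(array(0.37, c(8, 8, 8)), 0.05)
  d2 <- downsample_model(u, 2)
  expect_equal(d2$dims, c(4L, 4L, 4L))
  expect_equal(unique(as.vector(d2$bvf)), 0.37)
  expect_equal(d2$voxel_size, 0.1)

  alt <- array(0, c(2, 2, 2)); alt[c(1, 4, 6, 7)] <- 1   # 3D checkerboard
  expect_equal(as.vector(downsample_model(voxel_model(alt, 0.05), 2)$bvf), 0.5)

  # zero padding to a multiple of f adds only empty material
  m3 <- voxel_model(array(1, c(5, 5, 5)), 0.05)
  d4 <- downsample_model(m3, 4)
  expect_equal(d4$dims, c(2L, 2L, 2L))
  expect_equal(sum(d4$bvf) * 4^3, 125)                   # mass preserved
})

test_that("coarse boundary conditions reapply the same macroscopic strain", {
  law <- default_law()
  m <- solid_block(c(8, 8, 8))
  cm <- downsample_model(m, 2)
  b0 <- coarse_bcs(0, "z", cm, law)
  expect_true(all(b0$entries$value == 0))
  bf <- uniaxial_compression_bcs(m, law, 0.01, "z")
  bc <- coarse_bcs(0.01, "z", cm, law)
  # same physical specimen length, so the same prescribed face displacement
  expect_equal(min(bc$entries$value), min(bf$entries$value))
  expect_equal(min(bc$entries$value), -0.01 * 8 * 0.05)
  # permuting the axis permutes the spec
  by <- coarse_bcs(0.01, "y", cm, law)
  expect_equal(sort(unique(by$entries$d)), 2L)
  expect_equal(nrow(by$entries), nrow(bc$entries))
})

test_that("prolongation is exact for constant, affine and nested fields", {
  cm <- solid_block(c(4, 4, 4), 0.1)
  fm <- solid_block(c(8, 8, 8), 0.05)
  vc <- cm$dims + 1L
  uc <- array(0, c(3, vc))
  uc[1, , , ] <- 2.5; uc[2, , , ] <- -1; uc[3, , , ] <- 0.25
  uf <- prolong(uc, cm, fm)
  expect_lt(max(abs(uf[1, , , ] - 2.5)), 1e-12)
  expect_lt(max(abs(uf[3, , , ] - 0.25)), 1e-12)

  M <- matrix(c(0.1, 0.2, -0.3, 0, 0.5, 0.1, 0.7, -0.2, 0.4), 3, 3)
  cc <- c(1, -2, 0.5)
  affine <- function(vdims, h) {
    out <- array(0, c(3, vdims))
    for (i in seq_len(vdims[1])) for (j in seq_len(vdims[2]))
      for (k in seq_len(vdims[3])) {
        x <- c(i - 1, j - 1, k - 1) * h
        out[, i, j, k] <- M %*% x + cc
      }
    out
  }
  expect_equal(prolong(affine(cm$dims + 1L, 0.1), cm, fm),
               affine(fm$dims + 1L, 0.05), tolerance = 1e-12)

  # fine vertices coincident with coarse vertices take the coarse values
  uc2 <- array(withr::with_seed(5, rnorm(3 * prod(vc))), c(3, vc))
  uf2 <- prolong(uc2, cm, fm)
  expect_equal(uf2[, seq(1, 9, by = 2), seq(1, 9, by = 2), seq(1, 9, by = 2)],
               uc2, tolerance = 1e-14)
})

test_that("schedule validation rejects malformed factor lists", {
  expect_error(grid_schedule(c(4, 2)), "ending in 1")
  expect_error(grid_schedule(c(2, 4, 1)), "decreasing")
  expect_error(grid_schedule(c(4, 4, 1)), "decreasing")
  expect_error(grid_schedule(integer(0)), "decreasing|ending")
  expect_equal(grid_schedule(c(8, 4, 2, 1))$factors, c(8L, 4L, 2L, 1L))
})

test_that("a trivial schedule reproduces the plain solve", {
  m <- random_porous(c(12, 12, 12), 0.25, seed = 2)
  law <- default_law()
  bcs <- uniaxial_compression_bcs(m, law)
  pol <- tight_policy(1e-9)
  via_sched <- picg_solve(m, law, bcs, grid_schedule(1), pol)
  sys <- build_system(m, law)
  mon <- microfe:::make_stress_monitor(sys$op, sys$bcs, sys$model)
  plain <- pcg_solve(sys$op, sys$B, policy = pol, monitor = mon)
  expect_equal(via_sched$iterations[["1"]], plain$iterations)
  expect_equal(via_sched$stress,
               total_stress(sys$op, full_displacement(sys$op, plain$u),
                            sys$bcs, sys$model))
})

test_that("converged stiffness is independent of the grid schedule", {
  m <- random_porous(c(16, 16, 16), 0.2, seed = 1)
  s_plain <- solve_stiffness(m, schedule = 1, tol = 1e-8)
  s_picg <- solve_stiffness(m, schedule = c(4, 2, 1), tol = 1e-8)
  expect_lt(abs(s_picg - s_plain) / s_plain, 0.01)
})

test_that("warm starts reduce the fine-grid work and deeper budgets never hurt", {
  law <- default_law()
  fine_iters <- function(m, schedule, coarse_its = 200) {
    r <- simulate_compression(m, law, schedule = schedule,
                              coarse_iterations = coarse_its,
                              policy = tight_policy(1e-6))
    r$iterations[[length(r$iterations)]]
  }
  m <- random_porous(c(16, 16, 16), 0.2, seed = 4)
  expect_lt(fine_iters(m, c(4, 2, 1)), fine_iters(m, 1))
  # increasing the coarse budget (12 -> 200) does not increase fine-grid
  # iterations on average over seeds
  seeds <- 1:3
  it12 <- vapply(seeds, function(s)
    fine_iters(random_porous(c(16, 16, 16), 0.2, seed = s), c(4, 2, 1), 12), 0L)
  it200 <- vapply(seeds, function(s)
    fine_iters(random_porous(c(16, 16, 16), 0.2, seed = s), c(4, 2, 1), 200), 0L)
  expect_lte(mean(it200), mean(it12))
})
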