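test_that("PCG solves a hand-eliminated 2x2 system in two iterations", {
  A <- matrix(c(4, 1, 1, 3), 2, 2)
  sol <- pcg_solve(function(v) as.numeric(A %*% v), c(1, 2),
                   policy = stopping_policy("scaled-residual",
                                            tolerance = 1e-12))
  expect_equal(sol$u, c(1 / 11, 7 / 11), tolerance = 1e-10)
  expect_lte(sol$iterations, 2L)
  expect_true(sol$converged)
})

test_that("a warm start at the exact solution stops immediately", {
  sys <- build_system(tiny_random_model(2))
  exact <- pcg_solve(sys$op, sys$B, policy = tight_policy(1e-13))$u
  again <- pcg_solve(sys$op, sys$B, x0 = exact, policy = tight_policy(1e-8))
  expect_lte(again$iterations, 1L)
  expect_true(again$converged)
})

test_that("PCG matches a direct sparse solve on random porous fixtures", {
  # clamped ends: the reduced system is then strictly positive definite and
  # the direct solution unique, making the comparison well-posed
  for (s in c(1, 6, 13)) {
    sys <- build_system(tiny_random_model(s), end_condition = "clamped")
    ud <- as.numeric(Matrix::solve(assemble_stiffness(sys$op), sys$B))
    up <- pcg_solve(sys$op, sys$B, policy = tight_policy(1e-12))$u
    expect_lt(max(abs(up - ud)), 1e-8 * max(abs(ud)))
  }
})

test_that("A-norm error is non-increasing across CG iterations", {
  sys <- build_system(tiny_random_model(9), end_condition = "clamped")
  A <- dense_stiffness_oracle(sys$op)
  ustar <- solve(A, sys$B)
  errs <- c()
  mon_env <- new.env(); mon_env$us <- list()
  pcg_solve(sys$op, sys$B,
            policy = stopping_policy("fixed-iterations", iterations = 40),
            monitor = function(u, n) { mon_env$us[[n + 1]] <- u; 0 })
  for (u in mon_env$us) {
    e <- u - ustar
    errs <- c(errs, sqrt(sum(e * (A %*% e))))
  }
  expect_true(all(diff(errs) <= 1e-9 * errs[1]))
})

test_that("error estimator recovers an exact exponential decay", {
  n <- 0:120
  S <- 1 + exp(-0.1 * n)
  est <- estimate_relative_error(S, window = 30)
  fit <- attr(est, "fit")
  expect_equal(unname(fit["b"]), -0.1, tolerance = 1e-6)
  true_err <- exp(-0.1 * 120) / S[121]
  expect_gt(est / true_err, 0.9)
  expect_lt(est / true_err, 1.1)
})

test_that("estimator is unavailable for constant or rising series", {
  expect_true(is.na(estimate_relative_error(rep(2, 50), 30)))
  n <- 0:60
  expect_true(is.na(estimate_relative_error(1 + exp(0.05 * n), 30)))
  expect_true(is.na(estimate_relative_error(c(1, 2), 30)))
})

test_that("scaled residual behaves as a norm ratio", {
  B <- c(3, 4)
  expect_equal(scaled_residual(c(0, 0), B), 0)
  expect_equal(scaled_residual(B, B), 1)
  expect_error(scaled_residual(c(1, 1), c(0, 0)), "zero")
})

test_that("estimated-error stopping yields a recorded estimate and trace", {
  m <- random_porous(c(16, 16, 16), 0.18, seed = 3)
  r <- simulate_compression(m, default_law(), schedule = 1)
  expect_true(is.finite(r$estimated_error))
  expect_lte(r$estimated_error, 0.01)
  expect_gte(r$iterations[["1"]], 35L)          # window + 5 checks first
  expect_equal(nrow(r$trace$checks),
               r$iterations[["1"]] - 35L + 1L)
  expect_equal(length(r$trace$S), r$iterations[["1"]] + 1L)
})

test_that("z-partition balances free variables and nests outer in neighbours", {
  law <- default_law()
  m <- plate_rod_lattice(c(12, 12, 16), 4, 1)
  sys <- build_system(m, law)
  expect_error(partition_z(sys$dm, 17), "N_z")
  p1 <- partition_z(sys$dm, 1)
  expect_equal(p1$K, 1L)
  expect_length(p1$regions[[1]]$outer, 0L)
  expect_equal(unname(p1$regions[[1]]$inner), c(1L, sys$dm$n_free))

  for (K in c(2, 4)) {
    p <- partition_z(sys$dm, K)
    inner <- lapply(p$regions, function(r) r$inner[1]:r$inner[2])
    # inner sets partition all free variables
    expect_equal(sort(unlist(inner)), seq_len(sys$dm$n_free))
    # each outer range is inside a neighbour's inner range
    for (j in seq_len(K)) for (rg in p$regions[[j]]$outer) {
      owner <- if (rg[1] < p$regions[[j]]$inner[1]) j - 1L else j + 1L
      expect_true(rg[1] >= p$regions[[owner]]$inner[1] &&
                  rg[2] <= p$regions[[owner]]$inner[2])
    }
    # balance: inner sizes within one layer of N_v / K
    sizes <- vapply(inner, length, 0L)
    expect_lt(max(abs(sizes - sys$dm$n_free / K)), max(p$counts))
  }

  # uniform solid block cuts at the middle vertex layer
  blk <- solid_block(c(6, 6, 9))
  sysb <- build_system(blk, law)
  pb <- partition_z(sysb$dm, 2)
  expect_equal(pb$regions[[1]]$layers[2], 5L)   # vertex layers 1..10, cut at 5
})

test_that("partitioned PCG reproduces the serial iteration", {
  sys <- build_system(plate_rod_lattice(c(12, 12, 12), 4, 1))
  mon <- microfe:::make_stress_monitor(sys$op, sys$bcs, sys$model)
  pol <- stopping_policy("scaled-residual", tolerance = 1e-9)
  serial <- pcg_solve(sys$op, sys$B, policy = pol, monitor = mon)
  k1 <- partitioned_pcg(sys$op, sys$B, policy = pol,
                        partition = partition_z(sys$dm, 1), monitor = mon)
  expect_identical(serial$u, k1$u)               # bitwise for K = 1
  expect_identical(serial$trace$S, k1$trace$S)

  fixed <- stopping_policy("fixed-iterations", iterations = 50)
  s50 <- pcg_solve(sys$op, sys$B, policy = fixed, monitor = mon)
  for (K in c(2, 4)) {
    pk <- partitioned_pcg(sys$op, sys$B, policy = pol,
                          partition = partition_z(sys$dm, K), monitor = mon)
    expect_equal(pk$u, serial$u, tolerance = 1e-8)
    # per-iteration stress values agree to summation round-off for 50 iters
    p50 <- partitioned_pcg(sys$op, sys$B, policy = fixed,
                           partition = partition_z(sys$dm, K), monitor = mon)
    expect_equal(p50$trace$S, s50$trace$S, tolerance = 1e-12)
  }
})

test_that("final stiffness is independent of the partition count", {
  lat <- plate_rod_lattice(c(16, 16, 16), 4, 1)
  stiff <- vapply(c(1, 2, 4), function(K)
    solve_stiffness(lat, tol = 1e-9, partition_k = K), 0)
  expect_lt(max(abs(stiff - stiff[1])) / stiff[1], 1e-8)
})
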