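test_that("element modulus follows the material law", {
  m <- voxel_model(array(c(0, 1, 0.25, 0.6), c(4, 1, 1)), 0.05)
  law <- material_law(15000, 0.3)
  expect_equal(element_modulus(m, law, c(1, 1, 1)), 0)
  expect_equal(element_modulus(m, law, c(2, 1, 1)), 15000)
  expect_equal(element_modulus(m, law, c(3, 1, 1)), 3750)
  bin <- material_law(15000, 0.3, mode = "binary", binary_threshold = 0.5)
  expect_equal(element_modulus(m, bin, c(3, 1, 1)), 0)
  expect_equal(element_modulus(m, bin, c(4, 1, 1)), 15000)
  expect_equal(element_moduli(m, law), 15000 * m$bvf)
})

test_that("model and law constructors validate their invariants", {
  expect_error(voxel_model(array(1.5, c(2, 2, 2)), 0.05), "\\[0, 1\\]")
  expect_error(voxel_model(array(1, c(2, 2, 2)), c(0.05, 0.05, 0.1)),
               "anisotropic")
  expect_error(voxel_model(matrix(1, 2, 2), 0.05), "3D")
  expect_error(material_law(poisson_ratio = 0.5), "0.5")
  expect_error(material_law(tissue_modulus = -1), "positive")
})

test_that("active elements are the positive-modulus voxels", {
  law <- default_law()
  expect_equal(nrow(active_elements(solid_block(c(2, 2, 2)), law)), 8L)
  expect_error(active_elements(voxel_model(array(0, c(3, 3, 3)), 0.05), law),
               "no material")
  chk <- array(0, c(4, 4, 4))
  idx <- arrayInd(seq_len(64), c(4, 4, 4))
  chk[(rowSums(idx) %% 2) == 0] <- 1          # 3D checkerboard
  n_oracle <- sum(chk > 0)                    # enumeration
  expect_equal(nrow(active_elements(voxel_model(chk, 0.05), law)), n_oracle)
  expect_equal(n_oracle, 32L)
})

test_that("pruning removes exactly the unanchored components", {
  law <- default_law()
  solid <- solid_block(c(4, 4, 4))
  bcs <- uniaxial_compression_bcs(solid, law)
  expect_equal(prune_unanchored(solid, law, bcs, quiet = TRUE)$bvf, solid$bvf)

  # anchored walls plus a floating interior cube, separated by empty space
  bvf <- array(0, c(7, 7, 7))
  bvf[, , 1:2] <- 1; bvf[, , 6:7] <- 1; bvf[1, , ] <- 1   # spanning wall
  bvf[4:5, 4:5, 4] <- 1                                    # floating
  m <- voxel_model(bvf, 0.05)
  bcs <- uniaxial_compression_bcs(m, law)
  pruned <- prune_unanchored(m, law, bcs, quiet = TRUE)
  # cross-check against an igraph component labelling
  memb <- components_oracle(bvf > 0)
  lin <- which(bvf > 0)
  anchored_lab <- unique(memb[arrayInd(lin, dim(bvf))[, 3] %in% c(1, 7)])
  keep_lin <- lin[memb %in% anchored_lab]
  expect_equal(which(pruned$bvf > 0), sort(keep_lin))
  expect_equal(sum(pruned$bvf > 0), sum(bvf > 0) - 4)

  # two components both touching constrained faces are both kept
  two <- array(0, c(5, 5, 4))
  two[1:2, , ] <- 1; two[4:5, , ] <- 1
  m2 <- voxel_model(two, 0.05)
  bcs2 <- uniaxial_compression_bcs(m2, law)
  expect_equal(prune_unanchored(m2, law, bcs2, quiet = TRUE)$bvf, two)

  # idempotence
  expect_equal(prune_unanchored(pruned, law, bcs, quiet = TRUE)$bvf, pruned$bvf)
})

test_that("dof map numbers free variables densely in raster order", {
  law <- default_law()
  one <- solid_block(c(1, 1, 1))
  empty_bcs <- boundary_spec(data.frame(i = integer(), j = integer(),
                                        k = integer(), d = integer(),
                                        value = numeric()))
  dm1 <- build_dof_map(one, law, empty_bcs)
  expect_equal(dm1$n_free, 24L)          # 8 vertices x 3 directions
  expect_equal(dm1$n_elements, 1L)

  # 2x2x2 solid, top and bottom faces fully constrained in all 3 directions
  blk <- solid_block(c(2, 2, 2))
  verts <- expand.grid(i = 1:3, j = 1:3)
  ent <- do.call(rbind, lapply(c(1L, 3L), function(k)
    do.call(rbind, lapply(1:3, function(d)
      data.frame(i = verts$i, j = verts$j, k = k, d = d, value = 0)))))
  dm2 <- build_dof_map(blk, law, boundary_spec(ent))
  expect_equal(dm2$n_free, 81L - 2L * 9L * 3L)  # 27

  # solid-model bookkeeping: free + constrained = all vertex dofs
  expect_equal(dm2$n_free + nrow(ent), 3L * 27L)

  # round trip: every id maps back to a slot holding that id
  lk <- dof_lookup(dm2, seq_len(dm2$n_free))
  back <- mapply(function(i, j, k, d) dm2$var_id[d, i, j, k],
                 lk$i, lk$j, lk$k, lk$d)
  expect_equal(back, seq_len(dm2$n_free))

  # ordering: direction innermost, then x, then y, then z
  ord <- order(lk$k, lk$j, lk$i, lk$d)
  expect_equal(ord, seq_len(dm2$n_free))
})

test_that("variables per element stay near the empirical ratio of 4", {
  law <- default_law()
  # trabecular-scale features span several voxels, as in imaged bone
  for (m in list(plate_rod_lattice(c(16, 16, 16), 8, 4),
                 plate_rod_lattice(c(24, 24, 24), 6, 3),
                 plate_rod_lattice(c(20, 20, 20), 5, 3))) {
    sys <- build_system(m, law)
    r <- sys$dm$n_free / sys$dm$n_elements
    expect_gt(r, 3); expect_lt(r, 4.5)
  }
})

test_that("prescribed entries must lie on active-element vertices", {
  law <- default_law()
  m <- voxel_model(array(c(1, rep(0, 26)), c(3, 3, 3)), 0.05)
  bad <- boundary_spec(data.frame(i = 4, j = 4, k = 4, d = 1, value = 0))
  expect_error(build_dof_map(m, law, bad), "active")
})
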