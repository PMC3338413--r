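#' Synthetic structures
#'
#' Deterministic and seeded generators of voxel models that exercise every
#' solver path without external image data: solid blocks, layered composites,
#' periodic plate/rod lattices emulating the interconnected plates and struts
#' of trabecular bone, seeded random porous networks, and a resorption-like
#' degradation operator. All generators are pure functions of their arguments
#' (seeded ones restore the RNG state).
#'
#' @param dims integer vector `(nx, ny, nz)` of voxel counts.
#' @param voxel_size voxel edge length in mm (default 0.05 mm, a typical
#'   high-resolution CT scale).
#' @return a [voxel_model()].
#' @name synthetic_structures
NULL

#' @describeIn synthetic_structures BVF 1 everywhere.
#' @export
solid_block <- function(dims, voxel_size = 0.05) {
  voxel_model(array(1, dims), voxel_size)
}

#' @describeIn synthetic_structures equal-thickness stacks of constant BVF
#'   normal to `axis`; `fractions` gives one BVF per layer and the layer count
#'   must divide the axis dimension so boundaries fall on voxel planes.
#' @param fractions BVF value per layer.
#' @param axis stacking axis.
#' @export
layered_block <- function(dims, fractions, voxel_size = 0.05, axis = "z") {
  ax <- axis_index(axis)
  nl <- length(fractions)
  if (dims[ax] %% nl != 0L)
    stop("number of layers must divide the axis dimension")
  thick <- dims[ax] %/% nl
  layer_of <- rep(seq_len(nl), each = thick)
  bvf <- array(0, dims)
  idx <- slice.index(bvf, ax)
  bvf[] <- fractions[layer_of[idx]]
  voxel_model(bvf, voxel_size)
}

#' @describeIn synthetic_structures periodic plates normal to z and rods along
#'   z: voxel `(i, j, k)` is solid when `(k - 1) %% spacing < thickness`
#'   (plate) or both `(i - 1)` and `(j - 1)` satisfy the same condition (rod).
#'   Rods run the full height, so the lattice always spans the loaded faces
#'   and is one connected component.
#' @param spacing lattice period in voxels.
#' @param thickness plate/rod thickness in voxels (`< spacing`).
#' @export
plate_rod_lattice <- function(dims, spacing = 6L, thickness = 1L,
                              voxel_size = 0.05) {
  spacing <- as.integer(spacing); thickness <- as.integer(thickness)
  stopifnot(spacing >= 2L, thickness >= 1L, thickness < spacing)
  on_grid <- function(n) ((seq_len(n) - 1L) %% spacing) < thickness
  px <- on_grid(dims[1]); py <- on_grid(dims[2]); pz <- on_grid(dims[3])
  rod <- outer(outer(px, py, "&"), rep(TRUE, dims[3]), "&")
  plate <- outer(outer(rep(TRUE, dims[1]), rep(TRUE, dims[2]), "&"), pz, "&")
  voxel_model(array(as.numeric(rod | plate), dims), voxel_size)
}

# iterated neighbour smoothing with adjustable axial weight; periodic edges
smooth_noise <- function(noise, passes, axial_weight, axis) {
  shift <- function(a, ax, by) {
    n <- dim(a)[ax]
    idx <- ((seq_len(n) - 1L + by) %% n) + 1L
    switch(ax, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
           a[, , idx, drop = FALSE])
  }
  w <- c(1, 1, 1); w[axis] <- axial_weight
  for (p in seq_len(passes)) {
    acc <- noise
    tot <- 1
    for (ax in 1:3) {
      if (dim(noise)[ax] < 2L) next
      for (by in c(-1L, 1L)) {
        acc <- acc + w[ax] * shift(noise, ax, by)
        tot <- tot + w[ax]
      }
    }
    noise <- acc / tot
  }
  noise
}

#' @describeIn synthetic_structures thresholded smoothed Gaussian noise.
#'   Trabeculae align with habitual loading, so the field mixes 3D noise with
#'   an axially invariant 2D component (`axial_mix`) that forms load-bearing
#'   vertical ridges; the threshold is searched so that, after keeping only
#'   the components spanning both loaded faces, the achieved BVF is within
#'   `+/- 0.01` of `target_bvf`. Binary output (BVF 0/1). Same seed, same
#'   model.
#' @param target_bvf target bone-volume fraction.
#' @param smoothing number of neighbour-averaging passes applied to the noise.
#' @param axial_mix weight in `[0, 1)` of the axially invariant component.
#' @param seed RNG seed.
#' @export
random_porous <- function(dims, target_bvf = 0.12, smoothing = 3L,
                          axial_mix = 0.5, seed = 1L, voxel_size = 0.05,
                          axis = "z") {
  stopifnot(target_bvf > 0, target_bvf < 1, axial_mix >= 0, axial_mix < 1)
  ax <- axis_index(axis)
  field <- withr::with_seed(seed, {
    n3 <- smooth_noise(array(stats::rnorm(prod(dims)), dims), smoothing, 1, ax)
    cd <- dims; cd[ax] <- 1L
    n2 <- smooth_noise(array(stats::rnorm(prod(cd)), cd), smoothing, 1, ax)
    rep_idx <- rep(1L, dims[ax])
    n2 <- switch(ax, n2[rep_idx, , , drop = FALSE], n2[, rep_idx, , drop = FALSE],
                 n2[, , rep_idx, drop = FALSE])
    (1 - axial_mix) * n3 / stats::sd(n3) + axial_mix * n2 / stats::sd(n2)
  })
  spanning_bvf <- function(p) {
    thr <- stats::quantile(field, 1 - p, names = FALSE)
    act <- field >= thr
    lab <- label_components_cpp(as.logical(act), as.integer(dims))
    dim(lab) <- dims
    lo <- switch(ax, lab[1, , ], lab[, 1, ], lab[, , 1])
    hi <- switch(ax, lab[dims[1], , ], lab[, dims[2], ], lab[, , dims[3]])
    span <- intersect(setdiff(unique(as.vector(lo)), 0L),
                      setdiff(unique(as.vector(hi)), 0L))
    keep <- array(lab %in% span, dims)
    list(bvf = mean(keep), mask = keep)
  }
  # the post-selection BVF is monotone in the kept fraction p (growing the
  # active set can only grow or merge spanning components), so bisect
  lo <- 1e-4
  hi <- min(0.999, max(2 * target_bvf, target_bvf + 0.2))
  best <- spanning_bvf(hi)
  while (best$bvf < target_bvf && hi < 0.999) {
    hi <- min(0.999, hi + 0.2)
    best <- spanning_bvf(hi)
  }
  for (it in 1:40) {
    if (abs(best$bvf - target_bvf) <= 0.01) break
    mid <- (lo + hi) / 2
    res <- spanning_bvf(mid)
    if (res$bvf < target_bvf) lo <- mid else hi <- mid
    if (abs(res$bvf - target_bvf) < abs(best$bvf - target_bvf)) best <- res
  }
  if (abs(best$bvf - target_bvf) > 0.01)
    stop(sprintf(paste("random_porous: could not reach BVF %.3f +/- 0.01",
                       "(best %.3f); increase smoothing or target"),
                 target_bvf, best$bvf))
  voxel_model(array(as.numeric(best$mask), dims), voxel_size)
}

#' @describeIn synthetic_structures randomly zeroes a fraction of the surface
#'   voxels (active voxels with an inactive or out-of-volume 6-neighbour),
#'   emulating resorption for longitudinal/monotonicity studies.
#' @param model model to degrade.
#' @param removal_fraction fraction of surface voxels to remove, in `[0, 1]`.
#' @export
degrade <- function(model, removal_fraction, seed = 1L) {
  stopifnot(removal_fraction >= 0, removal_fraction <= 1)
  if (removal_fraction == 0) return(model)
  act <- model$bvf > 0
  d <- model$dims
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- act
  exposed <- !(pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
               pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
               pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
               pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
               pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
               pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)])
  surface <- which(act & exposed)
  n_rm <- floor(removal_fraction * length(surface))
  if (n_rm == 0L) return(model)
  rm_idx <- withr::with_seed(seed, sample(surface, n_rm))
  bvf <- model$bvf
  bvf[rm_idx] <- 0
  voxel_model(bvf, model$voxel_size)
}
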