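#' Voxel structural model
#'
#' Wraps a 3D bone-volume-fraction (BVF) grid as the structural model used by
#' the solver: one image voxel becomes one hexahedral (brick) element. Vertex
#' `(i, j, k)` (1-based) is the lower corner of voxel `(i, j, k)` and sits at
#' physical coordinate `(i - 1, j - 1, k - 1) * voxel_size`.
#'
#' @param bvf 3D numeric array of bone-volume fractions in `[0, 1]`
#'   (dimensionless).
#' @param voxel_size isotropic voxel edge length in mm (a scalar, or a length-3
#'   vector whose entries must be equal; anisotropic spacing is rejected
#'   because the element kernel assumes a cube).
#' @return An object of class `voxel_model` with fields `bvf`, `dims`,
#'   `voxel_size`.
#' @export
voxel_model <- function(bvf, voxel_size) {
  if (is.null(dim(bvf)) || length(dim(bvf)) != 3L)
    stop("`bvf` must be a 3D array")
  storage.mode(bvf) <- "double"
  if (anyNA(bvf) || any(!is.finite(bvf)))
    stop("`bvf` contains non-finite values")
  if (any(bvf < 0 | bvf > 1))
    stop("BVF values must lie in [0, 1]")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 3L) {
    if (diff(range(voxel_size)) > 1e-8 * max(voxel_size))
      stop("anisotropic voxel spacing is not supported (the element kernel assumes cubic voxels)")
    voxel_size <- voxel_size[1L]
  }
  if (length(voxel_size) != 1L || !is.finite(voxel_size) || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number")
  structure(list(bvf = bvf, dims = dim(bvf), voxel_size = voxel_size),
            class = "voxel_model")
}

#' @export
print.voxel_model <- function(x, ...) {
  cat(sprintf("<voxel_model> %d x %d x %d voxels, %.4g mm, mean BVF %.4f\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size, mean(x$bvf)))
  invisible(x)
}

#' Tissue material law
#'
#' Maps voxel BVF to an element Young's modulus. In `grayscale` mode the
#' modulus scales linearly with BVF (`tissue_modulus * BVF`); in `binary` mode
#' a voxel is either full-modulus bone (BVF at or above `binary_threshold`) or
#' empty. Poisson's ratio is shared by all elements.
#'
#' @param tissue_modulus Young's modulus at BVF = 1, in MPa. Default 15000 MPa,
#'   a common trabecular tissue value; override to match your calibration.
#' @param poisson_ratio Poisson's ratio, in `[0, 0.5)`. Default 0.3.
#' @param mode `"grayscale"` (default) or `"binary"`.
#' @param binary_threshold BVF cutoff used in binary mode, in `(0, 1]`.
#' @return An object of class `material_law`.
#' @export
material_law <- function(tissue_modulus = 15000, poisson_ratio = 0.3,
                         mode = c("grayscale", "binary"),
                         binary_threshold = 0.5) {
  mode <- match.arg(mode)
  if (!is.finite(tissue_modulus) || tissue_modulus <= 0)
    stop("`tissue_modulus` must be positive")
  if (!is.finite(poisson_ratio) || poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("`poisson_ratio` must lie in [0, 0.5)")
  if (!is.finite(binary_threshold) || binary_threshold <= 0 || binary_threshold > 1)
    stop("`binary_threshold` must lie in (0, 1]")
  structure(list(tissue_modulus = tissue_modulus, poisson_ratio = poisson_ratio,
                 mode = mode, binary_threshold = binary_threshold),
            class = "material_law")
}

#' Per-element Young's moduli
#'
#' @param model a [voxel_model()].
#' @param law a [material_law()].
#' @return `element_moduli()`: a 3D array of element moduli (MPa), zero where
#'   there is no material. `element_modulus()`: the modulus of one voxel.
#' @export
element_moduli <- function(model, law) {
  if (law$mode == "grayscale") {
    law$tissue_modulus * model$bvf
  } else {
    law$tissue_modulus * (model$bvf >= law$binary_threshold)
  }
}

#' @param element integer vector `(i, j, k)` (1-based voxel index).
#' @rdname element_moduli
#' @export
element_modulus <- function(model, law, element) {
  element <- as.integer(element)
  stopifnot(length(element) == 3L, all(element >= 1L), all(element <= model$dims))
  bvf <- model$bvf[element[1], element[2], element[3]]
  if (law$mode == "grayscale") law$tissue_modulus * bvf
  else law$tissue_modulus * (bvf >= law$binary_threshold)
}

#' Active elements of a model
#'
#' Voxels whose element modulus is positive; each such voxel carries one
#' hexahedral element.
#'
#' @inheritParams element_moduli
#' @return Integer matrix with one row per active element and columns
#'   `i, j, k` (1-based voxel indices), with the linear voxel indices as
#'   attribute `"linear"`. Raster (array) order.
#' @export
active_elements <- function(model, law) {
  act <- element_moduli(model, law) > 0
  lin <- which(act)
  if (length(lin) == 0L) stop("no material: every element modulus is zero")
  ind <- arrayInd(lin, model$dims)
  colnames(ind) <- c("i", "j", "k")
  attr(ind, "linear") <- lin
  ind
}

# logical (Vx,Vy,Vz) mask of vertices belonging to at least one active element
vertex_activity <- function(active) {
  d <- dim(active)
  va <- array(FALSE, d + 1L)
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    ix <- (1L + di):(d[1] + di); iy <- (1L + dj):(d[2] + dj); iz <- (1L + dk):(d[3] + dk)
    va[ix, iy, iz] <- va[ix, iy, iz] | active
  }
  va
}

# linear index of vertex (i,j,k) (1-based) in a (Vx,Vy,Vz) vertex grid
vertex_linear <- function(i, j, k, vdims) {
  (i - 1) + vdims[1] * ((j - 1) + vdims[2] * (k - 1)) + 1
}

#' Remove unanchored connected components
#'
#' Connected components of active elements (vertex-sharing, i.e. 26-neighbour
#' connectivity) that contain no constrained vertex cannot resist rigid motion
#' and would make the system singular. This sets their BVF to zero.
#'
#' @inheritParams element_moduli
#' @param bcs a [boundary_spec()] whose constrained vertices define anchoring.
#' @param quiet suppress the message reporting how many voxels were removed.
#' @return A pruned [voxel_model()].
#' @export
prune_unanchored <- function(model, law, bcs, quiet = FALSE) {
  stopifnot(inherits(bcs, "boundary_spec"))
  if (nrow(bcs$entries) == 0L) stop("boundary specification is empty")
  act <- element_moduli(model, law) > 0
  if (!any(act)) stop("no material: every element modulus is zero")
  lab <- label_components_cpp(as.logical(act), as.integer(model$dims))
  dim(lab) <- model$dims
  # a component is anchored if any of its elements touches a constrained vertex
  keep <- logical(max(lab))
  ent <- bcs$entries
  d <- model$dims
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    # voxel (i-di, j-dj, k-dk) has vertex (i,j,k) as a corner
    vi <- ent$i - di; vj <- ent$j - dj; vk <- ent$k - dk
    ok <- vi >= 1 & vi <= d[1] & vj >= 1 & vj <= d[2] & vk >= 1 & vk <= d[3]
    if (any(ok)) {
      l <- lab[cbind(vi[ok], vj[ok], vk[ok])]
      keep[l[l > 0]] <- TRUE
    }
  }
  if (!any(keep)) stop("structure not anchored: no component touches a constrained vertex")
  drop <- lab > 0 & !keep[pmax(lab, 1L)]
  n_removed <- sum(drop)
  if (n_removed > 0L) {
    bvf <- model$bvf
    bvf[drop] <- 0
    model <- voxel_model(bvf, model$voxel_size)
  }
  if (!quiet && n_removed > 0L)
    message(sprintf("pruned %d unanchored voxel(s) in %d floating component(s)",
                    n_removed, sum(!keep)))
  model
}

#' Build the free-variable numbering
#'
#' Assigns dense ids `1..N_v` to every unconstrained (vertex, direction) pair
#' of the active-element vertices, traversing vertices in raster order (z
#' slowest, then y, then x) with direction innermost, and records the
#' prescribed displacement for constrained pairs.
#'
#' @inheritParams prune_unanchored
#' @return An object of class `dof_map` with fields `var_id` (integer array
#'   `3 x Vx x Vy x Vz`; id of a free dof, 0 at a prescribed dof, `NA` at
#'   vertices of no active element), `bc_value` (prescribed displacements, mm),
#'   `free_pos` (linear positions of the free dofs, ascending in id),
#'   `n_free`, `n_elements`, `elem_lin` (linear indices of active voxels),
#'   `dims`, `vdims`, `voxel_size`.
#' @export
build_dof_map <- function(model, law, bcs) {
  stopifnot(inherits(bcs, "boundary_spec"))
  mods <- element_moduli(model, law)
  act <- mods > 0
  if (!any(act)) stop("no material: every element modulus is zero")
  d <- model$dims
  vdims <- d + 1L
  va <- vertex_activity(act)

  vid <- array(NA_integer_, c(3L, vdims))
  # d is the fastest index of var_id, so rep(each = 3) follows array order
  vid[rep(as.vector(va), each = 3L)] <- 0L

  ent <- bcs$entries
  bcv <- array(0, c(3L, vdims))
  if (nrow(ent) > 0L) {
    vlin <- vertex_linear(ent$i, ent$j, ent$k, vdims)
    pos <- (vlin - 1L) * 3L + ent$d
    if (anyDuplicated(pos)) stop("duplicate (vertex, direction) pairs in boundary spec")
    if (anyNA(vid[pos]))
      stop("prescribed entries must lie on vertices of active elements")
    vid[pos] <- -1L
    bcv[pos] <- ent$value
  }
  free_pos <- which(!is.na(vid) & vid == 0L)
  vid[free_pos] <- seq_along(free_pos)
  vid[!is.na(vid) & vid == -1L] <- 0L

  structure(list(var_id = vid, bc_value = bcv, free_pos = free_pos,
                 n_free = length(free_pos), n_elements = sum(act),
                 elem_lin = which(act), dims = d, vdims = vdims,
                 voxel_size = model$voxel_size),
            class = "dof_map")
}

#' @export
print.dof_map <- function(x, ...) {
  cat(sprintf("<dof_map> %d free variables, %d elements (N_v/N_e = %.2f)\n",
              x$n_free, x$n_elements, x$n_free / x$n_elements))
  invisible(x)
}

#' Reverse lookup of free-variable ids
#'
#' @param dofmap a [build_dof_map()] result.
#' @param ids integer vector of free-variable ids (1-based).
#' @return data frame with columns `i, j, k` (vertex, 1-based) and `d`
#'   (direction, 1 = x, 2 = y, 3 = z).
#' @export
dof_lookup <- function(dofmap, ids) {
  ids <- as.integer(ids)
  stopifnot(all(ids >= 1L), all(ids <= dofmap$n_free))
  ind <- arrayInd(dofmap$free_pos[ids], c(3L, dofmap$vdims))
  data.frame(i = ind[, 2], j = ind[, 3], k = ind[, 4], d = ind[, 1])
}
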