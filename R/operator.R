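#' Matrix-free element-by-element stiffness operator
#'
#' Builds the macroscopic stiffness operator `A` acting on the free variables
#' of a dof map, without ever assembling the global matrix: each application
#' gathers the 24 local displacements of every active element, multiplies by
#' the shared modulus-scaled kernel, and scatter-adds the resulting forces.
#' Prescribed dofs are eliminated, so `A` acts on the reduced system of
#' `n_free` equations.
#'
#' @inheritParams prune_unanchored
#' @param dofmap a [build_dof_map()] built from the same model, law and
#'   boundary spec.
#' @return An object of class `ebe_operator` holding the kernel, per-element
#'   moduli and the per-element global dof index tables.
#' @export
ebe_operator <- function(model, law, dofmap) {
  stopifnot(inherits(dofmap, "dof_map"))
  mods <- element_moduli(model, law)
  kernel <- unit_kernel(law$poisson_ratio, model$voxel_size)
  vdims <- dofmap$vdims
  elem_lin <- dofmap$elem_lin
  ai <- arrayInd(elem_lin, dofmap$dims)
  ne <- nrow(ai)

  gdof <- matrix(0L, 24L, ne)
  for (lv in 0:7) {
    di <- lv %% 2L; dj <- (lv %/% 2L) %% 2L; dk <- lv %/% 4L
    vlin0 <- (ai[, 1] - 1L + di) +
      vdims[1] * ((ai[, 2] - 1L + dj) + vdims[2] * (ai[, 3] - 1L + dk))
    for (dd in 1:3) gdof[3L * lv + dd, ] <- 3L * vlin0 + dd
  }
  dof <- matrix(dofmap$var_id[gdof], 24L, ne)
  if (anyNA(dof)) stop("internal error: active element touches an inactive vertex")
  val <- matrix(dofmap$bc_value[gdof], 24L, ne)

  structure(list(kernel = kernel, dofs = dof, gdofs = gdof, vals = val,
                 moduli = as.numeric(mods[elem_lin]), dofmap = dofmap,
                 dims = dofmap$dims, vdims = vdims,
                 voxel_size = model$voxel_size, n_free = dofmap$n_free),
            class = "ebe_operator")
}

#' @export
print.ebe_operator <- function(x, ...) {
  cat(sprintf("<ebe_operator> %d free variables, %d elements (matrix-free)\n",
              x$n_free, ncol(x$dofs)))
  invisible(x)
}

#' Apply the stiffness operator
#'
#' Computes `A %*% u` element by element.
#'
#' @param op an [ebe_operator()].
#' @param u numeric vector of length `n_free`.
#' @return numeric vector `A u` of length `n_free`.
#' @export
ebe_apply <- function(op, u) {
  if (length(u) != op$n_free) stop("length mismatch: expected n_free displacements")
  ebe_apply_cpp(op$kernel, op$dofs, op$moduli, as.numeric(u), op$n_free)
}

#' Right-hand side from boundary conditions
#'
#' `B = -(forces induced on the free dofs when the prescribed dofs take their
#' boundary values and the free dofs are zero)`; solving `A U = B` then yields
#' force equilibrium at every free dof with the prescribed displacements in
#' place.
#'
#' @inheritParams ebe_apply
#' @param bcs optional [boundary_spec()]; if given, it is checked for
#'   consistency with the prescribed values stored in the operator's dof map.
#' @return numeric vector of length `n_free`.
#' @export
rhs_from_bcs <- function(op, bcs = NULL) {
  if (!is.null(bcs)) {
    dm <- op$dofmap
    ent <- bcs$entries
    vlin <- vertex_linear(ent$i, ent$j, ent$k, dm$vdims)
    pos <- (vlin - 1L) * 3L + ent$d
    if (any(dm$var_id[pos] != 0L, na.rm = TRUE) ||
        any(abs(dm$bc_value[pos] - ent$value) > 0))
      stop("boundary spec does not match the operator's dof map")
  }
  ebe_rhs_cpp(op$kernel, op$dofs, op$vals, op$moduli, op$n_free)
}

#' Jacobi preconditioner diagonal
#'
#' Accumulates the diagonal of the modulus-scaled kernel into global positions
#' and returns the elementwise inverse (the application-ready form).
#'
#' @inheritParams ebe_apply
#' @return numeric vector of length `n_free`, the inverse diagonal of `A`.
#' @export
jacobi_diagonal <- function(op) {
  d <- ebe_diag_cpp(diag(op$kernel), op$dofs, op$moduli, op$n_free)
  if (any(d <= 0))
    stop("zero or negative stiffness diagonal: structure contains an unpruned floating dof")
  1 / d
}

#' Expand free-variable displacements to the full vertex grid
#'
#' @inheritParams ebe_apply
#' @param u displacements at the free dofs (mm).
#' @return numeric array `3 x Vx x Vy x Vz` with prescribed values filled in
#'   and zeros at vertices of no active element.
#' @export
full_displacement <- function(op, u) {
  dm <- op$dofmap
  stopifnot(length(u) == dm$n_free)
  full <- dm$bc_value        # prescribed values; zero elsewhere
  full[dm$free_pos] <- u
  full
}

#' Total vertex forces
#'
#' Sums, at every vertex and direction, the forces induced by the elements
#' containing that vertex. At equilibrium these vanish at free dofs and equal
#' the reaction forces at constrained dofs.
#'
#' @inheritParams ebe_apply
#' @param full_u full displacement array (`3 x Vx x Vy x Vz`, mm), e.g. from
#'   [full_displacement()].
#' @return numeric array `3 x Vx x Vy x Vz` of forces (N).
#' @export
total_vertex_forces <- function(op, full_u) {
  n_total <- 3L * prod(op$vdims)
  if (length(full_u) != n_total) stop("full displacement field has wrong length")
  f <- ebe_forces_full_cpp(op$kernel, op$gdofs, op$moduli, as.numeric(full_u), n_total)
  array(f, c(3L, op$vdims))
}

#' Assemble the sparse stiffness matrix (test oracle)
#'
#' Explicitly assembles `A` as a sparse matrix. This is the memory-hungry
#' representation the element-by-element operator avoids; it exists as an
#' independent cross-check for small models, not as a solver path.
#'
#' @inheritParams ebe_apply
#' @return a symmetric `dgCMatrix` of dimension `n_free x n_free`.
#' @export
assemble_stiffness <- function(op) {
  ne <- ncol(op$dofs)
  K <- op$kernel
  ii <- vector("list", ne); jj <- vector("list", ne); xx <- vector("list", ne)
  for (e in seq_len(ne)) {
    idx <- op$dofs[, e]
    f <- which(idx > 0L)
    ids <- idx[f]
    ii[[e]] <- rep(ids, times = length(f))
    jj[[e]] <- rep(ids, each = length(f))
    xx[[e]] <- as.vector(K[f, f, drop = FALSE]) * op$moduli[e]
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(op$n_free, op$n_free))
}
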