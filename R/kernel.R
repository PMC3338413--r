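#' Isotropic elasticity matrix
#'
#' The 6x6 Hooke matrix in Voigt order (xx, yy, zz, yz, xz, xy) with
#' engineering shear strains: normal diagonal `E(1-nu)/((1+nu)(1-2nu))`,
#' normal off-diagonal `E nu/((1+nu)(1-2nu))`, shear diagonal `E/(2(1+nu))`.
#'
#' @param E Young's modulus (MPa), `E >= 0`.
#' @param nu Poisson's ratio in `[0, 0.5)`.
#' @return 6x6 symmetric matrix (MPa).
#' @export
isotropic_elasticity <- function(E, nu) {
  if (!is.finite(E) || E < 0) stop("`E` must be nonnegative")
  if (!is.finite(nu) || nu < 0 || nu >= 0.5)
    stop("`nu` must lie in [0, 0.5): the material becomes incompressible at 0.5")
  C <- matrix(0, 6, 6)
  fac <- E / ((1 + nu) * (1 - 2 * nu))
  C[1:3, 1:3] <- fac * nu
  diag(C)[1:3] <- fac * (1 - nu)
  diag(C)[4:6] <- E / (2 * (1 + nu))
  C
}

# strain-displacement matrix (6 x 24) of the trilinear hex at natural
# coordinates (xi, eta, zeta) in [-1,1]^3 for edge length h.
# Local node order: binary over (i, j, k) with i fastest; direction innermost.
hex_b_matrix <- function(xi, eta, zeta, h) {
  sg <- hex_node_signs()
  B <- matrix(0, 6, 24)
  for (a in 1:8) {
    sx <- sg[a, 1]; sy <- sg[a, 2]; sz <- sg[a, 3]
    # dN/dx = dN/dxi * 2/h etc.
    dNx <- sx * (1 + sy * eta) * (1 + sz * zeta) / 8 * 2 / h
    dNy <- sy * (1 + sx * xi) * (1 + sz * zeta) / 8 * 2 / h
    dNz <- sz * (1 + sx * xi) * (1 + sy * eta) / 8 * 2 / h
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- dNx
    B[2, c0 + 2] <- dNy
    B[3, c0 + 3] <- dNz
    B[4, c0 + 2] <- dNz; B[4, c0 + 3] <- dNy
    B[5, c0 + 1] <- dNz; B[5, c0 + 3] <- dNx
    B[6, c0 + 1] <- dNy; B[6, c0 + 2] <- dNx
  }
  B
}

hex_node_signs <- function() {
  lv <- 0:7
  cbind(2 * (lv %% 2) - 1, 2 * ((lv %/% 2) %% 2) - 1, 2 * (lv %/% 4) - 1)
}

.kernel_cache <- new.env(parent = emptyenv())

#' Unit-modulus hexahedral element stiffness kernel
#'
#' The 24x24 stiffness matrix of a cubic 8-node element with trilinear shape
#' functions and unit Young's modulus, `K = integral B' C B dV`, evaluated by
#' 2x2x2 Gauss quadrature (exact for this integrand). Every element of a model
#' shares this kernel up to its modulus scale factor, so it is computed once
#' per `(nu, edge)` and cached. Local dof order: 8 vertices in `(i, j, k)`
#' binary order (i fastest) with direction innermost.
#'
#' @param nu Poisson's ratio in `[0, 0.5)`.
#' @param edge element edge length in mm.
#' @return 24x24 symmetric positive semi-definite matrix with a 6-dimensional
#'   null space (the rigid-body modes), in MPa x mm units such that
#'   `modulus * K %*% u` gives nodal forces in N for u in mm.
#' @export
unit_kernel <- function(nu, edge = 1) {
  stopifnot(is.finite(edge), edge > 0)
  key <- sprintf("%.17g_%.17g", nu, edge)
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  C <- isotropic_elasticity(1, nu)
  g <- c(-1, 1) / sqrt(3)
  detJ <- (edge / 2)^3
  K <- matrix(0, 24, 24)
  for (zeta in g) for (eta in g) for (xi in g) {
    B <- hex_b_matrix(xi, eta, zeta, edge)
    K <- K + crossprod(B, C %*% B) * detJ
  }
  K <- (K + t(K)) / 2
  .kernel_cache[[key]] <- K
  K
}

#' Element nodal forces
#'
#' Forces induced at the 8 vertices of one element by its vertex
#' displacements: `modulus * K %*% u`.
#'
#' @param kernel a [unit_kernel()].
#' @param modulus element Young's modulus (MPa).
#' @param u_elem 24 local vertex displacements (mm), kernel dof order.
#' @return 24 nodal forces (N, for mm/MPa inputs).
#' @export
element_forces <- function(kernel, modulus, u_elem) {
  stopifnot(length(u_elem) == 24L)
  drop(modulus * (kernel %*% u_elem))
}

#' Element strain energy
#'
#' `0.5 * modulus * u' K u`; zero for rigid-body motion, nonnegative
#' otherwise.
#'
#' @inheritParams element_forces
#' @return energy in N mm.
#' @export
element_strain_energy <- function(kernel, modulus, u_elem) {
  stopifnot(length(u_elem) == 24L)
  0.5 * modulus * drop(crossprod(u_elem, kernel %*% u_elem))
}
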