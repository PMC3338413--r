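# independent oracles used to cross-check the implementation

# dense stiffness assembly straight from the kernel and the dof-map arrays,
# written independently of the package's ebe/assemble code paths
dense_stiffness_oracle <- function(op) {
  n <- op$n_free
  A <- matrix(0, n, n)
  K <- op$kernel
  for (e in seq_len(ncol(op$dofs))) {
    idx <- op$dofs[, e]
    f <- which(idx > 0L)
    A[idx[f], idx[f]] <- A[idx[f], idx[f]] + op$moduli[e] * K[f, f]
  }
  A
}

# element kernel by brute-force refined quadrature (4x4x4 Gauss-Legendre),
# independent of the package's 2x2x2 rule
kernel_oracle_4pt <- function(nu, edge) {
  gp <- c(-0.8611363115940526, -0.3399810435848563,
          0.3399810435848563, 0.8611363115940526)
  gw <- c(0.3478548451374538, 0.6521451548625461,
          0.6521451548625461, 0.3478548451374538)
  C <- isotropic_elasticity(1, nu)
  K <- matrix(0, 24, 24)
  detJ <- (edge / 2)^3
  for (a in 1:4) for (b in 1:4) for (c in 1:4) {
    B <- microfe:::hex_b_matrix(gp[a], gp[b], gp[c], edge)
    K <- K + gw[a] * gw[b] * gw[c] * detJ * crossprod(B, C %*% B)
  }
  K
}

# connected components of active voxels under 26-connectivity via igraph
components_oracle <- function(active) {
  d <- dim(active)
  lin <- which(active)
  if (length(lin) == 0) return(integer(0))
  idx <- arrayInd(lin, d)
  id_of <- array(0L, d)
  id_of[lin] <- seq_along(lin)
  edges <- list()
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    to <- id_of[nb[ok, , drop = FALSE]]
    from <- seq_along(lin)[ok]
    keep <- to > 0
    edges[[r]] <- cbind(from[keep], to[keep])
  }
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(unique(t(apply(em, 1, sort))),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(lin) - igraph::vcount(g)))
  igraph::components(g)$membership
}

# rigid-body displacement of the 24 local element dofs
rigid_mode <- function(kind, edge = 1) {
  sg <- microfe:::hex_node_signs()
  xyz <- (sg + 1) / 2 * edge
  u <- matrix(0, 8, 3)
  if (kind %in% 1:3) u[, kind] <- 1
  if (kind == 4) { u[, 1] <- -xyz[, 2]; u[, 2] <- xyz[, 1] }   # rotation about z
  if (kind == 5) { u[, 2] <- -xyz[, 3]; u[, 3] <- xyz[, 2] }   # rotation about x
  if (kind == 6) { u[, 1] <- xyz[, 3]; u[, 3] <- -xyz[, 1] }   # rotation about y
  as.vector(t(u))
}
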