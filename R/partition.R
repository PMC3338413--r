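#' Load-balanced slab partition along z
#'
#' Splits the free variables into `K` contiguous slabs of vertex layers
#' perpendicular to z, choosing the `K - 1` cut planes by cumulative quantiles
#' of the per-layer free-variable counts so every slab's inner share is within
#' one layer of `N_v / K`. Vertices on the layers adjacent to a cut are the
#' duplicated *outer* vertices of the neighbouring region.
#'
#' @param dofmap a [build_dof_map()] result.
#' @param K number of sub-regions, `1 <= K <= N_z` (the voxel count along z).
#' @return An object of class `z_partition`: a list with `K`, per-layer
#'   free-dof counts, and `regions`, each region holding its vertex-layer
#'   range, inner id range, outer id ranges, and active-element indices
#'   (columns of the operator tables).
#' @export
partition_z <- function(dofmap, K) {
  stopifnot(inherits(dofmap, "dof_map"))
  K <- as.integer(K)
  nz <- dofmap$dims[3]
  if (K < 1L || K > nz) stop("`K` must lie in [1, N_z]")
  vdims <- dofmap$vdims
  per_layer <- 3L * vdims[1] * vdims[2]
  layer <- ((dofmap$free_pos - 1L) %/% per_layer) + 1L   # vertex layer, 1..Vz
  counts <- tabulate(layer, nbins = vdims[3])
  cum <- c(0L, cumsum(counts))                           # cum[L + 1] = ids up to layer L
  nv <- dofmap$n_free
  target <- nv / K

  cuts <- integer(K - 1L)
  prev <- 0L
  for (j in seq_len(K - 1L)) {
    lo <- prev + 1L
    hi <- vdims[3] - (K - j)        # leave at least one layer per remaining region
    cand <- lo:hi
    cuts[j] <- cand[which.min(abs(cum[cand + 1L] - j * target))]
    prev <- cuts[j]
  }
  bounds <- c(0L, cuts, vdims[3])

  elem_k <- arrayInd(dofmap$elem_lin, dofmap$dims)[, 3]
  regions <- vector("list", K)
  for (j in seq_len(K)) {
    a <- bounds[j] + 1L; b <- bounds[j + 1L]             # vertex layers of slab j
    inner <- c(cum[a] + 1L, cum[b + 1L])                 # id range (may be empty)
    outer <- list()
    if (a > 1L) outer$below <- c(cum[a - 1L] + 1L, cum[a])
    if (b < vdims[3]) outer$above <- c(cum[b + 1L] + 1L, cum[b + 2L])
    elements <- which(elem_k >= a - 1L & elem_k <= b)    # voxels touching the slab
    regions[[j]] <- list(layers = c(a, b), inner = inner, outer = outer,
                         elements = elements)
  }
  structure(list(K = K, counts = counts, regions = regions, n_free = nv),
            class = "z_partition")
}

#' @export
print.z_partition <- function(x, ...) {
  sizes <- vapply(x$regions, function(r) max(r$inner[2] - r$inner[1] + 1L, 0L), 0L)
  cat(sprintf("<z_partition> K = %d, inner sizes: %s\n", x$K,
              paste(sizes, collapse = ", ")))
  invisible(x)
}

range_seq <- function(rg) if (rg[2] < rg[1]) integer(0) else rg[1]:rg[2]

#' Partitioned preconditioned conjugate gradients
#'
#' Executes the slab-partitioned reorganisation of the CG iteration: per
#' region, the operator is applied on inner vertices only (step 1a) and
#' partial inner products are accumulated over the inner index sets (1b);
#' partials are reduced globally in ascending region order (2); updates are
#' applied per region (3a); and the search direction is exchanged on the
#' duplicated outer vertices (3b). Reductions always sum in ascending region
#' index, so the iterates are identical to [pcg_solve()] up to
#' summation-order round-off — with `K = 1` they are bitwise identical. The
#' region count is a data-layout contract, not a concurrency requirement.
#'
#' @inheritParams pcg_solve
#' @param op an [ebe_operator()].
#' @param partition a [partition_z()] of the same dof map.
#' @return same structure as [pcg_solve()].
#' @export
partitioned_pcg <- function(op, B, x0 = NULL, policy = stopping_policy(),
                            partition, monitor = NULL) {
  stopifnot(inherits(op, "ebe_operator"), inherits(partition, "z_partition"))
  if (partition$n_free != op$n_free) stop("partition does not match the operator's dof map")
  n <- op$n_free
  if (length(B) != n) stop("right-hand side has wrong length")
  if (is.null(x0)) x0 <- numeric(n)
  if (policy$mode == "estimated-error" && is.null(monitor))
    stop("estimated-error stopping needs a stress monitor")
  K <- partition$K
  regs <- partition$regions
  prec <- jacobi_diagonal(op)
  maxit <- resolve_max_iterations(policy, n)

  sub_dofs <- lapply(regs, function(r) op$dofs[, r$elements, drop = FALSE])
  sub_mod <- lapply(regs, function(r) op$moduli[r$elements])
  I <- lapply(regs, function(r) range_seq(r$inner))
  IO <- lapply(regs, function(r) sort(c(range_seq(r$inner),
                                        unlist(lapply(r$outer, range_seq)))))
  apply_sub <- function(j, v) ebe_apply_cpp(op$kernel, sub_dofs[[j]], sub_mod[[j]], v, n)
  exchange <- function(vecs) {           # copy p on outer layers from the owner region
    for (j in seq_len(K)) {
      for (rg in regs[[j]]$outer) {
        ix <- range_seq(rg)
        owner <- if (rg[1] < regs[[j]]$inner[1]) j - 1L else j + 1L
        vecs[[j]][ix] <- vecs[[owner]][ix]
      }
    }
    vecs
  }
  assemble <- function(vecs) {
    out <- numeric(n)
    for (j in seq_len(K)) out[I[[j]]] <- vecs[[j]][I[[j]]]
    out
  }
  reduce <- function(partials) {         # ascending region order, fixed
    s <- 0
    for (j in seq_len(K)) s <- s + partials[j]
    s
  }

  tr <- new_trace(maxit)
  bnorm <- sqrt(reduce(vapply(seq_len(K), function(j) sum(B[I[[j]]]^2), 0)))
  if (bnorm == 0) {
    tr$n <- 0L
    tr$sres[1L] <- 0
    if (!is.null(monitor)) tr$S[1L] <- monitor(as.numeric(x0), 0L)
    return(list(u = as.numeric(x0), trace = finish_trace(tr), iterations = 0L,
                converged = TRUE, estimated_error = NA_real_))
  }

  x <- lapply(seq_len(K), function(j) as.numeric(x0))
  r <- vector("list", K); z <- vector("list", K); p <- vector("list", K)
  for (j in seq_len(K)) {
    q0 <- apply_sub(j, as.numeric(x0))
    rj <- numeric(n)
    rj[I[[j]]] <- B[I[[j]]] - q0[I[[j]]]
    r[[j]] <- rj
    zj <- numeric(n); zj[I[[j]]] <- prec[I[[j]]] * rj[I[[j]]]
    z[[j]] <- zj
    p[[j]] <- zj
  }
  p <- exchange(p)
  rz <- reduce(vapply(seq_len(K), function(j) sum(r[[j]][I[[j]]] * z[[j]][I[[j]]]), 0))
  tr$n <- 0L
  tr$sres[1L] <- sqrt(reduce(vapply(seq_len(K), function(j) sum(r[[j]][I[[j]]]^2), 0))) / bnorm
  if (!is.null(monitor)) tr$S[1L] <- monitor(assemble(x), 0L)

  converged <- tr$sres[1L] < 1e-13
  est <- NA_real_
  n_it <- 0L
  while (!converged && n_it < maxit) {
    q <- lapply(seq_len(K), function(j) apply_sub(j, p[[j]]))          # 1a
    pq <- reduce(vapply(seq_len(K), function(j)
      sum(p[[j]][I[[j]]] * q[[j]][I[[j]]]), 0))                        # 1b + 2
    if (!is.finite(pq)) stop("divergence: non-finite values in CG iteration")
    if (pq <= 0) break
    alpha <- rz / pq
    for (j in seq_len(K)) {                                            # 3a
      io <- IO[[j]]; ij <- I[[j]]
      x[[j]][io] <- x[[j]][io] + alpha * p[[j]][io]
      r[[j]][ij] <- r[[j]][ij] - alpha * q[[j]][ij]
      z[[j]][ij] <- prec[ij] * r[[j]][ij]
    }
    n_it <- n_it + 1L
    tr$n <- n_it
    sres <- sqrt(reduce(vapply(seq_len(K), function(j) sum(r[[j]][I[[j]]]^2), 0))) / bnorm
    tr$sres[n_it + 1L] <- sres
    if (!is.null(monitor)) tr$S[n_it + 1L] <- monitor(assemble(x), n_it)
    if (!is.finite(sres)) stop("divergence: non-finite residual")

    rz_new <- reduce(vapply(seq_len(K), function(j)
      sum(r[[j]][I[[j]]] * z[[j]][I[[j]]]), 0))
    beta <- rz_new / rz
    rz <- rz_new
    for (j in seq_len(K)) {
      ij <- I[[j]]
      p[[j]][ij] <- z[[j]][ij] + beta * p[[j]][ij]
    }
    p <- exchange(p)                                                   # 3b

    converged <- switch(policy$mode,
      "scaled-residual" = sres <= policy$tolerance,
      "fixed-iterations" = FALSE,
      "estimated-error" = {
        ok <- FALSE
        if (n_it >= policy$window + 5L && n_it %% policy$cadence == 0L) {
          est <- estimate_relative_error(tr$S[seq_len(n_it + 1L)], policy$window)
          tr$check_n <- c(tr$check_n, n_it)
          tr$check_est <- c(tr$check_est, as.numeric(est))
          ok <- is.finite(est) && est <= policy$tolerance
        }
        ok || sres <= 1e-12
      })
  }
  if (policy$mode == "fixed-iterations") converged <- TRUE
  fit <- attr(est, "fit")
  list(u = assemble(x), trace = finish_trace(tr, fit), iterations = n_it,
       converged = converged, estimated_error = as.numeric(est))
}
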