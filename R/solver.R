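#' Stopping policy for the conjugate-gradient solver
#'
#' Three modes: `"estimated-error"` (default) stops when the stress-based
#' relative-error estimate drops below `tolerance`; `"scaled-residual"` stops
#' on `||r|| / ||B|| <= tolerance`; `"fixed-iterations"` runs exactly
#' `iterations` iterations (the mode used on the coarse pre-iteration grids).
#'
#' @param mode one of `"estimated-error"`, `"scaled-residual"`,
#'   `"fixed-iterations"`.
#' @param tolerance target relative error (default 0.01, i.e. 1% accuracy).
#' @param window number of most recent iterations entering the error-estimate
#'   fit (default 30).
#' @param max_iterations hard cap; default `min(10000, 10 * window * sqrt(N_v))`,
#'   resolved at solve time.
#' @param iterations iteration count for `"fixed-iterations"` mode.
#' @param cadence how often (in iterations) the error estimate is evaluated.
#' @return an object of class `stopping_policy`.
#' @export
stopping_policy <- function(mode = c("estimated-error", "scaled-residual",
                                     "fixed-iterations"),
                            tolerance = 0.01, window = 30L,
                            max_iterations = NULL, iterations = NULL,
                            cadence = 1L) {
  mode <- match.arg(mode)
  window <- as.integer(window)
  if (window < 3L) stop("`window` must be at least 3")
  if (!is.finite(tolerance) || tolerance <= 0) stop("`tolerance` must be positive")
  if (mode == "fixed-iterations" && is.null(iterations))
    stop("`iterations` is required for fixed-iterations mode")
  structure(list(mode = mode, tolerance = tolerance, window = window,
                 max_iterations = max_iterations, iterations = iterations,
                 cadence = as.integer(cadence)),
            class = "stopping_policy")
}

resolve_max_iterations <- function(policy, n) {
  if (policy$mode == "fixed-iterations") return(as.integer(policy$iterations))
  if (!is.null(policy$max_iterations)) return(as.integer(policy$max_iterations))
  min(10000L, as.integer(ceiling(10 * policy$window * sqrt(n))))
}

new_trace <- function(maxit) {
  env <- new.env(parent = emptyenv())
  env$S <- rep(NA_real_, maxit + 1L)     # S[n + 1] = total stress after iteration n
  env$sres <- rep(NA_real_, maxit + 1L)
  env$check_n <- integer(0)
  env$check_est <- numeric(0)
  env$n <- -1L
  env
}

finish_trace <- function(env, fit = NULL) {
  n <- env$n
  structure(list(S = env$S[seq_len(n + 1L)],
                 scaled_residual = env$sres[seq_len(n + 1L)],
                 checks = data.frame(n = env$check_n, estimate = env$check_est),
                 fit = fit, iterations = n),
            class = "convergence_trace")
}

#' @export
print.convergence_trace <- function(x, ...) {
  cat(sprintf("<convergence_trace> %d iterations, final S = %.6g, final scaled residual = %.3g\n",
              x$iterations, x$S[length(x$S)],
              x$scaled_residual[length(x$scaled_residual)]))
  invisible(x)
}

#' @export
as.data.frame.convergence_trace <- function(x, ...) {
  data.frame(n = seq_along(x$S) - 1L, S = x$S, scaled_residual = x$scaled_residual)
}

#' Scaled residual
#'
#' The conventional CG stopping quantity `||r||_2 / ||B||_2`.
#'
#' @param r residual vector.
#' @param B right-hand side; must be nonzero.
#' @return dimensionless scalar.
#' @export
scaled_residual <- function(r, B) {
  bn <- sqrt(sum(B^2))
  if (bn == 0) stop("scaled residual undefined: right-hand side is zero")
  sqrt(sum(r^2)) / bn
}

#' Stress-based relative-error estimate
#'
#' Models the total-stress series as `S_n = S_inf + alpha * exp(b n)` and
#' estimates the remaining relative error from a least-squares line fit of
#' `log |S_n - S_{n-1}|` against `n` over the most recent `window` iterations:
#' with fitted intercept `a` and slope `b`, the modeled error is
#' `exp(a + b n) / (|b| |S_n|)`. Zero differences are dropped from the fit;
#' a nonnegative slope or fewer than 3 usable points yields `NA` (estimate
#' unavailable; the solver keeps iterating).
#'
#' @param trace a `convergence_trace` (or a bare numeric vector of total
#'   stresses `S_0, S_1, ...`).
#' @param window number of most recent iterations to fit (default 30).
#' @return the estimated relative error, with the fitted `a`, `b` as attribute
#'   `"fit"`; `NA` if unavailable.
#' @export
estimate_relative_error <- function(trace, window = 30L) {
  S <- if (inherits(trace, "convergence_trace")) trace$S else as.numeric(trace)
  N <- length(S) - 1L                    # last iteration index
  if (N < 1L) return(NA_real_)
  n_all <- seq_len(N)                    # D_n defined for n >= 1
  D <- abs(S[n_all + 1L] - S[n_all])
  sel <- n_all > N - window & D > 0 & is.finite(D)
  if (sum(sel) < 3L) return(NA_real_)
  n <- n_all[sel]
  y <- log(D[sel])
  fit <- stats::lm.fit(cbind(1, n), y)
  a <- fit$coefficients[[1]]; b <- fit$coefficients[[2]]
  if (!is.finite(b) || b >= 0) return(structure(NA_real_, fit = c(a = a, b = b)))
  if (S[N + 1L] == 0) return(structure(NA_real_, fit = c(a = a, b = b)))
  est <- exp(a + b * N) / (abs(b) * abs(S[N + 1L]))
  structure(est, fit = c(a = a, b = b))
}

#' Preconditioned conjugate-gradient solve
#'
#' Jacobi-preconditioned CG on the reduced free-variable system `A u = B`.
#' `A` may be an [ebe_operator()] (the matrix-free path; the Jacobi diagonal
#' is derived automatically) or a plain function `function(v) A %*% v` (then
#' `precond` defaults to the identity). A `monitor` function, called as
#' `monitor(u, n)` after every iteration (and once for the initial guess),
#' records the total-stress series driving the `"estimated-error"` stopping
#' mode.
#'
#' @param A operator: [ebe_operator()] or `function(v)`.
#' @param B right-hand side (length `n_free`).
#' @param x0 initial displacement configuration; default zero.
#' @param precond inverse-diagonal preconditioner vector; default
#'   [jacobi_diagonal()] for an EBE operator, identity otherwise.
#' @param policy a [stopping_policy()].
#' @param monitor optional `function(u, n)` returning the monitored scalar
#'   (total stress, MPa). Required for `"estimated-error"` mode.
#' @return list with `u` (solution), `trace` (a `convergence_trace`),
#'   `iterations`, `converged`, `estimated_error` (last estimate, `NA` if
#'   never computed).
#' @export
pcg_solve <- function(A, B, x0 = NULL, precond = NULL,
                      policy = stopping_policy(), monitor = NULL) {
  if (inherits(A, "ebe_operator")) {
    op <- A
    Af <- function(v) ebe_apply(op, v)
    if (is.null(precond)) precond <- jacobi_diagonal(op)
  } else if (is.function(A)) {
    Af <- A
  } else stop("`A` must be an ebe_operator or a function")
  n <- length(B)
  if (is.null(x0)) x0 <- numeric(n)
  stopifnot(length(x0) == n)
  if (policy$mode == "estimated-error" && is.null(monitor))
    stop("estimated-error stopping needs a stress monitor")

  maxit <- resolve_max_iterations(policy, n)
  tr <- new_trace(maxit)
  x <- as.numeric(x0)
  bnorm <- sqrt(sum(B^2))
  if (bnorm == 0) {                      # homogeneous system: solution is x0 (= 0 load)
    tr$n <- 0L
    tr$sres[1L] <- 0
    if (!is.null(monitor)) tr$S[1L] <- monitor(x, 0L)
    return(list(u = x, trace = finish_trace(tr), iterations = 0L,
                converged = TRUE, estimated_error = NA_real_))
  }

  r <- B - Af(x)
  z <- if (is.null(precond)) r else precond * r
  p <- z
  rz <- sum(r * z)
  tr$n <- 0L
  tr$sres[1L] <- sqrt(sum(r^2)) / bnorm
  if (!is.null(monitor)) tr$S[1L] <- monitor(x, 0L)

  converged <- tr$sres[1L] < 1e-13      # warm start already at the solution
  est <- NA_real_
  n_it <- 0L
  while (!converged && n_it < maxit) {
    q <- Af(p)
    pq <- sum(p * q)
    if (!is.finite(pq)) stop("divergence: non-finite values in CG iteration")
    if (pq <= 0) break                   # exhausted the range space
    alpha <- rz / pq
    x <- x + alpha * p
    r <- r - alpha * q
    n_it <- n_it + 1L
    tr$n <- n_it
    sres <- sqrt(sum(r^2)) / bnorm
    tr$sres[n_it + 1L] <- sres
    if (!is.null(monitor)) tr$S[n_it + 1L] <- monitor(x, n_it)
    if (!is.finite(sres)) stop("divergence: non-finite residual")

    z <- if (is.null(precond)) r else precond * r
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p

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
        ok || sres <= 1e-12              # safety net near round-off level
      })
  }
  if (policy$mode == "fixed-iterations") converged <- TRUE
  fit <- attr(est, "fit")
  list(u = x, trace = finish_trace(tr, fit), iterations = n_it,
       converged = converged, estimated_error = as.numeric(est))
}
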