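#' Interaction matrices for generalized Lotka-Volterra communities
#'
#' The community model is dn_i/dt = n_i (r_i + sum_j A_ij n_j): entry
#' `A[i, j]` multiplies the density n_j in the growth equation of species i,
#' so column j of `A` collects the per-capita effects species j exerts on the
#' rest of the community. The diagonal holds self-regulation (negative for
#' self-limited species, 0 for species regulated only by their resources).
#'
#' @param entries square numeric matrix of per-capita interaction strengths.
#' @param guilds optional character vector of per-species labels (for example
#'   `"animal"`/`"plant"` or `"resource"`/`"consumer"`).
#' @return An `interaction_matrix`: the validated matrix with an optional
#'   `guilds` attribute.
#' @examples
#' A <- interaction_matrix(-diag(3))
#' @export
interaction_matrix <- function(entries, guilds = NULL) {
  A <- check_square(entries, "entries")
  S <- nrow(A)
  if (S < 1) stop("at least one species is required")
  if (!is.null(guilds)) {
    if (length(guilds) != S) stop("`guilds` must have one label per species")
    attr(A, "guilds") <- as.character(guilds)
  }
  class(A) <- c("interaction_matrix", class(A))
  A
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("interaction matrix: S = %d species\n", nrow(x)))
  g <- attr(x, "guilds")
  if (!is.null(g)) cat("guilds:", paste(sprintf("%s (%d)", names(table(g)), table(g)), collapse = ", "), "\n")
  print(unclass_im(x), ...)
  invisible(x)
}

#' Coarse-grained moments of an interaction matrix
#'
#' Computes the statistics that determine the feasibility volume of large
#' random communities: the mean diagonal d, and the mean `E1`, variance `E2`
#' and pairwise correlation `Ec` of the off-diagonal entries. `E1` and `E2`
#' are pooled over *all* off-diagonal entries, structural zeros included;
#' this is the pooling under which a random network with connectance C and
#' interaction-strength mean mu has E1 = C * mu. `Ec` is the Pearson
#' correlation of the symmetrically pooled pair cloud
#' {(A_ij, A_ji), (A_ji, A_ij)} over unordered pairs.
#'
#' @param A interaction matrix (S >= 2).
#' @param zero_is_absent if `TRUE`, a pair with both entries zero is counted
#'   as an absent interaction and connectance `C` is the fraction of unordered
#'   pairs with at least one nonzero entry; otherwise `C = 1`.
#' @return A `moment_summary` list with elements `S`, `C`, `d`, `E1`, `E2`,
#'   `Ec` (`Ec` is `NA` when `E2 = 0`, where it is undefined).
#' @export
empirical_moments <- function(A, zero_is_absent = FALSE) {
  A <- check_square(A)
  S <- nrow(A)
  if (S < 2) stop("moments require at least S = 2 species")
  off <- A[row(A) != col(A)]
  x <- A[upper.tri(A)]
  y <- t(A)[upper.tri(A)]
  E1 <- mean(off)
  E2 <- mean((off - E1)^2)
  Ec <- if (E2 > 0) mean((c(x, y) - E1) * (c(y, x) - E1)) / E2 else NA_real_
  C <- if (zero_is_absent) mean(x != 0 | y != 0) else 1
  structure(
    list(S = S, C = C, d = mean(diag(A)), E1 = E1, E2 = E2, Ec = Ec),
    class = "moment_summary"
  )
}

#' @export
print.moment_summary <- function(x, ...) {
  cat(sprintf("moments: S = %d, C = %.3f, d = %.4g, E1 = %.4g, E2 = %.4g, Ec = %s\n",
              x$S, x$C, x$d, x$E1, x$E2,
              if (is.na(x$Ec)) "undefined" else sprintf("%.4g", x$Ec)))
  invisible(x)
}

#' Negative definiteness of an interaction matrix
#'
#' A real matrix A is negative definite (in the generalized sense) when every
#' eigenvalue of A + A' is negative. For Lotka-Volterra dynamics this
#' guarantees that any feasible fixed point is globally stable, which is what
#' lets feasibility be studied as a purely geometric property of A.
#'
#' @param A interaction matrix.
#' @return List with `negative_definite` (logical; strict) and `margin`, the
#'   largest eigenvalue of (A + A')/2. The margin is negative exactly when the
#'   matrix is negative definite, and its magnitude measures the distance to
#'   the stability boundary.
#' @export
is_negative_definite <- function(A) {
  A <- check_square(A)
  margin <- max(eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  list(negative_definite = margin < 0, margin = margin)
}

#' Equilibrium of a Lotka-Volterra community
#'
#' Solves A n* = -r for the fixed point and reports whether it is feasible
#' (all abundances strictly positive, with a floating-point guard at
#' `tol_pos` times the largest component magnitude).
#'
#' @param A interaction matrix; must be invertible.
#' @param r intrinsic growth-rate vector.
#' @param tol_rcond reciprocal-condition-number threshold below which the
#'   system is declared degenerate.
#' @param tol_pos relative positivity tolerance.
#' @return List with `n_star` and logical `feasible`.
#' @export
equilibrium <- function(A, r, tol_rcond = 1e-12, tol_pos = 1e-12) {
  A <- check_square(A)
  r <- check_growth_rates(r, nrow(A))
  rc <- rcond(A)
  if (!is.finite(rc) || rc < tol_rcond) {
    stop_degenerate("interaction matrix is singular or near-singular", rc)
  }
  n_star <- as.numeric(solve(A, -r))
  feasible <- all(n_star > tol_pos * max(abs(n_star)))
  list(n_star = n_star, feasible = feasible)
}

#' Check a feasibility prediction by integrating the dynamics
#'
#' Numerically integrates dn_i/dt = n_i (r_i + sum_j A_ij n_j) from a
#' positive initial condition. For negative definite A, trajectories from any
#' positive initial state converge to the interior equilibrium when r lies in
#' the feasibility cone, and otherwise at least one species collapses towards
#' the boundary; this function reports which outcome occurred.
#'
#' @param A negative definite interaction matrix.
#' @param r growth-rate vector.
#' @param n0 strictly positive initial densities.
#' @param horizon integration time (model time units).
#' @param extinction_tol a species is scored extinct when it falls below
#'   `extinction_tol * max(n0)`.
#' @param reltol relative tolerance for matching the endpoint to -A^{-1} r.
#' @return List with `endpoint` (densities at the horizon) and `converged_to`,
#'   one of `"equilibrium"`, `"boundary"` or `"undecided"`.
#' @export
verify_by_integration <- function(A, r, n0, horizon = 1000,
                                  extinction_tol = 1e-8, reltol = 1e-6) {
  A <- check_square(A)
  S <- nrow(A)
  r <- check_growth_rates(r, S)
  n0 <- as.numeric(n0)
  if (length(n0) != S || any(!is.finite(n0)) || any(n0 <= 0)) {
    stop("`n0` must be a strictly positive vector of length S")
  }
  nd <- is_negative_definite(A)
  if (!nd$negative_definite) {
    stop("`A` must be negative definite: global stability of feasible fixed points is only guaranteed in that regime")
  }
  glv <- function(t, n, parms) {
    n <- pmax(n, 0)
    list(n * (r + as.numeric(A %*% n)))
  }
  sol <- deSolve::ode(
    y = n0, times = c(0, horizon / 2, horizon), func = glv, parms = NULL,
    method = "lsoda", rtol = 1e-10, atol = 1e-12 * max(n0)
  )
  if (attr(sol, "istate")[1L] < 0) {
    stop("numerical integration of the dynamics failed")
  }
  endpoint <- pmax(as.numeric(sol[nrow(sol), -1L]), 0)
  floor_ext <- extinction_tol * max(n0)
  rc <- rcond(A)
  converged <- "undecided"
  if (rc >= 1e-12) {
    n_eq <- as.numeric(solve(A, -r))
    if (all(n_eq > 0) &&
        max(abs(endpoint - n_eq)) <= reltol * max(abs(n_eq))) {
      converged <- "equilibrium"
    }
  }
  if (converged == "undecided" && any(endpoint < floor_ext)) {
    converged <- "boundary"
  }
  list(endpoint = endpoint, converged_to = converged)
}
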