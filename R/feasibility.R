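#' @title Size of the feasibility domain
#' @description
#' The feasibility domain of an interaction matrix A is the convex polyhedral
#' cone of growth-rate vectors r for which the equilibrium n* = -A^{-1} r has
#' all components positive; it is generated by the columns of -A. Its
#' normalized solid angle
#'
#'   Xi = 2^S * (fraction of directions r leading to a feasible equilibrium)
#'
#' is 1 for non-interacting self-regulated communities (A a negative diagonal
#' matrix) and spans exponential ranges as S grows, so all estimators here
#' work in log space. Writing r as an isotropic Gaussian vector Z and changing
#' variables n = -A^{-1} Z shows that the directional fraction equals the
#' positive-orthant probability of a centered Gaussian with covariance
#' (A'A)^{-1}, which is what [xi_orthant()] evaluates.
#' @name feasibility
NULL

new_feasibility_estimate <- function(ln_xi, stderr_ln, method, n_samples,
                                     seed = NULL, S = NA_integer_,
                                     degenerate = FALSE) {
  structure(
    list(
      ln_xi = ln_xi,
      xi = if (degenerate) 0 else exp(ln_xi),
      stderr_ln = stderr_ln,
      method = method,
      n_samples = n_samples,
      seed = seed,
      S = S,
      degenerate = degenerate
    ),
    class = "feasibility_estimate"
  )
}

#' @export
print.feasibility_estimate <- function(x, ...) {
  cat(sprintf("feasibility volume (%s): ln Xi = %.6g", x$method, x$ln_xi))
  if (is.finite(x$stderr_ln) && x$stderr_ln > 0) cat(sprintf(" +/- %.3g", x$stderr_ln))
  cat(sprintf("  [Xi = %.6g, S = %d]\n", x$xi, x$S))
  invisible(x)
}

#' Does a growth-rate vector admit feasible coexistence?
#'
#' Tests whether `r` lies in the feasibility cone of `A`, i.e. whether
#' -A^{-1} r is componentwise positive. Membership depends only on the
#' direction of `r`: `membership(A, c * r)` is identical for any c > 0.
#'
#' @inheritParams equilibrium
#' @return Logical flag.
#' @export
membership <- function(A, r, tol_rcond = 1e-12, tol_pos = 1e-12) {
  equilibrium(A, r, tol_rcond = tol_rcond, tol_pos = tol_pos)$feasible
}

#' Feasibility volume by direct sphere sampling
#'
#' Brute-force hit-or-miss estimator: isotropic growth-rate directions are
#' drawn and the hit fraction is scaled by 2^S. Serves as the model-free
#' oracle for [xi_orthant()]; it becomes exponentially inefficient as S grows
#' because the hit probability is at most Xi / 2^S.
#'
#' @param A interaction matrix.
#' @param n_samples number of sampled directions (>= 1000).
#' @param seed optional integer seed (RNG state is restored on exit).
#' @param chunk_size samples per block, to bound memory.
#' @return A `feasibility_estimate` with the binomial standard error
#'   propagated to the log scale. With zero hits `ln_xi` is `-Inf` and the
#'   standard error is undefined; a warning is emitted.
#' @export
xi_sphere_sampling <- function(A, n_samples = 1e5, seed = NULL,
                               chunk_size = 1e5) {
  A <- check_square(A)
  S <- nrow(A)
  n_samples <- as.integer(n_samples)
  if (n_samples < 1000) stop("use at least 1000 samples")
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1e-12) {
    # measure-zero cone: the feasible set has no interior
    return(new_feasibility_estimate(-Inf, 0, "sphere-sampling", n_samples,
                                    seed, S, degenerate = TRUE))
  }
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  Ainv <- solve(A)
  hits <- 0L
  done <- 0L
  while (done < n_samples) {
    m <- min(chunk_size, n_samples - done)
    # direction is all that matters, so the isotropic draws are not normalized
    Z <- matrix(stats::rnorm(S * m), nrow = S)
    N <- -Ainv %*% Z
    hits <- hits + sum(colSums(N > 0) == S)
    done <- done + m
  }
  p <- hits / n_samples
  if (hits == 0L) {
    warning("no feasible direction in ", n_samples,
            " samples; ln Xi reported as -Inf (upper bound ~ ",
            sprintf("%.3g", S * log(2) + log(3 / n_samples)), " on ln Xi)")
    return(new_feasibility_estimate(-Inf, Inf, "sphere-sampling", n_samples,
                                    seed, S))
  }
  ln_xi <- S * log(2) + log(p)
  se_ln <- sqrt((1 - p) / hits)
  out <- new_feasibility_estimate(ln_xi, se_ln, "sphere-sampling", n_samples,
                                  seed, S)
  out$hits <- hits
  out
}

# Log-space orthant probability of N(0, Sigma) over the positive orthant,
# by separation-of-variables with a randomized Richtmyer lattice rule.
# Each lattice point carries the log-product of the sequential conditional
# probabilities, so probabilities far below double precision (e.g. 2^-200)
# remain resolvable on the log scale.
orthant_lnprob <- function(Sigma, n_points = 2^14, n_replicates = 8,
                           seed = NULL) {
  S <- nrow(Sigma)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  L <- t(chol(Sigma))
  if (S == 1L) {
    return(list(lnp = log(0.5), se = 0))
  }
  q <- sqrt(first_primes(S - 1L))
  jj <- seq_len(n_points)
  lp <- numeric(n_replicates)
  for (rep in seq_len(n_replicates)) {
    shift <- stats::runif(S - 1L)
    logf <- rep(-log(2), n_points)   # first factor: P(X_1 > 0) = 1/2
    y <- matrix(0, n_points, S - 1L)
    for (k in seq_len(S - 1L)) {
      u <- abs(2 * ((jj * q[k] + shift[k]) %% 1) - 1)   # baker transform
      bk <- if (k == 1L) {
        rep(0, n_points)
      } else {
        -(y[, seq_len(k - 1L), drop = FALSE] %*% L[k, seq_len(k - 1L)]) / L[k, k]
      }
      dk <- stats::pnorm(bk)
      # inverse-CDF draw from the normal truncated to (bk, Inf)
      y[, k] <- stats::qnorm(pmin(dk + u * (1 - dk), 1 - 1e-16))
      bk1 <- -(y[, seq_len(k), drop = FALSE] %*% L[k + 1L, seq_len(k)]) / L[k + 1L, k + 1L]
      logf <- logf + stats::pnorm(bk1, lower.tail = FALSE, log.p = TRUE)
    }
    lp[rep] <- log_mean_exp(logf)
  }
  list(lnp = log_mean_exp(lp), se = stats::sd(lp) / sqrt(n_replicates))
}

#' Feasibility volume via the Gaussian orthant reduction
#'
#' Computes Xi = 2^S P(Z in cone) exactly up to quasi-Monte Carlo error:
#' the change of variables n = -A^{-1} Z maps the cone-membership event to
#' the positive orthant of a centered Gaussian with covariance (A'A)^{-1},
#' whose orthant probability is evaluated in log space by a randomized
#' lattice rule. This resolves Xi with near-arbitrary precision even when
#' the orthant probability is far below machine epsilon (large S).
#'
#' @param A interaction matrix (S >= 1).
#' @param n_points lattice points per replicate.
#' @param n_replicates independent randomizations; the spread across them
#'   yields the standard error of ln Xi.
#' @param seed optional integer seed.
#' @return A `feasibility_estimate`. Rank-deficient matrices (reciprocal
#'   condition number below 1e-12) have a measure-zero feasibility cone and
#'   are reported as `Xi = 0`, `ln_xi = -Inf`.
#' @export
xi_orthant <- function(A, n_points = 2^14, n_replicates = 8, seed = NULL) {
  A <- check_square(A)
  S <- nrow(A)
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1e-12) {
    return(new_feasibility_estimate(-Inf, 0, "orthant-qmc",
                                    n_points * n_replicates, seed, S,
                                    degenerate = TRUE))
  }
  Sigma <- chol2inv(chol(crossprod(A)))
  R <- stats::cov2cor((Sigma + t(Sigma)) / 2)
  est <- orthant_lnprob(R, n_points = n_points, n_replicates = n_replicates,
                        seed = seed)
  new_feasibility_estimate(S * log(2) + est$lnp, est$se, "orthant-qmc",
                           n_points * n_replicates, seed, S)
}

# Off-diagonal correlation of (A'A)^{-1} for the mean-field matrix
# A = d I + E1 (J - I); exact for all S, d < 0, E1.
meanfield_correlation <- function(S, d, E1) {
  alpha <- (d - E1)^2
  beta <- E1 * (2 * (d - E1) + S * E1)
  -beta / (alpha + (S - 1) * beta)
}

# ln Xi for an equicorrelated orthant problem with common correlation rho.
# rho > 0: exact, via the one-factor mixture representation reduced to a
#   single integral  P = E_z[ Phi(lambda z)^S ],  lambda^2 = rho/(1-rho).
# rho < 0: second-order (Gaussian-tilt) approximation of the same quantity;
#   no mixture representation exists on that side, but in the weak-interaction
#   regime the approximation is accurate to ~1% of ln Xi.
lnxi_equicorrelated <- function(S, rho) {
  if (abs(rho) < 1e-14) return(0)
  if (rho >= 1) return(S * log(2) - log(2))
  if (rho > 0) {
    lam <- sqrt(rho / (1 - rho))
    g <- function(z) stats::dnorm(z, log = TRUE) + S * stats::pnorm(lam * z, log.p = TRUE)
    zs <- seq(-10, max(10, 1.5 * S * lam), length.out = 512)
    off <- max(g(zs))
    val <- stats::integrate(function(z) exp(g(z) - off), -Inf, Inf,
                            rel.tol = 1e-10)$value
    S * log(2) + off + log(val)
  } else {
    lam2 <- rho / (1 - rho)           # negative; bounded below by -1/S
    b <- S * lam2 / pi
    (S^2 * lam2 / pi) / (1 + 2 * b) - 0.5 * log(1 + 2 * b)
  }
}

#' Closed-form feasibility volume of large random communities
#'
#' Complexity-feasibility relationship: for a large random community with
#' mean diagonal d < 0 and pooled off-diagonal mean E1 = C * mu, the
#' feasibility volume is approximated by replacing A with its expectation
#' (the mean-field matrix with all off-diagonal entries equal to E1). The
#' induced Gaussian orthant problem is equicorrelated with a correlation
#' that follows in closed form from (S, d, E1), and is evaluated by
#' [lnxi_equicorrelated] (exact one-dimensional reduction on the mutualistic
#' side E1 > 0, second-order tilt approximation on the competitive side).
#'
#' Xi equals 1 at E1 = 0 and, because d < 0, grows with S for E1 > 0 and
#' shrinks with S for E1 < 0: diversity helps feasibility under mutualism
#' and hurts it under competition.
#'
#' @param S number of species.
#' @param d mean diagonal entry (must be negative).
#' @param E1 pooled mean of off-diagonal interaction strengths.
#' @param log return ln Xi instead of Xi.
#' @return Xi (or ln Xi). A warning is attached when the parameters are
#'   outside the negative-definiteness validity region d + S * E1 < 0, where
#'   the approximation degrades.
#' @seealso [xi_analytic_refined()] for the variance- and
#'   correlation-corrected version.
#' @export
xi_analytic <- function(S, d = -1, E1, log = FALSE) {
  stopifnot(S >= 2, is.finite(d), is.finite(E1))
  if (d >= 0) stop("the mean self-regulation `d` must be negative")
  if (E1 > 0 && d + S * E1 >= 0) {
    warning("parameters at or beyond the negative-definiteness bound d + S*E1 < 0; the approximation is unreliable here")
  }
  ln <- lnxi_equicorrelated(S, meanfield_correlation(S, d, E1))
  if (log) ln else exp(ln)
}

# Equicorrelation implied by the expected Gram matrix E[A'A] of a random
# matrix with pooled moments (E1, E2); reduces to meanfield_correlation
# when E2 = 0.
effective_correlation <- function(S, d, E1, E2) {
  alpha <- d^2 + (S - 1) * (E2 + E1^2)
  beta <- 2 * d * E1 + (S - 2) * E1^2
  -beta / (alpha + (S - 2) * beta)
}

#' Refined feasibility volume using second moments
#'
#' Extends [xi_analytic()] with the pooled variance `E2` and pair correlation
#' `Ec` of the off-diagonal entries. Two corrections enter: the expected Gram
#' matrix E[A'A] (whose diagonal grows with E2) shifts the effective
#' equicorrelation, and entry-to-entry fluctuations of the induced pairwise
#' correlations contribute a negative second-order term
#' -2 S (S - 1) E2 (1 + Ec) / (pi^2 d^2) to ln Xi, so interaction-strength
#' variability always shrinks the feasibility domain. Reduces exactly to
#' [xi_analytic()] when `E2 = 0`.
#'
#' @inheritParams xi_analytic
#' @param E2 pooled variance of off-diagonal entries (>= 0).
#' @param Ec pairwise correlation of (A_ij, A_ji); ignored when `E2 = 0`.
#' @return Xi (or ln Xi), with a validity warning when `S * E2 / d^2 > 1`.
#' @export
xi_analytic_refined <- function(S, d = -1, E1, E2, Ec = 0, log = FALSE) {
  stopifnot(S >= 2, is.finite(d), is.finite(E1), is.finite(E2), E2 >= 0)
  if (d >= 0) stop("the mean self-regulation `d` must be negative")
  if (is.na(Ec)) Ec <- 0
  if (E1 > 0 && d + S * E1 >= 0) {
    warning("parameters at or beyond the negative-definiteness bound d + S*E1 < 0; the approximation is unreliable here")
  }
  if (S * E2 / d^2 > 1) {
    warning("interaction variance is large (S * E2 / d^2 > 1); the second-order correction may be inaccurate")
  }
  ln <- lnxi_equicorrelated(S, effective_correlation(S, d, E1, E2)) -
    2 * S * (S - 1) * E2 * (1 + Ec) / (pi^2 * d^2)
  if (log) ln else exp(ln)
}
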