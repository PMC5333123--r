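#' Shape of the feasibility cone
#'
#' After normalizing growth rates to unit length, the feasibility domain is a
#' spherical (S-1)-simplex whose vertices are the normalized columns of -A
#' (vertex i is the growth-rate direction at which only species i persists in
#' isolation of perturbations: r = -A n* with n* concentrated on species i).
#' The side length eta_ij is the angular distance between vertices i and j,
#' and cos(eta_ij) is the normalized overlap of how species i and j interact
#' with the whole community: identical interaction profiles (full niche
#' overlap) collapse the side to zero length, making coexistence of that pair
#' maximally fragile to growth-rate perturbations.
#'
#' @param A interaction matrix; no column of -A may be zero.
#' @param transpose set `TRUE` for matrices stored in the row-oriented
#'   convention (effects of species i listed along row i), in which case the
#'   rows of -A generate the cone instead of its columns.
#' @return A `cone_shape` list: `vertices` (S unit column vectors),
#'   `cos_eta` (S x S Gram matrix), `eta` (side lengths, arccos of
#'   `cos_eta`), and the moments `mean_cos`, `sd_cos` over unordered pairs
#'   (population standard deviation).
#' @export
cone_shape <- function(A, transpose = FALSE) {
  A <- check_square(A)
  if (transpose) A <- t(A)
  V <- -A
  nrm <- sqrt(colSums(V^2))
  if (any(nrm == 0)) {
    stop_degenerate("zero column in -A: the cone is degenerate", 0)
  }
  V <- sweep(V, 2, nrm, "/")
  G <- crossprod(V)
  G <- pmin(pmax(G, -1), 1)
  diag(G) <- 1
  g <- G[upper.tri(G)]
  structure(
    list(
      vertices = V,
      cos_eta = G,
      eta = acos(G),
      mean_cos = mean(g),
      sd_cos = sqrt(mean((g - mean(g))^2))
    ),
    class = "cone_shape"
  )
}

#' @export
print.cone_shape <- function(x, ...) {
  S <- ncol(x$vertices)
  cat(sprintf("feasibility-cone shape: S = %d, %d sides\n", S, S * (S - 1) / 2))
  cat(sprintf("cos(eta): mean = %.5g, sd = %.5g\n", x$mean_cos, x$sd_cos))
  invisible(x)
}

#' Moments of the side-length distribution
#'
#' @param shape a `cone_shape` (S >= 3 for a non-trivial dispersion).
#' @return Named numeric vector `c(mean_cos, sd_cos)` over the S(S-1)/2
#'   unordered pairs.
#' @export
side_moments <- function(shape) {
  stopifnot(inherits(shape, "cone_shape"))
  c(mean_cos = shape$mean_cos, sd_cos = shape$sd_cos)
}

#' Analytic side-length moments for random communities
#'
#' For a random interaction matrix with mean diagonal d and pooled
#' off-diagonal moments (E1, E2, Ec), the scalar product of two cone
#' generators and the squared generator norms concentrate around their
#' expectations, giving moments of cos(eta) that depend only on S, E1, E2
#' and Ec (and d). To leading order
#'
#'   mean = (2 d E1 + (S-2) E1^2) / (d^2 + (S-1)(E2 + E1^2))
#'   var  = (2 d^2 E2 (1+Ec) + (S-2)((E2+E1^2)^2 - E1^4)) /
#'          (d^2 + (S-1)(E2 + E1^2))^2
#'
#' and the implementation carries the expansion of X / sqrt(Y_i Y_j) (X the
#' generator scalar product, Y the squared norms) one order further,
#' evaluating the third- and fourth-moment terms under a Gaussian-pair
#' closure (exact for fully connected bivariate-normal ensembles, a
#' sub-percent refinement otherwise). The mean changes sign with E1/d
#' (mutualism tilts the generators towards each other, competition apart),
#' and both moments are invariant under rescaling of A.
#'
#' @param S number of species (>= 3).
#' @param E1,E2,Ec pooled off-diagonal moments (see [empirical_moments()]).
#' @param d mean diagonal entry, d < 0.
#' @return Named numeric vector `c(mean_cos, sd_cos)`.
#' @export
side_moments_analytic <- function(S, E1, E2, Ec = 0, d = -1) {
  stopifnot(S >= 3, is.finite(E1), is.finite(E2), E2 >= 0, d < 0)
  if (is.na(Ec)) Ec <- 0
  m2 <- E2 + E1^2
  if (S * m2 / d^2 > 1) {
    warning("interaction strengths are large (S * (E2 + E1^2) / d^2 > 1); the moment expansion may be inaccurate")
  }
  Yb <- d^2 + (S - 1) * m2                       # E[squared norm]
  Xb <- 2 * d * E1 + (S - 2) * E1^2              # E[scalar product]
  VX <- 2 * d^2 * E2 * (1 + Ec) + (S - 2) * (m2^2 - E1^4)
  # second-order terms (Gaussian-pair closure for 3rd/4th entry moments)
  VY <- (S - 1) * (4 * E1^2 * E2 + 2 * E2^2)     # Var[squared norm]
  Cyy <- 2 * Ec^2 * E2^2 + 4 * E1^2 * Ec * E2    # Cov[norms of a pair]
  CXY <- 2 * d * E1 * E2 * (1 + Ec) + 2 * (S - 2) * E1^2 * E2
  D <- 2 * d^2 * E2^2 * (1 + Ec)^2 + (S - 2) * 2 * E2^2 * (3 * E1^2 + E2)
  mean_cos <- (Xb / Yb) * (1 + 0.75 * VY / Yb^2 + 0.25 * Cyy / Yb^2) -
    CXY / Yb^2
  var_cos <- (VX / Yb^2) * (1 + 2 * VY / Yb^2 + Cyy / Yb^2) +
    (Xb^2 / Yb^2) * 0.5 * (VY + Cyy) / Yb^2 -
    2 * Xb * CXY / Yb^3 - 2 * D / Yb^3
  c(mean_cos = mean_cos, sd_cos = sqrt(max(var_cos, 0)))
}

#' Standardize an observed cone shape against a null ensemble
#'
#' Measures how unusual the side-length heterogeneity of a network is,
#' relative to shapes obtained from a null model (randomized adjacency,
#' cascade replicates, ...). Positive `z_sd` means more heterogeneous side
#' lengths than the null: some pairwise coexistence margins are much
#' narrower than the null expects.
#'
#' @param net_shape `cone_shape` of the focal system.
#' @param null_shapes list of at least 20 `cone_shape` objects from the null.
#' @return List with `z_mean` and `z_sd`, the standardized `mean_cos` and
#'   `sd_cos`.
#' @export
shape_zscore <- function(net_shape, null_shapes) {
  stopifnot(inherits(net_shape, "cone_shape"))
  if (length(null_shapes) < 20) stop("at least 20 null replicates are required")
  nm <- vapply(null_shapes, function(s) s$mean_cos, numeric(1))
  ns <- vapply(null_shapes, function(s) s$sd_cos, numeric(1))
  if (stats::sd(nm) == 0 || stats::sd(ns) == 0) {
    stop("degenerate null ensemble: zero variance across replicates")
  }
  list(
    z_mean = (net_shape$mean_cos - mean(nm)) / stats::sd(nm),
    z_sd = (net_shape$sd_cos - mean(ns)) / stats::sd(ns)
  )
}
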