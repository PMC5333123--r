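#' Specify a random interaction-matrix ensemble
#'
#' For each unordered species pair, an interaction is realized with
#' probability `C`; realized pairs (A_ij, A_ji) are drawn jointly from a
#' bivariate family with marginal mean `mu`, standard deviation `sigma` and
#' within-pair correlation `rho`, then an optional sign pattern is applied
#' and the orientation (which entry of the pair receives which draw) is
#' decided by a fair coin. The diagonal is constant at `d`.
#'
#' Families: `"bivariate-normal"` draws are plain Gaussians;
#' `"uniform"` and `"lognormal"` have the requested moments exactly and are
#' coupled through a Gaussian copula calibrated so the within-pair
#' correlation of the *marginals* equals `rho`. Sign patterns other than
#' `"unconstrained"` require a family whose support already respects the
#' signs (uniform with mu > sqrt(3) sigma, or lognormal), so no truncation or
#' folding distorts the moments: `"++"` keeps the positive draws, `"--"`
#' negates both, and `"+-"` assigns (+x, -y) to the two directions of each
#' pair (predator-prey style), which makes the pooled mean zero.
#'
#' @param S species count.
#' @param C connectance in `[0, 1]`.
#' @param mu,sigma,rho pair mean, standard deviation (>= 0) and correlation.
#' @param family one of `"bivariate-normal"`, `"uniform"`, `"lognormal"`.
#' @param sign_pattern one of `"unconstrained"`, `"+-"`, `"++"`, `"--"`.
#' @param d diagonal (self-regulation) value.
#' @param seed optional integer seed stored with the spec.
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(S, C, mu, sigma, rho = 0,
                          family = c("bivariate-normal", "uniform", "lognormal"),
                          sign_pattern = c("unconstrained", "+-", "++", "--"),
                          d = -1, seed = NULL) {
  family <- match.arg(family)
  sign_pattern <- match.arg(sign_pattern)
  stopifnot(S >= 1, C >= 0, C <= 1, sigma >= 0, abs(rho) <= 1, is.finite(mu),
            is.finite(d))
  if (sign_pattern != "unconstrained") {
    if (family == "bivariate-normal" && sigma > 0) {
      stop("a Gaussian family cannot enforce a sign pattern (unbounded support); use the uniform or lognormal family")
    }
    if (mu <= 0) stop("sign patterns require mu > 0 (the magnitude scale)")
    if (family == "uniform" && mu - sqrt(3) * sigma < 0) {
      stop("uniform support crosses zero (mu < sqrt(3) * sigma); the sign pattern cannot be guaranteed")
    }
  }
  if (family == "lognormal" && mu <= 0) {
    stop("the lognormal family requires mu > 0")
  }
  structure(
    list(S = as.integer(S), C = C, mu = mu, sigma = sigma, rho = rho,
         family = family, sign_pattern = sign_pattern, d = d, seed = seed),
    class = "ensemble_spec"
  )
}

# n pairs with exact marginal mean mu, sd sigma and correlation rho.
draw_pairs <- function(n, mu, sigma, rho, family) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  couple <- function(rz) cbind(z1, rz * z1 + sqrt(max(1 - rz^2, 0)) * z2)
  if (family == "bivariate-normal") {
    z <- couple(rho)
    return(mu + sigma * z)
  }
  if (family == "uniform") {
    # Gaussian copula: corr of the uniforms is (6/pi) asin(rz/2)
    rz <- 2 * sin(pi * rho / 6)
    u <- stats::pnorm(couple(rz))
    return(mu + sqrt(3) * sigma * (2 * u - 1))
  }
  # lognormal with exact mean/sd; copula calibrated through the
  # lognormal correlation identity corr = (exp(rz s^2) - 1)/(exp(s^2) - 1)
  s2 <- log(1 + sigma^2 / mu^2)
  m <- log(mu) - s2 / 2
  rz <- if (sigma == 0) 0 else log(1 + rho * (exp(s2) - 1)) / s2
  if (!is.finite(rz) || abs(rz) > 1) {
    stop("requested pair correlation is unattainable for this lognormal shape")
  }
  exp(m + sqrt(s2) * couple(rz))
}

#' Sample a random interaction matrix
#'
#' @param spec an [ensemble_spec()].
#' @param seed optional integer seed overriding `spec$seed`; identical spec
#'   and seed give bitwise-identical matrices.
#' @return An [interaction_matrix()].
#' @export
sample_random_matrix <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  seed <- seed %||% spec$seed
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  S <- spec$S
  A <- matrix(0, S, S)
  if (S >= 2 && spec$C > 0) {
    ut <- which(upper.tri(A), arr.ind = TRUE)
    link <- stats::runif(nrow(ut)) < spec$C
    n <- sum(link)
    xy <- draw_pairs(n, spec$mu, spec$sigma, spec$rho, spec$family)
    xy <- switch(spec$sign_pattern,
      "unconstrained" = xy,
      "++" = xy,
      "--" = -xy,
      "+-" = cbind(xy[, 1], -xy[, 2])
    )
    sw <- stats::runif(n) < 0.5                 # fair-coin orientation
    xy[sw, ] <- xy[sw, c(2, 1), drop = FALSE]
    A[ut[link, , drop = FALSE]] <- xy[, 1]
    A[ut[link, c(2, 1), drop = FALSE]] <- xy[, 2]
  }
  diag(A) <- spec$d
  interaction_matrix(A)
}

#' Pooled off-diagonal moments implied by an ensemble specification
#'
#' Connectance reduction: with entries absent with probability 1 - C and
#' realized pairs carrying mean mu, variance sigma^2 and correlation rho,
#' the moments pooled over all off-diagonal entries (zeros included) are
#'
#'   E1 = C mu
#'   E2 = C (sigma^2 + mu^2) - (C mu)^2
#'   Ec = (rho sigma^2 + (1 - C) mu^2) / (sigma^2 + (1 - C) mu^2)
#'
#' (for the unconstrained and sign-respecting patterns; the `"+-"` pattern
#' pools to mean zero with Ec = -(mu^2 + rho sigma^2)/(mu^2 + sigma^2)).
#'
#' @param spec an [ensemble_spec()].
#' @return List with `E1`, `E2`, `Ec` (`Ec` is `NA` when `E2 = 0`).
#' @export
analytic_moments <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  C <- spec$C; mu <- spec$mu; s2 <- spec$sigma^2; rho <- spec$rho
  out <- switch(spec$sign_pattern,
    "unconstrained" = ,
    "++" = list(
      E1 = C * mu,
      E2 = C * (s2 + mu^2) - (C * mu)^2,
      cov = C * (rho * s2 + mu^2) - (C * mu)^2
    ),
    "--" = list(
      E1 = -C * mu,
      E2 = C * (s2 + mu^2) - (C * mu)^2,
      cov = C * (rho * s2 + mu^2) - (C * mu)^2
    ),
    "+-" = list(
      E1 = 0,
      E2 = C * (s2 + mu^2),
      cov = -C * (mu^2 + rho * s2)
    )
  )
  list(
    E1 = out$E1,
    E2 = out$E2,
    Ec = if (out$E2 > 0) out$cov / out$E2 else NA_real_
  )
}

# ---------------------------------------------------------------------------
# Adjacency structures

new_adjacency <- function(kind, m, names_rows = NULL, names_cols = NULL) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  m[m != 0] <- 1
  if (kind == "bipartite") {
    structure(list(kind = "bipartite", incidence = m,
                   S_A = nrow(m), S_P = ncol(m), S = nrow(m) + ncol(m),
                   row_names = names_rows, col_names = names_cols),
              class = "adjacency_network")
  } else {
    stopifnot(nrow(m) == ncol(m))
    structure(list(kind = "directed", matrix = m, S = nrow(m),
                   names = names_rows),
              class = "adjacency_network")
  }
}

#' @export
print.adjacency_network <- function(x, ...) {
  if (x$kind == "bipartite") {
    cat(sprintf("bipartite network: %d x %d guilds, %d links\n",
                x$S_A, x$S_P, sum(x$incidence)))
  } else {
    cat(sprintf("directed network: S = %d, %d links\n", x$S, sum(x$matrix)))
  }
  invisible(x)
}

n_links <- function(net) {
  if (net$kind == "bipartite") sum(net$incidence) else sum(net$matrix)
}

#' Random bipartite adjacency (Erdos-Renyi incidence)
#'
#' Each of the `S_A * S_P` possible animal-plant links is present
#' independently with probability `C`.
#'
#' @param S_A,S_P guild sizes (animals and plants).
#' @param C connectance in `[0, 1]`.
#' @param seed optional integer seed.
#' @return A bipartite `adjacency_network`.
#' @export
sample_bipartite_adjacency <- function(S_A, S_P, C, seed = NULL) {
  stopifnot(S_A >= 1, S_P >= 1, C >= 0, C <= 1)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  m <- matrix(as.numeric(stats::runif(S_A * S_P) < C), S_A, S_P)
  new_adjacency("bipartite", m)
}

#' Cascade-model food web
#'
#' Species are ranked 1..S; for each pair i < j the higher-ranked species j
#' consumes i with probability `C`, so the adjacency (L_ij = 1 when j
#' consumes i) is strictly upper-triangular and acyclic.
#'
#' @param S species count.
#' @param C link probability.
#' @param seed optional integer seed.
#' @return A directed `adjacency_network`.
#' @export
cascade_adjacency <- function(S, C, seed = NULL) {
  stopifnot(S >= 1, C >= 0, C <= 1)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  L <- matrix(0, S, S)
  if (S >= 2) {
    ut <- upper.tri(L)
    L[ut] <- as.numeric(stats::runif(sum(ut)) < C)
  }
  new_adjacency("directed", L)
}

#' Randomize an adjacency network
#'
#' `mode = "links"` redraws link positions uniformly, preserving guild sizes
#' and the exact link count; for directed webs the links are placed on
#' distinct unordered pairs with random orientation, so no self-loops or
#' 2-cycles are created. `mode = "degree"` preserves both degree sequences:
#' bipartite networks use curveball trades (via \pkg{vegan}); directed
#' networks use checkerboard swaps that reject any swap creating a self-loop,
#' a duplicate link or a 2-cycle.
#'
#' @param net an `adjacency_network`.
#' @param mode `"links"` or `"degree"`.
#' @param seed optional integer seed.
#' @param n_swaps successful swaps to perform in degree mode (default
#'   `10 *` link count).
#' @return A randomized `adjacency_network`.
#' @export
randomize_adjacency <- function(net, mode = c("links", "degree"),
                                seed = NULL, n_swaps = NULL) {
  stopifnot(inherits(net, "adjacency_network"))
  mode <- match.arg(mode)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  if (mode == "links") {
    nl <- n_links(net)
    if (net$kind == "bipartite") {
      m <- matrix(0, net$S_A, net$S_P)
      m[sample.int(length(m), nl)] <- 1
      return(new_adjacency("bipartite", m))
    }
    S <- net$S
    upper <- matrix(0, S, S)
    pos <- sample(which(upper.tri(upper)), nl)
    flip <- stats::runif(nl) < 0.5
    upper[pos[!flip]] <- 1
    lower <- matrix(0, S, S)
    lower[pos[flip]] <- 1
    return(new_adjacency("directed", upper + t(lower)))
  }
  # degree-preserving
  if (net$kind == "bipartite") {
    nm <- vegan::nullmodel(net$incidence, "curveball")
    sim <- stats::simulate(nm, nsim = 1,
                           seed = if (is.null(seed)) NULL else as.integer(seed))
    return(new_adjacency("bipartite", sim[, , 1]))
  }
  L <- net$matrix
  links <- which(L == 1, arr.ind = TRUE)
  nl <- nrow(links)
  if (nl < 2) return(new_adjacency("directed", L))
  n_swaps <- n_swaps %||% (10L * nl)
  max_attempts <- 200L * n_swaps
  done <- 0L
  attempts <- 0L
  while (done < n_swaps) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("degree-preserving randomization failed: swap acceptance too low after ",
           max_attempts, " attempts")
    }
    pick <- sample.int(nl, 2)
    i1 <- links[pick[1], 1]; j1 <- links[pick[1], 2]
    i2 <- links[pick[2], 1]; j2 <- links[pick[2], 2]
    # propose (i1,j2), (i2,j1); reject loops, duplicates, 2-cycles
    if (i1 == j2 || i2 == j1) next
    if (L[i1, j2] == 1 || L[i2, j1] == 1) next
    if (L[j2, i1] == 1 || L[j1, i2] == 1) next
    L[i1, j1] <- 0; L[i2, j2] <- 0
    L[i1, j2] <- 1; L[i2, j1] <- 1
    links[pick[1], ] <- c(i1, j2)
    links[pick[2], ] <- c(i2, j1)
    done <- done + 1L
  }
  new_adjacency("directed", L)
}

#' Remove cannibalistic loops
#'
#' @param net a directed `adjacency_network`.
#' @return The network with a zero diagonal.
#' @export
strip_cannibalism <- function(net) {
  stopifnot(inherits(net, "adjacency_network"))
  if (net$kind != "directed") return(net)
  L <- net$matrix
  diag(L) <- 0
  out <- new_adjacency("directed", L, names_rows = net$names)
  out
}

#' Largest connected component of a network
#'
#' Components are computed on the undirected support graph (for bipartite
#' networks, the union graph over both guilds); species outside the largest
#' component are dropped.
#'
#' @param net an `adjacency_network`.
#' @return The restricted network, with an attribute `index_map`: for
#'   bipartite networks a list with the retained `rows` and `cols` indices of
#'   the original incidence, for directed networks the retained species
#'   indices.
#' @export
largest_connected_component <- function(net) {
  stopifnot(inherits(net, "adjacency_network"))
  if (n_links(net) == 0) stop("empty network: no connected component with links")
  if (net$kind == "bipartite") {
    g <- igraph::graph_from_biadjacency_matrix(net$incidence)
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    rows <- keep[keep <= net$S_A]
    cols <- keep[keep > net$S_A] - net$S_A
    out <- new_adjacency("bipartite",
                         net$incidence[rows, cols, drop = FALSE])
    attr(out, "index_map") <- list(rows = rows, cols = cols)
    return(out)
  }
  g <- igraph::graph_from_adjacency_matrix(net$matrix, mode = "directed")
  comp <- igraph::components(g, mode = "weak")
  keep <- which(comp$membership == which.max(comp$csize))
  out <- new_adjacency("directed", net$matrix[keep, keep, drop = FALSE])
  attr(out, "index_map") <- keep
  out
}

# ---------------------------------------------------------------------------
# Parameterization of structured networks

#' Specify a parameterization of a structured network
#'
#' Interaction strengths are drawn blockwise from bivariate normals whose
#' variance follows the squared-coefficient-of-variation convention
#' variance = cv * mean^2 per block. The beneficial mean is calibrated to the
#' stability boundary: mu_plus = scale * mu_max, where [mu_max()] is the
#' largest beneficial mean still giving a negative definite matrix, so
#' scale in (0, 1) guarantees negative definiteness by construction. The
#' detrimental mean is mu_minus = -mu_ratio * mu_plus.
#'
#' @param mu_ratio |mu_minus| / mu_plus (>= 0; 0 suppresses the detrimental
#'   or competitive block means).
#' @param cv squared-CV coefficient: block variance is `cv * mean^2`.
#' @param rho within-pair correlation of the two directions of a link.
#' @param scale fraction of `mu_max` at which `mu_plus` is set; values >= 1
#'   leave the guaranteed negative-definite region.
#' @param seed optional integer seed.
#' @return A `parameterization_spec` list.
#' @export
parameterization_spec <- function(mu_ratio = 0.5, cv = 0.5, rho = 0,
                                  scale = 0.25, seed = NULL) {
  stopifnot(mu_ratio >= 0, cv >= 0, abs(rho) <= 1, scale > 0)
  structure(
    list(mu_ratio = mu_ratio, cv = cv, rho = rho, scale = scale, seed = seed),
    class = "parameterization_spec"
  )
}

#' Calibrate the maximal beneficial interaction strength
#'
#' For a template matrix built at unit beneficial mean (diagonal 0, every
#' block mean proportional to mu_plus), the largest eigenvalue of the
#' symmetric part is linear in mu_plus, so the stability boundary is at
#' mu_max = |d| / lambda_max((B + B')/2). Returns `Inf` when the template's
#' symmetric part has no positive eigenvalue (the matrix is negative definite
#' at any scale).
#'
#' @param template square matrix with zero diagonal, drawn at unit scale.
#' @param d diagonal self-regulation that will be installed (d < 0).
#' @return Scalar mu_max.
#' @export
mu_max <- function(template, d = -1) {
  template <- check_square(template, "template")
  if (any(diag(template) != 0)) {
    stop("`template` must have a zero diagonal (the diagonal is installed separately)")
  }
  stopifnot(d < 0)
  lam <- max(eigen((template + t(template)) / 2, symmetric = TRUE,
                   only.values = TRUE)$values)
  if (lam <= 0) Inf else abs(d) / lam
}

# Dense within-guild block of pair draws: mean m, sd s, correlation rho.
dense_pair_block <- function(n, m, s, rho) {
  W <- matrix(0, n, n)
  if (n >= 2) {
    ut <- which(upper.tri(W), arr.ind = TRUE)
    z1 <- stats::rnorm(nrow(ut)); z2 <- stats::rnorm(nrow(ut))
    W[ut] <- m + s * z1
    W[ut[, c(2, 1), drop = FALSE]] <- m + s * (rho * z1 + sqrt(1 - rho^2) * z2)
  }
  W
}

#' Parameterize a mutualistic (bipartite) network
#'
#' Builds the full S x S interaction matrix over (animals, plants): dense
#' within-guild competition blocks with pairs drawn from a bivariate normal
#' at mean mu_minus (the adjacency carries no information about within-guild
#' interactions), and mutualistic cross blocks masked entrywise by the
#' incidence matrix and its transpose, the two directions of each realized
#' link drawn jointly at mean mu_plus. Variances are `cv * mean^2` per block
#' and the correlation `rho` couples the two members of every pair. The
#' whole off-diagonal structure is drawn at unit scale, `mu_plus` is set to
#' `scale * mu_max` (see [mu_max()]), the template is rescaled, and the
#' diagonal is fixed at -1.
#'
#' @param net a bipartite `adjacency_network` (rows = animals).
#' @param spec a [parameterization_spec()].
#' @param seed optional integer seed overriding `spec$seed`.
#' @return An [interaction_matrix()] with species ordered animals first, and
#'   attributes `mu_plus`, `mu_minus`, `mu_max`.
#' @export
parameterize_mutualistic <- function(net, spec, seed = NULL) {
  stopifnot(inherits(net, "adjacency_network"), inherits(spec, "parameterization_spec"))
  if (net$kind != "bipartite") stop("`net` must be bipartite")
  seed <- seed %||% spec$seed
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  SA <- net$S_A; SP <- net$S_P; S <- SA + SP
  Lb <- net$incidence
  s_minus <- sqrt(spec$cv) * spec$mu_ratio      # |mu_minus| = mu_ratio at unit scale
  s_plus <- sqrt(spec$cv)
  WA <- dense_pair_block(SA, -spec$mu_ratio, s_minus, spec$rho)
  WP <- dense_pair_block(SP, -spec$mu_ratio, s_minus, spec$rho)
  WAP <- matrix(0, SA, SP)
  WPA <- matrix(0, SP, SA)
  links <- which(Lb == 1, arr.ind = TRUE)
  if (nrow(links) > 0) {
    z1 <- stats::rnorm(nrow(links)); z2 <- stats::rnorm(nrow(links))
    WAP[links] <- 1 + s_plus * z1
    WPA[links[, c(2, 1), drop = FALSE]] <-
      1 + s_plus * (spec$rho * z1 + sqrt(1 - spec$rho^2) * z2)
  }
  template <- rbind(cbind(WA, WAP), cbind(WPA, WP))
  diag(template) <- 0
  mmax <- mu_max(template, d = -1)
  mu_plus <- if (is.finite(mmax)) spec$scale * mmax else 0
  A <- mu_plus * template
  diag(A) <- -1
  if (spec$scale >= 1) {
    nd <- is_negative_definite(A)
    warning(sprintf("scale >= 1 leaves the guaranteed stability region (margin = %.3g)", nd$margin))
  }
  out <- interaction_matrix(A, guilds = c(rep("animal", SA), rep("plant", SP)))
  attr(out, "mu_plus") <- mu_plus
  attr(out, "mu_minus") <- -spec$mu_ratio * mu_plus
  attr(out, "mu_max") <- mmax
  out
}

#' Parameterize a food web
#'
#' For each trophic link (species j consumes species i, L_ij = 1) the pair
#' (effect of prey on predator A_ji, effect of predator on prey A_ij) is
#' drawn from a bivariate normal with marginal means (mu_plus, mu_minus),
#' variances `cv * mean^2` and correlation `rho`; off-diagonal entries not on
#' a link are zero and the diagonal is -1. As for mutualistic networks the
#' template is drawn at unit scale and mu_plus is calibrated to
#' `scale * mu_max`. The web must be free of self-loops and 2-cycles (a
#' predator-prey pair interacting in both directions would make the two
#' blocks collide); see [strip_cannibalism()].
#'
#' @param net a directed `adjacency_network`.
#' @param spec a [parameterization_spec()].
#' @param seed optional integer seed overriding `spec$seed`.
#' @return An [interaction_matrix()] with attributes `mu_plus`, `mu_minus`,
#'   `mu_max`.
#' @export
parameterize_foodweb <- function(net, spec, seed = NULL) {
  stopifnot(inherits(net, "adjacency_network"), inherits(spec, "parameterization_spec"))
  if (net$kind != "directed") stop("`net` must be a directed food web")
  L <- net$matrix
  if (any(diag(L) != 0)) {
    stop("cannibalistic loops present; apply strip_cannibalism() first")
  }
  if (any(L == 1 & t(L) == 1)) {
    stop("2-cycles present (pairs linked in both directions); resolve or strip them before parameterizing")
  }
  seed <- seed %||% spec$seed
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  S <- net$S
  template <- matrix(0, S, S)
  links <- which(L == 1, arr.ind = TRUE)   # (i = prey, j = consumer)
  if (nrow(links) > 0) {
    z1 <- stats::rnorm(nrow(links)); z2 <- stats::rnorm(nrow(links))
    gain <- 1 + sqrt(spec$cv) * z1
    loss <- -spec$mu_ratio +
      sqrt(spec$cv) * spec$mu_ratio * (spec$rho * z1 + sqrt(1 - spec$rho^2) * z2)
    template[links[, c(2, 1), drop = FALSE]] <- gain   # A_ji: prey benefits predator
    template[links] <- loss                            # A_ij: predator costs prey
  }
  mmax <- mu_max(template, d = -1)
  mu_plus <- if (is.finite(mmax)) spec$scale * mmax else 0
  A <- mu_plus * template
  diag(A) <- -1
  if (spec$scale >= 1) {
    nd <- is_negative_definite(A)
    warning(sprintf("scale >= 1 leaves the guaranteed stability region (margin = %.3g)", nd$margin))
  }
  out <- interaction_matrix(A)
  attr(out, "mu_plus") <- mu_plus
  attr(out, "mu_minus") <- -spec$mu_ratio * mu_plus
  attr(out, "mu_max") <- mmax
  out
}

#' Standard parameterization sweep
#'
#' The default grid crosses mu_ratio in {0.5, 2}, cv in {0.5, 2}, rho in
#' {-0.9, -0.5, 0, 0.5, 0.9} and scale in {0.25, 0.75}, plus the
#' mu_ratio = 0 rows (no detrimental means); every argument can be replaced
#' to run a custom sweep.
#'
#' @param mu_ratio,cv,rho,scale vectors of values to cross.
#' @param include_zero_ratio also append the mu_ratio = 0 combinations.
#' @return A data frame, one row per parameterization.
#' @export
parameter_grid <- function(mu_ratio = c(0.5, 2), cv = c(0.5, 2),
                           rho = c(-0.9, -0.5, 0, 0.5, 0.9),
                           scale = c(0.25, 0.75), include_zero_ratio = TRUE) {
  g <- expand.grid(mu_ratio = mu_ratio, cv = cv, rho = rho, scale = scale,
                   KEEP.OUT.ATTRS = FALSE)
  if (include_zero_ratio && !0 %in% mu_ratio) {
    g0 <- expand.grid(mu_ratio = 0, cv = cv, rho = rho, scale = scale,
                      KEEP.OUT.ATTRS = FALSE)
    g <- rbind(g, g0)
  }
  g
}
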