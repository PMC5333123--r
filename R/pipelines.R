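# End-to-end workflows: ensemble sweeps over coarse-grained parameters and
# the empirical-network pipeline (parameterize, estimate, compare to nulls).

#' Sweep the feasibility volume over a random-ensemble grid
#'
#' For every grid row and replicate: sample an interaction matrix, screen
#' negative definiteness, and compute ln Xi (quasi-Monte Carlo estimator and
#' both analytic approximations) together with the side-length moments.
#' Cells whose sample fails the negative-definiteness screen are recorded
#' as skipped rows (`skipped = TRUE`, reason in `note`), never dropped, so
#' `nrow(grid) * n_replicates` always reconciles with the output rows.
#'
#' @param grid data frame with columns `S`, `C`, `mu`, `sigma`, `rho` and
#'   optionally `family`, `sign_pattern`, `d`.
#' @param n_replicates matrices per grid row.
#' @param n_points,n_qmc_replicates settings passed to [xi_orthant()].
#' @param seed master seed; per-cell streams are split deterministically so
#'   row order does not affect the draws.
#' @return Tidy data frame, one row per (cell, replicate).
#' @export
run_ensemble_sweep <- function(grid, n_replicates = 1, n_points = 2^13,
                               n_qmc_replicates = 6, seed = 1) {
  stopifnot(is.data.frame(grid),
            all(c("S", "C", "mu", "sigma", "rho") %in% names(grid)))
  rows <- vector("list", nrow(grid) * n_replicates)
  idx <- 0L
  for (g in seq_len(nrow(grid))) {
    cell <- grid[g, ]
    spec <- ensemble_spec(
      S = cell$S, C = cell$C, mu = cell$mu, sigma = cell$sigma, rho = cell$rho,
      family = as.character(cell$family %||% "bivariate-normal"),
      sign_pattern = as.character(cell$sign_pattern %||% "unconstrained"),
      d = cell$d %||% -1
    )
    mom <- analytic_moments(spec)
    for (rep in seq_len(n_replicates)) {
      idx <- idx + 1L
      sub <- split_seed(seed, (g - 1L) * n_replicates + rep)
      A <- sample_random_matrix(spec, seed = sub)
      nd <- is_negative_definite(A)
      base <- data.frame(
        cell = g, replicate = rep, S = spec$S, C = spec$C, mu = spec$mu,
        sigma = spec$sigma, rho = spec$rho, family = spec$family,
        E1 = mom$E1, E2 = mom$E2, Ec = mom$Ec %||% NA_real_,
        margin = nd$margin, seed = sub
      )
      if (!nd$negative_definite) {
        rows[[idx]] <- cbind(base, data.frame(
          skipped = TRUE, ln_xi = NA_real_, stderr_ln = NA_real_,
          ln_xi_analytic = NA_real_, ln_xi_refined = NA_real_,
          mean_cos = NA_real_, sd_cos = NA_real_,
          note = "not negative definite"))
        next
      }
      est <- xi_orthant(A, n_points = n_points,
                        n_replicates = n_qmc_replicates,
                        seed = split_seed(sub, 1))
      sh <- cone_shape(A)
      rows[[idx]] <- cbind(base, data.frame(
        skipped = FALSE, ln_xi = est$ln_xi, stderr_ln = est$stderr_ln,
        ln_xi_analytic = xi_analytic(spec$S, spec$d, mom$E1, log = TRUE),
        ln_xi_refined = xi_analytic_refined(spec$S, spec$d, mom$E1, mom$E2,
                                            mom$Ec %||% 0, log = TRUE),
        mean_cos = sh$mean_cos, sd_cos = sh$sd_cos, note = ""))
    }
  }
  do.call(rbind, rows)
}

null_shape_for <- function(net, spec, mode, seed, builder) {
  rnet <- if (mode == "cascade") {
    C <- n_links(net) / (net$S * (net$S - 1) / 2)
    cascade_adjacency(net$S, C, seed = seed)
  } else {
    randomize_adjacency(net, mode = mode, seed = seed)
  }
  A <- builder(rnet, spec, seed = split_seed(seed, 7))
  cone_shape(A)
}

#' Feasibility pipeline for structured (empirical or synthetic) networks
#'
#' For each network, parameterization and replicate: build the interaction
#' matrix with the beneficial mean calibrated to `scale * mu_max`, compute
#' ln Xi (quasi-Monte Carlo), the analytic prediction from the matrix's own
#' pooled moments, the side-length statistics, and standardized shape
#' comparisons against null models (`"links"` and `"degree"` randomizations
#' for all networks, plus the `"cascade"` model for food webs).
#'
#' @param networks named list of `adjacency_network` objects (or paths to
#'   incidence CSV / edge-list TSV files, dispatched on extension).
#' @param grid data frame of parameterizations (see [parameter_grid()]); use
#'   a subset for quick runs.
#' @param n_replicates matrix draws per (network, parameterization).
#' @param nulls null models for the shape comparison.
#' @param n_null replicates per null model (>= 20 for z-scores).
#' @param n_points,n_qmc_replicates settings passed to [xi_orthant()].
#' @param seed master seed.
#' @return Tidy data frame, one row per (network, parameterization,
#'   replicate); non-negative-definite draws are recorded with diagnostics.
#' @export
run_empirical_pipeline <- function(networks, grid = parameter_grid(),
                                   n_replicates = 1,
                                   nulls = c("links", "degree"), n_null = 20,
                                   n_points = 2^13, n_qmc_replicates = 6,
                                   seed = 1) {
  if (!is.list(networks) || inherits(networks, "adjacency_network")) {
    networks <- list(networks)
  }
  networks <- lapply(networks, function(x) {
    if (is.character(x)) {
      if (grepl("\\.csv$", x, ignore.case = TRUE)) read_incidence_csv(x)
      else read_edgelist(x)
    } else x
  })
  if (is.null(names(networks))) names(networks) <- paste0("net", seq_along(networks))
  rows <- list()
  idx <- 0L
  task <- 0L
  for (w in seq_along(networks)) {
    net <- networks[[w]]
    builder <- if (net$kind == "bipartite") parameterize_mutualistic else parameterize_foodweb
    net_nulls <- nulls
    if (net$kind == "directed" && !"cascade" %in% net_nulls) {
      net_nulls <- c(net_nulls, "cascade")
    }
    for (g in seq_len(nrow(grid))) {
      spec <- parameterization_spec(mu_ratio = grid$mu_ratio[g], cv = grid$cv[g],
                                    rho = grid$rho[g], scale = grid$scale[g])
      for (rep in seq_len(n_replicates)) {
        task <- task + 1L
        sub <- split_seed(seed, task)
        A <- builder(net, spec, seed = sub)
        nd <- is_negative_definite(A)
        mom <- empirical_moments(A)
        est <- xi_orthant(A, n_points = n_points,
                          n_replicates = n_qmc_replicates,
                          seed = split_seed(sub, 2))
        sh <- cone_shape(A)
        zs <- lapply(seq_along(net_nulls), function(k) {
          shapes <- lapply(seq_len(n_null), function(b) {
            null_shape_for(net, spec, net_nulls[k],
                           split_seed(sub, 100 + k * n_null + b), builder)
          })
          shape_zscore(sh, shapes)
        })
        names(zs) <- net_nulls
        row <- data.frame(
          network = names(networks)[w], kind = net$kind, S = nrow(A),
          links = n_links(net),
          mu_ratio = spec$mu_ratio, cv = spec$cv, rho = spec$rho,
          scale = spec$scale,
          mu_max = attr(A, "mu_max"), mu_plus = attr(A, "mu_plus"),
          negative_definite = nd$negative_definite, margin = nd$margin,
          E1 = mom$E1, E2 = mom$E2, Ec = mom$Ec,
          ln_xi = est$ln_xi, stderr_ln = est$stderr_ln,
          ln_xi_refined = xi_analytic_refined(nrow(A), mom$d, mom$E1, mom$E2,
                                              if (is.na(mom$Ec)) 0 else mom$Ec,
                                              log = TRUE),
          mean_cos = sh$mean_cos, sd_cos = sh$sd_cos,
          replicate = rep, seed = sub
        )
        for (k in seq_along(net_nulls)) {
          row[[paste0("z_mean_", net_nulls[k])]] <- zs[[k]]$z_mean
          row[[paste0("z_sd_", net_nulls[k])]] <- zs[[k]]$z_sd
        }
        idx <- idx + 1L
        rows[[idx]] <- row
      }
    }
  }
  nms <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (m in setdiff(nms, names(r))) r[[m]] <- NA_real_
    r[nms]
  })
  do.call(rbind, rows)
}
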