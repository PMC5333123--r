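test_that("degenerate specs collapse to their deterministic limits", {
  spec <- ensemble_spec(S = 6, C = 0, mu = 0.3, sigma = 0.1, d = -2)
  expect_equal(unclass(feasdom:::unclass_im(sample_random_matrix(spec, seed = 1))),
               -2 * diag(6))

  spec <- ensemble_spec(S = 20, C = 0.4, mu = 0.3, sigma = 0, rho = 0.7)
  A <- feasdom:::unclass_im(sample_random_matrix(spec, seed = 2))
  off <- A[row(A) != col(A)]
  expect_true(all(off %in% c(0, 0.3)))
  x <- A[upper.tri(A)]; y <- t(A)[upper.tri(A)]
  expect_true(all((x == 0) == (y == 0)))  # pairs realized jointly
})

test_that("sampling is bitwise reproducible under a seed", {
  spec <- ensemble_spec(S = 40, C = 0.3, mu = 0.1, sigma = 0.2, rho = -0.4,
                        family = "uniform", seed = 77)
  expect_identical(sample_random_matrix(spec), sample_random_matrix(spec))
  expect_false(identical(sample_random_matrix(spec, seed = 78),
                         sample_random_matrix(spec, seed = 79)))
})

test_that("sign patterns constrain every realized pair", {
  spec <- ensemble_spec(S = 30, C = 0.5, mu = 0.3, sigma = 0.1, rho = 0.2,
                        family = "uniform", sign_pattern = "+-")
  A <- feasdom:::unclass_im(sample_random_matrix(spec, seed = 4))
  x <- A[upper.tri(A)]; y <- t(A)[upper.tri(A)]
  realized <- x != 0
  expect_true(all(x[realized] * y[realized] < 0))

  spec <- ensemble_spec(S = 30, C = 0.5, mu = 0.3, sigma = 0.1,
                        family = "lognormal", sign_pattern = "++")
  A <- feasdom:::unclass_im(sample_random_matrix(spec, seed = 5))
  expect_true(all(A[row(A) != col(A)] >= 0))

  expect_error(ensemble_spec(S = 10, C = 0.5, mu = 0.3, sigma = 0.1,
                             sign_pattern = "++"), "Gaussian")
  expect_error(ensemble_spec(S = 10, C = 0.5, mu = 0.1, sigma = 0.2,
                             family = "uniform", sign_pattern = "++"),
               "support")
})

test_that("families matched on pooled moments produce matching samples", {
  target <- analytic_moments(ensemble_spec(400, 0.3, 0.1, 0.08, rho = 0.3))
  spec_n <- ensemble_spec(400, 0.3, 0.1, 0.08, rho = 0.3, family = "bivariate-normal")
  # uniform family at full connectance matched to the same pooled moments
  mu_u <- target$E1
  sd_u <- sqrt(target$E2)
  rho_u <- target$Ec
  spec_u <- ensemble_spec(400, 1, mu_u, sd_u, rho = rho_u, family = "uniform")
  mu_check <- analytic_moments(spec_u)
  expect_equal(mu_check$E1, target$E1, tolerance = 1e-12)
  expect_equal(mu_check$E2, target$E2, tolerance = 1e-12)
  expect_equal(mu_check$Ec, target$Ec, tolerance = 1e-12)

  emp_n <- empirical_moments(sample_random_matrix(spec_n, seed = 6))
  emp_u <- empirical_moments(sample_random_matrix(spec_u, seed = 7))
  n_entries <- 400 * 399
  se <- 3 * sqrt(2 * target$E2 / n_entries)
  expect_lt(abs(emp_n$E1 - emp_u$E1), se)
  expect_lt(abs(emp_n$E2 - emp_u$E2) / target$E2, 0.05)
  expect_lt(abs(emp_n$Ec - emp_u$Ec), 0.06)
})

test_that("connectance reduction has the E1 = C mu identity and C = 1 limits", {
  spec <- ensemble_spec(50, 1, 0.2, 0.1, rho = 0)
  m <- analytic_moments(spec)
  expect_equal(m$E1, 0.2)
  expect_equal(m$Ec * m$E2, 0)
  for (C in c(0.2, 0.7)) {
    m <- analytic_moments(ensemble_spec(50, C, -0.3, 0.2, rho = 0.5))
    expect_equal(m$E1, -C * 0.3)
  }
})

test_that("cascade and bipartite generators have the advertised structure", {
  net <- cascade_adjacency(10, 1, seed = 1)
  expect_equal(net$matrix, upper.tri(matrix(0, 10, 10)) * 1)
  expect_equal(sum(net$matrix), 45)
  expect_equal(sum(cascade_adjacency(10, 0, seed = 1)$matrix), 0)
  expect_equal(sum(sample_bipartite_adjacency(5, 8, 0, seed = 1)$incidence), 0)

  # binomial mean of the link count
  counts <- vapply(1:300, function(s) sum(cascade_adjacency(100, 0.2, seed = s)$matrix),
                   numeric(1))
  n_pairs <- 100 * 99 / 2
  se <- sqrt(n_pairs * 0.2 * 0.8 / 300)
  expect_lt(abs(mean(counts) - 0.2 * n_pairs), 3 * se)
})

test_that("randomizations preserve their invariants", {
  net <- sample_bipartite_adjacency(12, 9, 0.3, seed = 8)
  for (mode in c("links", "degree")) {
    r <- randomize_adjacency(net, mode, seed = 9)
    expect_equal(sum(r$incidence), sum(net$incidence))
    expect_equal(dim(r$incidence), dim(net$incidence))
  }
  r <- randomize_adjacency(net, "degree", seed = 10)
  expect_equal(rowSums(r$incidence), rowSums(net$incidence))
  expect_equal(colSums(r$incidence), colSums(net$incidence))

  fw <- cascade_adjacency(25, 0.25, seed = 11)
  r <- randomize_adjacency(fw, "links", seed = 12)
  expect_equal(sum(r$matrix), sum(fw$matrix))
  expect_true(all(diag(r$matrix) == 0))
  expect_true(!any(r$matrix == 1 & t(r$matrix) == 1))

  r <- randomize_adjacency(fw, "degree", seed = 13)
  expect_equal(rowSums(r$matrix), rowSums(fw$matrix))
  expect_equal(colSums(r$matrix), colSums(fw$matrix))
  expect_true(all(diag(r$matrix) == 0))
  expect_true(!any(r$matrix == 1 & t(r$matrix) == 1))
  expect_false(identical(r$matrix, fw$matrix))
})

test_that("cannibalism stripping and component extraction behave on fixtures", {
  L <- matrix(0, 4, 4)
  L[1, 2] <- 1; L[2, 3] <- 1; diag(L)[1] <- 1
  net <- feasdom:::new_adjacency("directed", L)
  s <- strip_cannibalism(net)
  expect_equal(sum(diag(s$matrix)), 0)
  expect_equal(sum(s$matrix), 2)

  # connected fixture is returned unchanged
  con <- sample_bipartite_adjacency(3, 3, 1, seed = 1)
  expect_equal(largest_connected_component(con)$incidence, con$incidence)

  # the larger of two blocks is retained
  lcc <- largest_connected_component(two_block_bipartite())
  expect_equal(lcc$S_A, 3)
  expect_equal(lcc$S_P, 3)
  expect_equal(attr(lcc, "index_map")$rows, 1:3)

  # an isolated species is dropped
  s <- strip_cannibalism(net)  # species 4 is isolated
  lcc <- largest_connected_component(s)
  expect_equal(lcc$S, 3)
})

test_that("mu_max exploits linearity of the stability margin", {
  expect_equal(mu_max(matrix(c(0, 2, 2, 0), 2), d = -1), 0.5)
  expect_equal(mu_max(matrix(0, 5, 5)), Inf)
  expect_error(mu_max(diag(3)), "zero diagonal")

  net <- sample_bipartite_adjacency(15, 20, 0.25, seed = 14)
  spec <- parameterization_spec(mu_ratio = 0.5, cv = 0.5, rho = 0.5, scale = 0.25)
  A <- parameterize_mutualistic(net, spec, seed = 15)
  mmax <- attr(A, "mu_max")
  template <- feasdom:::unclass_im(A) / attr(A, "mu_plus")
  diag(template) <- 0
  # margin at mu_plus = mu_max is exactly zero
  A_crit <- mmax * template; diag(A_crit) <- -1
  expect_lt(abs(is_negative_definite(A_crit)$margin), 1e-8)
  # margin is affine in mu_plus with slope lambda_max
  lam <- 1 / mmax
  for (mp in c(0.2, 0.6, 0.9) * mmax) {
    Am <- mp * template; diag(Am) <- -1
    expect_equal(is_negative_definite(Am)$margin, -1 + mp * lam,
                 tolerance = 1e-10)
  }
})

test_that("mutualistic parameterization respects the block contract", {
  net <- sample_bipartite_adjacency(10, 14, 0.3, seed = 16)
  spec <- parameterization_spec(mu_ratio = 0.5, cv = 0.5, rho = 0.3, scale = 0.25)
  A <- feasdom:::unclass_im(parameterize_mutualistic(net, spec, seed = 17))
  expect_equal(diag(A), rep(-1, 24))
  cross <- A[1:10, 11:24]
  expect_true(all((cross != 0) == (net$incidence == 1)))
  cross_t <- A[11:24, 1:10]
  expect_true(all((cross_t != 0) == (t(net$incidence) == 1)))

  # no within-guild interactions and deterministic cross entries in the
  # zero-competition, zero-variance limit
  spec0 <- parameterization_spec(mu_ratio = 0, cv = 0, rho = 0, scale = 0.25)
  A0 <- parameterize_mutualistic(net, spec0, seed = 18)
  mp <- attr(A0, "mu_plus")
  A0 <- feasdom:::unclass_im(A0)
  expect_equal(unique(c(A0[1:10, 1:10][upper.tri(matrix(0, 10, 10))])), 0)
  expect_equal(sort(unique(c(A0[1:10, 11:24]))), c(0, mp))
})

test_that("cross-block pair statistics match the prescription", {
  net <- sample_bipartite_adjacency(60, 60, 0.25, seed = 19)
  spec <- parameterization_spec(mu_ratio = 0.5, cv = 0.5, rho = 0.4, scale = 0.25)
  A <- parameterize_mutualistic(net, spec, seed = 20)
  mp <- attr(A, "mu_plus")
  A <- feasdom:::unclass_im(A)
  links <- which(net$incidence == 1, arr.ind = TRUE)
  x <- A[1:60, 61:120][links]
  y <- t(A[61:120, 1:60])[links]
  n <- length(x)
  expect_gt(n, 500)
  sd_th <- sqrt(spec$cv) * mp
  expect_lt(abs(mean(x) - mp), 3 * sd_th / sqrt(n))
  expect_lt(abs(mean(y) - mp), 3 * sd_th / sqrt(n))
  expect_lt(abs(sd(x) - sd_th) / sd_th, 3 / sqrt(2 * n))
  expect_lt(abs(cor(x, y) - spec$rho), 3 * (1 - spec$rho^2) / sqrt(n))
})

test_that("food-web parameterization pairs gains and losses per link", {
  fw <- cascade_adjacency(30, 0.2, seed = 21)
  spec0 <- parameterization_spec(mu_ratio = 0.5, cv = 0, rho = 0, scale = 0.25)
  A <- parameterize_foodweb(fw, spec0, seed = 22)
  mp <- attr(A, "mu_plus")
  A0 <- feasdom:::unclass_im(A)
  links <- which(fw$matrix == 1, arr.ind = TRUE)
  expect_equal(unique(A0[links[, c(2, 1)]]), mp)            # prey -> predator gain
  expect_equal(unique(A0[links]), -0.5 * mp)                # predator -> prey loss
  offlink <- A0; diag(offlink) <- 0
  offlink[links] <- 0; offlink[links[, c(2, 1)]] <- 0
  expect_true(all(offlink == 0))

  fw <- cascade_adjacency(80, 0.2, seed = 23)
  spec <- parameterization_spec(mu_ratio = 0.5, cv = 0.5, rho = 0.5, scale = 0.25)
  A <- feasdom:::unclass_im(parameterize_foodweb(fw, spec, seed = 24))
  links <- which(fw$matrix == 1, arr.ind = TRUE)
  gain <- A[links[, c(2, 1)]]
  loss <- A[links]
  n <- nrow(links)
  expect_lt(abs(cor(gain, loss) - spec$rho), 3 * (1 - spec$rho^2) / sqrt(n))

  # 2-cycles are rejected
  L <- matrix(0, 3, 3); L[1, 2] <- 1; L[2, 1] <- 1
  expect_error(parameterize_foodweb(feasdom:::new_adjacency("directed", L), spec),
               "2-cycle")
})

test_that("positive-mean ensembles beyond the mean-field bound fail the stability screen", {
  # d + S C mu = -1 + 200 * 0.5 * 0.02 = 1 > 0
  spec <- ensemble_spec(200, 0.5, 0.02, 0.01, rho = 0)
  flags <- vapply(1:10, function(s) {
    is_negative_definite(sample_random_matrix(spec, seed = s))$negative_definite
  }, logical(1))
  expect_true(all(!flags))
})

test_that("the default parameterization sweep covers the documented grid", {
  g <- parameter_grid()
  expect_equal(nrow(g), 2 * 2 * 5 * 2 + 2 * 5 * 2)
  expect_setequal(unique(g$rho), c(-0.9, -0.5, 0, 0.5, 0.9))
  expect_setequal(unique(g$scale), c(0.25, 0.75))
  # the sweep is configurable, e.g. to the alternative correlation set
  g2 <- parameter_grid(rho = c(-0.9, 0.5, 0, 0.5, 0.9))
  expect_setequal(unique(g2$rho), c(-0.9, 0, 0.5, 0.9))
})
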