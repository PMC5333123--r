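# feasdom

Geometry of coexistence in generalized Lotka–Volterra communities: how large
is the set of environmental conditions under which all species persist, and
what shape does it have?

For a community of S populations with dynamics

    dn_i/dt = n_i ( r_i + Σ_j A_ij n_j ),

the growth-rate vectors `r` compatible with a feasible equilibrium
(`n* = -A⁻¹ r > 0`) form a convex polyhedral cone generated by the columns
of `-A`. Its normalized solid angle

    Ξ = 2^S · P( isotropic r lies in the cone )

is the community's structural robustness: Ξ = 1 for self-regulated,
non-interacting species, larger when conditions for coexistence are
plentiful, smaller when they are scarce. When `A + Aᵀ` is negative definite
every feasible equilibrium is globally stable, so Ξ fully characterizes
coexistence. The package is written for community ecologists and
theoreticians who want to measure Ξ and the side lengths of the feasibility
cone for random ensembles, for mutualistic (bipartite) networks, and for
food webs.

What it provides:

* **Exact-to-QMC volume**: `xi_orthant()` reduces Ξ to a Gaussian
  positive-orthant probability with covariance `(AᵀA)⁻¹` and evaluates it by
  a log-space randomized lattice rule, resolving Ξ even when the orthant
  probability is ~2⁻²⁰⁰. `xi_sphere_sampling()` is the brute-force oracle.
* **Closed forms**: `xi_analytic(S, d, E1)` — the complexity–feasibility
  relationship for large random communities (Ξ grows with diversity under
  mutualistic means E1 > 0, shrinks under competitive means E1 < 0) — and
  `xi_analytic_refined()` adding variance (E2) and pair-correlation (Ec)
  corrections.
* **Shape**: `cone_shape()`, `side_moments()`, `side_moments_analytic()`,
  `shape_zscore()` — side lengths cos(η_ij) of the spherical simplex, i.e.
  pairwise niche overlap, whose dispersion pinpoints fragile directions.
* **Ensembles and networks**: moment-specified random matrices
  (`ensemble_spec()`, `sample_random_matrix()`), mutualistic and food-web
  parameterizations calibrated to the stability boundary via `mu_max()`,
  cascade and randomization null models, web-of-life-style incidence and
  edge-list readers, and end-to-end pipelines (`run_ensemble_sweep()`,
  `run_empirical_pipeline()`).

## Worked example

```r
library(feasdom)

spec <- ensemble_spec(S = 50, C = 0.3, mu = 0.04, sigma = 0.05, rho = 0.2)
A <- sample_random_matrix(spec, seed = 42)

is_negative_definite(A)$margin
#> [1] -0.2799309                      # < 0: feasible points are globally stable

empirical_moments(A, zero_is_absent = TRUE)
#> moments: S = 50, C = 0.311, d = -1, E1 = 0.01339, E2 = 0.00123, Ec = 0.4293

xi_orthant(A, seed = 1)
#> feasibility volume (orthant-qmc): ln Xi = 23.3706 +/- 0.0139  [Xi = 1.41169e+10, S = 50]

m <- analytic_moments(spec)
xi_analytic(50, -1, m$E1, log = TRUE)
#> [1] 20.93061

cone_shape(A)
#> feasibility-cone shape: S = 50, 1225 sides
#> cos(eta): mean = -0.017176, sd = 0.055947

side_moments_analytic(50, m$E1, m$E2, m$Ec)
#>    mean_cos      sd_cos
#> -0.01609802  0.05340381
```

Reading: this mildly mutualistic community (pooled mean interaction
E1 ≈ 0.013 > 0) has a feasibility domain e²³ ≈ 10¹⁰ times larger than the
non-interacting reference — mutualism at fixed stability margin widens the
range of conditions permitting coexistence, and the closed form predicts the
order of magnitude from three numbers. The side-length moments show a
near-isotropic cone (mean cos η ≈ 0) with modest heterogeneity, matching the
analytic prediction.

The infeasible counterpart: a community where unregulated consumers
outnumber their resources is rank deficient and gets Ξ = 0 — no open set of
conditions supports full coexistence (see `xi_orthant()` on a singular
matrix).

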