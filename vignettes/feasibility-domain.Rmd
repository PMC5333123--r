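---
title: "The feasibility domain of Lotka-Volterra communities: volume, shape, and random-matrix predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The feasibility domain of Lotka-Volterra communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feasdom)
```

## The model and the question

We consider a community of $S$ populations with generalized Lotka-Volterra
dynamics

$$\frac{dn_i}{dt} = n_i\Big(r_i + \sum_j A_{ij} n_j\Big),$$

where $r_i$ is the intrinsic growth rate of population $i$ and $A_{ij}$ the
per-capita effect of population $j$ on population $i$ (entry $(i,j)$
multiplies $n_j$ in the equation of species $i$; this orientation is fixed
throughout the package). A fixed point solves $A n^* = -r$ and is *feasible*
when all $n^*_i > 0$.

Whether a *particular* $r$ supports coexistence is a linear-algebra question.
The structural question addressed here is *how flexibly* $r$ may be chosen:
the set of growth-rate vectors compatible with feasibility is the convex
polyhedral cone generated by the columns of $-A$ (since $r = -A n^*$ with
$n^* > 0$), and its normalized solid angle

$$\Xi = 2^S \cdot \Pr\big(\text{isotropic } r \text{ lies in the cone}\big)$$

measures the fraction of environmental conditions under which the whole
community persists. The factor $2^S$ makes $\Xi = 1$ for self-regulated,
non-interacting communities ($A$ a negative diagonal matrix), which is the
natural reference point. Because membership depends only on the direction of
$r$, $\Xi$ is invariant under rescaling of $r$ and of $A$.

Feasibility is only meaningful when feasible fixed points are actually
reached. The package restricts attention to matrices whose symmetric part
$A + A^\top$ has only negative eigenvalues (negative definiteness in the
generalized sense). In that regime any feasible fixed point is globally
stable, so the geometry of the cone fully answers the coexistence question;
`is_negative_definite()` returns the margin (largest symmetric-part
eigenvalue) used for screening, and `verify_by_integration()` confirms the
dichotomy dynamically with an ODE solver. Diagonal stability with a
non-identity scaling matrix would be a weaker sufficient condition, but no
tractable test for it exists at large $S$, so it is deliberately out of
scope.

## Computing the volume

**Orthant reduction (`xi_orthant`).** Writing the isotropic direction as a
standard Gaussian vector $Z$ and changing variables $n = -A^{-1} Z$, the
cone-membership probability becomes the positive-orthant probability of a
centered Gaussian with covariance $(A^\top A)^{-1}$. The orthant probability
is evaluated by a separation-of-variables scheme: after a Cholesky
factorization, each coordinate is sampled from its conditional truncated
normal by inverse transform, and the product of the conditional tail
probabilities estimates the orthant probability. Integration uses a
randomized rank-1 lattice (Richtmyer generators $\sqrt{p_k}$ with a baker
transform); 8 independent random shifts of $2^{14}$ points are the default,
and the spread across shifts yields the standard error of $\ln \Xi$.

All accumulation happens on the log scale: each lattice point carries
$\sum_k \log$ of its conditional probabilities, combined by log-sum-exp.
This matters because the orthant probability is at most $2^{-S}$ — around
$10^{-30}$ at $S = 100$ — far below what a fixed-precision estimate of the
probability itself could resolve; the $2^S$ normalization is applied as
$S \ln 2$. On diagonal input every conditional probability equals $1/2$
exactly, so $\Xi = 1$ is reproduced to machine precision, and at $S = 2$ the
estimator reproduces the planar closed form
$\Xi = (2/\pi)\arccos\!\big({-2a}/(1+a^2)\big)$ for
$A = \bigl(\begin{smallmatrix} -1 & a \\ a & -1 \end{smallmatrix}\bigr)$
to better than $10^{-4}$.

**Sphere sampling (`xi_sphere_sampling`).** The brute-force hit-or-miss
estimator draws isotropic directions and counts feasible ones. It is exact
in expectation and model-free, which makes it the oracle used in the test
suite to cross-validate the lattice estimator, but its cost grows as $2^S$
hits become rare; it is impractical beyond a few tens of species.

**Degenerate matrices.** When the reciprocal condition number of $A$ falls
below $10^{-12}$ the cone is treated as measure-zero and $\Xi = 0$
(`ln_xi = -Inf`) is reported rather than an error. The canonical example is
a consumer-resource community in which unregulated consumers outnumber the
resources that regulate them: the consumer rows are linearly dependent on
the resource couplings, the matrix is rank deficient, and no open set of
growth rates yields coexistence. Feasible directions of invertible
consumer-resource systems always carry negative growth-rate components for
the consumers, reflecting their dependence on resources.

## Closed-form approximations

For a large random community, $\Xi$ is *universal*: it depends on the
interaction matrix only through $S$, the mean diagonal $d$, and the pooled
off-diagonal moments — mean $E_1$, variance $E_2$, and pair correlation
$E_c$. Pooling is over **all** off-diagonal entries, structural zeros
included, which is exactly the convention under which a random network with
connectance $C$ and interaction-strength mean $\mu$ has $E_1 = C\mu$ (and
$E_2 = C(\sigma^2 + \mu^2) - C^2\mu^2$,
$E_c = (\rho\sigma^2 + (1-C)\mu^2)/(\sigma^2 + (1-C)\mu^2)$, implemented in
`analytic_moments()`). Throughout the package $\sigma$ denotes the standard
deviation of realized interaction strengths; the variance convention is
isolated in `analytic_moments()` so it can be audited in one place.

**First-order form (`xi_analytic`).** Replacing $A$ by its expectation — the
mean-field matrix with every off-diagonal entry equal to $E_1$ — makes
$(A^\top A)^{-1}$ exactly equicorrelated with correlation

$$\rho^*(S, d, E_1) = \frac{-\beta}{\alpha + (S-1)\beta}, \qquad
\alpha = (d - E_1)^2,\quad \beta = E_1\,[\,2(d - E_1) + S E_1\,].$$

For $\rho^* > 0$ (mutualism-dominated means) the equicorrelated orthant
probability has an exact one-factor mixture representation,
$P = \mathbb{E}_z[\Phi(\lambda z)^S]$ with $\lambda^2 = \rho^*/(1-\rho^*)$,
which the package evaluates by a single adaptive one-dimensional
integration. For $\rho^* < 0$ (competition-dominated) no such mixture
exists; the package uses the second-order (Gaussian-tilt) approximation

$$\ln \Xi \approx \frac{S^2 \lambda^2/\pi}{1 + 2S\lambda^2/\pi}
 - \tfrac12 \ln\!\big(1 + 2S\lambda^2/\pi\big),$$

accurate to about 1% of $\ln \Xi$ in the weak-interaction regime (checked
against the lattice estimator at $S = 50$, $|E_1| = 0.005$). Because
$d < 0$, $\Xi$ grows with $S$ when $E_1 > 0$ and shrinks when $E_1 < 0$:
whether diversity and connectance help or hurt coexistence is decided by
the *sign* of the mean interaction strength. For $E_1 > 0$ the formula is
only meaningful inside the stability region $d + S E_1 < 0$ (negative
definiteness fails beyond it in the mean-field picture); a warning is
attached outside it.

**Second-moment refinement (`xi_analytic_refined`).** Two corrections add
the dependence on $E_2$ and $E_c$: the expected Gram matrix
$\mathbb{E}[A^\top A]$, whose diagonal grows by $(S-1)E_2$, shifts the
effective equicorrelation; and the fluctuations of the induced pairwise
correlations, with variance $2E_2(1+E_c)/d^2$ per pair, contribute
$-2S(S-1)E_2(1+E_c)/(\pi^2 d^2)$ to $\ln \Xi$ through the concavity of the
pairwise orthant factor. Interaction variability therefore always shrinks
the feasibility domain. The refinement reduces exactly to the first-order
form as $E_2 \to 0$. Both corrections are perturbative: outside the
weak-interaction regime (large $S E_2 / d^2$, or $E_1$ near the stability
bound) neglected higher-order terms can be comparable to the corrections
themselves, and the quasi-Monte Carlo estimator should be trusted instead.

## Shape: side lengths of the spherical simplex

Two cones of equal volume can respond very differently to perturbations.
On the unit sphere the feasibility domain is a spherical $(S-1)$-simplex
whose vertices are the normalized columns of $-A$; the side length
$\eta_{ij}$ is the angle between vertices $i$ and $j$, and

$$\cos \eta_{ij} = \frac{\langle v_i, v_j \rangle}{\|v_i\|\,\|v_j\|},
\qquad v_k = -A e_k$$

measures how similarly species $i$ and $j$ interact with the whole
community — their niche overlap. Identical interaction profiles collapse a
side to zero length: coexistence of that pair can then be destroyed by an
arbitrarily small growth-rate perturbation along one direction, no matter
how large $\Xi$ is. `cone_shape()` computes the full Gram matrix;
`side_moments()` summarizes it by the mean and population standard
deviation of $\cos\eta$ over unordered pairs. A constructive test in the
suite exhibits two $3$-species matrices tuned (by root-finding on the
lattice estimate) to the same $\Xi$ with very different side-length
dispersion: volume and shape are genuinely independent axes.

**Analytic moments (`side_moments_analytic`).** Unlike the volume, the side
length *distribution* is not universal, but its first two moments again
depend only on $(S, d, E_1, E_2, E_c)$. With $X = \langle v_i, v_j\rangle$
and $Y_i = \|v_i\|^2$, the leading-order moments are

$$\mathbb{E}[\cos\eta] \approx \frac{2dE_1 + (S-2)E_1^2}{d^2 + (S-1)(E_2+E_1^2)},
\qquad
\mathrm{Var}[\cos\eta] \approx \frac{2d^2E_2(1+E_c) + (S-2)\big[(E_2+E_1^2)^2 - E_1^4\big]}{\big[d^2 + (S-1)(E_2+E_1^2)\big]^2}.$$

The implementation carries the delta-method expansion of
$X/\sqrt{Y_i Y_j}$ one order further, using Gaussian moment identities to
express the required third and fourth entry moments through
$(E_1, E_2, E_c)$. This closure is exact for fully connected
bivariate-normal ensembles — where validation places the agreement with
simulation well inside Monte-Carlo error at $S = 200$ — and a sub-percent
refinement for sparse ensembles, whose higher moments deviate from the
closure. The mean changes sign with $E_1$ (for $d<0$): competition pushes
generators apart, mutualism aligns them.

`shape_zscore()` standardizes an observed shape against a null ensemble of
at least 20 randomized replicates; a positive `z_sd` flags a cone more
heterogeneous — more fragile in specific directions — than its null.

## Ensembles and structured networks

`sample_random_matrix()` realizes the pair-level generative model: each
unordered pair is present with probability $C$ and realized pairs are drawn
jointly with mean $\mu$, standard deviation $\sigma$ and within-pair
correlation $\rho$, with the orientation of an asymmetric pair decided by a
fair coin. Three families are provided. The Gaussian family is the
reference; the uniform and lognormal families are coupled through a
Gaussian copula calibrated so that the *marginal* pair correlation equals
$\rho$ exactly, which keeps `analytic_moments()` exact for every family and
makes moment-matched cross-family comparisons (the universality tests)
clean. Sign patterns `++`, `--` and `+-` are supported only for families
whose support already respects them (uniform with $\mu > \sqrt3\,\sigma$,
or lognormal); rejecting the Gaussian family here avoids truncation or
folding that would silently distort the moments.

**Mutualistic networks.** A bipartite incidence matrix (animals x plants)
masks the beneficial cross blocks; within-guild competition blocks are
dense, since the incidence carries no information about within-guild
interactions. Block means are $\mu_+$ (cross) and
$\mu_- = -\texttt{mu\_ratio}\cdot\mu_+$ (within), block variances follow
the squared-coefficient-of-variation convention
$\mathrm{var} = \texttt{cv}\cdot\mathrm{mean}^2$, and $\rho$ couples the two
directions of the *same* link (the partner pair) — the natural reading of a
pairwise draw, applied uniformly to all blocks. The entire off-diagonal
template is drawn at unit scale; because the leading symmetric-part
eigenvalue is then linear in $\mu_+$, the stability boundary
$\mu_{\max} = |d|/\lambda_{\max}$ is obtained from one eigendecomposition
(`mu_max()`), and setting $\mu_+ = \texttt{scale}\cdot\mu_{\max}$ with
`scale` $\in (0,1)$ guarantees negative definiteness by construction (the
margin equals $-(1-\texttt{scale})\,|d|$ exactly). Draws are plain bivariate
normals, not truncated to enforce signs; rare sign violations in the tails
are part of the model.

**Food webs.** Directed adjacency with $L_{ij} = 1$ meaning $j$ consumes
$i$, validated to be free of self-loops (`strip_cannibalism()`) and
2-cycles. Each trophic link draws the pair (gain to the consumer $\sim
\mu_+$, loss to the resource $\sim \mu_-$) jointly with correlation $\rho$;
calibration through $\mu_{\max}$ is identical.

**Null models.** `randomize_adjacency()` offers link-position
randomization (guild sizes and link count preserved; for directed webs the
links are re-placed on distinct unordered pairs with random orientation so
the no-2-cycle invariant survives) and degree-preserving randomization
(curveball trades for bipartite incidences, via vegan; constrained
checkerboard swaps for directed webs, rejecting any swap that would create
a loop, duplicate or 2-cycle). `cascade_adjacency()` provides the ordered
food-web null in which consumers eat only lower-ranked species. The
parameterization sweep of `parameter_grid()` defaults to `mu_ratio` and
`cv` in $\{0.5, 2\}$, `scale` in $\{0.25, 0.75\}$ and $\rho$ in
$\{-0.9, -0.5, 0, 0.5, 0.9\}$; the symmetric correlation set is the
package default (a plausible sign slip in circulating descriptions of this
sweep lists $0.5$ twice and $-0.5$ not at all), and the grid is fully
configurable so either reading can be run.

## Numerical choices

* **Log-space arithmetic everywhere**: $\Xi$ spans $e^{\pm 100}$ at
  $S \sim 100$; all estimators and formulas return or store $\ln \Xi$.
* **Degeneracy threshold**: reciprocal condition number $< 10^{-12}$
  declares $A$ singular; downstream $\Xi = 0$.
* **Feasibility tolerance**: $n^*_i > 10^{-12}\,\|n^*\|_\infty$ counts as
  positive, guarding against round-off at the cone boundary.
* **Dynamics**: `lsoda` with relative tolerance $10^{-10}$; extinction is
  scored below $10^{-8}$ of the initial scale; default horizon $10^3$ time
  units (extended in tests when trajectories decay slowly).
* **QMC defaults**: $8$ randomized shifts of $2^{14}$ lattice points;
  per-replicate seeds are split deterministically from the master seed
  (multiplicative-congruential splitting, kept below $2^{31}$), so results
  are order-independent and bitwise reproducible.
* **Validation problem sizes**: the test suite validates the estimators
  against the planar closed form and against sphere sampling on $50$
  communities with $S \le 15$; universality on moment-matched ensemble
  pairs at $S = 100$ with 20 replicates; the closed forms at $S = 50$,
  $|E_1| = 0.005$; and the side-length moments on fully connected Gaussian
  ensembles at $S = 200$ ($\mu = \pm 0.01$, $\sigma = 0.025$,
  $\rho \in \{0, 0.5\}$) with 50 replicates — weak-interaction conditions
  chosen because they are the stated validity regime of the expansions.

## What the synthetic generators do and do not emulate

The bundled generators produce Erdos-Renyi bipartite incidences, cascade
webs, and moment-specified random matrices. They reproduce the
coarse-grained quantities that the theory says matter — $S$, connectance,
interaction-strength moments, directedness — and they are what the test
suite exercises. They do **not** emulate the degree heterogeneity,
nestedness, modularity, or group structure of real interaction networks;
passing tests therefore demonstrate correctness of the geometry and the
estimators, not that structural effects in real webs are small. Readers
with empirical incidence matrices or edge lists can run the identical
pipeline (`run_empirical_pipeline()`) on their own files through
`read_incidence_csv()` / `read_edgelist()`.

## Known limitations

* Only linear functional responses: $A$ must not depend on $n$.
* Only the negative-definite stability regime; diagonally stable but
  non-negative-definite parameterizations are excluded by the screen.
* The closed-form volume approximations are perturbative; at strong
  coupling (near $\mu_{\max}$, or $S E_2/d^2 \gtrsim 1$) they can err by
  tens of percent and the lattice estimator should be used.
* The negative-correlation branch of `xi_analytic` is itself an
  approximation (~1% of $\ln\Xi$ in the weak regime); an exact closed form
  on that side is not available.
* Degree-preserving randomization of very dense directed webs can fail to
  find admissible swaps; the error is diagnostic, not silent.
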