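# Fixtures built in code: no data files needed.

# Consumer-resource community: S_r self-regulated resources (diagonal -1),
# S_c consumers (diagonal 0) coupled only to resources. With more consumers
# than resources the matrix is rank deficient and the feasibility cone has
# zero measure.
consumer_resource_matrix <- function(S_r = 3, S_c = 4, strength = 0.3,
                                     heterogeneous = FALSE) {
  S <- S_r + S_c
  A <- matrix(0, S, S)
  diag(A)[seq_len(S_r)] <- -1
  for (co in (S_r + 1):S) {
    for (re in seq_len(S_r)) {
      # heterogeneous consumption rates keep the consumer rows independent
      w <- if (heterogeneous) strength * (1 + 0.25 * ((co * re) %% 4)) else strength
      A[co, re] <- w     # resource benefits consumer
      A[re, co] <- -w    # consumer depletes resource
    }
  }
  interaction_matrix(A, guilds = c(rep("resource", S_r), rep("consumer", S_c)))
}

# Weakly competitive random community; negative definite with probability
# ~1 at these strengths (checked, resampled otherwise).
random_nd_matrix <- function(S, seed, mu = -0.05, sigma = 0.05, C = 0.5) {
  for (k in 0:20) {
    spec <- ensemble_spec(S, C, mu, sigma, rho = 0)
    A <- sample_random_matrix(spec, seed = seed + 1000L * k)
    if (is_negative_definite(A)$negative_definite) return(A)
  }
  stop("could not draw a negative definite matrix")
}

# Mean-field matrix: every off-diagonal entry equal to E1.
meanfield_matrix <- function(S, E1, d = -1) {
  A <- matrix(E1, S, S)
  diag(A) <- d
  interaction_matrix(A)
}

# Two disconnected bipartite blocks (3+3 and 2+2) for component tests.
two_block_bipartite <- function() {
  m <- matrix(0, 5, 5)
  m[1:3, 1:3] <- 1
  m[4:5, 4:5] <- 1
  feasdom:::new_adjacency("bipartite", m)
}

expect_joint_3se <- function(est1, est2) {
  se <- sqrt(est1$stderr_ln^2 + est2$stderr_ln^2)
  expect_lt(abs(est1$ln_xi - est2$ln_xi), 3 * max(se, 1e-12))
}
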