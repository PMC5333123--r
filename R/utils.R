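# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic stream splitting: one master seed, per-task sub-seeds.
# Kept below 2^31 - 1 and in exact double arithmetic so parallel or
# out-of-order execution reproduces the same draws.
split_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- as.double(seed) %% 2147483647
  as.integer((s * 48271 + as.double(k) * 1009 + 1) %% 2147483647)
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

# First n primes (square roots form the Richtmyer lattice generators).
first_primes <- function(n) {
  if (n < 1) return(integer(0))
  out <- integer(0)
  x <- 2L
  while (length(out) < n) {
    if (all(x %% out[out * out <= x] != 0L)) out <- c(out, x)
    x <- x + 1L
  }
  out
}

stop_degenerate <- function(msg, rcond = NA_real_, call = sys.call(-1)) {
  stop(errorCondition(
    sprintf("%s (reciprocal condition number = %.3g)", msg, rcond),
    class = c("feasdom_degenerate_error", "feasdom_error"),
    rcond = rcond, call = call
  ))
}

check_square <- function(A, arg = "A") {
  if (inherits(A, "interaction_matrix")) A <- unclass_im(A)
  A <- as.matrix(A)
  if (!is.numeric(A)) stop(sprintf("`%s` must be a numeric matrix", arg))
  if (nrow(A) != ncol(A)) stop(sprintf("`%s` must be square", arg))
  if (any(!is.finite(A))) stop(sprintf("`%s` contains non-finite entries", arg))
  A
}

unclass_im <- function(A) {
  attr(A, "guilds") <- NULL
  class(A) <- NULL
  A
}

check_growth_rates <- function(r, S) {
  r <- as.numeric(r)
  if (length(r) != S) stop("growth-rate vector length must equal S")
  if (any(!is.finite(r))) stop("growth rates must be finite")
  if (all(r == 0)) stop("the zero growth-rate vector has no direction")
  r
}
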