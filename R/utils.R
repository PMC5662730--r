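# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Attenuation of a Gaussian-copula correlation when pushed through Poisson
# margins with mean m: for small latent correlation r, the Pearson correlation
# of the counts is approximately r * c1^2 / m, where c1 = E[X Z] is the first
# Hermite coefficient of X = qpois(pnorm(Z), m).  Computed by quadrature.
poisson_copula_attenuation <- function(m) {
  if (m <= 0) return(1)
  z <- seq(-8, 8, length.out = 4001L)
  x <- stats::qpois(stats::pnorm(z), m)
  c1 <- sum(x * z * stats::dnorm(z)) * (z[2L] - z[1L])
  min(c1^2 / m, 1)
}

# reps x n matrix of equicorrelated Poisson counts with common mean `m` and
# target pairwise Pearson correlation `rho` (within Monte-Carlo error).  The
# latent equicorrelated normals share one common factor per row; the latent
# correlation is inflated to compensate for the copula attenuation.
rpois_equicorr <- function(reps, n, m, rho) {
  if (m < 0) stop("negative Poisson mean")
  if (m == 0) return(matrix(0L, reps, n))
  if (rho <= 0) {
    return(matrix(stats::rpois(reps * n, m), reps, n))
  }
  r <- min(rho / poisson_copula_attenuation(m), 0.99)
  z <- sqrt(r) * stats::rnorm(reps) +
    sqrt(1 - r) * matrix(stats::rnorm(reps * n), reps, n)
  matrix(stats::qpois(stats::pnorm(z), m), reps, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
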