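# Shared fixtures, built in code and cached per test run.

.fixtureCache <- new.env(parent = emptyenv())

# A mid-sized simulated flock reused across files.
testFlock <- function(n = 400, seed = 42) {
  key <- sprintf("flock_%d_%d", n, seed)
  if (is.null(.fixtureCache[[key]])) {
    .fixtureCache[[key]] <- simulateFlock(flockParams(), seed = seed,
                                          nBirds = n)
  }
  .fixtureCache[[key]]
}

# A deterministic noise-free phantom.
testPhantom <- function(noiseSd = 0, haze = 0, seed = 1) {
  makePhantom(phantomSpec(noiseSd = noiseSd, haze = haze, seed = seed))
}

# Draw latent bivariate normal and discretize both margins.
latentOrdinalPair <- function(n, rho, thrX, thrY, seed) {
  set.seed(seed)
  L <- chol(matrix(c(1, rho, rho, 1), 2))
  z <- matrix(stats::rnorm(2 * n), ncol = 2) %*% L
  list(x = findInterval(z[, 1], thrX), y = findInterval(z[, 2], thrY),
       zx = z[, 1], zy = z[, 2])
}

# Independent single-integral bivariate normal CDF used by oracles
# (deliberately not the package's kernel).
oracleBvnCdf <- function(h, k, rho) {
  if (is.infinite(h) && h > 0) return(stats::pnorm(k))
  if (is.infinite(k) && k > 0) return(stats::pnorm(h))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x) {
    stats::dnorm(x) * stats::pnorm((k - rho * x) / s)
  }, -Inf, h, rel.tol = 1e-10)$value
}
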