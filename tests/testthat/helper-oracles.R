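# Independent oracles and small utilities shared by the tests.
# These deliberately re-derive results through different routes than the
# package (plain fixed-point loop, 1-D root bisection, quadrature,
# histogramming) so agreement is evidence, not tautology.

# Plain fixed-point iteration for the self-consistent equations, written
# directly from their definition without log-sum-exp tricks or Newton steps.
# Only suitable for small, well-scaled instances.
fixed_point_oracle <- function(u, counts, tol = 1e-12, max_iter = 2e5,
                               f0 = NULL) {
  K <- nrow(u)
  f <- if (is.null(f0)) rep(0.3, K) else f0
  f <- f - f[1]
  for (it in seq_len(max_iter)) {
    den <- colSums(counts * exp(f - u))
    fn <- -log(as.vector(exp(-u) %*% (1 / den)))
    fn <- fn - fn[1]
    if (max(abs(fn - f)) < tol) return(fn)
    f <- fn
  }
  stop("fixed-point oracle did not converge")
}

# Bennett acceptance-ratio solution as a 1-D root: the sum of state-2
# mixture weights over all pooled samples must equal N2. Monotone in df,
# solved by safeguarded bisection via uniroot.
bar_bisection_oracle <- function(u, counts) {
  h <- function(df) {
    l1 <- log(counts[1]) - u[1, ]
    l2 <- log(counts[2]) + df - u[2, ]
    m <- pmax(l1, l2)
    sum(exp(l2 - m) / (exp(l1 - m) + exp(l2 - m))) - counts[2]
  }
  stats::uniroot(h, c(-500, 500), tol = 1e-13)$root
}

# Offset minimizing the max abs difference between two profiles defined up
# to an additive constant (Chebyshev alignment); returns the aligned max dev.
aligned_max_dev <- function(a, b) {
  d <- a - b
  (max(d) - min(d)) / 2
}

# Histogram PMF (kT, min-shifted) of samples on a bin grid, dropping
# out-of-range samples; the reference-run estimate for reweighting checks.
hist_pmf <- function(z, edges) {
  z <- z[z >= edges[1] & z <= edges[length(edges)]]
  h <- graphics::hist(z, breaks = edges, plot = FALSE)$counts
  p <- -log(h / sum(h))
  p - min(p[is.finite(p)])
}

# Small random MBAR instances (harmonic states, exact draws) for oracle
# equivalence sweeps.
random_instance <- function(K, n_max = 200) {
  sigma <- stats::runif(K, 0.7, 2.5)
  mu <- stats::runif(K, -1, 1)
  counts <- sample(5:n_max, K, replace = TRUE)
  x <- unlist(lapply(seq_len(K), function(i) stats::rnorm(counts[i], mu[i], sigma[i])))
  u <- matrix(0, K, sum(counts))
  for (i in seq_len(K)) u[i, ] <- (x - mu[i])^2 / (2 * sigma[i]^2)
  list(u = u, counts = counts)
}

# Double-well study system shared by the umbrella / scaling / dual-level tests
dw_potential <- function() toy_potential("double_well", height = 2.5, width = 1,
                                         bounds = c(-1.35, 1.35))
beta300 <- beta_from_temperature(300)
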