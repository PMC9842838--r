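#' Toy one-dimensional potentials with known ground truth
#'
#' Analytic potential-energy surfaces used by the synthetic-data generators,
#' chosen so every estimate the package produces can be checked against a
#' closed form or a one-dimensional quadrature. Available forms:
#' \describe{
#'   \item{harmonic}{\eqn{k (z - c)^2}}
#'   \item{double_well}{\eqn{h ((z/w)^2 - 1)^2}: wells at \eqn{\pm w},
#'     barrier height \eqn{h} at \eqn{z = 0}}
#'   \item{periodic_cosine}{\eqn{(h/2)(1 - \cos(2 \pi z / P))}: minima at
#'     multiples of the period P}
#'   \item{table}{linear interpolation of a user (z, U) table}
#' }
#'
#' @param type form tag, see above
#' @param k,center harmonic parameters (kcal/mol per squared CV unit; CV units)
#' @param height barrier height h, kcal/mol
#' @param width well position w, CV units
#' @param period period P, CV units
#' @param z,U table of abscissae and energies for \code{type = "table"}
#' @param bounds domain bounds used by quadrature and samplers
#' @return an object of class \code{"toy_potential"} with an element
#'   \code{fn(z)} evaluating the energy in kcal/mol
#' @export
toy_potential <- function(type = c("harmonic", "double_well",
                                   "periodic_cosine", "table"),
                          k = 1, center = 0, height = 2.5, width = 1,
                          period = 360, z = NULL, U = NULL,
                          bounds = NULL) {
  type <- match.arg(type)
  fn <- switch(type,
    harmonic = {
      force(k); force(center)
      function(zz) k * (zz - center)^2
    },
    double_well = {
      force(height); force(width)
      function(zz) height * ((zz / width)^2 - 1)^2
    },
    periodic_cosine = {
      force(height); force(period)
      function(zz) height / 2 * (1 - cos(2 * pi * zz / period))
    },
    table = {
      if (is.null(z) || is.null(U)) stop("'table' potentials need 'z' and 'U'")
      stats::approxfun(z, U, rule = 2)
    })
  if (is.null(bounds)) {
    bounds <- switch(type,
                     harmonic = center + c(-1, 1) * 30 / sqrt(max(k, 1e-8)),
                     double_well = c(-3, 3) * width,
                     periodic_cosine = c(0, period),
                     table = range(z))
  }
  probe <- seq(bounds[1L], bounds[2L], length.out = 101L)
  if (any(!is.finite(fn(probe)))) stop("potential is not finite on its domain")
  structure(list(type = type, fn = fn, bounds = bounds,
                 period = if (type == "periodic_cosine") period,
                 params = list(k = k, center = center, height = height,
                               width = width, period = period)),
            class = "toy_potential")
}

#' @export
print.toy_potential <- function(x, ...) {
  cat("<toy_potential>", x$type, " on [",
      paste(format(x$bounds, digits = 4), collapse = ", "), "]\n")
  invisible(x)
}

# record generator parameters so every dataset can be regenerated bit-identically
make_manifest <- function(generator, seed, ...) {
  c(list(generator = generator, seed = seed), list(...))
}

#' Exact Gaussian samples from harmonic states
#'
#' Draws N independent samples from each of K Gaussian (harmonic-state)
#' distributions with standard deviations \code{sigma} and means
#' \code{centers}, builds the dimensionless reduced-potential matrix
#' \eqn{u_i(x) = (x - \mu_i)^2 / (2 \sigma_i^2)} on the pooled samples, and
#' returns the analytic free energies
#' \eqn{f_i = -\ln(\sigma_i \sqrt{2\pi})} computed in closed form. This is the
#' exactness oracle for the solver: the estimator's \eqn{\Delta \hat f} must
#' recover the analytic differences within statistical error.
#'
#' @param sigma per-state standard deviations
#' @param centers per-state means (recycled; default 0)
#' @param n samples per state (recycled)
#' @param seed RNG seed
#' @return list with \code{u} (a \code{reduced_potential_matrix}), pooled
#'   samples \code{x}, \code{f_analytic} (anchored to state 1) and a
#'   regeneration \code{manifest}
#' @export
gen_harmonic_states <- function(sigma, centers = 0, n, seed) {
  K <- length(sigma)
  centers <- rep_len(centers, K)
  n <- rep_len(as.integer(n), K)
  stopifnot(all(sigma > 0), all(n >= 1L))
  set.seed(seed)
  x <- unlist(lapply(seq_len(K), function(i) stats::rnorm(n[i], centers[i], sigma[i])))
  u <- matrix(0, K, sum(n))
  for (i in seq_len(K)) u[i, ] <- (x - centers[i])^2 / (2 * sigma[i]^2)
  f <- -log(sigma * sqrt(2 * pi))
  rpm <- structure(list(u = u, counts = n, origin = rep.int(seq_len(K), n),
                        mode = "synthetic", states = NULL),
                   class = "reduced_potential_matrix")
  list(u = rpm, x = x, f_analytic = f - f[1L],
       manifest = make_manifest("gen_harmonic_states", seed, sigma = sigma,
                                centers = centers, n = n))
}

#' Exact independent Boltzmann samples from a 1-D toy potential
#'
#' Draws independent samples from \eqn{p(z) \propto e^{-\beta [U(z) +
#' U_{restraint}(z)]}} on the potential's (bounded) domain by inverse-CDF
#' lookup on a fine grid. This honors the estimator's premise of uncorrelated
#' samples exactly, so the synthetic fixtures carry no hidden autocorrelation;
#' \code{\link{mcmc_sample}} is the alternative when a correlated
#' trajectory-like series is wanted.
#'
#' @param potential a \code{\link{toy_potential}} with finite bounds
#' @param beta inverse temperature, 1/(kcal/mol)
#' @param n number of samples
#' @param restraint optional list \code{(spring_k, z_ref, periodic)}, added in
#'   the \eqn{k (\Delta z)^2} convention
#' @param grid_n grid resolution for the inverse CDF
#' @return numeric vector of n independent samples
#' @export
sample_boltzmann <- function(potential, beta, n, restraint = NULL,
                             grid_n = 20001L) {
  stopifnot(inherits(potential, "toy_potential"), n >= 1L)
  b <- potential$bounds
  if (!all(is.finite(b))) stop("'potential' must have finite bounds")
  grid <- seq(b[1L], b[2L], length.out = grid_n)
  e <- potential$fn(grid)
  if (!is.null(restraint))
    e <- e + restraint_energy(restraint$spring_k, grid, restraint$z_ref,
                              restraint$periodic)
  lw <- -beta * e
  w <- exp(lw - max(lw))
  cdf <- cumsum(w)
  cdf <- cdf / cdf[length(cdf)]
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approx(cdf[keep], grid[keep], stats::runif(n), rule = 2)$y
}

#' Metropolis sampling of a toy potential
#'
#' Simple Metropolis chain targeting
#' \eqn{\exp(-\beta [U(z) + U_{restraint}(z)])} with uniform step proposals,
#' standing in for the biased MD trajectories the estimator normally consumes.
#' Burn-in is discarded and the chain is thinned by \code{stride} so the
#' exported samples are approximately decorrelated.
#'
#' @param potential a \code{\link{toy_potential}}
#' @param beta inverse temperature, 1/(kcal/mol)
#' @param n number of exported samples
#' @param restraint optional list \code{(spring_k, z_ref, periodic)} added to
#'   the potential in the \eqn{k (\Delta z)^2} convention
#' @param step_size half-width of the uniform proposal
#' @param burn_in discarded initial steps
#' @param stride thinning stride between exported samples
#' @param x0 starting point (defaults to restraint center or domain midpoint)
#' @param seed RNG seed
#' @return numeric vector of n samples with attributes \code{acceptance}
#'   (acceptance rate) and \code{manifest}
#' @details Proposals outside the potential's domain bounds are rejected
#'   (hard walls), so the chain targets the same bounded density as
#'   \code{\link{sample_boltzmann}} and the quadrature references.
#' @export
mcmc_sample <- function(potential, beta, n, restraint = NULL,
                        step_size = 0.25, burn_in = 500L, stride = 10L,
                        x0 = NULL, seed = NULL) {
  stopifnot(inherits(potential, "toy_potential"), step_size > 0, n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  energy <- function(z) {
    e <- potential$fn(z)
    if (!is.null(restraint))
      e <- e + restraint_energy(restraint$spring_k, z, restraint$z_ref,
                                restraint$periodic)
    e
  }
  if (is.null(x0))
    x0 <- if (!is.null(restraint)) restraint$z_ref[1L] else mean(potential$bounds)
  n_steps <- burn_in + n * stride
  # pre-drawn proposals/uniforms keep the R loop tight
  prop <- stats::runif(n_steps, -step_size, step_size)
  logu <- log(stats::runif(n_steps))
  out <- numeric(n)
  x <- x0
  e <- energy(x)
  acc <- 0L
  j <- 0L
  b <- potential$bounds
  for (t in seq_len(n_steps)) {
    xn <- x + prop[t]
    if (xn >= b[1L] && xn <= b[2L]) {
      en <- energy(xn)
      if (logu[t] < -beta * (en - e)) {
        x <- xn; e <- en; acc <- acc + 1L
      }
    }
    if (t > burn_in && (t - burn_in) %% stride == 0L) {
      j <- j + 1L
      out[j] <- x
    }
  }
  attr(out, "acceptance") <- acc / n_steps
  attr(out, "manifest") <- make_manifest("mcmc_sample", seed,
                                         potential = potential$type,
                                         beta = beta, n = n,
                                         step_size = step_size,
                                         burn_in = burn_in, stride = stride)
  out
}

#' Independent samples along a temperature ladder
#'
#' Draws exact independent samples at each inverse temperature of a ladder
#' (state 1 = lowest temperature = largest beta) and records the system
#' potential energy of every sample, the input the scaling-mode estimator
#' needs. Betas must be strictly decreasing (temperatures increasing).
#'
#' @param potential a \code{\link{toy_potential}} with finite bounds
#' @param betas strictly decreasing inverse temperatures, 1/(kcal/mol)
#' @param n samples per temperature (recycled)
#' @param seed RNG seed
#' @return list of \code{\link{sample_set}}s (cv = position, energy column
#'   \code{U_system}) with a \code{manifest} attribute
#' @export
gen_temperature_ladder <- function(potential, betas, n, seed) {
  if (any(diff(betas) >= 0))
    stop("'betas' must be strictly decreasing (temperature increasing)")
  K <- length(betas)
  n <- rep_len(as.integer(n), K)
  set.seed(seed)
  sets <- lapply(seq_len(K), function(i) {
    z <- sample_boltzmann(potential, beta = betas[i], n = n[i])
    sample_set(origin = i, cv = z,
               energies = data.frame(U_system = potential$fn(z)))
  })
  attr(sets, "manifest") <- make_manifest("gen_temperature_ladder", seed,
                                          potential = potential$type,
                                          betas = betas, n = n)
  sets
}

#' Synthetic alchemical perturbation chain
#'
#' Draws exact independent samples from each mixed state
#' \eqn{U_\lambda = (1-\lambda) U_{start} + \lambda U_{end}} of a coupling
#' schedule, evaluates the neighbor reduced energies exactly from the
#' analytic potentials, and computes the reference free-energy difference of
#' every neighbor pair by one-dimensional quadrature of
#' \eqn{-\ln \int e^{-\beta U_\lambda} dz}.
#'
#' @param U_start,U_end \code{\link{toy_potential}}s at coupling 0 and 1
#' @param lambdas increasing schedule in [0, 1]
#' @param beta inverse temperature, 1/(kcal/mol)
#' @param n samples per state (recycled)
#' @param seed RNG seed
#' @param full_matrix if \code{TRUE}, also return the full K x N
#'   reduced-potential matrix over the pooled samples (for cross-checking the
#'   chain against the simultaneous multi-state solution)
#' @return list with \code{sets} (list of \code{\link{neighbor_energy_set}}s),
#'   \code{delta_f_ref} (per-pair quadrature reference), \code{total_ref},
#'   optionally \code{u_full} and \code{counts}, plus a \code{manifest}
#' @export
gen_fep_chain <- function(U_start, U_end, lambdas, beta, n, seed,
                          full_matrix = FALSE) {
  stopifnot(all(lambdas >= 0), all(lambdas <= 1), !is.unsorted(lambdas, strictly = TRUE))
  K <- length(lambdas)
  n <- rep_len(as.integer(n), K)
  mix <- function(lam) function(z) (1 - lam) * U_start$fn(z) + lam * U_end$fn(z)
  lo <- min(U_start$bounds[1L], U_end$bounds[1L])
  hi <- max(U_start$bounds[2L], U_end$bounds[2L])
  zg <- seq(lo, hi, length.out = 2001L)
  set.seed(seed)
  samples <- vector("list", K)
  for (i in seq_len(K)) {
    pot_i <- toy_potential("table", z = zg, U = mix(lambdas[i])(zg),
                           bounds = c(lo, hi))
    samples[[i]] <- sample_boltzmann(pot_i, beta = beta, n = n[i])
  }
  sets <- lapply(seq_len(K), function(i) {
    z <- samples[[i]]
    neighbor_energy_set(i, u_self = beta * mix(lambdas[i])(z),
                        u_prev = if (i > 1L) beta * mix(lambdas[i - 1L])(z),
                        u_next = if (i < K) beta * mix(lambdas[i + 1L])(z),
                        lambda = lambdas[i])
  })
  f_ref <- vapply(lambdas, function(lam)
    free_energy_quadrature(mix(lam), beta, lo, hi), 0)
  out <- list(sets = sets, delta_f_ref = diff(f_ref),
              total_ref = f_ref[K] - f_ref[1L],
              manifest = make_manifest("gen_fep_chain", seed,
                                       lambdas = lambdas, beta = beta, n = n))
  if (full_matrix) {
    pooled <- unlist(samples, use.names = FALSE)
    u_full <- matrix(0, K, length(pooled))
    for (i in seq_len(K)) u_full[i, ] <- beta * mix(lambdas[i])(pooled)
    out$u_full <- u_full
    out$counts <- n
    out$x <- pooled
  }
  out
}

#' Dual-level (low-level / high-level) umbrella data
#'
#' Emulates umbrella sampling run with a cheap low-level (LL) potential whose
#' samples are later corrected with high-level (HL) single-point energies:
#' each window draws exact independent samples from LL + restraint, both
#' energy columns are recorded for every sample, and the HL reference PMF is
#' available by quadrature. \code{HL = LL + correction}, with the correction
#' a bounded smooth function supplied by the caller.
#'
#' @param LL a \code{\link{toy_potential}} (low-level surface)
#' @param correction function of z giving HL - LL in kcal/mol
#' @param centers umbrella window centers
#' @param spring_k restraint constant(s), \eqn{k (\Delta z)^2} convention
#' @param beta inverse temperature, 1/(kcal/mol)
#' @param n samples per window (recycled)
#' @param seed RNG seed
#' @return list with \code{samplesets} (CV plus \code{U_LL}, \code{U_HL}
#'   energy columns), \code{states} (full-mode \code{\link{thermo_state}}s
#'   with the LL column and the window restraints), \code{target}
#'   (restraint-free HL target state), \code{hl_fn} (the HL energy function)
#'   and a \code{manifest}
#' @export
gen_dual_level <- function(LL, correction, centers, spring_k, beta, n, seed) {
  K <- length(centers)
  n <- rep_len(as.integer(n), K)
  spring_k <- rep_len(spring_k, K)
  hl_fn <- function(z) LL$fn(z) + correction(z)
  set.seed(seed)
  samplesets <- lapply(seq_len(K), function(i) {
    z <- sample_boltzmann(LL, beta = beta, n = n[i],
                          restraint = list(spring_k = spring_k[i],
                                           z_ref = centers[i]))
    sample_set(origin = i, cv = z,
               energies = data.frame(U_LL = LL$fn(z), U_HL = hl_fn(z)))
  })
  states <- lapply(seq_len(K), function(i)
    thermo_state("full", beta = beta, energy_column = "U_LL",
                 spring_k = spring_k[i], z_ref = centers[i]))
  target <- thermo_state("full", beta = beta, energy_column = "U_HL")
  list(samplesets = samplesets, states = states, target = target,
       hl_fn = hl_fn,
       manifest = make_manifest("gen_dual_level", seed, centers = centers,
                                spring_k = spring_k, beta = beta, n = n))
}

#' Synthetic umbrella-sampling windows
#'
#' Draws exact independent samples from every restrained window density
#' \eqn{p_i(z) \propto e^{-\beta [U(z) + k_i (z - z_i^{ref})^2]}} of an
#' umbrella ladder and returns the sample sets together with the matching
#' restraint-mode states, ready for \code{\link{build_reduced_matrix}}.
#'
#' @param potential a \code{\link{toy_potential}} with finite bounds
#' @param centers window centers (e.g. from \code{\link{window_ladder}})
#' @param spring_k restraint constant(s), \eqn{k (\Delta z)^2} convention
#' @param beta inverse temperature, 1/(kcal/mol)
#' @param n samples per window (recycled)
#' @param seed RNG seed
#' @return list with \code{samplesets}, \code{states}, pooled \code{cv} and a
#'   \code{manifest}
#' @export
gen_umbrella_windows <- function(potential, centers, spring_k, beta, n, seed) {
  K <- length(centers)
  n <- rep_len(as.integer(n), K)
  spring_k <- rep_len(spring_k, K)
  set.seed(seed)
  samplesets <- lapply(seq_len(K), function(i) {
    z <- sample_boltzmann(potential, beta = beta, n = n[i],
                          restraint = list(spring_k = spring_k[i],
                                           z_ref = centers[i]))
    sample_set(origin = i, cv = z)
  })
  states <- lapply(seq_len(K), function(i)
    thermo_state("restraint", beta = beta, spring_k = spring_k[i],
                 z_ref = centers[i]))
  list(samplesets = samplesets, states = states,
       cv = unlist(lapply(samplesets, function(s) drop(s$cv))),
       manifest = make_manifest("gen_umbrella_windows", seed,
                                potential = potential$type, centers = centers,
                                spring_k = spring_k, beta = beta, n = n))
}

#' Free energy of a 1-D potential by quadrature
#'
#' \eqn{f = -\ln \int e^{-\beta U(z)} dz}, the dimensionless configuration
#' free energy used as ground truth by the synthetic generators.
#'
#' @param fn energy function of z (kcal/mol), or a \code{\link{toy_potential}}
#' @param beta inverse temperature, 1/(kcal/mol)
#' @param lower,upper integration bounds (default: the potential's bounds)
#' @return dimensionless free energy
#' @export
free_energy_quadrature <- function(fn, beta, lower = NULL, upper = NULL) {
  if (inherits(fn, "toy_potential")) {
    if (is.null(lower)) lower <- fn$bounds[1L]
    if (is.null(upper)) upper <- fn$bounds[2L]
    fn <- fn$fn
  }
  # shift by the minimum so the integrand is O(1)
  zs <- seq(lower, upper, length.out = 2001L)
  u0 <- min(beta * fn(zs))
  val <- stats::integrate(function(z) exp(-(beta * fn(z) - u0)), lower, upper,
                          rel.tol = 1e-8, subdivisions = 500L,
                          stop.on.error = FALSE)$value
  -(log(val) - u0)
}

#' Exact binned PMF of a 1-D potential by quadrature
#'
#' Boltzmann bin probabilities \eqn{p_b \propto \int_b e^{-\beta U(z)} dz}
#' integrated bin by bin, returned as a min-shifted PMF in kT on the same bin
#' convention as \code{\link{mbar_pmf}}. This is the ground truth the
#' estimators are compared against.
#'
#' @inheritParams free_energy_quadrature
#' @param bin_edges numeric vector of bin edges
#' @return list with \code{centers}, \code{prob} (normalized bin
#'   probabilities) and \code{pmf} (kT, minimum 0)
#' @export
pmf_quadrature <- function(fn, beta, bin_edges) {
  if (inherits(fn, "toy_potential")) fn <- fn$fn
  B <- length(bin_edges) - 1L
  raw <- vapply(seq_len(B), function(b) {
    zs <- seq(bin_edges[b], bin_edges[b + 1L], length.out = 201L)
    u0 <- min(beta * fn(zs))
    v <- stats::integrate(function(z) exp(-(beta * fn(z) - u0)),
                          bin_edges[b], bin_edges[b + 1L],
                          rel.tol = 1e-8, stop.on.error = FALSE)$value
    log(v) - u0
  }, 0)
  prob <- exp(raw - logsumexp(raw))
  pmf <- -(raw - logsumexp(raw))
  list(centers = (bin_edges[-(B + 1L)] + bin_edges[-1L]) / 2,
       prob = prob, pmf = pmf - min(pmf))
}

#' Two-dimensional periodic toy surface
#'
#' A pair of dihedral-like coordinates on \eqn{[-180, 180)^2} with a
#' two-basin cosine landscape, provided to exercise 2-D PMF bookkeeping
#' (binning, min-shift, empty bins); it has no quantitative quadrature oracle
#' attached. Samples are drawn by componentwise Metropolis.
#'
#' @param beta inverse temperature, 1/(kcal/mol)
#' @param n number of exported samples
#' @param seed RNG seed
#' @param height landscape amplitude, kcal/mol
#' @param step_size,burn_in,stride Metropolis settings
#' @return n x 2 matrix of angles in degrees with a \code{manifest} attribute
#' @export
gen_2d_periodic <- function(beta, n, seed, height = 2, step_size = 30,
                            burn_in = 500L, stride = 10L) {
  set.seed(seed)
  U <- function(p) height * (1 - cos(pi / 180 * (p[1L] + 60)) *
                               cos(pi / 180 * (p[2L] - 45)))
  wrap <- function(a) (a + 180) %% 360 - 180
  n_steps <- burn_in + n * stride
  out <- matrix(0, n, 2L)
  x <- c(0, 0)
  e <- U(x)
  j <- 0L
  for (t in seq_len(n_steps)) {
    xn <- wrap(x + stats::runif(2L, -step_size, step_size))
    en <- U(xn)
    if (log(stats::runif(1L)) < -beta * (en - e)) { x <- xn; e <- en }
    if (t > burn_in && (t - burn_in) %% stride == 0L) {
      j <- j + 1L
      out[j, ] <- x
    }
  }
  attr(out, "manifest") <- make_manifest("gen_2d_periodic", seed, beta = beta,
                                         n = n, height = height)
  out
}
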