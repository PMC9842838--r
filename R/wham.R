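#' Binned WHAM for umbrella-sampling data
#'
#' Reference implementation of the weighted histogram analysis method, the
#' binned estimator whose zero-bin-width limit is the multistate
#' acceptance-ratio estimator. Histograms the pooled window trajectories on
#' the given bins (half-open \code{[e_i, e_{i+1})}, last bin closed) and
#' iterates the standard self-consistent pair
#' \deqn{p_b \propto H_b / \sum_k N_k e^{f_k} c_{kb}, \qquad
#'       f_k = -\ln \sum_b c_{kb} \, p_b}
#' where \eqn{c_{kb} = \exp[-\beta k_k (z_b - z_k^{ref})^2]} is the window
#' bias evaluated at the bin center (the same \eqn{k (\Delta z)^2} restraint
#' convention as the rest of the package, minimum-image when a period is
#' declared). The first window's free energy is anchored to zero.
#'
#' @param cv list of per-window numeric vectors of collective-variable samples
#' @param spring_k restraint constant(s), recycled over windows
#'   (kcal/mol per squared CV unit, \eqn{k (\Delta z)^2} convention)
#' @param z_ref vector of window centers, one per window
#' @param beta inverse temperature in 1/(kcal/mol)
#' @param bin_edges numeric vector of bin edges covering all samples
#' @param periodic optional CV period for the restraint minimum image
#' @param tolerance convergence threshold on max |change in window f|
#' @param max_iterations iteration cap
#' @return an object of class \code{"wham_fit"}: window free energies
#'   \code{f} (dimensionless, first window 0), unbiased per-bin probabilities
#'   \code{density} (summing to 1), \code{pmf} in kT (min-shifted, \code{NA}
#'   on empty bins), \code{bin_edges}, \code{centers}, per-bin histogram
#'   counts and the iteration count
#' @seealso \code{\link{mbar_pmf}} for the binless estimate on the same data
#' @export
wham_umbrella <- function(cv, spring_k, z_ref, beta, bin_edges,
                          periodic = NULL, tolerance = 1e-8,
                          max_iterations = 1e5L) {
  if (!is.list(cv)) cv <- list(cv)
  K <- length(cv)
  if (length(z_ref) != K) stop("'z_ref' must have one center per window")
  spring_k <- rep_len(spring_k, K)
  Nk <- vapply(cv, length, 0L)
  if (any(Nk == 0L)) stop("empty window trajectory")
  edges <- as.numeric(bin_edges)
  B <- length(edges) - 1L
  centers <- (edges[-(B + 1L)] + edges[-1L]) / 2
  pooled <- unlist(cv, use.names = FALSE)
  bin <- findInterval(pooled, edges, rightmost.closed = TRUE)
  if (any(bin == 0L | pooled > edges[B + 1L]))
    stop("bins do not cover the sampled CV range")
  H <- tabulate(bin, nbins = B)

  # window bias at bin centers: c[k, b] = exp(-u_k(z_b))
  log_c <- matrix(0, K, B)
  for (k in seq_len(K))
    log_c[k, ] <- -beta * restraint_energy(spring_k[k], centers, z_ref[k],
                                           periodic)

  f <- numeric(K)
  logH <- ifelse(H > 0L, log(H), -Inf)
  logN <- log(Nk)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # log denominator per bin: ln sum_k N_k exp(f_k) c_kb
    logden <- col_logsumexp(log_c + (logN + f))
    logp <- logH - logden
    logp <- logp - logsumexp(logp)
    fnew <- -vapply(seq_len(K), function(k) logsumexp(log_c[k, ] + logp), 0)
    fnew <- fnew - fnew[1L]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta <= tolerance) break
    if (iter >= max_iterations)
      stop("WHAM did not converge in ", max_iterations,
           " iterations (last change ", format(delta, digits = 4), ")")
  }
  logden <- col_logsumexp(log_c + (logN + f))
  logp <- logH - logden
  logp <- logp - logsumexp(logp)
  density <- exp(logp)
  pmf <- -logp
  occupied <- H > 0L
  pmf <- pmf - min(pmf[occupied])
  pmf[!occupied] <- NA_real_
  structure(list(f = f, density = density, pmf = pmf, bin_edges = edges,
                 centers = centers, counts = H, n_iterations = iter,
                 beta = beta),
            class = "wham_fit")
}

#' @export
print.wham_fit <- function(x, ...) {
  cat("WHAM fit:", length(x$f), "windows,", sum(x$counts), "samples,",
      length(x$centers), "bins\n")
  cat("  converged in", x$n_iterations, "iterations; PMF range 0 to",
      format(max(x$pmf, na.rm = TRUE), digits = 4), "kT\n")
  invisible(x)
}

#' @export
as.data.frame.wham_fit <- function(x, ...) {
  data.frame(bin_center = x$centers, pmf = x$pmf, se = NA_real_,
             eff_count = x$counts, empty = x$counts == 0L)
}
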