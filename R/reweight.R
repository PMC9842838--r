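#' Normalized log weights of the pooled samples under a target state
#'
#' The mixture-importance weights that turn the pooled samples into an
#' ensemble of the (possibly unsampled) target state:
#' \eqn{\log w_n = -u_{target}(x_n) - \ln \sum_k N_k e^{\hat f_k - u_k(x_n)}},
#' normalized so \eqn{\sum_n w_n = 1}. The normalization makes the weights
#' invariant under any constant shift of \code{u_target}.
#'
#' @param object an \code{\link{mbar}} fit
#' @param u_target reduced potential of the target state on the pooled samples
#'   (length N, or a scalar recycled; 0 is the restraint-free target of
#'   umbrella sampling)
#' @return numeric vector of log weights with \code{sum(exp(.)) == 1}
#' @export
target_log_weights <- function(object, u_target) {
  stopifnot(inherits(object, "mbar"))
  N <- length(object$log_denominator)
  if (length(u_target) == 1L) u_target <- rep.int(u_target, N)
  if (length(u_target) != N)
    stop("'u_target' must have one entry per pooled sample (", N, ")")
  lw <- -u_target - object$log_denominator
  norm <- logsumexp(lw)
  if (!is.finite(norm))
    stop("target state has no overlap with samples (all weights zero)")
  lw - norm
}

#' Free energy of a target state by reweighting
#'
#' \eqn{\hat f_{target} = -\ln \sum_n \exp[-u_{target}(x_n) -
#' \ln \sum_k N_k e^{\hat f_k - u_k(x_n)}]}. When \code{u_target} equals the
#' reduced potential of a sampled state this reproduces that state's
#' \eqn{\hat f} exactly; the returned value is in the same gauge as the fit
#' (anchored at state 1).
#'
#' @inheritParams target_log_weights
#' @return dimensionless free energy (scalar)
#' @export
target_free_energy <- function(object, u_target) {
  stopifnot(inherits(object, "mbar"))
  N <- length(object$log_denominator)
  if (length(u_target) == 1L) u_target <- rep.int(u_target, N)
  if (length(u_target) != N)
    stop("'u_target' must have one entry per pooled sample (", N, ")")
  f <- -logsumexp(-u_target - object$log_denominator)
  if (!is.finite(f))
    stop("target state has no overlap with samples (all weights zero)")
  f
}

#' Thermodynamic average of an observable at a target state
#'
#' Weighted average \eqn{\sum_n A_n w_n} with the normalized target weights.
#' For non-negative observables this coincides with the free-energy-ratio form
#' \eqn{\exp[\hat f_{target} - \hat f_{target,A}]}; the direct weighted sum is
#' used so observables of either sign are supported.
#'
#' @inheritParams target_log_weights
#' @param A numeric vector of per-sample observable values (length N)
#' @return estimated average (scalar)
#' @export
mbar_expectation <- function(object, u_target, A) {
  lw <- target_log_weights(object, u_target)
  if (length(A) != length(lw))
    stop("'A' must have one entry per pooled sample (", length(lw), ")")
  sum(A * exp(lw))
}

#' Potential of mean force by reweighting
#'
#' Bins the pooled collective-variable values and accumulates the normalized
#' target weights per bin (an indicator-function observable), giving
#' \eqn{PMF_b = -\ln \sum_{n \in b} w_n} in units of kT, shifted so the
#' minimum over non-empty bins is zero. Supports 1-D and 2-D collective
#' variables. Bins are half-open \code{[edge_i, edge_{i+1})} with the last bin
#' closed.
#'
#' Per-bin standard errors are estimated by re-solving the estimator on
#' per-state contiguous blocks (\code{se = "block"}) or on within-state
#' bootstrap resamples (\code{se = "bootstrap"}). Each replicate profile is
#' gauge-fixed by subtracting its value at the full estimate's minimum bin
#' before the spread is taken, since a PMF is defined only up to a constant.
#'
#' @inheritParams target_log_weights
#' @param cv numeric vector (1-D) or N x 2 matrix (2-D) of collective-variable
#'   values for the pooled samples
#' @param bin_edges numeric vector of bin edges (1-D) or list of two such
#'   vectors (2-D)
#' @param se \code{"none"}, \code{"block"} or \code{"bootstrap"}
#' @param n_blocks number of contiguous per-state blocks for \code{"block"}
#' @param n_replicates bootstrap replicates for \code{"bootstrap"}
#' @param seed RNG seed for the bootstrap
#' @param units \code{"kT"} (default) or \code{"kcal/mol"}; conversion uses
#'   \code{temperature}
#' @param temperature temperature in K, required for \code{units = "kcal/mol"}
#' @return an object of class \code{"mbar_pmf"}: bin edges/centers, \code{pmf},
#'   \code{se}, \code{eff_count} (per-bin effective sample count
#'   \eqn{(\sum w)^2 / \sum w^2}), \code{empty} flags
#' @export
mbar_pmf <- function(object, u_target, cv, bin_edges,
                     se = c("none", "block", "bootstrap"),
                     n_blocks = 10L, n_replicates = 50L, seed = NULL,
                     units = c("kT", "kcal/mol"), temperature = NULL) {
  se <- match.arg(se)
  units <- match.arg(units)
  stopifnot(inherits(object, "mbar"))
  cv <- as.matrix(cv)
  d <- ncol(cv)
  if (d > 2L) stop("PMFs are supported for 1 or 2 collective variables")
  if (d == 1L) bin_edges <- list(as.numeric(bin_edges))
  if (!is.list(bin_edges) || length(bin_edges) != d)
    stop("'bin_edges' must match the CV dimension")
  N <- length(object$log_denominator)
  if (nrow(cv) != N) stop("'cv' must have one row per pooled sample (", N, ")")

  lw_full <- target_log_weights(object, u_target)
  bins <- bin_assign(cv, bin_edges)
  if (all(is.na(bins$idx)))
    stop("all bins are empty: the bin grid does not cover any sample")
  prof <- pmf_from_logweights(lw_full, bins$idx, bins$n_bins)
  # gauge anchor for resampled profiles: the best-populated bin, which is the
  # most stable under resampling (the reported PMF itself stays min-shifted)
  anchor <- which.max(prof$eff_count)

  se_vec <- rep(NA_real_, bins$n_bins)
  if (se != "none") {
    estimator <- function(idx) {
      sub <- suppressWarnings(
        mbar(object$u[, idx, drop = FALSE],
             counts = tabulate_counts(object, idx),
             tolerance = object$tolerance, initial_f = object$f_hat))
      ut <- if (length(u_target) == 1L) u_target else u_target[idx]
      lw <- target_log_weights(sub, ut)
      p <- pmf_from_logweights(lw, bins$idx[idx], bins$n_bins)
      out <- p$raw - p$raw[anchor]
      out[p$empty] <- NA_real_
      out
    }
    reps <- if (se == "block")
      block_se(estimator, object$counts, n_blocks = n_blocks)
    else
      bootstrap_se(estimator, object$counts, n_replicates = n_replicates,
                   seed = seed)
    se_vec <- reps$se
  }

  scale <- 1
  if (units == "kcal/mol") {
    if (is.null(temperature))
      stop("'temperature' is required to report the PMF in kcal/mol")
    scale <- kB_kcal * temperature
  }
  pmf <- prof$raw - min(prof$raw[!prof$empty])
  pmf[prof$empty] <- NA_real_
  centers <- lapply(bin_edges, function(e) (utils::head(e, -1L) + e[-1L]) / 2)
  structure(list(bin_edges = if (d == 1L) bin_edges[[1L]] else bin_edges,
                 centers = if (d == 1L) centers[[1L]] else centers,
                 dim = d, shape = bins$shape,
                 pmf = pmf * scale, se = se_vec * scale,
                 eff_count = prof$eff_count, empty = prof$empty,
                 units = units, se_method = se),
            class = "mbar_pmf")
}

# map pooled subset index -> per-state counts, keeping state order
tabulate_counts <- function(object, idx) {
  tabulate(object$origin[idx], nbins = length(object$counts))
}

# assign samples to (possibly 2-D) bins; half-open, last bin closed
bin_assign <- function(cv, bin_edges) {
  d <- ncol(cv)
  nb <- vapply(bin_edges, function(e) length(e) - 1L, 0L)
  idx_d <- matrix(0L, nrow(cv), d)
  for (j in seq_len(d)) {
    e <- bin_edges[[j]]
    i <- findInterval(cv[, j], e, rightmost.closed = TRUE)
    i[cv[, j] < e[1L] | cv[, j] > e[length(e)]] <- 0L
    idx_d[, j] <- i
  }
  ok <- rowSums(idx_d == 0L) == 0L
  idx <- rep(NA_integer_, nrow(cv))
  if (d == 1L) idx[ok] <- idx_d[ok, 1L]
  else idx[ok] <- idx_d[ok, 1L] + (idx_d[ok, 2L] - 1L) * nb[1L]
  list(idx = idx, n_bins = prod(nb), shape = nb)
}

pmf_from_logweights <- function(lw, bin_idx, n_bins) {
  raw <- rep(Inf, n_bins)
  eff <- numeric(n_bins)
  inb <- !is.na(bin_idx)
  sp <- split(lw[inb], bin_idx[inb])
  for (nm in names(sp)) {
    b <- as.integer(nm)
    l1 <- logsumexp(sp[[nm]])
    raw[b] <- -l1
    eff[b] <- exp(2 * l1 - logsumexp(2 * sp[[nm]]))
  }
  empty <- !is.finite(raw)
  list(raw = raw, eff_count = eff, empty = empty)
}

#' @export
print.mbar_pmf <- function(x, ...) {
  cat("<mbar_pmf>", if (x$dim == 1L) length(x$pmf) else
    paste(x$shape, collapse = " x "), "bins,", sum(!x$empty), "occupied;",
    "units:", x$units, "\n")
  rng <- range(x$pmf, na.rm = TRUE)
  cat("  range:", format(rng[1L], digits = 4), "to",
      format(rng[2L], digits = 4), x$units, "\n")
  invisible(x)
}

#' @export
as.data.frame.mbar_pmf <- function(x, ...) {
  if (x$dim == 1L) {
    data.frame(bin_center = x$centers, pmf = x$pmf, se = x$se,
               eff_count = x$eff_count, empty = x$empty)
  } else {
    g <- expand.grid(bin_center_1 = x$centers[[1L]],
                     bin_center_2 = x$centers[[2L]])
    cbind(g, data.frame(pmf = x$pmf, se = x$se, eff_count = x$eff_count,
                        empty = x$empty))
  }
}

#' @export
plot.mbar_pmf <- function(x, ...) {
  if (x$dim == 1L) {
    ok <- !x$empty
    graphics::plot(x$centers[ok], x$pmf[ok], type = "l",
                   xlab = "collective variable",
                   ylab = paste0("PMF (", x$units, ")"), ...)
    if (any(is.finite(x$se[ok])))
      graphics::segments(x$centers[ok], x$pmf[ok] - x$se[ok],
                         x$centers[ok], x$pmf[ok] + x$se[ok], col = "grey50")
  } else {
    z <- matrix(x$pmf, x$shape[1L], x$shape[2L])
    graphics::image(x$centers[[1L]], x$centers[[2L]], z,
                    xlab = "CV 1", ylab = "CV 2", ...)
    graphics::contour(x$centers[[1L]], x$centers[[2L]], z, add = TRUE)
  }
  invisible(x)
}
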