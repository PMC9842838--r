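#' Neighbor reduced-energy set for one alchemical state
#'
#' Per-state input of the accumulation (free-energy perturbation) workflow:
#' the reduced energies of the state's own potential and of its immediate
#' neighbors along the coupling schedule, evaluated on the state's own
#' samples. Interior states carry both neighbors; the first state has only
#' \code{u_next}, the last only \code{u_prev}. \code{+Inf} entries are legal
#' (zero Boltzmann weight, e.g. core overlap at decoupled endpoints).
#'
#' @param index state position along the chain (1-based)
#' @param u_self dimensionless \eqn{u_i(x_{in})}
#' @param u_prev dimensionless \eqn{u_{i-1}(x_{in})}, or \code{NULL}
#' @param u_next dimensionless \eqn{u_{i+1}(x_{in})}, or \code{NULL}
#' @param lambda optional coupling value (metadata only; estimation uses only
#'   the energy columns)
#' @return an object of class \code{"neighbor_energy_set"}
#' @export
neighbor_energy_set <- function(index, u_self, u_prev = NULL, u_next = NULL,
                                lambda = NULL) {
  n <- length(u_self)
  for (nm in c("u_prev", "u_next")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != n)
      stop("'", nm, "' must have the same length as 'u_self'")
  }
  chk <- c(u_self, u_prev, u_next)
  if (anyNA(chk) || any(chk == -Inf))
    stop("neighbor energies must be finite or +Inf")
  structure(list(index = as.integer(index), n = n, u_self = as.numeric(u_self),
                 u_prev = if (!is.null(u_prev)) as.numeric(u_prev),
                 u_next = if (!is.null(u_next)) as.numeric(u_next),
                 lambda = lambda),
            class = "neighbor_energy_set")
}

#' Two-state (Bennett acceptance ratio) free-energy difference
#'
#' Estimates \eqn{\Delta \hat f_{i,i+1} = \hat f_{i+1} - \hat f_i} for one
#' neighbor pair by solving the two-state case of the MBAR self-consistent
#' equations, which is identical to Bennett's acceptance-ratio solution.
#' Both directions must contribute samples; there is no single-direction
#' fallback.
#'
#' @param set_i \code{\link{neighbor_energy_set}} for state i (needs
#'   \code{u_next})
#' @param set_j \code{\link{neighbor_energy_set}} for state i+1 (needs
#'   \code{u_prev})
#' @param se \code{"block"}, \code{"bootstrap"} or \code{"none"}
#' @param n_blocks,n_replicates,seed resampling parameters, see
#'   \code{\link{block_se}} and \code{\link{bootstrap_se}}
#' @return list with \code{delta_f}, \code{se} and the underlying
#'   \code{\link{mbar}} fit
#' @export
bar_pair <- function(set_i, set_j, se = c("block", "none", "bootstrap"),
                     n_blocks = 10L, n_replicates = 50L, seed = NULL) {
  se <- match.arg(se)
  stopifnot(inherits(set_i, "neighbor_energy_set"),
            inherits(set_j, "neighbor_energy_set"))
  if (set_j$index != set_i$index + 1L)
    stop("'set_j' must be the immediate successor of 'set_i' in the chain")
  if (is.null(set_i$u_next))
    stop("state ", set_i$index, " is missing 'u_next' (forward energies)")
  if (is.null(set_j$u_prev))
    stop("state ", set_j$index, " is missing 'u_prev' (reverse energies)")
  if (set_i$n < 2L || set_j$n < 2L)
    stop("both states must contribute at least 2 samples")
  u <- rbind(c(set_i$u_self, set_j$u_prev),
             c(set_i$u_next, set_j$u_self))
  counts <- c(set_i$n, set_j$n)
  fit <- suppressWarnings(mbar(u, counts = counts))
  est_se <- NA_real_
  if (se != "none") {
    estimator <- function(idx) {
      sub <- suppressWarnings(
        mbar(u[, idx, drop = FALSE],
             counts = tabulate(rep.int(1:2, counts)[idx], nbins = 2L),
             initial_f = fit$f_hat))
      sub$f_hat[2L]
    }
    est_se <- if (se == "block") block_se(estimator, counts, n_blocks)$se
    else bootstrap_se(estimator, counts, n_replicates, seed)$se
  }
  list(delta_f = fit$f_hat[2L], se = est_se, fit = fit)
}

#' One-sided exponential (Zwanzig) free-energy average
#'
#' \eqn{\Delta \hat f = -\ln \langle e^{-\Delta u} \rangle} over samples of
#' the origin state, evaluated with log-sum-exp stabilization.
#'
#' @param delta_u \eqn{u_{target} - u_{origin}} at origin-state samples
#' @return dimensionless free-energy difference (scalar)
#' @examples
#' exp_average(c(0, log(2))) # -log(0.75)
#' @export
exp_average <- function(delta_u) {
  if (!length(delta_u)) stop("'delta_u' is empty")
  -(logsumexp(-delta_u) - log(length(delta_u)))
}

#' Accumulate neighbor free-energy differences along a chain
#'
#' Cumulative sums of the per-pair estimates; the total equals the sum of pair
#' estimates exactly. The total standard error defaults to the quadrature sum
#' of per-pair SEs (an independence approximation: interior sample sets are
#' shared by two pairs); \code{\link{fep_estimate}} instead applies block
#' averaging to the whole chain, which respects that sharing.
#'
#' @param delta_f per-pair free-energy differences, in chain order
#' @param se optional per-pair standard errors
#' @param total_se optional externally computed SE of the total, overriding
#'   the quadrature sum
#' @return an object of class \code{"fep_chain"}: per-pair table with
#'   cumulative profile, plus \code{total} and \code{total_se}
#' @export
accumulate_chain <- function(delta_f, se = NULL, total_se = NULL) {
  if (!length(delta_f)) stop("empty chain")
  if (anyNA(delta_f)) stop("gap in chain: missing pair estimate(s)")
  if (is.null(se)) se <- rep(NA_real_, length(delta_f))
  if (length(se) != length(delta_f)) stop("'se' must match 'delta_f'")
  tab <- data.frame(pair = seq_along(delta_f), delta_f = delta_f, se = se,
                    cumulative = cumsum(delta_f))
  if (is.null(total_se))
    total_se <- if (all(is.finite(se))) sqrt(sum(se^2)) else NA_real_
  structure(list(pairs = tab, total = sum(delta_f), total_se = total_se,
                 se_combiner = if (is.null(total_se)) "pairsum" else "given"),
            class = "fep_chain")
}

#' Free-energy perturbation by neighbor-pair accumulation
#'
#' Runs the two-state estimator over every neighbor pair of an ordered chain
#' of \code{\link{neighbor_energy_set}}s and accumulates the differences to
#' the endpoint total \eqn{\Delta f_{start,end} = \sum_i \Delta f_{i,i+1}}.
#' The coupling schedule itself is never needed: only the neighbor energy
#' columns enter.
#'
#' The total SE is estimated by block averaging over time applied to the whole
#' chain (each block re-estimates every pair on the same time slice, so the
#' sharing of interior sample sets between adjacent pairs is respected);
#' \code{se = "pairsum"} sums per-pair variances instead, which is faster but
#' assumes independent pairs.
#'
#' @param sets list of \code{\link{neighbor_energy_set}}s with contiguous
#'   indices (first has no \code{u_prev}, last no \code{u_next})
#' @param se \code{"block"} or \code{"pairsum"}
#' @param n_blocks blocks for the block-averaging combiner
#' @return an object of class \code{"fep_chain"} (see
#'   \code{\link{accumulate_chain}})
#' @export
fep_estimate <- function(sets, se = c("block", "pairsum"), n_blocks = 10L) {
  se <- match.arg(se)
  K <- length(sets)
  if (K < 2L) stop("a chain needs at least 2 states")
  idx <- vapply(sets, function(s) s$index, 0L)
  if (any(diff(idx) != 1L)) stop("gap in chain: state indices must be contiguous")
  pairs <- vector("list", K - 1L)
  for (i in seq_len(K - 1L)) {
    pairs[[i]] <- bar_pair(sets[[i]], sets[[i + 1L]],
                           se = if (se == "pairsum") "block" else "none",
                           n_blocks = n_blocks)
  }
  delta_f <- vapply(pairs, `[[`, 0, "delta_f")
  pair_se <- vapply(pairs, `[[`, 0, "se")

  total_se <- NULL
  if (se == "block") {
    # per-state contiguous time blocks; every pair re-estimated on each slice
    B <- as.integer(n_blocks)
    ns <- vapply(sets, function(s) s$n, 0L)
    if (any(ns < B)) stop("'n_blocks' exceeds the sample count of some state")
    memb <- lapply(ns, function(n) as.integer(ceiling(seq_len(n) / (n / B))))
    pairvals <- matrix(NA_real_, B, K - 1L)
    for (b in seq_len(B)) {
      subsets <- lapply(seq_len(K), function(i) {
        keep <- memb[[i]] == b
        s <- sets[[i]]
        neighbor_energy_set(s$index, s$u_self[keep],
                            u_prev = if (!is.null(s$u_prev)) s$u_prev[keep],
                            u_next = if (!is.null(s$u_next)) s$u_next[keep],
                            lambda = s$lambda)
      })
      pairvals[b, ] <- vapply(seq_len(K - 1L), function(i)
        bar_pair(subsets[[i]], subsets[[i + 1L]], se = "none")$delta_f, 0)
    }
    total_se <- stats::sd(rowSums(pairvals)) / sqrt(B)
    pair_se <- apply(pairvals, 2L, stats::sd) / sqrt(B)
  }
  out <- accumulate_chain(delta_f, se = pair_se, total_se = total_se)
  out$se_combiner <- se
  out
}

#' @export
print.fep_chain <- function(x, ...) {
  cat("FEP accumulation chain:", nrow(x$pairs), "neighbor pairs\n")
  print(x$pairs, row.names = FALSE, digits = 6)
  cat("\nTotal delta f =", format(x$total, digits = 6), "+/-",
      format(x$total_se, digits = 3), "(", x$se_combiner, "SE )\n")
  invisible(x)
}

#' @export
plot.fep_chain <- function(x, ...) {
  cum <- c(0, x$pairs$cumulative)
  graphics::plot(seq_along(cum) - 1L, cum, type = "b", xlab = "state index",
                 ylab = "cumulative delta f (kT)", ...)
  invisible(x)
}
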