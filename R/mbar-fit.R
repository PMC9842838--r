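#' Fit the multistate Bennett acceptance ratio estimator
#'
#' Solves the MBAR self-consistent equations
#' \deqn{\hat f_i = -\ln \sum_{j,n} \frac{\exp[-u_i(x_{jn})]}
#'   {\sum_k N_k \exp[\hat f_k - u_k(x_{jn})]}}
#' for the dimensionless free energies \eqn{\hat f_i} of K thermodynamic
#' states, given the reduced potential of every state evaluated on the pooled
#' samples. Free energies are defined up to an additive constant and are
#' anchored at \eqn{\hat f_1 = 0}.
#'
#' The solver combines plain self-consistent (fixed-point) iteration with a
#' damped Newton-Raphson stage: fixed-point steps are taken until the residual
#' drops below \code{sc_threshold}, then Newton updates (on the K-1 free
#' components, using the gradient and Hessian of the convex MBAR objective
#' whose stationarity condition is the self-consistent equation) with
#' step-halving and a fixed-point fallback whenever a Newton step fails to
#' reduce the residual. All sums are evaluated in log space, so reduced
#' potentials of \code{+Inf} (e.g. overlapping-core configurations at
#' alchemical endpoints) are legal and contribute zero weight.
#'
#' States with zero samples are allowed: they do not enter the mixture
#' denominator, and their free energy is evaluated afterwards by reweighting
#' (they behave exactly like appended target states).
#'
#' @param u a \code{\link{build_reduced_matrix}} result, or a plain K x N
#'   numeric matrix of dimensionless reduced potentials over pooled samples
#' @param counts integer vector of per-state sample counts (required when
#'   \code{u} is a plain matrix); \code{sum(counts)} must equal \code{ncol(u)}
#' @param tolerance convergence threshold on the max-norm residual
#'   \eqn{\max_i |f_i - \mathrm{RHS}_i(f)|}
#' @param max_iterations iteration cap; exceeding it raises a diagnostic error
#'   carrying the residual trace
#' @param initial_f optional starting free energies (length K, any gauge)
#' @param sc_threshold residual below which Newton steps are attempted
#' @return an object of class \code{"mbar"}: list with \code{f_hat} (length K,
#'   \code{f_hat[1] == 0}), \code{log_denominator} (per pooled sample,
#'   \eqn{\ln \sum_k N_k e^{\hat f_k - u_k}}), \code{counts}, \code{u},
#'   \code{ess} (per-state effective sample size of the reweighting weights),
#'   \code{n_iterations}, \code{final_residual}, \code{converged}
#' @references Shirts & Chodera's multistate reweighting estimator; Bennett's
#'   two-state acceptance-ratio method is recovered for K = 2.
#' @seealso \code{\link{target_free_energy}}, \code{\link{mbar_pmf}},
#'   \code{\link{bar_pair}}
#' @examples
#' set.seed(1)
#' x1 <- rnorm(2000, 0, 1); x2 <- rnorm(2000, 0, 2)
#' x <- c(x1, x2)
#' u <- rbind(x^2 / 2, x^2 / 8)   # two harmonic states, sigma = 1, 2
#' fit <- mbar(u, counts = c(2000, 2000))
#' coef(fit)[2]                   # close to -log(2)
#' @export
mbar <- function(u, counts = NULL, tolerance = 1e-8, max_iterations = 1e5L,
                 initial_f = NULL, sc_threshold = 1e-2) {
  rpm <- NULL
  if (inherits(u, "reduced_potential_matrix")) {
    rpm <- u
    counts <- u$counts
    u <- u$u
  }
  u <- as.matrix(u)
  K <- nrow(u)
  if (is.null(counts)) stop("'counts' is required when 'u' is a plain matrix")
  counts <- as.integer(counts)
  if (length(counts) != K) stop("length(counts) must equal nrow(u)")
  if (sum(counts) != ncol(u)) stop("sum(counts) must equal ncol(u)")
  if (any(counts < 0)) stop("negative sample counts")
  if (anyNA(u) || any(u == -Inf)) stop("reduced potentials must be finite or +Inf")
  active <- which(counts > 0L)
  if (!length(active)) stop("at least one state must have samples")

  ua <- u[active, , drop = FALSE]
  Na <- counts[active]
  logN <- log(Na)
  if (any(!is.finite(col_max(-ua))))
    stop("some sample has u = +Inf in every sampled state (all-infinite column)")

  f <- if (is.null(initial_f)) numeric(length(active)) else {
    if (length(initial_f) != K) stop("length(initial_f) must equal K")
    fi <- initial_f[active]
    fi - fi[1L]
  }

  rhs <- function(f) {
    d <- col_logsumexp((logN + f) - ua)
    r <- vapply(seq_along(f),
                function(i) -logsumexp(-ua[i, ] - d), 0)
    list(f = r - r[1L], d = d)
  }

  newton_update <- function(f, d) {
    # W[k, n] = N_k exp(f_k - u_kn) / denominator; columns sum to 1
    W <- exp(sweep((logN + f) - ua, 2L, d, "-"))
    g <- rowSums(W) - Na
    H <- diag(rowSums(W), nrow = length(f)) - tcrossprod(W)
    free <- -1L # drop anchored first component
    step <- tryCatch(solve(H[free, free, drop = FALSE], g[free]),
                     error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    fn <- f
    fn[-1L] <- f[-1L] - step
    fn
  }

  res_of <- function(f) max(abs(f - rhs(f)$f))

  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    step <- rhs(f)
    res <- max(abs(f - step$f))
    trace <- c(trace, res)
    if (res <= tolerance) { f <- step$f; break }
    if (iter >= max_iterations) {
      cond <- simpleError(paste0("MBAR solver did not converge in ",
                                 max_iterations, " iterations (residual ",
                                 format(res, digits = 4), ")"))
      cond$residual_trace <- trace
      class(cond) <- c("mbar_convergence_error", class(cond))
      stop(cond)
    }
    if (res >= sc_threshold) {
      f <- step$f
      next
    }
    # Newton stage with step halving; fall back to the fixed-point update
    fn <- newton_update(f, step$d)
    accepted <- FALSE
    if (!is.null(fn)) {
      for (h in 0:4) {
        cand <- f + (fn - f) / 2^h
        if (res_of(cand) < res) { f <- cand; accepted <- TRUE; break }
      }
    }
    if (!accepted) f <- step$f
  }

  d <- col_logsumexp((logN + f) - ua)
  f_full <- numeric(K)
  f_full[active] <- f
  inactive <- setdiff(seq_len(K), active)
  for (i in inactive) f_full[i] <- -logsumexp(-u[i, ] - d)
  f_full <- f_full - f_full[1L]

  ess <- vapply(seq_len(K), function(k) {
    lw <- -u[k, ] - d
    lw <- lw - logsumexp(lw)
    1 / sum(exp(2 * lw))
  }, 0)
  if (any(ess < 50))
    warning("low overlap: effective sample size < 50 for state(s) ",
            paste(which(ess < 50), collapse = ", "),
            "; free-energy estimates there may have large uncertainties")

  structure(list(f_hat = f_full, log_denominator = d, counts = counts,
                 u = u, origin = if (!is.null(rpm)) rpm$origin else
                   rep.int(seq_len(K), counts),
                 mode = if (!is.null(rpm)) rpm$mode else NA_character_,
                 ess = ess, n_iterations = iter, final_residual = trace[iter],
                 residual_trace = trace, converged = TRUE,
                 tolerance = tolerance),
            class = "mbar")
}

#' One self-consistent (fixed-point) update of the MBAR equations
#'
#' Evaluates the right-hand side of the self-consistent equations for all
#' states and re-anchors the result to \code{f[1] = 0}. Computed in log space
#' so no intermediate exponential can overflow.
#'
#' @param f current free energies (length K, \code{f[1] == 0})
#' @param u K x N reduced-potential matrix
#' @param counts per-state sample counts
#' @return updated free-energy vector
#' @export
self_consistent_step <- function(f, u, counts) {
  u <- as.matrix(u)
  active <- which(counts > 0L)
  logNf <- log(counts[active]) + f[active]
  d <- col_logsumexp(logNf - u[active, , drop = FALSE])
  r <- vapply(seq_len(nrow(u)), function(i) -logsumexp(-u[i, ] - d), 0)
  r - r[1L]
}

#' One damped Newton-Raphson update for the MBAR equations
#'
#' Takes a Newton step on the K-1 free components using the gradient and
#' Hessian of the convex MBAR objective; the step is halved until it reduces
#' the residual, and falls back to \code{\link{self_consistent_step}} when the
#' Hessian is singular or no damping level helps.
#'
#' @inheritParams self_consistent_step
#' @return updated free-energy vector
#' @export
newton_step <- function(f, u, counts) {
  u <- as.matrix(u)
  if (any(counts == 0L))
    stop("newton_step requires all states to have samples; drop zero-count states")
  logN <- log(counts)
  d <- col_logsumexp((logN + f) - u)
  W <- exp(sweep((logN + f) - u, 2L, d, "-"))
  g <- rowSums(W) - counts
  H <- diag(rowSums(W), nrow = length(f)) - tcrossprod(W)
  step <- tryCatch(solve(H[-1L, -1L, drop = FALSE], g[-1L]),
                   error = function(e) NULL)
  base_res <- mbar_residual(f, u, counts)
  if (!is.null(step) && all(is.finite(step))) {
    for (h in 0:4) {
      cand <- f
      cand[-1L] <- f[-1L] - step / 2^h
      if (mbar_residual(cand, u, counts) < base_res || base_res == 0) return(cand)
    }
  }
  self_consistent_step(f, u, counts)
}

#' Max-norm residual of the MBAR self-consistent equations
#'
#' \eqn{\max_i |f_i - \mathrm{RHS}_i(f)|} with the right-hand side re-anchored
#' to its first component, so the residual is invariant under a constant shift
#' of \code{f} followed by re-anchoring.
#'
#' @inheritParams self_consistent_step
#' @return non-negative scalar
#' @export
mbar_residual <- function(f, u, counts) {
  max(abs(f - self_consistent_step(f, u, counts)))
}

#' @export
coef.mbar <- function(object, ...) {
  stats::setNames(object$f_hat, paste0("state_", seq_along(object$f_hat)))
}

#' @export
print.mbar <- function(x, ...) {
  K <- length(x$f_hat)
  cat("MBAR fit:", K, "states,", sum(x$counts), "pooled samples\n")
  cat("  converged in", x$n_iterations, "iterations (residual",
      format(x$final_residual, digits = 3), ")\n")
  cat("  f_hat (anchored f_1 = 0):",
      paste(format(x$f_hat, digits = 5), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.mbar <- function(object, ...) {
  tab <- data.frame(state = seq_along(object$f_hat),
                    N = object$counts,
                    f_hat = object$f_hat,
                    delta_f = object$f_hat - object$f_hat[1L],
                    ess = object$ess)
  out <- list(table = tab, n_iterations = object$n_iterations,
              final_residual = object$final_residual,
              tolerance = object$tolerance)
  class(out) <- "summary.mbar"
  out
}

#' @export
print.summary.mbar <- function(x, ...) {
  cat("MBAR estimate (dimensionless free energies, f_1 = 0)\n\n")
  print(x$table, row.names = FALSE, digits = 6)
  cat("\nConverged in", x$n_iterations, "iterations; residual",
      format(x$final_residual, digits = 3), "( tolerance",
      format(x$tolerance), ")\n")
  if (any(x$table$ess < 50))
    cat("Warning: effective sample size < 50 for state(s)",
        paste(x$table$state[x$table$ess < 50], collapse = ", "),
        "- poor overlap\n")
  invisible(x)
}

#' Predict free energies, averages or weights at a target state
#'
#' Convenience dispatcher over \code{\link{target_free_energy}},
#' \code{\link{mbar_expectation}} and \code{\link{target_log_weights}}.
#'
#' @param object an \code{\link{mbar}} fit
#' @param u_target reduced potential of the target state on the pooled samples
#'   (vector of length N, or a scalar recycled, e.g. 0 for a restraint-free
#'   target)
#' @param what \code{"free_energy"}, \code{"expectation"} or \code{"weights"}
#' @param A per-sample observable values (required for expectations)
#' @param ... unused
#' @return a scalar free energy, a scalar average, or a vector of normalized
#'   log weights
#' @export
predict.mbar <- function(object, u_target = 0,
                         what = c("free_energy", "expectation", "weights"),
                         A = NULL, ...) {
  what <- match.arg(what)
  switch(what,
         free_energy = target_free_energy(object, u_target),
         expectation = {
           if (is.null(A)) stop("'A' is required for what = \"expectation\"")
           mbar_expectation(object, u_target, A)
         },
         weights = target_log_weights(object, u_target))
}
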