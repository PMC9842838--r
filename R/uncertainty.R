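#' Describe a resampling plan
#'
#' Small container tying together the uncertainty method and its parameters,
#' used by the pipeline configuration.
#'
#' @param method \code{"block"} or \code{"bootstrap"}
#' @param n_blocks number of contiguous per-state blocks (>= 2)
#' @param n_replicates number of bootstrap replicates (>= 2)
#' @param seed RNG seed for the bootstrap
#' @return an object of class \code{"resampling_plan"}
#' @export
resampling_plan <- function(method = c("block", "bootstrap"), n_blocks = 10L,
                            n_replicates = 50L, seed = NULL) {
  method <- match.arg(method)
  if (method == "block" && n_blocks < 2L) stop("'n_blocks' must be >= 2")
  if (method == "bootstrap" && n_replicates < 2L)
    stop("'n_replicates' must be >= 2")
  structure(list(method = method, n_blocks = as.integer(n_blocks),
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "resampling_plan")
}

# contiguous per-state block membership over the pooled sample index
# returns integer vector: block id (1..B) of each pooled sample
block_membership <- function(counts, n_blocks) {
  counts <- as.integer(counts)
  B <- as.integer(n_blocks)
  if (B < 2L) stop("'n_blocks' must be >= 2")
  pos <- counts[counts > 0L]
  if (any(pos < B))
    stop("'n_blocks' (", B, ") exceeds the sample count of some state (min ",
         min(pos), ")")
  unlist(lapply(counts, function(n) {
    if (n == 0L) integer(0)
    else as.integer(ceiling(seq_len(n) / (n / B)))
  }), use.names = FALSE)
}

#' Block-averaging standard error
#'
#' Splits every state's samples into \code{n_blocks} contiguous-in-time
#' blocks, evaluates the estimator on each block (block b pools the b-th slice
#' of every state), and reports \eqn{SE = sd(\mathrm{blocks}) / \sqrt{B}}
#' (sample standard deviation, B-1 denominator). Works for scalar- or
#' vector-valued estimators; components that fail to evaluate in a block
#' (e.g. empty PMF bins) may be returned as \code{NA} and are dropped
#' per-component.
#'
#' @param estimator function taking an integer vector of pooled sample indices
#'   and returning a numeric scalar or vector
#' @param counts per-state sample counts (pooled sample order: state 1 first)
#' @param n_blocks number of blocks B (>= 2, and no larger than any state's
#'   sample count)
#' @return list with \code{se} (same shape as the estimator value) and
#'   \code{estimates} (B x length matrix of block values)
#' @export
block_se <- function(estimator, counts, n_blocks = 10L) {
  memb <- block_membership(counts, n_blocks)
  B <- as.integer(n_blocks)
  vals <- lapply(seq_len(B), function(b) estimator(which(memb == b)))
  est <- do.call(rbind, lapply(vals, rbind))
  n_ok <- colSums(!is.na(est))
  se <- apply(est, 2L, stats::sd, na.rm = TRUE) / sqrt(pmax(n_ok, 1L))
  se[n_ok < 2L] <- NA_real_
  list(se = unname(drop(se)), estimates = est)
}

#' Bootstrap standard error and percentile interval
#'
#' Resamples each state's samples with replacement, independently within each
#' state (sample counts preserved), re-evaluates the estimator on every
#' replicate, and reports the standard deviation over replicates plus a 95\%
#' percentile interval. Replicates in which the estimator fails are dropped
#' with a warning; at least half must survive. Assumes decorrelated input
#' samples.
#'
#' @inheritParams block_se
#' @param n_replicates number of bootstrap replicates R (>= 2)
#' @param seed RNG seed; the same seed reproduces the same replicate stream
#' @return list with \code{se}, \code{ci} (2.5/97.5 percentiles) and
#'   \code{estimates} (R x length matrix, failed replicates removed)
#' @export
bootstrap_se <- function(estimator, counts, n_replicates = 50L, seed = NULL) {
  R <- as.integer(n_replicates)
  if (R < 2L) stop("'n_replicates' must be >= 2")
  counts <- as.integer(counts)
  offsets <- c(0L, cumsum(counts))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  vals <- vector("list", R)
  failed <- 0L
  for (r in seq_len(R)) {
    idx <- unlist(lapply(seq_along(counts), function(j) {
      if (counts[j] == 0L) integer(0)
      else offsets[j] + sample.int(counts[j], counts[j], replace = TRUE)
    }), use.names = FALSE)
    vals[[r]] <- tryCatch(estimator(idx), error = function(e) {
      failed <<- failed + 1L
      NULL
    })
  }
  vals <- vals[!vapply(vals, is.null, TRUE)]
  if (failed > 0L)
    warning(failed, " bootstrap replicate(s) failed and were dropped")
  if (length(vals) < R / 2)
    stop("fewer than half of the bootstrap replicates survived (",
         length(vals), "/", R, ")")
  est <- do.call(rbind, lapply(vals, rbind))
  n_ok <- colSums(!is.na(est))
  se <- apply(est, 2L, stats::sd, na.rm = TRUE)
  se[n_ok < 2L] <- NA_real_
  ci <- apply(est, 2L, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  list(se = unname(drop(se)), ci = ci, estimates = est)
}

#' Stride subsampler
#'
#' Keeps every \code{stride}-th pooled sample within each state, a simple way
#' to thin autocorrelated time series before estimation (the estimator itself
#' assumes uncorrelated samples).
#'
#' @param counts per-state sample counts
#' @param stride keep every stride-th sample (>= 1)
#' @return integer vector of pooled sample indices to keep
#' @export
stride_subsample <- function(counts, stride) {
  stride <- as.integer(stride)
  if (stride < 1L) stop("'stride' must be >= 1")
  offsets <- c(0L, cumsum(as.integer(counts)))
  unlist(lapply(seq_along(counts), function(j) {
    if (counts[j] == 0L) integer(0)
    else offsets[j] + seq.int(1L, counts[j], by = stride)
  }), use.names = FALSE)
}
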