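#' Define a thermodynamic state
#'
#' A state is the combination of parameters that defines a reduced potential
#' \eqn{u_i(x) = \beta_i [U_i(x) + p_i V(x) + \mu_i^T n(x)]}. The \code{mode}
#' tag records how the potential-energy part is obtained from sample data:
#' \describe{
#'   \item{restraint}{umbrella-sampling windows; only the harmonic restraint
#'     \eqn{k_i (z - z_i^{ref})^2} enters, the shared system energy cancels.}
#'   \item{scaling}{temperature replica exchange; \eqn{u_i = \beta_i U_{system}}.}
#'   \item{accumulation}{alchemical perturbation chains; states are defined by
#'     their neighbor reduced-energy columns (see \code{\link{bar_pair}}), not
#'     by this constructor's energy fields.}
#'   \item{full}{full potential-energy tables (solute tempering, dual-level
#'     QM/MM); \code{energy_column} names the column holding \eqn{U_i}, and an
#'     optional restraint is added on top.}
#' }
#'
#' @param mode one of \code{"restraint"}, \code{"scaling"}, \code{"accumulation"},
#'   \code{"full"}
#' @param temperature temperature in K; alternative to \code{beta}
#' @param beta inverse temperature in 1/(kcal/mol); exactly one of
#'   \code{temperature}/\code{beta} must be given
#' @param pressure optional pressure such that pressure times the volume column
#'   is in kcal/mol
#' @param chem_potentials optional numeric vector of chemical potentials
#'   (kcal/mol per molecule), paired with molecule-count columns
#' @param spring_k restraint constant(s), kcal/mol per squared CV unit, in the
#'   \eqn{k (\Delta z)^2} convention (no 1/2 factor); see \code{half_spring}
#' @param z_ref restraint center(s) in CV units
#' @param periodic optional per-CV period for minimum-image wrapping of the
#'   restraint displacement (e.g. 360 for angles in degrees); default none
#' @param lambda optional alchemical coupling in [0,1] (metadata only)
#' @param energy_column name of the energy column holding \eqn{U_i} (mode
#'   \code{"full"})
#' @param half_spring if \code{TRUE}, \code{spring_k} is interpreted in the
#'   \eqn{\frac{1}{2} k (\Delta z)^2} convention used by some MD engines and
#'   converted internally
#' @return an object of class \code{"thermo_state"}
#' @seealso \code{\link{build_reduced_matrix}}, \code{\link{reduce_potential}}
#' @export
thermo_state <- function(mode = c("restraint", "scaling", "accumulation", "full"),
                         temperature = NULL, beta = NULL,
                         pressure = NULL, chem_potentials = NULL,
                         spring_k = NULL, z_ref = NULL, periodic = NULL,
                         lambda = NULL, energy_column = NULL,
                         half_spring = FALSE) {
  mode <- match.arg(mode)
  if (is.null(beta)) {
    if (is.null(temperature))
      stop("one of 'beta' or 'temperature' is required")
    beta <- beta_from_temperature(temperature)
  } else if (!is.null(temperature)) {
    stop("give either 'beta' or 'temperature', not both")
  }
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("'beta' must be a single positive number")
  if (!is.null(lambda) &&
      (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1))
    stop("'lambda' must lie in [0, 1]")
  if (!is.null(spring_k)) {
    if (any(spring_k < 0)) stop("'spring_k' must be >= 0")
    if (isTRUE(half_spring)) spring_k <- spring_k / 2
  }
  if (mode == "restraint") {
    if (is.null(spring_k) || is.null(z_ref))
      stop("mode 'restraint' requires 'spring_k' and 'z_ref'")
  }
  if (mode == "full" && is.null(energy_column))
    stop("mode 'full' requires 'energy_column'")
  if (!is.null(z_ref) && !is.null(periodic) &&
      length(periodic) != 1L && length(periodic) != length(z_ref))
    stop("'periodic' must be scalar or match the CV dimension")
  structure(list(mode = mode, beta = beta, pressure = pressure,
                 chem_potentials = chem_potentials,
                 spring_k = spring_k, z_ref = z_ref, periodic = periodic,
                 lambda = lambda, energy_column = energy_column),
            class = "thermo_state")
}

#' @export
print.thermo_state <- function(x, ...) {
  cat("<thermo_state>", x$mode, " beta =", format(x$beta, digits = 6))
  if (!is.null(x$z_ref))
    cat("  k =", paste(format(x$spring_k), collapse = ","),
        " z_ref =", paste(format(x$z_ref), collapse = ","))
  if (!is.null(x$energy_column)) cat("  U column =", x$energy_column)
  if (!is.null(x$lambda)) cat("  lambda =", x$lambda)
  cat("\n")
  invisible(x)
}

#' Samples drawn at one origin state
#'
#' Container for the per-state time series consumed by
#' \code{\link{build_reduced_matrix}}: collective-variable values, named energy
#' columns (kcal/mol), and optional volume / molecule-count columns. All
#' columns must have the same number of rows.
#'
#' @param origin index of the state the samples were generated at
#' @param cv numeric vector or N x d matrix of collective-variable values
#' @param energies data frame (or named list) of energy columns, kcal/mol
#' @param volume optional numeric volume column
#' @param mol_counts optional integer matrix/data frame of molecule counts
#' @return an object of class \code{"sample_set"} with element \code{n} rows
#' @export
sample_set <- function(origin, cv = NULL, energies = NULL, volume = NULL,
                       mol_counts = NULL) {
  n <- NA_integer_
  if (!is.null(cv)) {
    cv <- as.matrix(cv)
    storage.mode(cv) <- "double"
    n <- nrow(cv)
  }
  if (!is.null(energies)) {
    energies <- as.data.frame(energies)
    if (is.na(n)) n <- nrow(energies)
    if (nrow(energies) != n) stop("energy columns must have the same number of rows as 'cv'")
  }
  if (!is.null(volume)) {
    volume <- as.numeric(volume)
    if (is.na(n)) n <- length(volume)
    if (length(volume) != n) stop("'volume' length mismatch")
  }
  if (!is.null(mol_counts)) {
    mol_counts <- as.matrix(mol_counts)
    if (is.na(n)) n <- nrow(mol_counts)
    if (nrow(mol_counts) != n) stop("'mol_counts' row mismatch")
  }
  if (is.na(n)) n <- 0L
  structure(list(origin = as.integer(origin), n = as.integer(n), cv = cv,
                 energies = energies, volume = volume, mol_counts = mol_counts),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set> origin state", x$origin, "-", x$n, "samples")
  if (!is.null(x$cv)) cat(",", ncol(x$cv), "CV column(s)")
  if (!is.null(x$energies))
    cat(", energies:", paste(names(x$energies), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Harmonic restraint energy
#'
#' Evaluates \eqn{\sum_d k_d (\Delta z_d)^2} (no 1/2 factor) where
#' \eqn{\Delta z_d} is the minimum-image displacement when a period is declared
#' for that CV dimension.
#'
#' @param spring_k restraint constant, scalar or one per CV dimension
#'   (kcal/mol per squared CV unit)
#' @param z numeric vector (one sample per element, 1-D CV) or N x d matrix
#' @param z_ref restraint center, length d
#' @param periodic optional period(s); \code{NULL} (default) means non-periodic
#' @return numeric vector of restraint energies, kcal/mol
#' @examples
#' restraint_energy(1, 2, 0)                 # 4
#' restraint_energy(1, 179, -179, periodic = 360) # minimum image: (2)^2 = 4
#' @export
restraint_energy <- function(spring_k, z, z_ref, periodic = NULL) {
  z <- as.matrix(z)
  d <- ncol(z)
  if (length(z_ref) != d)
    stop("dimension mismatch: 'z' has ", d, " column(s), 'z_ref' has length ",
         length(z_ref))
  k <- rep_len(spring_k, d)
  dz <- sweep(z, 2L, z_ref, "-")
  if (!is.null(periodic)) {
    per <- rep_len(periodic, d)
    for (j in seq_len(d)) {
      if (is.finite(per[j]) && per[j] > 0)
        dz[, j] <- dz[, j] - per[j] * round(dz[, j] / per[j])
    }
  }
  drop(dz^2 %*% k)
}

#' Reduced potential of samples under one state
#'
#' Computes \eqn{u_i(x) = \beta_i [U_i(x) + p_i V(x) + \mu_i^T n(x)]} for every
#' sample in a \code{\link{sample_set}}. The potential-energy part depends on
#' the state's mode: restraint states use only the restraint energy evaluated
#' on the CV columns (the shared system energy cancels from the estimator),
#' scaling states use the \code{U_system} energy column, full states use the
#' column named by \code{energy_column} plus the restraint when one is
#' configured. Pressure-volume and chemical-potential terms are added when the
#' state declares them; omitted terms contribute zero.
#'
#' @param state a \code{\link{thermo_state}}
#' @param samples a \code{\link{sample_set}}
#' @return numeric vector of dimensionless reduced potentials, one per sample
#' @export
reduce_potential <- function(state, samples) {
  stopifnot(inherits(state, "thermo_state"), inherits(samples, "sample_set"))
  n <- samples$n
  U <- numeric(n)
  pick_energy <- function(col) {
    if (is.null(samples$energies) || is.null(samples$energies[[col]]))
      stop("missing column '", col, "' in sample set for state mode '",
           state$mode, "'")
    e <- samples$energies[[col]]
    bad <- is.na(e) | e == -Inf
    if (any(bad))
      stop("non-finite energy in column '", col, "' at sample(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "))
    e
  }
  if (state$mode == "restraint") {
    if (is.null(samples$cv)) stop("missing column 'cv' in sample set for restraint state")
    U <- restraint_energy(state$spring_k, samples$cv, state$z_ref, state$periodic)
  } else if (state$mode == "scaling") {
    U <- pick_energy("U_system")
  } else if (state$mode == "full") {
    U <- pick_energy(state$energy_column)
    if (!is.null(state$spring_k) && !is.null(state$z_ref)) {
      if (is.null(samples$cv)) stop("missing column 'cv' for restrained full-mode state")
      U <- U + restraint_energy(state$spring_k, samples$cv, state$z_ref,
                                state$periodic)
    }
  } else {
    stop("mode 'accumulation' states are estimated from neighbor energy sets; ",
         "see bar_pair()/fep_estimate()")
  }
  out <- U
  if (!is.null(state$pressure)) {
    if (is.null(samples$volume))
      stop("missing column 'volume' for a state with declared pressure")
    out <- out + state$pressure * samples$volume
  }
  if (!is.null(state$chem_potentials)) {
    if (is.null(samples$mol_counts))
      stop("missing column 'mol_counts' for a state with chemical potentials")
    out <- out + drop(samples$mol_counts %*% state$chem_potentials)
  }
  state$beta * out
}

#' Build the reduced-potential matrix
#'
#' Pools the samples of all sample sets and evaluates every state's reduced
#' potential on every pooled sample, giving the K x N matrix the estimator
#' consumes. All states must share one mode. States beyond the number of
#' sample sets are allowed and get a sample count of zero: they are target
#' states whose free energy is obtained by reweighting, and they do not enter
#' the mixture denominator.
#'
#' @param states list of \code{\link{thermo_state}} objects (length K)
#' @param samplesets list of \code{\link{sample_set}} objects (length <= K);
#'   sample set j holds the samples generated at state j
#' @return an object of class \code{"reduced_potential_matrix"}: list with the
#'   K x N matrix \code{u}, the per-state sample counts \code{counts}, the
#'   pooled-sample origin map \code{origin} and the shared \code{mode}
#' @export
build_reduced_matrix <- function(states, samplesets) {
  if (inherits(states, "thermo_state")) states <- list(states)
  if (inherits(samplesets, "sample_set")) samplesets <- list(samplesets)
  K <- length(states)
  J <- length(samplesets)
  if (J > K) stop("more sample sets than states")
  modes <- vapply(states, function(s) s$mode, "")
  if (length(unique(modes)) != 1L)
    stop("all states must share one mode; got: ", paste(unique(modes), collapse = ", "))
  if (modes[1L] == "accumulation")
    stop("accumulation mode uses neighbor energy sets; see fep_estimate()")
  counts <- integer(K)
  counts[seq_len(J)] <- vapply(samplesets, function(s) s$n, 0L)
  if (J > 0L && any(counts[seq_len(J)] == 0L))
    stop("sample set(s) ", paste(which(counts[seq_len(J)] == 0L), collapse = ", "),
         " are empty; zero-sample states are only allowed as appended targets")
  N <- sum(counts)
  u <- matrix(NA_real_, K, N)
  origin <- rep.int(seq_len(J), counts[seq_len(J)])
  for (i in seq_len(K)) {
    col0 <- 0L
    for (j in seq_len(J)) {
      u[i, col0 + seq_len(counts[j])] <- reduce_potential(states[[i]], samplesets[[j]])
      col0 <- col0 + counts[j]
    }
  }
  structure(list(u = u, counts = counts, origin = origin, mode = modes[1L],
                 states = states),
            class = "reduced_potential_matrix")
}

#' @export
print.reduced_potential_matrix <- function(x, ...) {
  cat("<reduced_potential_matrix>", nrow(x$u), "states x", ncol(x$u),
      "pooled samples (mode:", paste0(x$mode, ")"), "\n")
  cat("  counts:", paste(x$counts, collapse = " "), "\n")
  invisible(x)
}

#' Umbrella window ladder
#'
#' Inclusive arithmetic sequence of window centers from \code{start} to
#' \code{stop} in steps of \code{spacing}, robust to floating-point spacings
#' (0 to 180 by 3 gives 61 centers; -1 to 1 by 0.1 gives 21).
#'
#' @param start,stop first and last center (CV units); \code{stop >= start}
#' @param spacing positive step; ignored when \code{start == stop}
#' @return numeric vector of centers
#' @export
window_ladder <- function(start, stop, spacing) {
  if (stop < start) stop("'stop' must be >= 'start'")
  if (start == stop) return(start)
  if (!is.numeric(spacing) || spacing <= 0) stop("'spacing' must be > 0")
  n <- floor((stop - start) / spacing + 1e-9) + 1L
  start + (seq_len(n) - 1L) * spacing
}
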