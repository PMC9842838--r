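#' Boltzmann constant in kcal/(mol K)
#'
#' Used everywhere energies in kcal/mol are reduced to dimensionless form.
#' Fixed to the CODATA-derived value commonly used by MD packages.
#' @export
kB_kcal <- 0.0019872041

#' Inverse temperature from a temperature in Kelvin
#'
#' @param temperature temperature in K, positive
#' @return beta in 1/(kcal/mol)
#' @examples
#' beta_from_temperature(300) # ~1.6774
#' @export
beta_from_temperature <- function(temperature) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  1 / (kB_kcal * temperature)
}

# log(sum(exp(x))) without overflow; empty -> -Inf, all -Inf -> -Inf
logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (m == -Inf) return(-Inf)
  if (!is.finite(m)) return(Inf)
  m + log(sum(exp(x - m)))
}

# column-wise max of a matrix with few rows: K vectorised pmax passes
col_max <- function(X) {
  m <- X[1L, ]
  K <- nrow(X)
  if (K > 1L) for (k in 2L:K) m <- pmax(m, X[k, ])
  m
}

# column-wise logsumexp of a K x N matrix (K small); -Inf columns stay -Inf
col_logsumexp <- function(X) {
  m <- col_max(X)
  mf <- ifelse(is.finite(m), m, 0)
  s <- 0
  for (k in seq_len(nrow(X))) s <- s + exp(X[k, ] - mf)
  out <- mf + log(s)
  bad <- !is.finite(m)
  out[bad] <- m[bad]
  out
}

# format a numeric scalar/vector at full (17 significant digit) precision
format_full <- function(x) formatC(x, digits = 17, format = "g")
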