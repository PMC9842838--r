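#' Read a collective-variable trajectory file
#'
#' Whitespace- or comma-delimited text, one sample per row: column 1 is the
#' sample index, columns 2..d+1 the CV values. Lines starting with \code{#}
#' are skipped. Ragged rows raise an error naming the offending line.
#'
#' @param path file path
#' @return data frame with columns \code{index}, \code{z1}, ..., \code{zd}
#' @export
read_cv_file <- function(path) {
  tab <- read_delimited(path, header = FALSE)
  names(tab) <- c("index", paste0("z", seq_len(ncol(tab) - 1L)))
  tab
}

#' Read an energy table
#'
#' Delimited text with a header row: column 1 is the sample index, the
#' remaining columns are named energies (kcal/mol). Comment lines (\code{#})
#' are skipped.
#'
#' @param path file path
#' @return data frame; first column renamed \code{index}
#' @export
read_energy_file <- function(path) {
  tab <- read_delimited(path, header = TRUE)
  names(tab)[1L] <- "index"
  tab
}

#' Read a per-state neighbor-energy file
#'
#' Header row naming the reduced-energy columns (\code{u_prev}, \code{u_self},
#' \code{u_next}; first/last states omit the absent neighbor), one row per
#' sample.
#'
#' @param path file path
#' @param index chain position of the state
#' @return a \code{\link{neighbor_energy_set}}
#' @export
read_neighbor_file <- function(path, index) {
  tab <- read_delimited(path, header = TRUE)
  if (is.null(tab$u_self)) stop("neighbor file ", path, " lacks a 'u_self' column")
  neighbor_energy_set(index, u_self = tab$u_self, u_prev = tab$u_prev,
                      u_next = tab$u_next)
}

# shared delimited-text reader: '#' comments, whitespace or comma separators,
# ragged rows rejected with their line number
read_delimited <- function(path, header) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no data rows in ", path)
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  w <- lengths(parts)
  if (any(w != w[1L]))
    stop("ragged row in ", path, " at line ", lineno[which(w != w[1L])[1L]],
         " (", w[which(w != w[1L])[1L]], " fields, expected ", w[1L], ")")
  nms <- NULL
  if (header) {
    nms <- parts[[1L]]
    parts <- parts[-1L]
    if (!length(parts)) stop("no data rows in ", path)
  }
  m <- matrix(unlist(parts, use.names = FALSE), nrow = length(parts),
              byrow = TRUE)
  suppress <- function(x) suppressWarnings(as.numeric(x))
  df <- as.data.frame(apply(m, 2L, suppress), stringsAsFactors = FALSE)
  if (anyNA(df)) {
    bad <- which(rowSums(is.na(df)) > 0L)[1L]
    stop("non-numeric field in ", path, " at data row ", bad)
  }
  if (!is.null(nms)) names(df) <- nms
  df
}

#' Write a collective-variable trajectory file
#'
#' Inverse of \code{\link{read_cv_file}}: index column then CV columns, space
#' separated, values at 17 significant digits so a write/read round trip is
#' the identity.
#'
#' @param z numeric vector or matrix of CV values
#' @param path output path
#' @param header_lines optional comment lines (written with a leading
#'   \code{#})
#' @export
write_cv_file <- function(z, path, header_lines = NULL) {
  z <- as.matrix(z)
  rows <- cbind(seq_len(nrow(z)), z)
  txt <- apply(rows, 1L, function(r)
    paste(c(sprintf("%d", r[1L]), format_full(r[-1L])), collapse = " "))
  writeLines(c(if (!is.null(header_lines)) paste("#", header_lines), txt),
             path)
  invisible(path)
}

#' Write a named energy table with a header row
#'
#' @param energies data frame of named energy columns
#' @param path output path
#' @param header_lines optional comment lines
#' @export
write_energy_file <- function(energies, path, header_lines = NULL) {
  energies <- as.data.frame(energies)
  txt <- apply(as.matrix(energies), 1L, function(r)
    paste(format_full(r), collapse = " "))
  hdr <- paste(c("index", names(energies)), collapse = " ")
  body <- paste(seq_len(nrow(energies)), txt)
  writeLines(c(if (!is.null(header_lines)) paste("#", header_lines),
               hdr, body), path)
  invisible(path)
}

#' Write a neighbor-energy file
#'
#' @param set a \code{\link{neighbor_energy_set}}
#' @param path output path
#' @param header_lines optional comment lines
#' @export
write_neighbor_file <- function(set, path, header_lines = NULL) {
  cols <- list()
  if (!is.null(set$u_prev)) cols$u_prev <- set$u_prev
  cols$u_self <- set$u_self
  if (!is.null(set$u_next)) cols$u_next <- set$u_next
  df <- as.data.frame(cols)
  txt <- apply(as.matrix(df), 1L, function(r)
    paste(format_full(r), collapse = " "))
  writeLines(c(if (!is.null(header_lines)) paste("#", header_lines),
               paste(names(df), collapse = " "), txt), path)
  invisible(path)
}

#' Sort replica-indexed series into parameter-indexed series
#'
#' Replica-exchange output is usually written per replica, while the
#' estimator needs per-parameter (e.g. per-temperature) series. Given the
#' exchange map recording which parameter each replica held in each period,
#' this routes every sample to its parameter: sample n of the sorted series
#' for parameter i comes from the replica that held parameter i during n's
#' period.
#'
#' @param series list of per-replica numeric vectors (equal length), or a
#'   matrix with one column per replica
#' @param param_index n_periods x n_replicas integer matrix;
#'   \code{param_index[p, r]} is the parameter id replica r holds in period p.
#'   Every row must be a permutation of 1..n_replicas. The series length must
#'   be divisible by n_periods.
#' @return list of per-parameter numeric vectors
#' @export
demux_replicas <- function(series, param_index) {
  if (is.matrix(series)) series <- lapply(seq_len(ncol(series)), function(j) series[, j])
  R <- length(series)
  len <- unique(lengths(series))
  if (length(len) != 1L) stop("replica series must have equal length")
  param_index <- as.matrix(param_index)
  if (ncol(param_index) != R)
    stop("'param_index' must have one column per replica")
  P <- nrow(param_index)
  for (p in seq_len(P)) {
    if (!identical(sort(as.integer(param_index[p, ])), seq_len(R)))
      stop("period ", p, " of 'param_index' is not a permutation of 1..", R)
  }
  if (len %% P != 0L)
    stop("series length (", len, ") is not divisible by the number of periods (",
         P, ")")
  chunk <- len %/% P
  out <- lapply(seq_len(R), function(i) numeric(len))
  for (p in seq_len(P)) {
    rows <- (p - 1L) * chunk + seq_len(chunk)
    for (r in seq_len(R)) {
      i <- param_index[p, r]
      out[[i]][rows] <- series[[r]][rows]
    }
  }
  out
}

#' Write a PMF as CSV
#'
#' Columns: bin center(s), pmf, se, eff_count, empty flag; numeric values at
#' 17 significant digits. A comment header records the package version, seed
#' and configuration hash when provided.
#'
#' @param pmf an \code{\link{mbar_pmf}} or \code{\link{wham_umbrella}} result
#' @param path output path
#' @param header_lines optional comment lines
#' @export
write_pmf_csv <- function(pmf, path, header_lines = NULL) {
  df <- as.data.frame(pmf)
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) df[[j]] <- format_full(df[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste("#", header_lines), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
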