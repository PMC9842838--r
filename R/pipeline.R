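#' Run the full estimation pipeline from a declarative configuration
#'
#' Thin driver tying the package together: reads the input files named by the
#' configuration, builds the reduced-potential matrix for the configured mode,
#' solves the self-consistent equations, reweights to the target state, and
#' writes the report files. The command-line front end
#' (\code{inst/cli/mbar.R}) is a wrapper around this function, so CLI and
#' library calls produce identical numbers.
#'
#' Configuration fields (YAML file or named list):
#' \describe{
#'   \item{mode}{\code{"umbrella"}, \code{"remd"}, \code{"fep"} or
#'     \code{"full"}}
#'   \item{output_dir}{directory for the report files (created)}
#'   \item{seed}{RNG seed used for any resampling}
#'   \item{temperature / beta}{temperature in K, or inverse temperature
#'     directly; \code{reduced: true} declares already-dimensionless inputs
#'     (beta = 1)}
#'   \item{cv_files, centers, spring_k, periodic, half_spring}{umbrella and
#'     full-mode window data}
#'   \item{energy_files, temperatures}{scaling-mode (replica-exchange) data}
#'   \item{energy_column, target_column}{full-mode state/target energy
#'     column names}
#'   \item{neighbor_files}{accumulation-mode manifest, chain order}
#'   \item{bins}{list \code{min}, \code{max}, \code{nbins} for the PMF grid
#'     (note: a bare \code{n} key in YAML 1.1 parses as a boolean, so the
#'     key is \code{nbins}; \code{n} is still accepted from list configs)}
#'   \item{tolerance}{solver tolerance}
#'   \item{uncertainty}{list \code{method} (block/bootstrap),
#'     \code{n_blocks}, \code{n_replicates}}
#' }
#'
#' Outputs written to \code{output_dir}: \code{free_energy.json} (per-state
#' free energies, differences to state 1, effective sample sizes, solver
#' diagnostics), \code{pmf.csv} when a bin grid is configured, and
#' \code{chain.csv} for accumulation mode. Every file carries a header with
#' the package version, seed and configuration hash. On any stage error the
#' partially written outputs are removed.
#'
#' @param config path to a YAML file, or an equivalent named list
#' @return (invisibly) a list with the fitted objects and the output paths
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config error: 'config' must be a list or YAML path")
  mode <- config$mode
  if (is.null(mode) || !mode %in% c("umbrella", "remd", "fep", "full"))
    stop("config error: 'mode' must be one of umbrella, remd, fep, full")
  out_dir <- config$output_dir
  if (is.null(out_dir)) stop("config error: 'output_dir' is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  beta <- config_beta(config, required = mode != "remd" && mode != "fep")
  if (!is.null(config$seed)) set.seed(config$seed)
  tol <- config$tolerance %||% 1e-8
  plan <- config$uncertainty %||% list(method = "block")
  hash <- config_hash(config)
  hdr <- c(paste("mbar version", utils::packageVersion("mbar")),
           paste("seed", config$seed %||% "none"),
           paste("config", hash))

  written <- character(0)
  stage <- "input"
  outputs <- tryCatch({
    result <- list()
    if (mode == "fep") {
      files <- config$neighbor_files
      if (is.null(files)) stop("config error: 'neighbor_files' is required for fep mode")
      sets <- lapply(seq_along(files), function(i) read_neighbor_file(files[[i]], i))
      stage <- "estimate"
      chain <- fep_estimate(sets,
                            se = if ((plan$method %||% "block") == "block")
                              "block" else "pairsum",
                            n_blocks = plan$n_blocks %||% 10L)
      stage <- "report"
      chain_path <- file.path(out_dir, "chain.csv")
      df <- chain$pairs
      for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- format_full(df[[j]])
      con <- file(chain_path, "w")
      writeLines(paste("#", hdr), con)
      utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
      close(con)
      written <- c(written, chain_path)
      rep_path <- file.path(out_dir, "free_energy.json")
      jsonlite::write_json(list(header = hdr, total_delta_f = chain$total,
                                total_se = chain$total_se,
                                pair_delta_f = chain$pairs$delta_f,
                                pair_se = chain$pairs$se),
                           rep_path, auto_unbox = TRUE, digits = NA)
      written <- c(written, rep_path)
      result <- list(chain = chain, paths = written)
    } else {
      built <- switch(mode,
        umbrella = build_umbrella_inputs(config, beta),
        remd = build_remd_inputs(config),
        full = build_full_inputs(config, beta))
      stage <- "solve"
      fit <- mbar(built$rpm, tolerance = tol)
      stage <- "reweight"
      pmf <- NULL
      if (!is.null(config$bins)) {
        if (is.null(built$cv)) stop("config error: 'cv_files' required for a PMF")
        nb <- config$bins$nbins %||% config$bins$n
        if (is.null(config$bins$min) || is.null(config$bins$max) ||
            !is.numeric(nb))
          stop("config error: 'bins' needs numeric 'min', 'max' and 'nbins'")
        edges <- seq(config$bins$min, config$bins$max, length.out = nb + 1L)
        pmf <- mbar_pmf(fit, built$u_target, built$cv, edges,
                        se = plan$method %||% "block",
                        n_blocks = plan$n_blocks %||% 10L,
                        n_replicates = plan$n_replicates %||% 50L,
                        seed = config$seed)
      }
      stage <- "report"
      rep_path <- file.path(out_dir, "free_energy.json")
      jsonlite::write_json(list(header = hdr, f_hat = fit$f_hat,
                                delta_f_to_state1 = fit$f_hat - fit$f_hat[1L],
                                counts = fit$counts, ess = fit$ess,
                                n_iterations = fit$n_iterations,
                                final_residual = fit$final_residual,
                                tolerance = tol),
                           rep_path, auto_unbox = TRUE, digits = NA)
      written <- c(written, rep_path)
      if (!is.null(pmf)) {
        pmf_path <- file.path(out_dir, "pmf.csv")
        write_pmf_csv(pmf, pmf_path, header_lines = hdr)
        written <- c(written, pmf_path)
      }
      result <- list(fit = fit, pmf = pmf, paths = written)
    }
    result
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(outputs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_beta <- function(config, required = TRUE) {
  if (isTRUE(config$reduced)) return(1)
  if (!is.null(config$beta)) return(config$beta)
  if (!is.null(config$temperature)) return(beta_from_temperature(config$temperature))
  if (required)
    stop("config error: one of 'temperature', 'beta' or 'reduced: true' is required")
  NULL
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

build_umbrella_inputs <- function(config, beta) {
  for (fld in c("cv_files", "centers", "spring_k"))
    if (is.null(config[[fld]]))
      stop("config error: '", fld, "' is required for umbrella mode")
  files <- config$cv_files
  centers <- unlist(config$centers)
  if (length(files) != length(centers))
    stop("config error: 'cv_files' and 'centers' lengths differ")
  k <- rep_len(unlist(config$spring_k), length(files))
  states <- lapply(seq_along(files), function(i)
    thermo_state("restraint", beta = beta, spring_k = k[i],
                 z_ref = centers[i], periodic = config$periodic,
                 half_spring = isTRUE(config$half_spring)))
  samplesets <- lapply(seq_along(files), function(i) {
    tab <- read_cv_file(files[[i]])
    sample_set(origin = i, cv = as.matrix(tab[, -1L, drop = FALSE]))
  })
  cv <- do.call(rbind, lapply(samplesets, function(s) s$cv))
  list(rpm = build_reduced_matrix(states, samplesets),
       u_target = 0, cv = if (ncol(cv) == 1L) drop(cv) else cv)
}

build_remd_inputs <- function(config) {
  if (is.null(config$temperatures))
    stop("config error: 'temperatures' is required for remd (scaling) mode")
  if (is.null(config$energy_files))
    stop("config error: 'energy_files' is required for remd mode")
  temps <- unlist(config$temperatures)
  files <- config$energy_files
  if (length(files) != length(temps))
    stop("config error: 'energy_files' and 'temperatures' lengths differ")
  betas <- beta_from_temperature(temps)
  states <- lapply(betas, function(b) thermo_state("scaling", beta = b))
  samplesets <- vector("list", length(files))
  cv <- NULL
  for (i in seq_along(files)) {
    tab <- read_energy_file(files[[i]])
    if (is.null(tab$U_system))
      stop("config error: energy file ", files[[i]], " lacks a 'U_system' column")
    cv_i <- NULL
    if (!is.null(config$cv_files)) {
      cv_i <- as.matrix(read_cv_file(config$cv_files[[i]])[, -1L, drop = FALSE])
      if (nrow(cv_i) != nrow(tab))
        stop("config error: cv/energy row mismatch for state ", i)
    }
    samplesets[[i]] <- sample_set(origin = i, cv = cv_i,
                                  energies = tab[, -1L, drop = FALSE])
    cv <- rbind(cv, cv_i)
  }
  rpm <- build_reduced_matrix(states, samplesets)
  # target: the lowest temperature (state 1)
  list(rpm = rpm, u_target = rpm$u[1L, ],
       cv = if (!is.null(cv) && ncol(cv) == 1L) drop(cv) else cv)
}

build_full_inputs <- function(config, beta) {
  if (is.null(config$energy_files))
    stop("config error: 'energy_files' is required for full mode")
  if (is.null(config$energy_column) || is.null(config$target_column))
    stop("config error: 'energy_column' and 'target_column' are required for full mode")
  files <- config$energy_files
  centers <- unlist(config$centers)
  k <- if (!is.null(config$spring_k))
    rep_len(unlist(config$spring_k), length(files))
  states <- lapply(seq_along(files), function(i)
    thermo_state("full", beta = beta, energy_column = config$energy_column,
                 spring_k = if (!is.null(k)) k[i],
                 z_ref = if (!is.null(centers)) centers[i],
                 periodic = config$periodic,
                 half_spring = isTRUE(config$half_spring)))
  target <- thermo_state("full", beta = beta,
                         energy_column = config$target_column)
  samplesets <- vector("list", length(files))
  cv <- NULL
  for (i in seq_along(files)) {
    tab <- read_energy_file(files[[i]])
    cv_i <- NULL
    if (!is.null(config$cv_files)) {
      cv_i <- as.matrix(read_cv_file(config$cv_files[[i]])[, -1L, drop = FALSE])
      if (nrow(cv_i) != nrow(tab))
        stop("config error: cv/energy row mismatch for state ", i)
    }
    samplesets[[i]] <- sample_set(origin = i, cv = cv_i,
                                  energies = tab[, -1L, drop = FALSE])
    cv <- rbind(cv, cv_i)
  }
  rpm <- build_reduced_matrix(states, samplesets)
  u_target <- unlist(lapply(samplesets, function(s)
    reduce_potential(target, s)), use.names = FALSE)
  list(rpm = rpm, u_target = u_target,
       cv = if (!is.null(cv) && ncol(cv) == 1L) drop(cv) else cv)
}
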