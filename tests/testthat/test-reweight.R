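test_that("target weights are uniform for the sampled state and shift invariant", {
  set.seed(2)
  x <- rnorm(50)
  u <- matrix(x^2 / 2, 1)
  fit <- suppressWarnings(mbar(u, counts = 50L))
  lw <- target_log_weights(fit, u[1, ])
  expect_equal(exp(lw), rep(1 / 50, 50))
  expect_equal(target_log_weights(fit, u[1, ] + 11.3), lw)
  expect_error(target_log_weights(fit, rep(Inf, 50)), "no overlap")
})

test_that("reweighting to a sampled state reproduces its free energy exactly", {
  g <- gen_harmonic_states(sigma = c(1, 1.8, 2.6), n = 400, seed = 5)
  fit <- mbar(g$u)
  for (i in 1:3)
    expect_equal(target_free_energy(fit, g$u$u[i, ]), fit$f_hat[i],
                 tolerance = 1e-12)
  expect_equal(target_free_energy(fit, g$u$u[2, ] + 2.5), fit$f_hat[2] + 2.5,
               tolerance = 1e-12)
})

test_that("restraint-free umbrella target matches the quadrature reference", {
  pot <- dw_potential()
  gen <- gen_umbrella_windows(pot, window_ladder(-1, 1, 0.2), spring_k = 10,
                              beta = beta300, n = 800, seed = 8)
  rpm <- build_reduced_matrix(gen$states, gen$samplesets)
  fit <- suppressWarnings(mbar(rpm))
  est <- function(idx) {
    cnt <- tabulate(rpm$origin[idx], nbins = length(rpm$counts))
    sub <- suppressWarnings(mbar(rpm$u[, idx, drop = FALSE], counts = cnt,
                                 initial_f = fit$f_hat))
    target_free_energy(sub, 0)
  }
  bs <- block_se(est, rpm$counts, n_blocks = 8)
  # oracle: -ln Z(unrestrained) + ln Z(window 1), both by quadrature
  c1 <- gen$states[[1]]$z_ref
  ref <- free_energy_quadrature(pot, beta300) -
    free_energy_quadrature(function(z) pot$fn(z) + 10 * (z - c1)^2, beta300,
                           pot$bounds[1], pot$bounds[2])
  expect_lt(abs(target_free_energy(fit, 0) - ref), 3 * bs$se)
})

test_that("expectations are normalized, linear and reduce to plain means", {
  g <- gen_harmonic_states(sigma = c(1, 2), n = 300, seed = 6)
  fit <- mbar(g$u)
  N <- sum(g$u$counts)
  expect_equal(mbar_expectation(fit, 0, rep(1, N)), 1)
  expect_equal(mbar_expectation(fit, 0, rep(2.5, N)), 2.5)
  x1 <- rnorm(40); u1 <- matrix(x1^2 / 2, 1)
  fit1 <- suppressWarnings(mbar(u1, counts = 40L))
  expect_equal(mbar_expectation(fit1, u1[1, ], x1), mean(x1))
})

test_that("direct weighted averages equal the free-energy-ratio form for A > 0", {
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  g <- gen_harmonic_states(sigma = c(1, 1.5), n = 400, seed = 10)
  fit <- mbar(g$u)
  A <- exp(-abs(g$x))           # positive observable
  u_t <- 0.3 * g$x^2            # some target
  direct <- mbar_expectation(fit, u_t, A)
  f_t <- target_free_energy(fit, u_t)
  f_tA <- -lse(log(A) - u_t - fit$log_denominator)
  expect_equal(direct, exp(f_t - f_tA), tolerance = 1e-12)
})

test_that("ESS of reweighting degrades for extrapolated narrower targets", {
  g <- gen_harmonic_states(sigma = c(1, 2), n = 2000, seed = 12)
  fit <- mbar(g$u)
  ess_of <- function(u_t) {
    lw <- target_log_weights(fit, u_t)
    1 / sum(exp(2 * lw))
  }
  narrow <- (g$x)^2 / (2 * 0.25^2)  # sigma = 0.25, sampled nowhere
  expect_gt(ess_of(g$u$u[1, ]), ess_of(narrow))
})

test_that("PMFs are flat for uniform weights and flag empty bins", {
  # equal occupancy by construction: deterministic positions
  z <- rep(seq(0.05, 0.95, 0.1), each = 10)
  u <- matrix(0, 1, length(z))
  fit <- mbar(u, counts = length(z))
  pmf <- mbar_pmf(fit, 0, z, seq(0, 1, 0.1))
  expect_equal(pmf$pmf, rep(0, 10))
  # empty bin: flagged NA and excluded from the min-shift
  pmf2 <- mbar_pmf(fit, 0, z, seq(0, 1.2, 0.1))
  expect_true(all(pmf2$empty[11:12]))
  expect_true(all(is.na(pmf2$pmf[11:12])))
  expect_equal(min(pmf2$pmf, na.rm = TRUE), 0)
  expect_error(mbar_pmf(fit, 0, z + 100, seq(0, 1, 0.1)), "empty|bins")
})

test_that("per-bin probabilities recombine to the normalized weights", {
  g <- gen_harmonic_states(sigma = c(1, 1.5), n = 500, seed = 14)
  fit <- mbar(g$u)
  edges <- seq(-8, 8, length.out = 33)  # covers every sample
  pmf <- mbar_pmf(fit, 0, g$x, edges)
  p_bins <- exp(-pmf$pmf[!pmf$empty])
  p_bins <- p_bins / sum(p_bins)
  lw <- target_log_weights(fit, 0)
  ref <- tapply(exp(lw), cut(g$x, edges, right = FALSE), sum)
  ref <- as.numeric(ref[!is.na(ref)])
  expect_equal(p_bins, ref / sum(ref), tolerance = 1e-12)
})

test_that("estimates are invariant under splitting a sample set", {
  g <- gen_harmonic_states(sigma = c(1, 2), n = 400, seed = 16)
  # split state 2's samples into two batches attached to duplicate state rows
  u_split <- rbind(g$u$u, g$u$u[2, ])
  counts_split <- c(400L, 250L, 150L)
  fit <- mbar(g$u, tolerance = 1e-12)
  fit_s <- mbar(u_split, counts = counts_split, tolerance = 1e-12)
  expect_equal(fit_s$f_hat[2], fit$f_hat[2], tolerance = 1e-10)
  edges <- seq(-6, 6, length.out = 25)
  p1 <- mbar_pmf(fit, 0, g$x, edges)$pmf
  p2 <- mbar_pmf(fit_s, 0, g$x, edges)$pmf
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("umbrella PMF tracks the quadrature ground truth", {
  pot <- dw_potential()
  gen <- gen_umbrella_windows(pot, window_ladder(-1, 1, 0.1), spring_k = 10,
                              beta = beta300, n = 600, seed = 18)
  fit <- suppressWarnings(mbar(build_reduced_matrix(gen$states, gen$samplesets)))
  edges <- seq(-1.1, 1.1, length.out = 26)
  pmf <- mbar_pmf(fit, 0, gen$cv, edges)
  ref <- pmf_quadrature(pot, beta300, edges)
  ok <- !pmf$empty & pmf$eff_count >= 50
  expect_lt(aligned_max_dev(pmf$pmf[ok], ref$pmf[ok]), 0.2)
})

test_that("kcal/mol reporting scales the PMF by kT", {
  z <- rep(seq(0.05, 0.95, 0.1), times = c(1:5, 5:1)) # uneven occupancy
  u <- matrix(0, 1, length(z))
  fit <- suppressWarnings(mbar(u, counts = length(z)))
  p_kt <- mbar_pmf(fit, 0, z, seq(0, 1, 0.1))
  p_kc <- mbar_pmf(fit, 0, z, seq(0, 1, 0.1), units = "kcal/mol",
                   temperature = 300)
  expect_equal(p_kc$pmf, p_kt$pmf * kB_kcal * 300)
  expect_error(mbar_pmf(fit, 0, z, seq(0, 1, 0.1), units = "kcal/mol"),
               "temperature")
})

test_that("two-dimensional PMFs bin, shift and flag correctly", {
  ang <- gen_2d_periodic(beta = 1.7, n = 800, seed = 20)
  u <- matrix(0, 1, nrow(ang))
  fit <- mbar(u, counts = nrow(ang))
  edges <- list(seq(-180, 180, length.out = 13), seq(-180, 180, length.out = 13))
  pmf <- mbar_pmf(fit, 0, ang, edges)
  expect_equal(pmf$shape, c(12L, 12L))
  expect_length(pmf$pmf, 144L)
  expect_equal(min(pmf$pmf, na.rm = TRUE), 0)
  expect_true(all(is.na(pmf$pmf[pmf$empty])))
  df <- as.data.frame(pmf)
  expect_equal(nrow(df), 144L)
  expect_error(mbar_pmf(fit, 0, cbind(ang, ang[, 1]),
                        list(1:2, 1:2, 1:2)), "1 or 2")
})
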