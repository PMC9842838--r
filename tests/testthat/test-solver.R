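test_that("degenerate and symmetric instances solve exactly", {
  # single state: anchored zero
  fit1 <- suppressWarnings(mbar(matrix(rnorm(5), 1), counts = 5))
  expect_identical(fit1$f_hat, 0)
  # two identical states with equal counts: zero difference
  u <- matrix(rnorm(20), 2, 10, byrow = FALSE)
  u[2, ] <- u[1, ]
  fit2 <- suppressWarnings(mbar(u, counts = c(5, 5)))
  expect_equal(fit2$f_hat[2], 0, tolerance = 1e-10)
  expect_true(fit2$converged)
})

test_that("Gaussian two-state difference recovers the analytic -ln 2", {
  g <- gen_harmonic_states(sigma = c(1, 2), n = 10000, seed = 42)
  fit <- mbar(g$u)
  est <- function(idx) {
    cnt <- tabulate(g$u$origin[idx], nbins = 2)
    suppressWarnings(mbar(g$u$u[, idx, drop = FALSE], counts = cnt,
                          initial_f = fit$f_hat))$f_hat[2]
  }
  bs <- bootstrap_se(est, g$u$counts, n_replicates = 50, seed = 7)
  expect_lt(abs(fit$f_hat[2] - (-log(2))), 3 * bs$se)
})

test_that("self_consistent_step is a fixed point at the solution", {
  g <- gen_harmonic_states(sigma = c(1, 1.6, 2.4), n = 400, seed = 3)
  fit <- mbar(g$u, tolerance = 1e-13)
  stepped <- self_consistent_step(fit$f_hat, fit$u, fit$counts)
  expect_equal(stepped, fit$f_hat, tolerance = 1e-12)
  # K = 1 and fully symmetric states stay at zero
  expect_equal(self_consistent_step(0, matrix(rnorm(4), 1), 4L), 0)
  u0 <- matrix(0, 3, 9)
  expect_equal(self_consistent_step(rep(0, 3), u0, c(3L, 3L, 3L)), rep(0, 3))
})

test_that("newton_step vanishes at the fixed point and accelerates convergence", {
  g <- gen_harmonic_states(sigma = c(1, 1.6, 2.4), n = 400, seed = 3)
  fit <- mbar(g$u, tolerance = 1e-13)
  upd <- newton_step(fit$f_hat, fit$u, fit$counts)
  expect_lt(max(abs(upd - fit$f_hat)), 1e-10)

  # near the solution the residual contracts at least quadratically-fast
  f_near <- fit$f_hat + c(0, 1e-3, -1e-3)
  r0 <- mbar_residual(f_near, fit$u, fit$counts)
  r1 <- mbar_residual(newton_step(f_near, fit$u, fit$counts), fit$u, fit$counts)
  expect_lt(r1, 50 * r0^2)

  # hybrid Newton path needs fewer iterations than pure self-consistency
  f_sc <- rep(0, 3)
  it_sc <- 0
  repeat {
    it_sc <- it_sc + 1
    fn <- self_consistent_step(f_sc, g$u$u, g$u$counts)
    if (max(abs(fn - f_sc)) < 1e-8 || it_sc > 5000) break
    f_sc <- fn
  }
  expect_lt(fit$n_iterations, it_sc)
})

test_that("the residual is zero at solutions and gauge invariant", {
  expect_equal(mbar_residual(0, matrix(rnorm(3), 1), 3L), 0)
  u <- matrix(rnorm(12), 2, 6); u[2, ] <- u[1, ]
  expect_lt(mbar_residual(c(0, 0), u, c(3L, 3L)), 1e-12)
  g <- gen_harmonic_states(sigma = c(1, 2, 3), n = 100, seed = 9)
  f <- c(0, 0.4, -0.2)
  shifted <- (f + 5) - (f[1] + 5)
  expect_equal(mbar_residual(f, g$u$u, g$u$counts),
               mbar_residual(shifted, g$u$u, g$u$counts))
})

test_that("mixture weights normalize to one for every sampled state", {
  g <- gen_harmonic_states(sigma = c(1, 1.5, 2), n = 300, seed = 11)
  fit <- mbar(g$u)
  for (k in 1:3) {
    w <- exp(fit$f_hat[k] - fit$u[k, ] - fit$log_denominator)
    expect_equal(sum(w), 1, tolerance = 1e-8)
  }
})

test_that("adding a constant to one row shifts only that state's free energy", {
  g <- gen_harmonic_states(sigma = c(1, 1.7, 2.3), n = 250, seed = 13)
  fit <- mbar(g$u, tolerance = 1e-12)
  u2 <- g$u$u
  u2[2, ] <- u2[2, ] + 3.7
  fit2 <- mbar(u2, counts = g$u$counts, tolerance = 1e-12)
  expect_equal(fit2$f_hat[2] - fit$f_hat[2], 3.7, tolerance = 1e-9)
  expect_equal(fit2$f_hat[3], fit$f_hat[3], tolerance = 1e-9)
})

test_that("permuting states permutes the estimates up to re-anchoring", {
  g <- gen_harmonic_states(sigma = c(1, 1.5, 2.2, 0.8), n = 150, seed = 17)
  fit <- mbar(g$u, tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  fitp <- mbar(g$u$u[perm, ], counts = g$u$counts[perm], tolerance = 1e-12)
  expect_equal(fitp$f_hat, fit$f_hat[perm] - fit$f_hat[perm][1],
               tolerance = 1e-9)
})

test_that("solutions match an independent fixed-point oracle on random instances", {
  set.seed(23)
  for (r in 1:12) {
    K <- sample(2:4, 1)
    inst <- random_instance(K)
    fit <- suppressWarnings(mbar(inst$u, counts = inst$counts, tolerance = 1e-12))
    oracle <- fixed_point_oracle(inst$u, inst$counts, f0 = rep(0.3, K))
    expect_equal(fit$f_hat, oracle, tolerance = 1e-7)
  }
})

test_that("the two-state solution equals the Bennett bisection root", {
  set.seed(29)
  for (r in 1:10) {
    inst <- random_instance(2)
    fit <- suppressWarnings(mbar(inst$u, counts = inst$counts, tolerance = 1e-12))
    expect_equal(fit$f_hat[2], bar_bisection_oracle(inst$u, inst$counts),
                 tolerance = 1e-8)
  }
})

test_that("zero-count states behave as appended targets", {
  g <- gen_harmonic_states(sigma = c(1, 2), n = 500, seed = 31)
  u3 <- rbind(g$u$u, (g$x - 0.3)^2 / 2)
  fit <- mbar(u3, counts = c(g$u$counts, 0L))
  # appended state's free energy equals direct reweighting
  fit2 <- mbar(g$u)
  expect_equal(fit$f_hat[3], target_free_energy(fit2, u3[3, ]))
  expect_equal(fit$f_hat[1:2], fit2$f_hat)
})

test_that("solver failures raise informative conditions", {
  g <- gen_harmonic_states(sigma = c(1, 3), n = 200, seed = 37)
  err <- tryCatch(mbar(g$u, max_iterations = 2L, tolerance = 1e-14),
                  error = function(e) e)
  expect_s3_class(err, "mbar_convergence_error")
  expect_true(length(err$residual_trace) >= 1)
  # a sample with +Inf in every sampled state is rejected
  u <- matrix(c(1, 2, Inf, Inf), 2, 2)
  expect_error(mbar(u, counts = c(1L, 1L)), "all-infinite")
  expect_error(mbar(matrix(numeric(0), 1, 0), counts = 0L),
               "at least one state")
})

test_that("+Inf reduced potentials act as zero weight without poisoning sums", {
  g <- gen_harmonic_states(sigma = c(1, 1.4), n = 300, seed = 41)
  u <- g$u$u
  u[2, 5] <- Inf  # one unreachable configuration for state 2
  fit <- mbar(u, counts = g$u$counts)
  expect_true(all(is.finite(fit$f_hat)))
  expect_true(fit$converged)
})

test_that("effective sample sizes flag targets with poor overlap", {
  # appended target far outside the sampled region
  set.seed(43)
  x <- rnorm(400, 0, 1)
  u <- rbind(x^2 / 2, (x - 6)^2 / 2)
  expect_warning(fit <- mbar(u, counts = c(400L, 0L)), "overlap")
  expect_lt(fit$ess[2], 50)
  expect_gt(fit$ess[1], 100)
})
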