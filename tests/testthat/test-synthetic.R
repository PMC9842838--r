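test_that("harmonic-state generation is reproducible with analytic truth", {
  g1 <- gen_harmonic_states(sigma = c(1, 2), n = 500, seed = 61)
  g2 <- gen_harmonic_states(sigma = c(1, 2), n = 500, seed = 61)
  expect_identical(g1$x, g2$x)
  # analytic difference confirmed by independent quadrature of the
  # Boltzmann integral
  quad <- function(s) -log(integrate(function(x) exp(-x^2 / (2 * s^2)),
                                     -Inf, Inf)$value)
  expect_equal(g1$f_analytic[2], quad(2) - quad(1), tolerance = 1e-9)
  expect_equal(g1$f_analytic[2], -log(2), tolerance = 1e-12)
  g3 <- gen_harmonic_states(sigma = c(1, 2), n = 10000, seed = 62)
  v <- tapply(g3$x, g3$u$origin, var)
  expect_lt(abs(v[[1]] - 1) / 1, 0.05)
  expect_lt(abs(v[[2]] - 4) / 4, 0.05)
})

test_that("the exact Boltzmann sampler reproduces quadrature moments", {
  pot <- dw_potential()
  set.seed(63)
  z <- sample_boltzmann(pot, beta300, 20000)
  q <- integrate(function(x) exp(-beta300 * pot$fn(x)), -1.35, 1.35)$value
  m2_ref <- integrate(function(x) x^2 * exp(-beta300 * pot$fn(x)),
                      -1.35, 1.35)$value / q
  expect_lt(abs(mean(z^2) - m2_ref) / m2_ref, 0.03)
  set.seed(63)
  expect_identical(z, sample_boltzmann(pot, beta300, 20000))
})

test_that("Metropolis sampling behaves in its limiting regimes", {
  flat <- toy_potential("table", z = c(0, 1), U = c(0, 0), bounds = c(0, 1))
  # vanishing step size: everything is accepted
  z0 <- mcmc_sample(flat, beta = 1, n = 200, step_size = 1e-8, seed = 64)
  expect_gt(attr(z0, "acceptance"), 0.999)
  # flat potential with hard walls: uniform histogram
  z <- mcmc_sample(toy_potential("harmonic", k = 0, bounds = c(0, 1)),
                   beta = 1, n = 5000, step_size = 0.5, x0 = 0.5, seed = 65)
  h <- table(cut(as.numeric(z), seq(0, 1, 0.1)))
  expect_gt(chisq.test(h)$p.value, 0.001)
})

test_that("Metropolis histograms match the Boltzmann quadrature", {
  pot <- dw_potential()
  z <- as.numeric(mcmc_sample(pot, beta = beta300 / 2, n = 20000,
                              step_size = 0.5, stride = 5, seed = 66))
  edges <- seq(-1.35, 1.35, length.out = 16)
  q <- pmf_quadrature(pot, beta300 / 2, edges)
  h <- hist(z, breaks = edges, plot = FALSE)$counts
  expect_gt(chisq.test(h, p = q$prob)$p.value, 0.001)
})

test_that("temperature ladders satisfy equipartition and reproducibility", {
  pot <- toy_potential("harmonic", k = 1, bounds = c(-20, 20))
  betas <- c(2, 1, 0.5)
  sets <- gen_temperature_ladder(pot, betas, n = 10000, seed = 67)
  for (i in 1:3) {
    meanU <- mean(sets[[i]]$energies$U_system)
    expect_lt(abs(meanU - 1 / (2 * betas[i])) / (1 / (2 * betas[i])), 0.05)
  }
  sets2 <- gen_temperature_ladder(pot, betas, n = 10000, seed = 67)
  expect_identical(sets[[2]]$cv, sets2[[2]]$cv)
  expect_error(gen_temperature_ladder(pot, c(1, 1), 10, seed = 1),
               "decreasing")
  # equal temperatures drawn separately are statistically indistinguishable
  set.seed(68); a <- sample_boltzmann(pot, 1, 3000)
  set.seed(69); b <- sample_boltzmann(pot, 1, 3000)
  expect_gt(suppressWarnings(ks.test(a, b)$p.value), 0.01)
})

test_that("coupling chains honor the mixing rule and degenerate schedules", {
  us <- toy_potential("harmonic", k = 1, bounds = c(-6, 6))
  ue <- toy_potential("harmonic", k = 1, center = 1, bounds = c(-6, 7))
  ch <- gen_fep_chain(us, ue, lambdas = c(0, 0.5, 1), beta = 2, n = 200,
                      seed = 70)
  # mixing identity on the interior state: u_mid = (u_prev + u_next) / 2
  # because the schedule is equally spaced and the mixture is linear
  s2 <- ch$sets[[2]]
  expect_equal(s2$u_self, (s2$u_prev + s2$u_next) / 2, tolerance = 1e-12)
  # identical endpoints: lambda = 0 energies equal U_start evaluations
  # exactly, and all references vanish
  same <- gen_fep_chain(us, us, lambdas = c(0, 1), beta = 1, n = 300, seed = 71)
  expect_identical(same$sets[[1]]$u_self, same$sets[[1]]$u_next)
  expect_equal(same$delta_f_ref, 0, tolerance = 1e-9)
  expect_equal(fep_estimate(same$sets, se = "pairsum", n_blocks = 5)$total, 0,
               tolerance = 1e-9)
})

test_that("the harmonic chain total matches quadrature within noise", {
  us <- toy_potential("harmonic", k = 1, bounds = c(-6, 6))
  ue <- toy_potential("table", z = seq(-6, 7, 0.01),
                      U = (seq(-6, 7, 0.01) - 1)^2 + 1, bounds = c(-6, 7))
  ch <- gen_fep_chain(us, ue, lambdas = seq(0, 1, 0.2), beta = 1, n = 800,
                      seed = 72)
  # closed form: equal spring constants, offset b = 1 -> total beta * b
  expect_equal(ch$total_ref, 1, tolerance = 1e-4)
  res <- fep_estimate(ch$sets, se = "block", n_blocks = 5)
  expect_lt(abs(res$total - ch$total_ref), 3 * res$total_se)
})

test_that("dual-level data reduces to the low level when the correction vanishes", {
  pot <- dw_potential()
  centers <- window_ladder(-1, 1, 0.2)
  dl <- gen_dual_level(pot, function(z) 0 * z, centers, spring_k = 10,
                       beta = beta300, n = 800, seed = 73)
  rpm <- build_reduced_matrix(c(dl$states, list(dl$target)), dl$samplesets)
  fit <- suppressWarnings(mbar(rpm))
  cv <- unlist(lapply(dl$samplesets, function(s) drop(s$cv)))
  edges <- seq(-1.1, 1.1, length.out = 23)
  pmf <- mbar_pmf(fit, rpm$u[length(dl$states) + 1L, ], cv, edges,
                  se = "block", n_blocks = 8)
  ref <- pmf_quadrature(pot, beta300, edges)   # HL == LL ground truth
  ok <- !pmf$empty & pmf$eff_count >= 50
  se <- pmax(pmf$se[ok], 1e-3)
  dev <- pmf$pmf[ok] - ref$pmf[ok]
  off <- sum(dev / se^2) / sum(1 / se^2)
  expect_lt(max(abs(dev - off) / se), 4)
  dl2 <- gen_dual_level(pot, function(z) 0 * z, centers, spring_k = 10,
                        beta = beta300, n = 800, seed = 73)
  expect_identical(dl$samplesets[[3]]$cv, dl2$samplesets[[3]]$cv)
})

test_that("generator manifests are sufficient to regenerate bit-identically", {
  g <- gen_harmonic_states(sigma = c(1, 1.5), n = 100, seed = 74)
  m <- g$manifest
  g2 <- do.call(gen_harmonic_states,
                list(sigma = m$sigma, centers = m$centers, n = m$n,
                     seed = m$seed))
  expect_identical(g$x, g2$x)
  sets <- gen_temperature_ladder(toy_potential("harmonic", k = 1,
                                               bounds = c(-10, 10)),
                                 c(2, 1), n = 50, seed = 75)
  expect_named(attr(sets, "manifest"), c("generator", "seed", "potential",
                                         "betas", "n"))
})
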