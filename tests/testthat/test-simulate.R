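test_that("draw sets are reproducible and internally consistent", {
  p <- circuit_params(sigma_up = 0.5, kappa = 0.25, sigma_down = 0.3,
                      rho_up = 0.4, rho_down = -0.2, n_pathways = 2)
  f <- list(piecewise_nonlinearity(-1, 1),
            piecewise_nonlinearity(-1, 1, polarity = "OFF"))
  d1 <- simulate_circuit(p, f, n = 500, seed = 99)
  d2 <- simulate_circuit(p, f, n = 500, seed = 99)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_equal(d1$r_1, d1$stage_1 + d1$zeta_1)
  expect_equal(d1$r_2, d1$stage_2 + d1$zeta_2)
  d3 <- simulate_circuit(p, f, n = 500, seed = 100)
  expect_false(identical(d1$s, d3$s))
})

test_that("a zero nonlinearity with no downstream noise yields zero responses", {
  p <- circuit_params(kappa = 0.5, sigma_down = 0)
  d <- simulate_circuit(p, constant_nl(0), n = 200, seed = 1)
  expect_true(all(d$r_1 == 0))
})

test_that("scaled-Poisson stage has mean f and variance kappa * f", {
  # fixed conditional mean f = 0.5 via a constant transfer function
  p <- circuit_params(kappa = 0.25, sigma_down = 0)
  d <- simulate_circuit(p, constant_nl(0.5), n = 2e5, seed = 3)
  se_mean <- sqrt(0.125 / 2e5)
  expect_within(mean(d$r_1), 0.5, 4 * se_mean)
  # SE of the variance of kappa*Poisson via fourth-moment formula (~sqrt(2/n)*var)
  expect_within(stats::var(d$r_1), 0.125, 4 * sqrt(2 / 2e5) * 0.125 * 1.5)
  # kappa = 0 collapses to a deterministic stage
  p0 <- circuit_params(kappa = 0, sigma_down = 0)
  d0 <- simulate_circuit(p0, constant_nl(0.5), n = 100, seed = 4)
  expect_true(all(d0$r_1 == 0.5))
})

test_that("binomial and multiplicative-Gaussian variants match their moments", {
  pb <- circuit_params(kappa = 0, sigma_down = 0, poisson_variant = "binomial",
                       binomial_n = 10)
  db <- simulate_circuit(pb, constant_nl(0.5), n = 2e5, seed = 5)
  expect_within(mean(db$stage_1), 0.5, 4 * sqrt(0.025 / 2e5))
  expect_within(stats::var(db$stage_1), 0.025, 4 * sqrt(2 / 2e5) * 0.025 * 1.5)
  pm <- circuit_params(kappa = 0.25, sigma_down = 0,
                       poisson_variant = "multiplicative_gaussian")
  dm <- simulate_circuit(pm, constant_nl(0.5), n = 2e5, seed = 6)
  # same conditional mean and variance as the scaled-Poisson stage
  expect_within(mean(dm$stage_1), 0.5, 4 * sqrt(0.125 / 2e5))
  expect_within(stats::var(dm$stage_1), 0.125, 4 * sqrt(2 / 2e5) * 0.125)
})

test_that("noise correlations converge to their parameters", {
  p <- circuit_params(sigma_up = 2, sigma_down = 0.5, kappa = 0,
                      rho_up = 0.0625, rho_down = -0.6, n_pathways = 2)
  f <- list(piecewise_nonlinearity(-1, 1), piecewise_nonlinearity(-1, 1))
  d <- simulate_circuit(p, f, n = 2e5, seed = 7)
  tol <- 4 / sqrt(2e5)
  expect_within(stats::cor(d$eta_1, d$eta_2), 0.0625, tol)
  expect_within(stats::cor(d$zeta_1, d$zeta_2), -0.6, tol)
  # total inputs realize rho_eff
  expect_within(stats::cor(d$s + d$eta_1, d$s + d$eta_2),
                effective_correlation(p), tol)
})

test_that("conditional moments match their closed forms and the simulator", {
  f <- piecewise_nonlinearity(0, 1)
  p <- circuit_params(kappa = 1, sigma_down = 0)
  cm <- conditional_moments(p, f, 1)
  expect_equal(cm$mean, 1)
  expect_equal(cm$variance, 1)
  p2 <- circuit_params(kappa = 0, sigma_down = 0.3)
  cm2 <- conditional_moments(p2, f, 0.4)
  expect_equal(cm2$variance, 0.09)
  # simulated conditional variance at fixed z
  p3 <- circuit_params(kappa = 0.5, sigma_down = 0.2)
  z_fix <- 0.6
  cm3 <- conditional_moments(p3, f, z_fix)
  d <- simulate_circuit(p3, constant_nl(predict(f, z_fix)), n = 1e5, seed = 8)
  expect_within(stats::var(d$r_1), cm3$variance,
                5 * sqrt(2 / 1e5) * cm3$variance * 2)
})

test_that("draw sets export to CSV with a JSON sidecar", {
  p <- circuit_params(kappa = 0.1, sigma_down = 0.2)
  d <- simulate_circuit(p, piecewise_nonlinearity(-1, 1), n = 50, seed = 2)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_draws(d, tf)
  back <- utils::read.csv(tf)
  expect_equal(back$r_1, d$r_1)
  side <- jsonlite::fromJSON(paste0(tf, ".json"))
  expect_equal(side$seed, 2)
  expect_equal(side$params$kappa, 0.1)
})
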