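test_that("self-consistency residuals meet the tolerance across regimes", {
  pres <- noise_regime_presets("single")
  for (i in seq_len(nrow(pres))) {
    sol <- solve_single(circuit_params(sigma_up = pres$sigma_up[i],
                                       kappa = pres$kappa[i],
                                       sigma_down = pres$sigma_down[i]))
    expect_true(sol$converged, label = pres$label[i])
    expect_lt(sol$residual, 1e-8)
    # kink relations in rescaled coordinates
    m <- effcoding:::ramp_moments(sol$x0, sol$x1)
    w <- sol$x1 - sol$x0
    expect_equal(sol$x0, w * (pres$kappa[i] / 2 - m$mean_f),
                 tolerance = 1e-6)
  }
})

test_that("solutions are scale covariant: (x0, x1) depend only on kappa and sigma_down", {
  s1 <- solve_single(circuit_params(sigma_s = 1, sigma_up = 0.5,
                                    kappa = 0.2, sigma_down = 0.3))
  s2 <- solve_single(circuit_params(sigma_s = 2.5, sigma_up = 1.25,
                                    kappa = 0.2, sigma_down = 0.3))
  expect_equal(c(s1$x0, s1$x1), c(s2$x0, s2$x1), tolerance = 1e-7)
  # doubling upstream noise at fixed stimulus: raw slope falls, rescaled fixed
  a <- solve_single(circuit_params(sigma_up = 0.5, kappa = 0.1,
                                   sigma_down = 0.1))
  b <- solve_single(circuit_params(sigma_up = 1.0, kappa = 0.1,
                                   sigma_down = 0.1))
  expect_lt(slope_offset(b)[["slope"]], slope_offset(a)[["slope"]])
  expect_equal(slope_offset(b, rescaled = TRUE)[["slope"]],
               slope_offset(a, rescaled = TRUE)[["slope"]],
               tolerance = 1e-5)
})

test_that("slope and offset trends follow the preset sweeps", {
  # upstream branch: slope decreases, offset stays near zero (kappa = 0)
  sl_up <- sapply(c(0.2, 0.6, 1.2, 2.5), function(su)
    slope_offset(solve_single(circuit_params(sigma_up = su, kappa = 0,
                                             sigma_down = 0.05))))
  expect_true(all(diff(sl_up["slope", ]) < 0))
  expect_true(all(abs(sl_up["offset", ]) < 1e-5))
  # downstream branch: slope increases, offset near zero
  sl_dn <- sapply(c(0.1, 0.3, 0.6, 1.2), function(sd)
    slope_offset(solve_single(circuit_params(sigma_up = 0.05, kappa = 0,
                                             sigma_down = sd))))
  expect_true(all(diff(sl_dn["slope", ]) > 0))
  expect_true(all(abs(sl_dn["offset", ]) < 1e-5))
  # Poisson branch: slope increases and the offset moves off-center
  sl_k <- sapply(c(0.05, 0.2, 0.8, 2), function(k)
    slope_offset(solve_single(circuit_params(sigma_up = 0.05, kappa = k,
                                             sigma_down = 0.05))))
  expect_true(all(diff(sl_k["slope", ]) > 0))
  expect_true(all(diff(sl_k["offset", ]) > 0))
  expect_gt(sl_k["offset", 4], 0.1)
})

test_that("the analytic optimum is never beaten by a parametric sweep", {
  # oracle grid of parameter sets; sweep in the piecewise family can approach
  # the optimum, the logistic family bounds it from above
  sets <- expand.grid(sigma_up = c(0.1, 0.8), kappa = c(0, 0.4),
                      sigma_down = c(0.05, 0.5))
  for (i in seq_len(nrow(sets))) {
    p <- circuit_params(sigma_up = sets$sigma_up[i], kappa = sets$kappa[i],
                        sigma_down = sets$sigma_down[i])
    sol <- solve_single(p)
    sw <- sweep_logistic(p, shape = "piecewise", method = "closed_form",
                         nu_grid = exp(seq(log(0.1), log(8),
                                           length.out = 15)),
                         phi_grid = seq(-1.5, 1.5, length.out = 15))
    expect_lte(sol$mse, sw$best$score * (1 + 1e-6))
  }
})

test_that("solution objects expose the modelling-idiom methods", {
  p <- circuit_params(sigma_up = 0.5, kappa = 0.2, sigma_down = 0.2)
  sol <- solve_single(p)
  co <- coef(sol)
  expect_named(co, c("x0", "x1", "z0", "z1", "D", "D0", "mse", "snr"))
  expect_equal(predict(sol, sol$z0), 0, tolerance = 1e-12)
  expect_equal(predict(sol, sol$z1), 1, tolerance = 1e-12)
  d <- simulate(sol, seed = 3, n = 2000)
  expect_s3_class(d, "draw_set")
  r <- residuals(sol, n = 5000, seed = 4)
  # decoded residual variance matches the reported MSE
  expect_within(mean(r^2), sol$mse, 6 * stats::sd(r^2) / sqrt(5000))
  expect_output(print(sol), "converged")
})

test_that("the noise-free response stage is flagged instead of looping", {
  expect_warning(
    sol <- solve_single(circuit_params(sigma_up = 0.5, kappa = 0,
                                       sigma_down = 0)),
    "diverges")
  expect_false(sol$converged)
  # MSE limit is the upstream-noise floor
  expect_equal(sol$mse, 0.25 / 1.25)
})
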