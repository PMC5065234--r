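test_that("binless estimator recovers closed-form entropies", {
  set.seed(31)
  h_u <- entropy_binless(stats::pnorm(stats::rnorm(1e5)))  # uniform, collision-free
  expect_within(h_u$value, 0, 0.02)
  h_g <- entropy_binless(stats::rnorm(1e5))
  expect_within(h_g$value, 0.5 * log2(2 * pi * exp(1)), 0.02)
  # independent 2-D Gaussian: entropies add
  h_2 <- entropy_binless(matrix(stats::rnorm(2e5), ncol = 2))
  expect_within(h_2$value, log2(2 * pi * exp(1)), 0.05)
})

test_that("binned estimator recovers closed-form entropies", {
  set.seed(32)
  h_u <- entropy_binned(stats::runif(1e5), n_bins = 50)
  expect_within(h_u$value, 0, 0.02)
  x <- stats::rnorm(1e5)
  h_g <- entropy_binned(x, n_bins = 50, range = c(-5, 5))
  expect_within(h_g$value, 0.5 * log2(2 * pi * exp(1)), 0.05)
})

test_that("binless and binned estimates agree on continuous samples", {
  set.seed(33)
  x <- stats::rnorm(5e4, sd = 0.7)
  hb <- entropy_binless(x)$value
  hn <- entropy_binned(x, n_bins = 50, range = range(x))$value
  expect_within(hb, hn, 0.05)
})

test_that("duplicate samples are rejected with a recommendation to bin", {
  x <- c(1, 2, 3, 2)
  err <- expect_error(entropy_binless(x),
                      class = "effcoding_duplicate_samples")
  expect_match(conditionMessage(err), "entropy_binned")
  expect_error(entropy_binned(rep(1, 100)), "point mass")
})

test_that("a constant channel carries no information", {
  p <- circuit_params(kappa = 0, sigma_down = 0.2)
  mi <- mutual_information(p, constant_nl(0.5), n_stimuli = 4000,
                           n_repeats = 2000, n_cond = 10, n_reps = 2,
                           seed = 41)
  expect_within(as.numeric(mi), 0, 0.05)
})

test_that("conditional response entropy of a downstream-only circuit is Gaussian", {
  sd_down <- 0.3
  p <- circuit_params(kappa = 0, sigma_down = sd_down)
  # response at a pinned stimulus is f(s0) + zeta
  set.seed(42)
  d <- simulate_circuit(p, constant_nl(0.4), n = 5e4, seed = 42)
  h <- entropy_binless(d$r_1)
  expect_within(h$value, 0.5 * log2(2 * pi * exp(1) * sd_down^2), 0.03)
})

test_that("MI of the CDF-nonlinearity circuit matches direct integration", {
  # downstream noise only; f = stimulus CDF makes the stage output uniform,
  # so p(r) is a uniform-Gaussian convolution with an erf closed form
  sd_down <- 0.2
  p <- circuit_params(kappa = 0, sigma_down = sd_down)
  xg <- nl_grid(241)
  fcdf <- tabulated_nonlinearity(xg, stats::pnorm(xg))
  p_r <- function(r) {
    (stats::pnorm(r / sd_down) - stats::pnorm((r - 1) / sd_down))
  }
  HR <- stats::integrate(function(r) {
    d <- p_r(r); ifelse(d > 1e-300, -d * log2(d), 0)
  }, -1.5, 2.5, rel.tol = 1e-10)$value
  mi_true <- HR - 0.5 * log2(2 * pi * exp(1) * sd_down^2)
  mi <- mutual_information(p, fcdf, n_stimuli = 2e4, n_repeats = 2e4,
                           n_cond = 24, n_reps = 3, seed = 43)
  expect_within(as.numeric(mi), mi_true, 0.05)
})

test_that("MI of a piecewise-linear downstream-only circuit matches its convolution", {
  # ramp on [z0, z1]: stage output density is a mixture of two point masses
  # (clipped regions) and a scaled-Gaussian interior; convolve numerically
  sd_down <- 0.15
  z0 <- -0.8; z1 <- 1.0
  p <- circuit_params(kappa = 0, sigma_down = sd_down)
  f <- piecewise_nonlinearity(z0, z1)
  w <- z1 - z0
  # density of u = f(s), s ~ N(0,1): atoms at 0 and 1 plus interior density
  p_r <- function(r) {
    vapply(r, function(ri) {
      atom <- stats::pnorm(z0) * stats::dnorm(ri, 0, sd_down) +
        (1 - stats::pnorm(z1)) * stats::dnorm(ri, 1, sd_down)
      interior <- stats::integrate(function(u)
        stats::dnorm(z0 + u * w) * w * stats::dnorm(ri, u, sd_down),
        0, 1, rel.tol = 1e-8)$value
      atom + interior
    }, numeric(1))
  }
  HR <- stats::integrate(function(r) {
    d <- p_r(r); ifelse(d > 1e-300, -d * log2(d), 0)
  }, -1.5, 2.5, rel.tol = 1e-8)$value
  mi_true <- HR - 0.5 * log2(2 * pi * exp(1) * sd_down^2)
  mi <- mutual_information(p, f, n_stimuli = 2e4, n_repeats = 2e4,
                           n_cond = 24, n_reps = 3, seed = 44)
  expect_within(as.numeric(mi), mi_true, 0.05)
})

test_that("MI is non-negative and invariant under affine response rescaling", {
  p <- circuit_params(sigma_up = 0.3, kappa = 0, sigma_down = 0.25)
  f <- logistic_nonlinearity(2, 0)
  mi <- mutual_information(p, f, n_stimuli = 5000, n_repeats = 4000,
                           n_cond = 12, n_reps = 2, seed = 45)
  expect_gt(as.numeric(mi) + 0.05, 0)
  # affine invariance: both entropy terms shift by the same log|a|
  set.seed(46)
  x <- stats::rnorm(2e4)
  h1 <- entropy_binless(x)$value
  h2 <- entropy_binless(3 * x + 2)$value
  expect_within(h2 - h1, log2(3), 0.02)
})

test_that("discretized responses trigger the binned fallback", {
  p <- circuit_params(kappa = 0.5, sigma_down = 0)
  f <- piecewise_nonlinearity(-1, 1)
  mi <- mutual_information(p, f, n_stimuli = 3000, n_repeats = 2000,
                           n_cond = 8, n_reps = 1, seed = 47)
  expect_identical(attr(mi, "estimator"), "binned")
  expect_true(is.finite(as.numeric(mi)))
})
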