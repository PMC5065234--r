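test_that("converged fixed points pass an independent residual check", {
  p <- dual_params(0.5, 0.25, 0.25, 0)
  for (cls in c("on_off", "on_on")) {
    s <- picard_solve(p, cls, seed = 1)
    expect_true(s$converged)
    # optimality conditions re-evaluated at a different quadrature order
    expect_lt(solution_residual(s, n_quad = 400), 10 * s$control$tol)
  }
})

test_that("uncorrelated inputs decouple into two single-pathway copies", {
  p <- dual_params(0, 0.25, 0.25, 0)
  s <- picard_solve(p, "on_on", seed = 2)
  single <- solve_single(circuit_params(kappa = 0.25, sigma_down = 0.25))
  ref <- predict(single$f_rescaled, s$f1$x)
  expect_lt(max(abs(s$f1$f - ref)), 1e-3)
  expect_lt(max(abs(s$f2$f - ref)), 1e-3)
  # two independent estimates beat one: dual MSE below single MSE
  expect_lt(s$mse, solve_single(circuit_params(sigma_s = 1, sigma_up = 2,
                                               kappa = 0.25,
                                               sigma_down = 0.25))$mse)
})

test_that("perfectly correlated inputs give piecewise-linear optima", {
  p <- dual_params(1, 0.25, 0.25, 0)
  s <- picard_solve(p, "on_off", seed = 1)
  expect_true(s$converged)
  for (f in list(s$f1, s$f2)) {
    v <- f$f
    dx <- diff(f$x)[1]
    d2 <- diff(diff(v)) / dx^2          # second differences
    interior <- v[2:(length(v) - 1)] > 0.02 & v[2:(length(v) - 1)] < 0.98
    # exclude the two grid cells around each kink
    kinks <- which(abs(diff(interior)) > 0)
    mask <- interior
    for (k in kinks) mask[max(1, k - 2):min(length(mask), k + 2)] <- FALSE
    if (any(mask)) expect_lt(max(abs(d2[mask])), 0.05)
  }
})

test_that("ON-OFF pairs are anti-symmetric at symmetric parameters", {
  s <- picard_solve(dual_params(0.75, 0.5, 0.25, 0), "on_off", seed = 3)
  expect_true(s$strategy %in% c("ON_OFF", "OFF_ON"))
  expect_lt(attr(s$strategy, "antisymmetry"), 1e-2)
})

test_that("classification follows the weight signs and the sup-norm rule", {
  s <- picard_solve(dual_params(0.5, 0.25, 0.25, 0), "on_on", seed = 4)
  # identical pair: equal weights, equal shapes
  expect_identical(as.character(s$strategy), "ON_ON_identical")
  fake <- s
  fake$D2 <- -fake$D2
  expect_true(as.character(classify_solution(fake)) %in%
                c("ON_OFF", "OFF_ON"))
  fake2 <- s
  fake2$f2$f <- pmin(1, s$f2$f + 0.2)
  expect_identical(classify_solution(fake2), "ON_ON_split")
})

test_that("multi-seed solving replicates and brackets both classes", {
  p <- dual_params(0.5, 0.25, 0.25, 0)
  ens <- multi_seed_solve(p, n_seeds = 3, seed = 5)
  expect_gte(ens$n_converged, 4)
  labs <- names(ens$best)
  expect_true(any(labs %in% c("ON_OFF", "OFF_ON")))
  expect_true(any(labs %in% c("ON_ON_identical", "ON_ON_split", "OFF_OFF")))
  # co-converged seeds agree closely at benign parameters
  expect_true(all(ens$dispersion < 1e-2))
  # a single seed reproduces the underlying solve
  one <- multi_seed_solve(p, n_seeds = 1, init_classes = "on_off", seed = 7)
  direct <- picard_solve(p, "on_off", seed = 7)
  expect_equal(one$best[[names(one$best)[1]]]$mse, direct$mse)
})

test_that("another Picard step changes a converged solution by less than tol", {
  p <- dual_params(0.25, 0.5, 0.5, -0.25)
  s <- picard_solve(p, "on_off", seed = 6)
  expect_true(s$converged)
  expect_lt(utils::tail(s$change_trace, 1), s$control$tol)
})

test_that("increasing Poisson strength pushes ON-OFF bases apart", {
  base_rise <- function(f) {   # input at which the rising form leaves 0
    x <- f$x; v <- f$f
    if (v[length(v)] < v[1]) { x <- -rev(x); v <- rev(v) }
    x[min(which(v > 0.02))]
  }
  lo <- picard_solve(dual_params(0.5, 0.1, 0.1, 0), "on_off", seed = 1)
  hi <- picard_solve(dual_params(0.5, 0.9, 0.1, 0), "on_off", seed = 1)
  expect_gt(base_rise(hi$f1), base_rise(lo$f1))
  expect_gt(base_rise(hi$f2), base_rise(lo$f2))
})

test_that("the winner's MSE is below a coarse logistic-pair sweep", {
  p <- dual_params(0.5, 0.25, 0.25, 0)
  ens <- multi_seed_solve(p, n_seeds = 2, seed = 8)
  best_mse <- min(vapply(ens$best, function(s) s$mse, numeric(1)))
  sw <- sweep_logistic(p, method = "closed_form",
                       nu_grid = c(-2, -1, 1, 2, 4),
                       phi_grid = c(-0.8, 0, 0.8))
  expect_lte(best_mse, sw$best$score)
})

test_that("dual solutions serialize to JSON plus nonlinearity tables", {
  s <- picard_solve(dual_params(0.5, 0.25, 0.25, 0), "on_off", seed = 1)
  tf <- withr::local_tempfile(fileext = ".json")
  write_dual_solution(s, tf)
  rec <- jsonlite::fromJSON(tf)
  expect_equal(rec$mse, s$mse)
  expect_equal(rec$strategy, "ON_OFF")
  f1 <- read_nonlinearity(sub("\\.json$", "_f1.txt", tf))
  expect_equal(f1$f, s$f1$f, tolerance = 1e-8)
})
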