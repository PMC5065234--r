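# shared helpers: parameter constructors and small frozen fixtures

dual_params <- function(rho_eff, kappa, sigma_down, rho_down = 0,
                        sigma_s = 1, sigma_up = 2) {
  circuit_params(sigma_s = sigma_s, sigma_up = sigma_up, kappa = kappa,
                 sigma_down = sigma_down,
                 rho_up = rho_up_for_effective(rho_eff, sigma_s, sigma_up),
                 rho_down = rho_down, n_pathways = 2L)
}

constant_nl <- function(value, xmax = 15) {
  tabulated_nonlinearity(seq(-xmax, xmax, length.out = 9L),
                         rep(value, 9L))
}

expect_within <- function(x, target, tol) {
  expect_true(abs(x - target) <= tol,
              label = sprintf("%.6g within %.3g of %.6g", x, tol, target))
}
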