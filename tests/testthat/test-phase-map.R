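test_that("phase-map cells are internally consistent and winner-invariant", {
  pm <- phase_map(rho_eff = c(0.25, 0.75), kappa = 0.5,
                  sigma_down = c(0.25, 0.75), rho_down = c(-0.5, 0.5),
                  n_seeds = 2, seed = 13)
  expect_true(all(pm$converged))
  expect_true(all(pm$pct_diff >= 0))
  win_mse <- ifelse(pm$winner == "ON_OFF", pm$mse_on_off, pm$mse_on_on)
  oth_mse <- ifelse(pm$winner == "ON_OFF", pm$mse_on_on, pm$mse_on_off)
  expect_true(all(win_mse <= oth_mse))
  # changing (sigma_s, sigma_up) at fixed rho_eff never changes the winner
  pm2 <- rescale_phase_map(pm, sigma_s = 1, sigma_up = 1)
  expect_identical(pm2$winner, pm$winner)
  expect_false(isTRUE(all.equal(pm2$pct_diff, pm$pct_diff)))
  # ON-OFF subtracts correlated downstream noise: it wins at rho_down > 0
  expect_true(all(pm$winner[pm$rho_down > 0] == "ON_OFF"))
  expect_true(all(pm$winner[pm$rho_down < 0] == "ON_ON"))
})

test_that("percent differences agree between the identity and Monte Carlo", {
  p <- dual_params(0.5, 0.5, 0.5, 0.75)
  ens <- multi_seed_solve(p, n_seeds = 2, seed = 17)
  fb <- effcoding:::family_best(ens)
  pct_closed <- 100 * (fb$on_on$mse - fb$on_off$mse) / fb$on_on$mse
  mc_of <- function(sol) {
    fr <- list(rescale_nonlinearity(sol$f1, p, "to_raw"),
               rescale_nonlinearity(sol$f2, p, "to_raw"))
    mse(p, fr, method = "monte_carlo", n = 4e5, reps = 3, seed = 18)
  }
  m_off <- mc_of(fb$on_off); m_on <- mc_of(fb$on_on)
  pct_mc <- 100 * (as.numeric(m_on) - as.numeric(m_off)) / as.numeric(m_on)
  se_pct <- 100 * sqrt(attr(m_on, "se")^2 + attr(m_off, "se")^2) /
    as.numeric(m_on)
  expect_within(pct_mc, pct_closed, max(5 * se_pct, 0.3))
})

test_that("the polarity crossover sits at rho_down = 0 as kappa vanishes", {
  b <- boundary_rho_down(kappa = 1e-6, rho_eff = 0.5, sigma_down = 0.5,
                         n_seeds = 2, seed = 19, tol = 0.02)
  expect_within(as.numeric(b), 0, 0.02)
})

test_that("ON-ON splitting appears only at high effective correlation", {
  thr <- splitting_threshold(kappa = 1, sigma_down = 0.1, rho_down = 0,
                             range = c(0.88, 1), resolution = 0.02,
                             n_seeds = 2, seed = 23)
  expect_false(attr(thr, "no_split"))
  expect_gte(as.numeric(thr), 0.9)
  expect_lte(as.numeric(thr), 1)
  # below the scan the optimum is identical
  scan <- attr(thr, "scan")
  expect_true(all(scan$strategy[scan$rho_eff < as.numeric(thr)] ==
                    "ON_ON_identical", na.rm = TRUE))
})

test_that("trend traces reproduce the qualitative sweep phenomenology", {
  ctl <- list()
  tr_k <- sweep_trends("kappa", grid = c(0.1, 0.9),
                       fixed = list(rho_eff = 0.5, kappa = NA,
                                    sigma_down = 0.1, rho_down = 0),
                       n_seeds = 1, seed = 29, control = ctl)
  for (cls in unique(tr_k$class)) {
    sub <- tr_k[tr_k$class == cls, ]
    # Poisson noise steepens both pathways
    expect_gt(abs(sub$slope1[2]), abs(sub$slope1[1]))
  }
  tr_d <- sweep_trends("sigma_down", grid = c(0.1, 1.0),
                       fixed = list(rho_eff = 0.5, kappa = 0.25,
                                    sigma_down = NA, rho_down = 0),
                       n_seeds = 1, seed = 31, control = ctl)
  sub <- tr_d[tr_d$class == "on_off", ]
  expect_gt(abs(sub$slope1[2]), abs(sub$slope1[1]))      # steeper
  expect_lt(abs(sub$offset1[2]), abs(sub$offset1[1]))    # recentered
  tr_r <- sweep_trends("rho_eff", grid = c(0.25, 0.95),
                       fixed = list(rho_eff = NA, kappa = 0.1,
                                    sigma_down = 0.1, rho_down = 0),
                       n_seeds = 1, seed = 37, control = ctl)
  sub <- tr_r[tr_r$class == "on_off", ]
  # ON-OFF offsets separate as inputs decorrelate less (rho_eff -> 1)
  sep <- abs(sub$offset1 - sub$offset2)
  expect_gt(sep[2], sep[1])
})

test_that("phase maps export to CSV and round-trip their cells", {
  pm <- phase_map(rho_eff = 0.5, kappa = 0.5, sigma_down = 0.5,
                  rho_down = c(-0.5, 0.5), n_seeds = 1, seed = 41)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_phase_map(pm, tf)
  back <- utils::read.csv(tf)
  expect_equal(back$pct_diff, pm$pct_diff, tolerance = 1e-10)
  meta <- jsonlite::fromJSON(paste0(tf, ".json"))
  expect_equal(meta$n_cells, nrow(pm))
})
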