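# Strategy maps over noise-parameter space: which polarity class (ON-OFF vs
# ON-ON) is globally optimal, by how much, and where ON-ON pairs split.

onoff_labels <- c("ON_OFF", "OFF_ON")
onon_labels <- c("ON_ON_identical", "ON_ON_split", "OFF_OFF")

# best readout term (=> lowest MSE) per polarity family from an ensemble
family_best <- function(ens) {
  pick <- function(labels) {
    cand <- ens$best[names(ens$best) %in% labels]
    if (!length(cand)) return(NULL)
    cand[[which.max(vapply(cand, function(s) s$readout_term, numeric(1)))]]
  }
  list(on_off = pick(onoff_labels), on_on = pick(onon_labels))
}

#' Map the globally optimal strategy over noise-parameter space
#'
#' For every cell of a grid over \eqn{(\rho_{eff}, \kappa, \sigma_{down},
#' \rho_{down})}, solves for the best ON-OFF and best ON-ON pair (via
#' [multi_seed_solve()]) and records the winning polarity class and the
#' percent decrease in MSE of the winner relative to the best solution of
#' the other class.  Each \eqn{\rho_{eff}} is realized by fixing
#' `sigma_s`, `sigma_up` and choosing \eqn{\rho_{up}} accordingly; the
#' rescaled solutions (and hence the winner) depend on the realization only
#' through \eqn{\rho_{eff}}, while the MSE magnitudes (and so the percent
#' differences) depend on \eqn{\sigma_s, \sigma_{up}} — use
#' [rescale_phase_map()] to re-express a computed map at another
#' realization without re-solving.
#'
#' @param rho_eff,kappa,sigma_down,rho_down Grid vectors.
#' @param sigma_s,sigma_up Realization of the stimulus/upstream-noise scale.
#' @param n_seeds Random initializations per class and cell.
#' @param seed Base seed.
#' @param control Passed to [picard_solve()].
#' @return An object of class `phase_map`: a data.frame with one row per
#'   cell (`rho_eff`, `kappa`, `sigma_down`, `rho_down`, `rho_up`,
#'   `T_on_off`, `T_on_on` readout terms, `mse_on_off`, `mse_on_on`,
#'   `winner`, `winner_strategy`, `pct_diff`, `converged`).
#' @export
phase_map <- function(rho_eff = c(0, 0.25, 0.5, 0.75, 1),
                      kappa = 1, sigma_down = c(0.1, 0.25, 0.5, 0.75, 1),
                      rho_down = seq(-1, 1, by = 0.25),
                      sigma_s = 1, sigma_up = 2,
                      n_seeds = 20L, seed = 1L, control = list()) {
  cells <- expand.grid(rho_eff = rho_eff, kappa = kappa,
                       sigma_down = sigma_down, rho_down = rho_down,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ce <- cells[i, ]
    rho_up <- rho_up_for_effective(ce$rho_eff, sigma_s, sigma_up)
    p <- circuit_params(sigma_s = sigma_s, sigma_up = sigma_up,
                        kappa = ce$kappa, sigma_down = ce$sigma_down,
                        rho_up = rho_up, rho_down = ce$rho_down,
                        n_pathways = 2L)
    ens <- multi_seed_solve(p, n_seeds = n_seeds, seed = seed + i * 10000L,
                            control = control)
    fb <- family_best(ens)
    rows[[i]] <- phase_cell_row(ce, rho_up, fb, p)
  }
  out <- do.call(rbind, rows)
  structure(out, sigma_s = sigma_s, sigma_up = sigma_up,
            class = c("phase_map", "data.frame"))
}

phase_cell_row <- function(ce, rho_up, fb, p) {
  c_eff <- p$sigma_s^2 / (p$sigma_s^2 + p$sigma_up^2)
  Tof <- if (is.null(fb$on_off)) NA_real_ else fb$on_off$readout_term
  Ton <- if (is.null(fb$on_on)) NA_real_ else fb$on_on$readout_term
  mof <- p$sigma_s^2 * (1 - c_eff * Tof)
  mon <- p$sigma_s^2 * (1 - c_eff * Ton)
  conv <- !is.na(Tof) && !is.na(Ton)
  if (conv) {
    if (mof <= mon) {
      winner <- "ON_OFF"; wstrat <- as.character(fb$on_off$strategy)
      pct <- 100 * (mon - mof) / mon
    } else {
      winner <- "ON_ON"; wstrat <- as.character(fb$on_on$strategy)
      pct <- 100 * (mof - mon) / mof
    }
  } else {
    winner <- NA_character_; wstrat <- NA_character_; pct <- NA_real_
  }
  data.frame(rho_eff = ce$rho_eff, kappa = ce$kappa,
             sigma_down = ce$sigma_down, rho_down = ce$rho_down,
             rho_up = rho_up, T_on_off = Tof, T_on_on = Ton,
             mse_on_off = mof, mse_on_on = mon,
             winner = winner, winner_strategy = wstrat, pct_diff = pct,
             converged = conv, stringsAsFactors = FALSE)
}

#' Re-express a phase map at another stimulus/upstream-noise realization
#'
#' The rescaled solutions stored in a [phase_map()] depend on
#' \eqn{(\rho_{eff}, \kappa, \sigma_{down}, \rho_{down})} only; this
#' recomputes the MSE values, winner, and percent differences for new
#' `sigma_s`, `sigma_up` from the stored readout terms without re-solving.
#'
#' @param pm A `phase_map`.
#' @param sigma_s,sigma_up New realization.
#' @return A `phase_map` with updated MSE columns and attributes.
#' @export
rescale_phase_map <- function(pm, sigma_s = 1, sigma_up = 2) {
  stopifnot(inherits(pm, "phase_map"))
  c_eff <- sigma_s^2 / (sigma_s^2 + sigma_up^2)
  pm$mse_on_off <- sigma_s^2 * (1 - c_eff * pm$T_on_off)
  pm$mse_on_on <- sigma_s^2 * (1 - c_eff * pm$T_on_on)
  onoff_wins <- pm$mse_on_off <= pm$mse_on_on
  pm$winner <- ifelse(onoff_wins, "ON_OFF", "ON_ON")
  pm$pct_diff <- ifelse(onoff_wins,
                        100 * (pm$mse_on_on - pm$mse_on_off) / pm$mse_on_on,
                        100 * (pm$mse_on_off - pm$mse_on_on) / pm$mse_on_off)
  pm$rho_up <- vapply(pm$rho_eff, function(re)
    tryCatch(rho_up_for_effective(re, sigma_s, sigma_up),
             error = function(e) NA_real_), numeric(1))
  attr(pm, "sigma_s") <- sigma_s
  attr(pm, "sigma_up") <- sigma_up
  pm
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("Strategy phase map: %d cells (sigma_s = %g, sigma_up = %g)\n",
              nrow(x), attr(x, "sigma_s"), attr(x, "sigma_up")))
  tb <- table(x$winner, useNA = "ifany")
  for (nm in names(tb)) cat(sprintf("  %s wins in %d cells\n", nm, tb[[nm]]))
  cat(sprintf("  max percent MSE difference: %.3g%%\n",
              max(x$pct_diff, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.phase_map <- function(x, rho_eff = NULL, ...) {
  d <- as.data.frame(x)
  if (!is.null(rho_eff)) d <- d[abs(d$rho_eff - rho_eff) < 1e-9, ]
  col <- ifelse(d$winner == "ON_OFF", "darkgreen",
                ifelse(d$winner_strategy == "ON_ON_split", "blue", "purple"))
  graphics::plot(d$rho_down, d$sigma_down, pch = 19, col = col,
                 cex = 0.5 + 2 * sqrt(pmax(0, d$pct_diff) /
                                        max(d$pct_diff, 1e-9, na.rm = TRUE)),
                 xlab = "rho_down", ylab = "sigma_down", ...)
  graphics::legend("topleft", c("ON-OFF", "ON-ON identical", "ON-ON split"),
                   col = c("darkgreen", "purple", "blue"), pch = 19,
                   bty = "n")
  invisible(x)
}

#' Export a phase map as long-format CSV (plus JSON metadata)
#'
#' @param pm A `phase_map`.
#' @param path CSV path; metadata goes to `<path>.json`.
#' @export
write_phase_map <- function(pm, path) {
  utils::write.csv(as.data.frame(pm), path, row.names = FALSE)
  writeLines(jsonlite::toJSON(list(sigma_s = attr(pm, "sigma_s"),
                                   sigma_up = attr(pm, "sigma_up"),
                                   n_cells = nrow(pm)),
                              auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' Equal-MSE crossover of the polarity classes in downstream correlation
#'
#' Bisection in \eqn{\rho_{down}} on the sign of
#' `MSE(best ON-OFF) - MSE(best ON-ON)`.  ON-OFF readouts subtract the
#' downstream noise while ON-ON readouts add it, so ON-OFF wins for
#' positively correlated downstream noise; as \eqn{\kappa \to 0} the
#' crossover approaches \eqn{\rho_{down} = 0} for every
#' \eqn{\sigma_{down}}.
#'
#' @param kappa,rho_eff,sigma_down Fixed cell parameters.
#' @param interval Bracketing interval in `rho_down`.
#' @param tol Bisection half-width at which to stop.
#' @param sigma_s,sigma_up Realization (affects MSE values, not the sign).
#' @param n_seeds,seed,control Solver settings per evaluation.
#' @return The crossover `rho_down`, with attribute `"evals"` (number of
#'   bisection evaluations).
#' @export
boundary_rho_down <- function(kappa, rho_eff = 0.5, sigma_down = 0.5,
                              interval = c(-0.5, 0.5), tol = 0.02,
                              sigma_s = 1, sigma_up = 2,
                              n_seeds = 3L, seed = 1L, control = list()) {
  rho_up <- rho_up_for_effective(rho_eff, sigma_s, sigma_up)
  gap <- function(rd) {        # > 0 iff ON-OFF wins (larger readout term)
    p <- circuit_params(sigma_s = sigma_s, sigma_up = sigma_up,
                        kappa = kappa, sigma_down = sigma_down,
                        rho_up = rho_up, rho_down = rd, n_pathways = 2L)
    ens <- multi_seed_solve(p, n_seeds = n_seeds,
                            seed = seed + round(1e4 * (rd + 1)),
                            control = control)
    fb <- family_best(ens)
    if (is.null(fb$on_off) || is.null(fb$on_on))
      stop("a polarity class failed to converge at rho_down = ", rd,
           call. = FALSE)
    fb$on_off$readout_term - fb$on_on$readout_term
  }
  lo <- interval[1L]; hi <- interval[2L]
  glo <- gap(lo); ghi <- gap(hi)
  evals <- 2L
  if (glo * ghi > 0)
    stop("no sign change of the class MSE difference on the interval",
         call. = FALSE)
  while ((hi - lo) / 2 > tol) {
    mid <- (lo + hi) / 2
    gm <- gap(mid)
    evals <- evals + 1L
    if (gm == 0) { lo <- mid; hi <- mid; break }
    if (gm * glo < 0) { hi <- mid; ghi <- gm } else { lo <- mid; glo <- gm }
  }
  out <- (lo + hi) / 2
  attr(out, "evals") <- evals
  out
}

#' Smallest effective correlation with a split ON-ON optimum
#'
#' Scans \eqn{\rho_{eff}} upward at fixed \eqn{(\kappa, \sigma_{down},
#' \rho_{down})}, classifying the best ON-ON solution at each point as
#' identical or split, and returns the smallest \eqn{\rho_{eff}} whose
#' ON-ON optimum is split.  If no split is found below 1 the function
#' returns 1 with attribute `"no_split" = TRUE` (and `split_at_one`
#' recording whether the delta-kernel point itself splits).
#'
#' @param kappa,sigma_down,rho_down Fixed parameters.
#' @param range Scan range of `rho_eff`.
#' @param resolution Scan step.
#' @param sigma_s,sigma_up Realization used to build `rho_up`.
#' @param n_seeds,seed,control Solver settings.
#' @return The threshold `rho_eff` (attributes `"no_split"`, `"scan"`).
#' @export
splitting_threshold <- function(kappa, sigma_down, rho_down = 0,
                                range = c(0.875, 1), resolution = 0.01,
                                sigma_s = 1, sigma_up = 2,
                                n_seeds = 3L, seed = 1L, control = list()) {
  grid <- seq(range[1L], range[2L], by = resolution)
  if (abs(grid[length(grid)] - 1) > 1e-9 && range[2L] >= 1) grid <- c(grid, 1)
  scan <- data.frame(rho_eff = grid, strategy = NA_character_,
                     split = NA, stringsAsFactors = FALSE)
  for (i in seq_along(grid)) {
    rho_up <- rho_up_for_effective(grid[i], sigma_s, sigma_up)
    p <- circuit_params(sigma_s = sigma_s, sigma_up = sigma_up,
                        kappa = kappa, sigma_down = sigma_down,
                        rho_up = rho_up, rho_down = rho_down,
                        n_pathways = 2L)
    ens <- tryCatch(multi_seed_solve(p, n_seeds = n_seeds,
                                     init_classes = "on_on",
                                     seed = seed + i * 100L,
                                     control = control),
                    error = function(e) NULL)
    fb <- if (is.null(ens)) list(on_on = NULL) else family_best(ens)
    if (is.null(fb$on_on)) next
    scan$strategy[i] <- as.character(fb$on_on$strategy)
    scan$split[i] <- scan$strategy[i] == "ON_ON_split"
    if (isTRUE(scan$split[i])) {
      out <- grid[i]
      attr(out, "no_split") <- FALSE
      attr(out, "scan") <- scan[seq_len(i), ]
      return(out)
    }
  }
  out <- 1
  attr(out, "no_split") <- TRUE
  attr(out, "scan") <- scan
  out
}

#' Rescaled slope and offset traces along a noise-parameter axis
#'
#' Solves both polarity classes along a one-parameter sweep and reports the
#' rescaled slope and offset of each pathway's optimal nonlinearity,
#' mirroring the sweep-trend summaries of the strategy analysis: increasing
#' \eqn{\kappa} steepens the nonlinearities and shifts them off-center;
#' increasing \eqn{\sigma_{down}} steepens and re-centers them;
#' \eqn{\rho_{eff}} mostly moves the offsets (apart for ON-OFF pairs as
#' \eqn{\rho_{eff} \to 1}).
#'
#' @param axis `"rho_eff"`, `"kappa"`, or `"sigma_down"`.
#' @param grid Values along the axis.
#' @param fixed Named list of the other parameters (`rho_eff`, `kappa`,
#'   `sigma_down`, `rho_down`).
#' @param sigma_s,sigma_up Realization.
#' @param n_seeds,seed,control Solver settings.
#' @return Data.frame with one row per (grid point, class): columns `axis`,
#'   `value`, `class`, `strategy`, `slope1`, `offset1`, `slope2`, `offset2`,
#'   `mse`.
#' @export
sweep_trends <- function(axis = c("rho_eff", "kappa", "sigma_down"),
                         grid,
                         fixed = list(rho_eff = 0.5, kappa = 0.25,
                                      sigma_down = 0.25, rho_down = 0),
                         sigma_s = 1, sigma_up = 2,
                         n_seeds = 3L, seed = 1L, control = list()) {
  axis <- match.arg(axis)
  rows <- list()
  for (i in seq_along(grid)) {
    par <- modifyList(fixed, stats::setNames(list(grid[i]), axis))
    rho_up <- rho_up_for_effective(par$rho_eff, sigma_s, sigma_up)
    p <- circuit_params(sigma_s = sigma_s, sigma_up = sigma_up,
                        kappa = par$kappa, sigma_down = par$sigma_down,
                        rho_up = rho_up, rho_down = par$rho_down,
                        n_pathways = 2L)
    ens <- multi_seed_solve(p, n_seeds = n_seeds, seed = seed + i * 100L,
                            control = control)
    fb <- family_best(ens)
    for (cls in c("on_off", "on_on")) {
      sol <- fb[[cls]]
      if (is.null(sol)) next
      so1 <- nl_slope_offset(sol$f1)
      so2 <- nl_slope_offset(sol$f2)
      rows[[length(rows) + 1L]] <- data.frame(
        axis = axis, value = grid[i], class = cls,
        strategy = as.character(sol$strategy),
        slope1 = so1[["slope"]], offset1 = so1[["offset"]],
        slope2 = so2[["slope"]], offset2 = so2[["offset"]],
        mse = sol$mse, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
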