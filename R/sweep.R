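#' Sweep logistic nonlinearities for the best slope and offset
#'
#' Mirrors the simulation route to the optimal encoder: parameterize the
#' nonlinearity as a logistic curve \eqn{f(z) = 1/(1 + e^{-\nu(z-\phi)})},
#' evaluate the objective (MSE of the optimal linear readout, or mutual
#' information) on a grid of \eqn{(\nu, \phi)} combinations, and return the
#' best grid point together with the set of near-optimal points (within 1%
#' of the optimum).  For the MSE objective each grid point is scored by
#' simulating the full model and fitting the decoding weights to the sample
#' (common random numbers across grid points sharpen the comparison);
#' `method = "closed_form"` scores by quadrature instead.  For a two-pathway
#' model the grid is the product of per-pathway \eqn{(\nu, \phi)} grids and
#' negative \eqn{\nu} encodes OFF polarity.
#'
#' @param p A `circuit_params` object.
#' @param objective `"mse"` (minimized) or `"mi"` (maximized).
#' @param shape Parametric family: `"logistic"` (smooth sigmoid) or
#'   `"piecewise"` (clipped ramp of width `1/nu` centred at `phi`, the
#'   shape of the exact solution).
#' @param nu_grid Slope values (default 25 log-spaced in \[0.4, 40\] raw
#'   units; include negative values for OFF pathways).
#' @param phi_grid Offset values (default 25 linear in +/- 3 rescaled units).
#' @param n_draws,n_reps Simulation scale per grid point (the study-scale
#'   default of 1e7 draws and 5 repetitions is heavy; reduce for interactive
#'   work).
#' @param seed Seed shared across grid points (common random numbers).
#' @param method Scoring route for the MSE objective.
#' @param mi_args List of overrides passed to [mutual_information()].
#' @param n_quad Quadrature order for `method = "closed_form"`.
#' @return An object of class `sweep_result`: `grid` (a data.frame with one
#'   row per evaluated combination and its score), `best` (row of the
#'   optimum), `near_optimal` (rows within 1% of the optimum), `objective`.
#' @export
sweep_logistic <- function(p, objective = c("mse", "mi"),
                           shape = c("logistic", "piecewise"),
                           nu_grid = NULL, phi_grid = NULL,
                           n_draws = 1e7, n_reps = 5L, seed = 1L,
                           method = c("monte_carlo", "closed_form"),
                           mi_args = list(), n_quad = 200L) {
  validate_circuit_params(p)
  objective <- match.arg(objective)
  shape <- match.arg(shape)
  method <- match.arg(method)
  sz <- input_scale(p)
  if (is.null(nu_grid)) nu_grid <- exp(seq(log(0.4), log(40),
                                           length.out = 25L)) / sz
  if (is.null(phi_grid)) phi_grid <- seq(-3, 3, length.out = 25L) * sz
  make_nl <- function(nu, phi) {
    if (shape == "logistic") return(logistic_nonlinearity(nu, phi))
    w <- 1 / abs(nu)
    piecewise_nonlinearity(phi - w / 2, phi + w / 2,
                           polarity = if (nu < 0) "OFF" else "ON")
  }

  if (p$n_pathways == 1L) {
    grid <- expand.grid(nu = nu_grid, phi = phi_grid)
    flist_of <- function(row) list(make_nl(row$nu, row$phi))
  } else {
    grid <- expand.grid(nu1 = nu_grid, phi1 = phi_grid,
                        nu2 = nu_grid, phi2 = phi_grid)
    flist_of <- function(row) list(make_nl(row$nu1, row$phi1),
                                   make_nl(row$nu2, row$phi2))
  }

  score_one <- function(row) {
    fl <- flist_of(row)
    f <- if (p$n_pathways == 1L) fl[[1L]] else fl
    if (objective == "mi") {
      args <- modifyList(list(p = p, f = f, seed = seed), mi_args)
      v <- do.call(mutual_information, args)
      return(c(score = as.numeric(v), se = attr(v, "se")))
    }
    if (method == "closed_form") {
      return(c(score = mse(p, f, method = "closed_form", n_quad = n_quad),
               se = 0))
    }
    v <- mse(p, f, method = "monte_carlo", n = n_draws, reps = n_reps,
             seed = seed)
    c(score = as.numeric(v), se = attr(v, "se"))
  }

  sc <- t(vapply(seq_len(nrow(grid)), function(i) score_one(grid[i, ]),
                 numeric(2)))
  grid$score <- sc[, 1L]
  grid$se <- sc[, 2L]
  minimize <- objective == "mse"
  ibest <- if (minimize) which.min(grid$score) else which.max(grid$score)
  bestv <- grid$score[ibest]
  near <- if (minimize) grid$score <= bestv * 1.01
          else grid$score >= bestv * 0.99
  structure(list(grid = grid, best = grid[ibest, , drop = FALSE],
                 near_optimal = grid[near, , drop = FALSE],
                 objective = objective, shape = shape, method = method,
                 params = p),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Parametric sweep (%s, %d grid points)\n", x$objective,
              nrow(x$grid)))
  cat("  best: "); print(x$best, row.names = FALSE)
  cat(sprintf("  %d grid points within 1%% of the optimum\n",
              nrow(x$near_optimal)))
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, ...) {
  if (!all(c("nu", "phi") %in% names(x$grid))) {
    stop("plotting is implemented for single-pathway sweeps", call. = FALSE)
  }
  nu <- sort(unique(x$grid$nu)); phi <- sort(unique(x$grid$phi))
  z <- matrix(x$grid$score[order(x$grid$phi, x$grid$nu)],
              nrow = length(nu))
  graphics::image(log(nu), phi, z, xlab = "log slope nu", ylab = "offset phi",
                  main = sprintf("%s over (nu, phi)", x$objective), ...)
  graphics::points(log(x$best$nu), x$best$phi, pch = 4, lwd = 2)
  invisible(x)
}

#' Export a sweep result
#'
#' One CSV row per grid point plus a JSON summary (best point, objective,
#' near-optimal count).
#'
#' @param x A `sweep_result`.
#' @param path CSV path; the summary goes to `<path>.json`.
#' @export
write_sweep_result <- function(x, path) {
  utils::write.csv(x$grid, path, row.names = FALSE)
  summ <- list(objective = x$objective, method = x$method,
               best = as.list(x$best),
               n_near_optimal = nrow(x$near_optimal),
               params = unclass(x$params))
  writeLines(jsonlite::toJSON(summ, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' Percent excess MSE of a candidate nonlinearity
#'
#' `100 * (MSE_candidate - MSE_reference) / MSE_reference`, both evaluated
#' in closed form at their respective optimal linear decoding weights.
#'
#' @param p A `circuit_params` object.
#' @param f_candidate,f_reference Nonlinearities (or lists of two).
#' @param n_quad Quadrature order.
#' @return Percent excess MSE (>= 0 when the reference is optimal).
#' @export
suboptimality_gap <- function(p, f_candidate, f_reference, n_quad = 200L) {
  m_c <- mse(p, f_candidate, method = "closed_form", n_quad = n_quad)
  m_r <- mse(p, f_reference, method = "closed_form", n_quad = n_quad)
  100 * (m_c - m_r) / m_r
}
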